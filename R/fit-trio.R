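#' Fit a genotype-by-accessibility interaction model for one trio
#'
#' Fits the four-term ordinary least squares model
#' \deqn{y = \beta_0 + \beta_1 x_1 + \beta_2 x_2 + \beta_3 x_1 x_2 + \varepsilon}
#' where \code{y} is gene expression (log2 TPM), \code{x1} the dosage
#' genotype at a marker (0/1/2) and \code{x2} the accessibility of an open
#' chromatin peak (TMM scale). The non-additive interaction term
#' \eqn{\beta_3 x_1 x_2} is tested against the additive null
#' (\eqn{\beta_3 = 0}) with a partial F-test on 1 and \eqn{n - 4} degrees
#' of freedom.
#'
#' Degenerate inputs (constant genotype or constant peak intensity) raise a
#' condition of class \code{"gei_degenerate_input"}; scan drivers catch it
#' and count the trio as skipped. A design where the product column lies in
#' the span of the main effects yields a flagged fit with \code{f_stat = NA}.
#'
#' @param y numeric vector of expression values (log2 TPM).
#' @param g numeric vector of genotype dosages, same length as \code{y}.
#' @param a numeric vector of peak intensities, same length as \code{y}.
#' @param gene_id,variant_id,peak_id optional identifiers carried through
#'   to the result.
#' @return An object of class \code{"trio_fit"} with components
#'   \code{betas} (named length-4 coefficient vector), \code{se},
#'   \code{rss_full}, \code{rss_null}, \code{f_stat}, \code{p_raw},
#'   \code{p_adj} (\code{NA} until a family-wise adjustment is applied),
#'   \code{retained} (\code{NULL} until term selection), \code{model_class},
#'   \code{n}, \code{df_residual}, \code{sigma}, \code{fitted},
#'   \code{residuals} and \code{collinear}.
#' @seealso [stepwise_select()], [classify_model()], [run_scan()]
#' @examples
#' set.seed(1)
#' g <- rbinom(40, 2, 0.5)
#' a <- rlnorm(40, 1, 0.5)
#' y <- 2 + 1 * g + 0.5 * a + 0.25 * g * a + rnorm(40, 0, 0.3)
#' fit <- fit_trio(y, g, a)
#' coef(fit)
#' @export
fit_trio <- function(y, g, a, gene_id = NA_character_,
                     variant_id = NA_character_, peak_id = NA_character_) {
  y <- as.numeric(y); g <- as.numeric(g); a <- as.numeric(a)
  n <- length(y)
  if (length(g) != n || length(a) != n)
    stop("y, g and a must have equal length")
  if (n < 8L)
    stop("at least 8 samples are required to fit the four-term model")
  if (anyNA(y) || anyNA(g) || anyNA(a))
    stop("missing values are not supported")
  if (stats::var(g) == 0)
    stop_degenerate("genotype vector is constant (monomorphic marker)")
  if (stats::var(a) == 0)
    stop_degenerate("peak intensity vector is constant")

  core <- .fit_trio_core(y, g, a)

  fit <- structure(
    c(list(gene_id = gene_id, variant_id = variant_id, peak_id = peak_id),
      core,
      list(p_adj = NA_real_, retained = NULL, model_class = NA_character_)),
    class = "trio_fit")
  fit
}

# Core OLS + F computation shared by fit_trio() and the scan loop.
# Returns plain numbers; no validation.
.fit_trio_core <- function(y, g, a) {
  n <- length(y)
  X <- cbind(1, g, a, g * a)
  fv <- stats::lm.fit(X, y)
  collinear <- fv$rank < 4L

  res <- fv$residuals
  rss_full <- sum(res * res)
  resn <- stats::lm.fit(X[, 1:3, drop = FALSE], y)$residuals
  rss_null <- sum(resn * resn)

  betas <- c("(Intercept)" = NA_real_, x1 = NA_real_, x2 = NA_real_,
             x1x2 = NA_real_)
  se <- betas
  sigma <- NA_real_
  f_stat <- NA_real_
  p_raw <- NA_real_

  if (!collinear) {
    cf <- fv$coefficients
    betas[] <- cf
    df2 <- n - 4L
    sigma2 <- rss_full / df2
    sigma <- sqrt(sigma2)
    # SEs from the R factor of the QR decomposition
    R <- qr.R(fv$qr)
    xtx_inv <- chol2inv(R)
    se[fv$qr$pivot] <- sqrt(diag(xtx_inv) * sigma2)
    # F-test of the interaction term against the additive null
    tol <- 1e-12 * max(1, sum((y - mean(y))^2))
    num <- max(rss_null - rss_full, 0)
    if (rss_full <= tol) {
      if (num <= tol) { f_stat <- 0; p_raw <- 1 } else { f_stat <- Inf; p_raw <- 0 }
    } else {
      f_stat <- num / (rss_full / df2)
      p_raw <- stats::pf(f_stat, 1, df2, lower.tail = FALSE)
    }
  }

  list(betas = betas, se = se, rss_full = rss_full, rss_null = rss_null,
       f_stat = f_stat, p_raw = p_raw, n = n, df_residual = n - 4L,
       sigma = sigma, fitted = y - res, residuals = res,
       collinear = collinear)
}

stop_degenerate <- function(msg) {
  stop(errorCondition(msg, class = c("gei_degenerate_input", "error")))
}

#' Backward AIC term selection for one trio
#'
#' Starting from the full four-term model, repeatedly drops the term whose
#' removal most decreases \eqn{AIC = n \ln(RSS/n) + 2k} (with \eqn{k} the
#' number of estimated coefficients, intercept included), honouring
#' marginality: the interaction must be dropped before either main effect.
#' Stops when no admissible drop decreases the AIC.
#'
#' Ties (AIC difference below 1e-12) are broken by dropping the interaction
#' first, otherwise \code{x2}, so selection is deterministic.
#'
#' @inheritParams fit_trio
#' @return Character vector: the retained subset of
#'   \code{c("x1", "x2", "x1x2")}.
#' @export
stepwise_select <- function(y, g, a) {
  y <- as.numeric(y); g <- as.numeric(g); a <- as.numeric(a)
  n <- length(y)
  if (length(g) != n || length(a) != n)
    stop("y, g and a must have equal length")
  if (n < 8L) stop("at least 8 samples are required")
  if (stats::var(g) == 0)
    stop_degenerate("genotype vector is constant (monomorphic marker)")
  if (stats::var(a) == 0)
    stop_degenerate("peak intensity vector is constant")
  .stepwise_core(y, g, a)$retained
}

# AIC used throughout the backward search. RSS is floored at a small
# multiple of the response scale so that (numerically) perfect fits rank
# by the 2k penalty instead of round-off noise.
.aic_rss <- function(rss, n, k, floor = 1e-30)
  n * log(max(rss, floor) / n) + 2 * k

.model_rss <- function(y, g, a, terms) {
  X <- switch(paste(sort(terms), collapse = ","),
    "x1,x1x2,x2" = cbind(1, g, a, g * a),
    "x1,x2"      = cbind(1, g, a),
    "x1"         = cbind(1, g),
    "x2"         = cbind(1, a),
    cbind(rep(1, length(y))))
  r <- stats::lm.fit(X, y)$residuals
  sum(r * r)
}

.stepwise_core <- function(y, g, a, rss_full = NULL, rss_add = NULL) {
  n <- length(y)
  cache <- list("x1,x1x2,x2" = rss_full, "x1,x2" = rss_add)
  rss_of <- function(terms) {
    key <- paste(sort(terms), collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) hit else .model_rss(y, g, a, terms)
  }
  floor <- 1e-12 * max(1, sum(y * y))
  cur <- c("x1", "x2", "x1x2")
  cur_rss <- rss_of(cur)
  cur_aic <- .aic_rss(cur_rss, n, length(cur) + 1L, floor)
  path <- list()
  repeat {
    droppable <- if ("x1x2" %in% cur) "x1x2" else cur
    if (length(droppable) == 0L) break
    cand_aic <- vapply(droppable, function(tm) {
      .aic_rss(rss_of(setdiff(cur, tm)), n, length(cur), floor)
    }, numeric(1))
    # deterministic tie-break: interaction first, else x2
    ord <- order(cand_aic,
                 match(droppable, c("x1x2", "x2", "x1")))
    best <- ord[1]
    if (length(droppable) > 1L &&
        abs(cand_aic[ord[1]] - cand_aic[ord[2]]) < 1e-12) {
      pref <- intersect(c("x1x2", "x2", "x1"), droppable[ord[1:2]])[1]
      best <- which(droppable == pref)
    }
    if (cand_aic[best] < cur_aic) {
      cur <- setdiff(cur, droppable[best])
      cur_aic <- cand_aic[best]
      if (length(cur) == 0L) break
    } else break
  }
  list(retained = cur, aic = cur_aic)
}

#' Map a retained term set to a model class
#'
#' @param retained character vector, a marginality-respecting subset of
#'   \code{c("x1", "x2", "x1x2")}.
#' @return One of \code{"interacting"}, \code{"additive"},
#'   \code{"genotype_only"}, \code{"atac_only"}, \code{"null"}.
#' @export
classify_model <- function(retained) {
  retained <- as.character(retained)
  bad <- setdiff(retained, c("x1", "x2", "x1x2"))
  if (length(bad))
    stop("unknown terms: ", paste(bad, collapse = ", "))
  if ("x1x2" %in% retained && !all(c("x1", "x2") %in% retained))
    stop("non-hierarchical term set: interaction retained without both main effects")
  key <- paste(sort(unique(retained)), collapse = ",")
  if (key == "") return("null")
  switch(key,
    "x1,x1x2,x2" = "interacting",
    "x1,x2"      = "additive",
    "x1"         = "genotype_only",
    "x2"         = "atac_only",
    stop("invalid term set: ", key))
}

#' Bonferroni adjustment for a scan batch
#'
#' Multiplies each raw p-value by the family size \code{m} and caps at 1.
#' The family is the number of models attempted in the batch (successful
#' fits; degenerate skips are excluded and logged by the scan driver).
#'
#' @param p numeric vector of raw p-values in [0, 1].
#' @param m family size, at least \code{length(p)}.
#' @return Adjusted p-values, same length as \code{p}.
#' @export
bonferroni_adjust <- function(p, m) {
  p <- as.numeric(p)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  if (m < length(p))
    stop("family size m must be at least length(p)")
  stats::p.adjust(p, method = "bonferroni", n = m)
}

#' @export
print.trio_fit <- function(x, digits = 4, ...) {
  cat("Genotype-by-accessibility trio fit\n")
  ids <- c(x$gene_id, x$variant_id, x$peak_id)
  if (!all(is.na(ids)))
    cat("  trio: ", paste(ids, collapse = " / "), "\n", sep = "")
  cat("  n = ", x$n, ", coefficients:\n", sep = "")
  print(round(x$betas, digits))
  if (!is.null(x$retained))
    cat("  retained terms: ",
        if (length(x$retained)) paste(x$retained, collapse = ", ") else "(none)",
        "  [", x$model_class, "]\n", sep = "")
  cat("  interaction F = ", format(x$f_stat, digits = digits),
      ", p = ", format(x$p_raw, digits = digits), sep = "")
  if (!is.na(x$p_adj))
    cat(", adjusted p = ", format(x$p_adj, digits = digits), sep = "")
  cat("\n")
  invisible(x)
}

#' @export
coef.trio_fit <- function(object, ...) object$betas

#' @export
residuals.trio_fit <- function(object, ...) object$residuals

#' @export
fitted.trio_fit <- function(object, ...) object$fitted

#' @export
summary.trio_fit <- function(object, ...) {
  est <- object$betas
  se <- object$se
  tval <- est / se
  pval <- 2 * stats::pt(abs(tval), object$df_residual, lower.tail = FALSE)
  tab <- cbind(Estimate = est, `Std. Error` = se, `t value` = tval,
               `Pr(>|t|)` = pval)
  out <- list(coefficients = tab, sigma = object$sigma,
              f_stat = object$f_stat, p_raw = object$p_raw,
              p_adj = object$p_adj, n = object$n,
              df_residual = object$df_residual,
              model_class = object$model_class, retained = object$retained)
  class(out) <- "summary.trio_fit"
  out
}

#' @export
print.summary.trio_fit <- function(x, digits = 4, ...) {
  cat("Trio fit summary (n = ", x$n, ")\n\n", sep = "")
  stats::printCoefmat(x$coefficients, digits = digits, P.values = TRUE,
                      has.Pvalue = TRUE)
  cat("\nResidual SD: ", format(x$sigma, digits = digits),
      " on ", x$df_residual, " df\n", sep = "")
  cat("Interaction F(1, ", x$df_residual, ") = ",
      format(x$f_stat, digits = digits), ", p = ",
      format(x$p_raw, digits = digits), "\n", sep = "")
  if (!is.null(x$retained))
    cat("Retained: ", paste(x$retained, collapse = ", "),
        " [", x$model_class, "]\n", sep = "")
  invisible(x)
}

#' @export
predict.trio_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  if (!all(c("g", "a") %in% names(newdata)))
    stop("newdata must have columns 'g' and 'a'")
  b <- object$betas
  b["(Intercept)"] + b["x1"] * newdata$g + b["x2"] * newdata$a +
    b["x1x2"] * newdata$g * newdata$a
}

#' @export
simulate.trio_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$fitted
  out <- as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu), 0, object$sigma)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.trio_fit <- function(x, ...) {
  graphics::plot(x$fitted, x$fitted + x$residuals,
                 xlab = "Fitted (log2 TPM)", ylab = "Observed (log2 TPM)",
                 main = "Trio fit: observed vs fitted", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
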