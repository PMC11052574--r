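#' Classify the coefficient sign pattern of an interacting model
#'
#' When genotype, accessibility and interaction effects all share a sign
#' the combination is synergistic; an interaction sign opposite to two
#' agreeing main effects indicates redundancy or interference; disagreeing
#' main effects give a mixed pattern. Models missing a required term from
#' their retained set are incomplete. A retained coefficient within
#' \code{tol} of zero takes sign zero and forces the mixed label, flagged.
#'
#' @param betas numeric: either named (\code{x1}, \code{x2}, \code{x1x2}),
#'   a length-3 vector (b1, b2, b3), or a length-4 vector (b0..b3).
#' @param retained character subset of \code{c("x1","x2","x1x2")}.
#' @param tol zero tolerance for coefficient signs (default 1e-12).
#' @return list of class \code{"effect_class"}: \code{label} (one of
#'   \code{synergy}, \code{redundancy_interference}, \code{mixed},
#'   \code{incomplete}), \code{sign_pattern}, \code{magnitude_flags}
#'   (\code{|b3|>|b2|}, \code{|b3|>|b1|}, \code{|b3|>both}),
#'   \code{zero_flag}.
#' @export
classify_signs <- function(betas, retained = c("x1", "x2", "x1x2"),
                           tol = 1e-12) {
  b <- .extract_b123(betas)
  if (any(!is.finite(b))) stop("betas must be finite")
  sgn <- ifelse(abs(b) < tol, 0, sign(b))
  names(sgn) <- c("x1", "x2", "x1x2")
  mag <- c(int_gt_atac = abs(b[3]) > abs(b[2]),
           int_gt_geno = abs(b[3]) > abs(b[1]),
           int_gt_both = abs(b[3]) > abs(b[2]) && abs(b[3]) > abs(b[1]))
  zero_flag <- any(sgn == 0)
  label <- if (!all(c("x1", "x2", "x1x2") %in% retained)) {
    "incomplete"
  } else if (zero_flag) {
    "mixed"
  } else if (sgn[1] == sgn[2] && sgn[2] == sgn[3]) {
    "synergy"
  } else if (sgn[1] == sgn[2] && sgn[3] == -sgn[1]) {
    "redundancy_interference"
  } else {
    "mixed"
  }
  structure(list(label = label, sign_pattern = sgn, magnitude_flags = mag,
                 zero_flag = zero_flag),
            class = "effect_class")
}

#' @export
print.effect_class <- function(x, ...) {
  cat("Effect class: ", x$label, "  (signs ",
      paste(x$sign_pattern, collapse = "/"), ")\n", sep = "")
  invisible(x)
}

.extract_b123 <- function(betas) {
  if (!is.null(names(betas)) && all(c("x1", "x2", "x1x2") %in% names(betas)))
    return(unname(betas[c("x1", "x2", "x1x2")]))
  if (length(betas) == 4) return(unname(betas[2:4]))
  if (length(betas) == 3) return(unname(betas))
  stop("betas must supply the x1, x2 and x1x2 coefficients")
}

#' Relative magnitude of interaction vs main effects
#'
#' Over significant interacting models (by default) reports the
#' proportions with \code{|b3| > |b2|}, \code{|b3| > |b1|} and
#' \code{|b3|} greater than both, plus the fraction with a negative
#' accessibility main effect (\code{b2 < 0}).
#'
#' @param models scan model table (or \code{gei_scan}) with columns
#'   \code{beta1..beta3}, \code{model_class}, \code{significant}.
#' @param significant_only restrict to significant models (default TRUE).
#' @param interacting_only restrict to interacting models (default TRUE);
#'   set FALSE to widen to all (significant) models.
#' @return list: \code{n}, \code{prop_int_gt_atac}, \code{prop_int_gt_geno},
#'   \code{prop_int_gt_both}, \code{prop_negative_atac}, \code{counts}.
#' @export
magnitude_summary <- function(models, significant_only = TRUE,
                              interacting_only = TRUE) {
  mo <- .as_model_table(models)
  if (significant_only) mo <- mo[mo$significant, , drop = FALSE]
  if (interacting_only)
    mo <- mo[!is.na(mo$model_class) & mo$model_class == "interacting", ,
             drop = FALSE]
  if (nrow(mo) == 0)
    stop(errorCondition("no qualifying models",
                        class = c("gei_empty_input", "error")))
  gt_atac <- abs(mo$beta3) > abs(mo$beta2)
  gt_geno <- abs(mo$beta3) > abs(mo$beta1)
  list(n = nrow(mo),
       prop_int_gt_atac = mean(gt_atac),
       prop_int_gt_geno = mean(gt_geno),
       prop_int_gt_both = mean(gt_atac & gt_geno),
       prop_negative_atac = mean(mo$beta2 < 0),
       counts = c(int_gt_atac = sum(gt_atac), int_gt_geno = sum(gt_geno),
                  int_gt_both = sum(gt_atac & gt_geno),
                  negative_atac = sum(mo$beta2 < 0)))
}

#' Distribution of sign-pattern classes across models
#'
#' Applies [classify_signs()] to each (by default significant interacting)
#' model and tabulates labels. Fractions partition the classified models.
#'
#' @inheritParams magnitude_summary
#' @return data frame \code{label}, \code{count}, \code{fraction} (absent
#'   when the table is empty).
#' @export
sign_class_distribution <- function(models, significant_only = TRUE,
                                    interacting_only = TRUE) {
  mo <- .as_model_table(models)
  if (significant_only) mo <- mo[mo$significant, , drop = FALSE]
  if (interacting_only)
    mo <- mo[!is.na(mo$model_class) & mo$model_class == "interacting", ,
             drop = FALSE]
  labs <- c("synergy", "redundancy_interference", "mixed", "incomplete")
  if (nrow(mo) == 0)
    return(data.frame(label = labs, count = 0L, stringsAsFactors = FALSE))
  got <- vapply(seq_len(nrow(mo)), function(i) {
    ret <- strsplit(mo$retained[i], ",", fixed = TRUE)[[1]]
    classify_signs(c(x1 = mo$beta1[i], x2 = mo$beta2[i], x1x2 = mo$beta3[i]),
                   retained = ret)$label
  }, character(1))
  cnt <- table(factor(got, levels = labs))
  data.frame(label = labs, count = as.integer(cnt),
             fraction = as.numeric(cnt) / nrow(mo),
             stringsAsFactors = FALSE)
}
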