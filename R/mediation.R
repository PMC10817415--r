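#' Proportion of the total effect that is mediated
#'
#' 100 * mediation / total. Following the convention of published mediation
#' tables the mediation effect is rounded to 5 decimals before division and
#' the percentage displayed to 1 decimal; the unrounded value is also
#' returned. When mediation and total effects disagree in sign the
#' decomposition is "inconsistent mediation" and no percentage is reported.
#'
#' @param mediation indirect (mediated) effect on the log/linear scale.
#' @param total total exposure-outcome effect on the same scale.
#' @return list with `proportion` (percent, from the 5-dp-rounded
#'   mediation effect; NA when undefined), `proportion_unrounded`,
#'   `consistent` (sign agreement flag).
#' @export
proportion_mediated <- function(mediation, total) {
  if (!is_scalar_number(total) || total == 0)
    return(list(proportion = NA_real_, proportion_unrounded = NA_real_,
                consistent = NA))
  consistent <- mediation == 0 || sign(mediation) == sign(total)
  if (!consistent)
    return(list(proportion = NA_real_,
                proportion_unrounded = 100 * mediation / total,
                consistent = FALSE))
  list(proportion = 100 * round(mediation, 5) / total,
       proportion_unrounded = 100 * mediation / total,
       consistent = TRUE)
}

#' Two-step mediation decomposition (product of coefficients)
#'
#' Combines three pairwise MR estimates — the total exposure-outcome effect,
#' the exposure-mediator effect (beta1), and the mediator-outcome effect
#' (beta2) — into the mediated (indirect) effect beta1 * beta2, with the
#' Sobel delta-method SE sqrt(beta1^2 se2^2 + beta2^2 se1^2), normal 95% CI
#' and two-sided p. The direct effect is total - mediated, so
#' direct + mediated = total holds exactly before any display rounding.
#'
#' @param total,step1,step2 `mr_estimate` objects (or lists with `beta` and
#'   `se`) on the log/linear effect scale: exposure->outcome,
#'   exposure->mediator, mediator->outcome.
#' @return An `mr_mediation` list: `total_effect`, `beta1`, `beta2`,
#'   `mediation_effect` (unrounded), `mediation_rounded` (5 dp),
#'   `se_mediation`, `ci_low`, `ci_high`, `pvalue`, `direct_effect`,
#'   `proportion_mediated` (percent), `proportion_unrounded`,
#'   `consistent`.
#' @export
two_step_mediation <- function(total, step1, step2) {
  b_tot <- total$beta; b1 <- step1$beta; b2 <- step2$beta
  stopifnot(is_scalar_number(b_tot), is_scalar_number(b1), is_scalar_number(b2))
  med <- b1 * b2
  se1 <- step1$se; se2 <- step2$se
  if (is_scalar_number(se1) && is_scalar_number(se2)) {
    se_med <- sqrt(b1^2 * se2^2 + b2^2 * se1^2)
    ci_low <- med - Z975 * se_med
    ci_high <- med + Z975 * se_med
    pvalue <- if (se_med > 0) 2 * stats::pnorm(-abs(med / se_med)) else as.numeric(med == 0)
  } else {
    warnf("missing SE(s) for the mediation delta method; CI and p omitted")
    se_med <- ci_low <- ci_high <- pvalue <- NA_real_
  }
  prop <- proportion_mediated(med, b_tot)
  structure(list(total_effect = b_tot, beta1 = b1, beta2 = b2,
                 mediation_effect = med, mediation_rounded = round(med, 5),
                 se_mediation = se_med, ci_low = ci_low, ci_high = ci_high,
                 pvalue = pvalue,
                 direct_effect = b_tot - med,
                 proportion_mediated = prop$proportion,
                 proportion_unrounded = prop$proportion_unrounded,
                 consistent = prop$consistent),
            class = "mr_mediation")
}

#' @export
print.mr_mediation <- function(x, ...) {
  cat(sprintf("Total effect:     %.5f\n", x$total_effect))
  cat(sprintf("beta1 (X->M):     %.5f\n", x$beta1))
  cat(sprintf("beta2 (M->Y):     %.5f\n", x$beta2))
  cat(sprintf("Mediation effect: %.5f (95%% CI %.5f to %.5f; p = %.4g)\n",
              x$mediation_rounded, x$ci_low, x$ci_high, x$pvalue))
  cat(sprintf("Direct effect:    %.5f\n", x$direct_effect))
  if (isTRUE(x$consistent))
    cat(sprintf("Mediated proportion: %.1f%%\n", x$proportion_mediated))
  else if (isFALSE(x$consistent))
    cat("Inconsistent mediation (opposite signs); no proportion reported\n")
  else
    cat("Mediated proportion undefined (total effect is zero)\n")
  invisible(x)
}

#' One-row mediation table
#'
#' Serializes an `mr_mediation` result in the layout of a published
#' mediation table: total effect, beta1, beta2, mediation effect (each with
#' 95% CI where available), the delta-method p and the mediated proportion,
#' plus unrounded values.
#'
#' @param med an `mr_mediation` result.
#' @param total,step1,step2 optional `mr_estimate` objects supplying the CI
#'   columns for the three input effects.
#' @return one-row data.frame.
#' @export
mediation_table <- function(med, total = NULL, step1 = NULL, step2 = NULL) {
  ci <- function(e, which) if (is.null(e)) NA_real_ else e[[which]]
  data.frame(
    total_effect = med$total_effect,
    total_ci_low = ci(total, "ci_low"), total_ci_high = ci(total, "ci_high"),
    beta1 = med$beta1,
    beta1_ci_low = ci(step1, "ci_low"), beta1_ci_high = ci(step1, "ci_high"),
    beta2 = med$beta2,
    beta2_ci_low = ci(step2, "ci_low"), beta2_ci_high = ci(step2, "ci_high"),
    mediation_effect = med$mediation_rounded,
    mediation_ci_low = med$ci_low, mediation_ci_high = med$ci_high,
    pvalue = med$pvalue,
    direct_effect = med$direct_effect,
    proportion_mediated_pct = med$proportion_mediated,
    proportion_unrounded_pct = med$proportion_unrounded,
    mediation_effect_unrounded = med$mediation_effect,
    stringsAsFactors = FALSE)
}
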