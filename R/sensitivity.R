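#' Cochran's Q heterogeneity statistic
#'
#' Q = sum w_j (ratio_j - center)^2 over the Wald ratios, referred to a
#' chi-square upper tail. Around the IVW center the degrees of freedom are
#' k - 1; around the Egger fit (residual heterogeneity) they are k - 2.
#'
#' @param h an `mr_harmonized` set (k >= 2).
#' @param center value the deviations are taken about; defaults to the IVW
#'   point estimate.
#' @param context `"ivw"` (df = k - 1) or `"egger"` (df = k - 2; deviations
#'   about the Egger fitted line).
#' @return list with `context`, `Q`, `df`, `pvalue`.
#' @export
cochran_q <- function(h, center = NULL, context = c("ivw", "egger")) {
  context <- match.arg(context)
  k <- nrow(h)
  if (k < 2L) stopf("Cochran's Q requires >=2 instruments")
  if (context == "egger") {
    if (k < 3L) stopf("Egger heterogeneity requires >=3 instruments")
    fit <- egger_fit(h)
    return(list(context = "egger", Q = fit$Q, df = k - 2L,
                pvalue = fit$Q_pvalue))
  }
  w <- wald_ratios(h)
  if (is.null(center)) center <- sum(w$weight * w$ratio) / sum(w$weight)
  Q <- sum(w$weight * (w$ratio - center)^2)
  list(context = "ivw", Q = Q, df = k - 1L,
       pvalue = stats::pchisq(Q, k - 1L, lower.tail = FALSE))
}

#' Heterogeneity table (IVW and Egger contexts)
#'
#' @param h an `mr_harmonized` set.
#' @param alpha significance level for the heterogeneity flag.
#' @return data.frame with one row per context: `context`, `Q`, `df`,
#'   `pvalue`, `heterogeneity` (logical flag at `alpha`).
#' @export
heterogeneity <- function(h, alpha = 0.05) {
  rows <- list(cochran_q(h, context = "ivw"))
  if (nrow(h) >= 3L) rows <- c(rows, list(cochran_q(h, context = "egger")))
  out <- do.call(rbind, lapply(rows, function(r)
    data.frame(context = r$context, Q = r$Q, df = r$df, pvalue = r$pvalue,
               heterogeneity = r$pvalue < alpha, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' MR-Egger intercept test for directional horizontal pleiotropy
#'
#' A non-zero Egger intercept indicates that instruments exert, on average,
#' a direct effect on the outcome not channelled through the exposure.
#'
#' @param h an `mr_harmonized` set (k >= 3).
#' @param alpha significance level below which pleiotropy is flagged.
#' @return list with `intercept`, `se`, `pvalue`, `df`, and `pleiotropy`
#'   (logical flag).
#' @export
egger_intercept_test <- function(h, alpha = 0.05) {
  if (nrow(h) < 3L) stopf("Egger intercept test requires >=3 instruments")
  fit <- egger_fit(h)
  list(intercept = fit$intercept, se = fit$intercept_se,
       pvalue = fit$intercept_pvalue, df = nrow(h) - 2L,
       pleiotropy = fit$intercept_pvalue < alpha)
}

#' Leave-one-out sensitivity analysis
#'
#' Refits the IVW estimator k times, each time excluding one instrument,
#' and appends the full-set fit. An exclusion is flagged influential when
#' the remaining-SNP estimate changes sign relative to the full-set
#' estimate, escapes the full-set confidence interval, or leaves the
#' full-set estimate outside its own confidence interval (the latter
#' catches outliers whose presence inflates the random-effects CI).
#'
#' @param h an `mr_harmonized` set (k >= 2).
#' @return data.frame with columns `excluded` ("All" for the full fit),
#'   `n_snps`, `beta`, `se`, `ci_low`, `ci_high`, `pvalue`, `flagged`.
#' @export
leave_one_out <- function(h) {
  k <- nrow(h)
  if (k < 2L) stopf("leave-one-out requires >=2 instruments")
  full <- mr_ivw(h)
  row_of <- function(label, est, flagged)
    data.frame(excluded = label, n_snps = est$n_snps, beta = est$beta,
               se = est$se, ci_low = est$ci_low, ci_high = est$ci_high,
               pvalue = est$pvalue, flagged = flagged,
               stringsAsFactors = FALSE)
  rows <- lapply(seq_len(k), function(i) {
    est <- mr_ivw(h[-i, , drop = FALSE])
    flagged <- sign(est$beta) != sign(full$beta) ||
      est$beta < full$ci_low || est$beta > full$ci_high ||
      full$beta < est$ci_low || full$beta > est$ci_high
    row_of(h$snp[i], est, flagged)
  })
  out <- rbind(do.call(rbind, rows), row_of("All", full, FALSE))
  rownames(out) <- NULL
  out
}

#' Reverse-direction MR analysis
#'
#' Re-runs instrument selection with the former outcome as exposure and
#' applies the estimator battery with the roles swapped. Degrades to a
#' structured not-estimable result (rather than an error) when the reverse
#' exposure has no significant independent instruments, and flags "no
#' causal effect" when the reverse IVW p-value is at or above `alpha`.
#'
#' @param exposure,outcome `mr_summary` datasets in the *reverse* roles
#'   (i.e. pass the original outcome as `exposure`).
#' @param ld LD source for clumping.
#' @param config an [instrument_config()].
#' @param alpha significance level for the causal-effect flag.
#' @param n_boot,seed,bandwidth_factor,penalty_k estimator settings, see
#'   [mr_all()].
#' @return list with `estimable`; when estimable also `estimates` (the
#'   [mr_all()] table), `ivw` (the IVW `mr_estimate`), `n_snps`,
#'   `no_causal_effect`; otherwise `reason`.
#' @export
reverse_direction <- function(exposure, outcome, ld = NULL,
                              config = instrument_config(), alpha = 0.05,
                              n_boot = 1000, seed = NULL,
                              bandwidth_factor = 1, penalty_k = 20) {
  sel <- select_instruments(exposure, ld, config)
  if (length(sel$snps) == 0L)
    return(list(estimable = FALSE,
                reason = "no significant independent instruments for the reverse exposure"))
  h <- tryCatch(harmonize(exposure, outcome, sel$snps),
                error = function(e) NULL)
  if (is.null(h))
    return(list(estimable = FALSE,
                reason = "no instruments survived harmonization in the reverse direction"))
  ivw <- mr_ivw(h)
  list(estimable = TRUE,
       estimates = mr_all(h, n_boot = n_boot, seed = seed,
                          bandwidth_factor = bandwidth_factor,
                          penalty_k = penalty_k),
       ivw = ivw, n_snps = nrow(h),
       no_causal_effect = ivw$pvalue >= alpha)
}
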