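#' Per-SNP Wald ratios
#'
#' The per-variant causal estimate: outcome effect divided by exposure
#' effect, with first-order standard error se_out/|beta_exp| (exposure-side
#' variance ignored, the convention shared by IVW and the median/mode
#' estimators) and inverse-variance weight.
#'
#' @param h an `mr_harmonized` set.
#' @return data.frame with columns `snp`, `ratio`, `se`, `weight`.
#' @export
wald_ratios <- function(h) {
  if (nrow(h) == 0L) stopf("empty instrument set")
  zero <- h$beta_exp == 0
  if (any(zero)) stopf("zero exposure effect for SNP(s): %s",
                       paste(h$snp[zero], collapse = ", "))
  se <- h$se_out / abs(h$beta_exp)
  data.frame(snp = h$snp, ratio = h$beta_out / h$beta_exp,
             se = se, weight = 1 / se^2, stringsAsFactors = FALSE)
}

mr_estimate <- function(method, beta, se, n_snps, pvalue = NULL, df = NULL,
                        extras = list()) {
  if (is.null(pvalue)) {
    z <- beta / se
    pvalue <- if (is.null(df)) 2 * stats::pnorm(-abs(z))
              else 2 * stats::pt(-abs(z), df = df)
  }
  crit <- if (is.null(df)) Z975 else stats::qt(0.975, df = df)
  ci_low <- beta - crit * se
  ci_high <- beta + crit * se
  structure(list(method = method, beta = beta, se = se,
                 ci_low = ci_low, ci_high = ci_high, pvalue = pvalue,
                 or_ = beta_to_or(beta), or_low = beta_to_or(ci_low),
                 or_high = beta_to_or(ci_high),
                 n_snps = n_snps, extras = extras),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s (%d SNPs): beta = %.5f (SE %.5f), 95%% CI [%.5f, %.5f], p = %.4g\n",
              x$method, x$n_snps, x$beta, x$se, x$ci_low, x$ci_high, x$pvalue))
  cat(sprintf("  OR = %.5f [%.5f, %.5f]\n", x$or_, x$or_low, x$or_high))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, n_snps = x$n_snps, beta = x$beta, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, pvalue = x$pvalue,
             or = x$or_, or_low = x$or_low, or_high = x$or_high,
             stringsAsFactors = FALSE)
}

#' Convert a log-scale effect to an odds ratio
#'
#' Exponentiates and rounds to 5 decimals, the precision causal-effect
#' tables are conventionally printed at.
#'
#' @param beta log-scale effect (vectorized).
#' @return `exp(beta)` rounded to 5 decimal places.
#' @export
beta_to_or <- function(beta) round(exp(beta), 5)

# parametric bootstrap SE for point estimators of a harmonized set:
# redraw (beta_exp, beta_out) from their sampling normals, recompute.
bootstrap_se <- function(h, point_fun, n_boot, seed) {
  k <- nrow(h)
  with_seed(seed, {
    ests <- vapply(seq_len(n_boot), function(b) {
      hb <- h
      hb$beta_exp <- stats::rnorm(k, h$beta_exp, h$se_exp)
      hb$beta_out <- stats::rnorm(k, h$beta_out, h$se_out)
      point_fun(hb)
    }, numeric(1))
    stats::sd(ests)
  })
}

#' Inverse-variance-weighted estimator (multiplicative random effects)
#'
#' The primary estimator: inverse-variance-weighted mean of the Wald
#' ratios. The fixed-effect SE (sum of weights)^-1/2 is inflated by
#' sqrt(Q/(k-1)) when Cochran's Q exceeds its degrees of freedom, and never
#' deflated, so the random-effects SE is always >= the fixed-effect SE.
#' With a single instrument the estimate degenerates to the Wald ratio.
#'
#' @param h an `mr_harmonized` set.
#' @param random_effects inflate the SE under heterogeneity (default TRUE).
#' @return An `mr_estimate`; `extras` carries `Q`, `Q_df`, `Q_pvalue`,
#'   `se_fixed`.
#' @export
mr_ivw <- function(h, random_effects = TRUE) {
  w <- wald_ratios(h)
  k <- nrow(w)
  if (k == 1L)
    return(mr_estimate("Wald ratio", w$ratio, w$se, 1L))
  beta <- sum(w$weight * w$ratio) / sum(w$weight)
  se_fixed <- 1 / sqrt(sum(w$weight))
  Q <- sum(w$weight * (w$ratio - beta)^2)
  infl <- if (random_effects) max(1, sqrt(Q / (k - 1))) else 1
  se <- se_fixed * infl
  mr_estimate(if (random_effects) "Inverse variance weighted" else "IVW (fixed effects)",
              beta, se, k,
              extras = list(Q = Q, Q_df = k - 1,
                            Q_pvalue = stats::pchisq(Q, k - 1, lower.tail = FALSE),
                            se_fixed = se_fixed))
}

ivw_point <- function(h) {
  w <- wald_ratios(h)
  sum(w$weight * w$ratio) / sum(w$weight)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome effects on exposure effects with a free
#' intercept, instruments oriented so every exposure effect is positive.
#' The slope is the causal estimate; a non-zero intercept indicates
#' directional horizontal pleiotropy. SEs use a multiplicative
#' overdispersion factor floored at 1 and a t reference with k-2 df.
#'
#' @param h an `mr_harmonized` set with at least 3 instruments.
#' @return An `mr_estimate` for the slope; `extras` carries the intercept
#'   (`intercept`, `intercept_se`, `intercept_pvalue`) and the Egger
#'   heterogeneity statistic (`Q`, `Q_df`, `Q_pvalue`).
#' @export
mr_egger <- function(h) {
  k <- nrow(h)
  if (k < 3L) stopf("Egger requires >=3 instruments (got %d)", k)
  fit <- egger_fit(h)
  mr_estimate("MR Egger", fit$slope, fit$slope_se, k, df = k - 2,
              extras = list(intercept = fit$intercept,
                            intercept_se = fit$intercept_se,
                            intercept_pvalue = fit$intercept_pvalue,
                            Q = fit$Q, Q_df = k - 2, Q_pvalue = fit$Q_pvalue))
}

egger_fit <- function(h) {
  k <- nrow(h)
  flip <- sign(h$beta_exp)
  flip[flip == 0] <- 1
  bx <- h$beta_exp * flip
  by <- h$beta_out * flip
  w <- 1 / h$se_out^2
  if (stats::var(bx) == 0) stopf("Egger design is singular: all exposure effects identical")
  X <- cbind(1, bx)
  XtWX <- crossprod(X, w * X)
  coef <- solve(XtWX, crossprod(X, w * by))
  resid <- by - X %*% coef
  Q <- sum(w * resid^2)
  sigma2 <- max(1, Q / (k - 2))
  vcov <- solve(XtWX) * sigma2
  se <- sqrt(diag(vcov))
  tI <- coef[1] / se[1]
  list(intercept = coef[1], intercept_se = se[1],
       intercept_pvalue = 2 * stats::pt(-abs(tI), df = k - 2),
       slope = coef[2], slope_se = se[2],
       Q = Q, Q_pvalue = stats::pchisq(Q, k - 2, lower.tail = FALSE))
}

egger_point <- function(h) egger_fit(h)$slope

#' Simple-median estimator
#'
#' Unweighted median of the Wald ratios; SE by parametric bootstrap
#' (effects redrawn from their sampling distributions).
#'
#' @param h an `mr_harmonized` set with at least 3 instruments.
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed for the bootstrap (NULL: use current stream).
#' @return An `mr_estimate`.
#' @export
mr_simple_median <- function(h, n_boot = 1000, seed = NULL) {
  if (nrow(h) < 3L) stopf("simple median requires >=3 instruments")
  point <- function(hh) stats::median(wald_ratios(hh)$ratio)
  beta <- point(h)
  se <- bootstrap_se(h, point, n_boot, seed)
  mr_estimate("Simple median", beta, se, nrow(h))
}

# interpolated weighted median of x with positive weights w
weighted_median_point <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  S <- cumsum(w)
  p <- (S - w / 2) / sum(w)
  if (0.5 <= p[1]) return(x[1])
  if (0.5 >= p[length(p)]) return(x[length(x)])
  stats::approx(p, x, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median estimator
#'
#' Inverse-variance-weighted median of the Wald ratios: ratios are ordered,
#' standardized cumulative weights (S_j - w_j/2)/S_tot computed, and the
#' ratio interpolated at cumulative weight 0.5. Consistent when instruments
#' carrying at least half the weight are valid. SE by parametric bootstrap.
#'
#' @inheritParams mr_simple_median
#' @return An `mr_estimate`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = NULL) {
  if (nrow(h) < 3L) stopf("weighted median requires >=3 instruments")
  point <- function(hh) {
    w <- wald_ratios(hh)
    weighted_median_point(w$ratio, w$weight)
  }
  beta <- point(h)
  se <- bootstrap_se(h, point, n_boot, seed)
  mr_estimate("Weighted median", beta, se, nrow(h))
}

penalized_weights <- function(ratio, weight, penalty_k) {
  bwm <- weighted_median_point(ratio, weight)
  Qj <- weight * (ratio - bwm)^2
  qj <- stats::pchisq(Qj, df = 1, lower.tail = FALSE)
  weight * pmin(1, penalty_k * qj)
}

#' Penalized-weighted-median estimator
#'
#' Downweights heterogeneous instruments: each SNP's contribution to
#' Cochran's Q about the weighted-median estimate is referred to a
#' chi-square(1) upper tail, and its weight multiplied by
#' min(1, penalty_k * q_j) before re-running the weighted median.
#'
#' @inheritParams mr_simple_median
#' @param penalty_k penalization constant (default 20).
#' @return An `mr_estimate`.
#' @export
mr_penalized_weighted_median <- function(h, penalty_k = 20, n_boot = 1000,
                                         seed = NULL) {
  if (nrow(h) < 3L) stopf("penalized weighted median requires >=3 instruments")
  point <- function(hh) {
    w <- wald_ratios(hh)
    pw <- penalized_weights(w$ratio, w$weight, penalty_k)
    if (all(pw == 0)) stopf("all penalized weights are zero (penalty_k = %g)", penalty_k)
    weighted_median_point(w$ratio, pw)
  }
  beta <- point(h)
  se <- bootstrap_se(h, point, n_boot, seed)
  mr_estimate("Penalised weighted median", beta, se, nrow(h))
}

mode_point <- function(ratio, weight, bandwidth_factor) {
  k <- length(ratio)
  s <- min(stats::sd(ratio), stats::mad(ratio))
  hbw <- bandwidth_factor * 0.9 * s * k^(-1 / 5)
  if (!is.finite(hbw) || hbw <= 0) return(ratio[1])   # all ratios identical
  grid <- seq(min(ratio) - 3 * hbw, max(ratio) + 3 * hbw, length.out = 512)
  dens <- vapply(grid, function(x)
    sum(weight * stats::dnorm((x - ratio) / hbw)), numeric(1))
  # ties at the maximum resolved toward the smallest ratio value
  grid[which(dens == max(dens))[1]]
}

#' Mode-based estimators (simple and weighted)
#'
#' The mode of the normal-kernel-smoothed density of the Wald ratios,
#' located by a 512-point grid search over [min - 3h, max + 3h] with
#' modified Silverman bandwidth h = phi * 0.9 * min(sd, MAD) * k^(-1/5).
#' Unit weights give the simple mode, inverse-variance weights the weighted
#' mode. Consistent when the largest group of instruments sharing a causal
#' estimate is valid (ZEMPA). SE by parametric bootstrap.
#'
#' @inheritParams mr_simple_median
#' @param weighted use inverse-variance weights (weighted mode) rather than
#'   unit weights (simple mode).
#' @param bandwidth_factor multiplier phi on the modified Silverman
#'   bandwidth (default 1).
#' @return An `mr_estimate`.
#' @export
mr_mode <- function(h, weighted = FALSE, bandwidth_factor = 1,
                    n_boot = 1000, seed = NULL) {
  if (nrow(h) < 3L) stopf("mode estimators require >=3 instruments")
  point <- function(hh) {
    w <- wald_ratios(hh)
    wt <- if (weighted) w$weight else rep(1, nrow(w))
    mode_point(w$ratio, wt, bandwidth_factor)
  }
  beta <- point(h)
  se <- bootstrap_se(h, point, n_boot, seed)
  mr_estimate(if (weighted) "Weighted mode" else "Simple mode",
              beta, se, nrow(h))
}

#' @rdname mr_mode
#' @export
mr_simple_mode <- function(h, bandwidth_factor = 1, n_boot = 1000, seed = NULL)
  mr_mode(h, weighted = FALSE, bandwidth_factor = bandwidth_factor,
          n_boot = n_boot, seed = seed)

#' @rdname mr_mode
#' @export
mr_weighted_mode <- function(h, bandwidth_factor = 1, n_boot = 1000, seed = NULL)
  mr_mode(h, weighted = TRUE, bandwidth_factor = bandwidth_factor,
          n_boot = n_boot, seed = seed)

# profile negative log-likelihood: bilinear measurement-error model with the
# per-SNP true exposure effects profiled out in closed form.
ml_profile_nll <- function(theta, bx, by, sx2, sy2)
  0.5 * sum((by - theta * bx)^2 / (sy2 + theta^2 * sx2))

#' Maximum-likelihood estimator
#'
#' Models observed effects as beta_exp_j ~ N(xi_j, se_exp_j^2) and
#' beta_out_j ~ N(theta * xi_j, se_out_j^2), profiles out the latent xi_j in
#' closed form, and maximizes the profile likelihood over theta numerically
#' from the IVW starting value. Unlike the ratio-based estimators this
#' accounts for exposure-side measurement error. SE from the observed
#' information (numerical second derivative at the optimum).
#'
#' @param h an `mr_harmonized` set.
#' @param max_iter optimizer iteration budget.
#' @return An `mr_estimate`.
#' @export
mr_maximum_likelihood <- function(h, max_iter = 200) {
  w <- wald_ratios(h)
  if (nrow(h) == 1L)
    return(mr_estimate("Wald ratio", w$ratio, w$se, 1L))
  bx <- h$beta_exp; by <- h$beta_out
  sx2 <- h$se_exp^2; sy2 <- h$se_out^2
  start <- ivw_point(h)
  opt <- stats::optim(start, ml_profile_nll, bx = bx, by = by,
                      sx2 = sx2, sy2 = sy2, method = "BFGS",
                      control = list(maxit = max_iter), hessian = TRUE)
  if (opt$convergence != 0)
    stopf("maximum-likelihood optimizer failed to converge (code %d, start %.4g)",
          opt$convergence, start)
  info <- opt$hessian[1, 1]
  if (!is.finite(info) || info <= 0)
    stopf("maximum-likelihood information is not positive at the optimum")
  mr_estimate("Maximum likelihood", opt$par, 1 / sqrt(info), nrow(h))
}

#' Run the full eight-estimator battery
#'
#' IVW (random effects), MR-Egger, simple/weighted/penalized-weighted
#' median, simple/weighted mode, and maximum likelihood, on one harmonized
#' exposure-outcome pair. Methods whose instrument-count preconditions fail
#' are skipped with a message row.
#'
#' @param h an `mr_harmonized` set.
#' @param n_boot,seed bootstrap settings shared by the resampling methods
#'   (each method gets a distinct stream derived from `seed`).
#' @param bandwidth_factor mode-estimator bandwidth multiplier.
#' @param penalty_k penalized-weighted-median constant.
#' @return data.frame with one row per method (columns of
#'   `as.data.frame.mr_estimate`); estimates retrievable via the
#'   `estimates` attribute.
#' @export
mr_all <- function(h, n_boot = 1000, seed = NULL, bandwidth_factor = 1,
                   penalty_k = 20) {
  sub_seed <- function(i) if (is.null(seed)) NULL else seed + i
  fits <- list(
    ivw = function() mr_ivw(h),
    egger = function() mr_egger(h),
    simple_median = function() mr_simple_median(h, n_boot, sub_seed(1)),
    weighted_median = function() mr_weighted_median(h, n_boot, sub_seed(2)),
    penalized_weighted_median = function()
      mr_penalized_weighted_median(h, penalty_k, n_boot, sub_seed(3)),
    simple_mode = function() mr_simple_mode(h, bandwidth_factor, n_boot, sub_seed(4)),
    weighted_mode = function() mr_weighted_mode(h, bandwidth_factor, n_boot, sub_seed(5)),
    maximum_likelihood = function() mr_maximum_likelihood(h))
  ests <- lapply(fits, function(f) tryCatch(f(), error = function(e) e))
  rows <- lapply(names(ests), function(nm) {
    e <- ests[[nm]]
    if (inherits(e, "error"))
      data.frame(method = nm, n_snps = nrow(h), beta = NA_real_, se = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_, pvalue = NA_real_,
                 or = NA_real_, or_low = NA_real_, or_high = NA_real_,
                 stringsAsFactors = FALSE)
    else as.data.frame(e)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, estimates = ests)
}
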