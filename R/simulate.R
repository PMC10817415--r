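#' Simulation configuration for a three-trait causal chain
#'
#' Parameters of the generating model for GWAS summary statistics of an
#' exposure, a mediator and an outcome linked by the chain
#' exposure -> mediator -> outcome plus a direct exposure -> outcome path:
#' total effect = theta_direct + theta_xm * theta_my. Defaults emulate a
#' protein-exposure / protein-mediator / binary-disease-outcome design:
#' a small pQTL exposure GWAS (n = 3,301) with 3 instruments, a mediator
#' GWAS (n = 21,758) with 7 instruments, a large outcome GWAS
#' (n = 337,199, effects on the log-odds scale), and chain coefficients
#' giving a total effect of 0.00208 with 55.9% of it mediated.
#'
#' @param k_snps exposure instrument count.
#' @param k_med_snps mediator-specific instrument count (SNPs affecting the
#'   mediator but not the exposure).
#' @param k_out_snps outcome-specific instrument count (default 0; used for
#'   reverse-direction calibration).
#' @param n_exp,n_med,n_out GWAS sample sizes.
#' @param maf_range effect-allele-frequency range, within (0, 0.5].
#' @param gamma_sd SD of true per-allele instrument effects (applies to
#'   each trait's own instruments), rejection-sampled until the expected
#'   GWAS p-value clears genome-wide significance.
#' @param theta_xm,theta_my,theta_direct chain coefficients.
#' @param pleiotropy_mean,pleiotropy_sd direct SNP -> outcome effects of the
#'   exposure instruments (directional when the mean is non-zero).
#' @param ld_proxy_count correlated proxy SNPs planted per exposure
#'   instrument.
#' @param ld_proxy_r2 target r^2 between a proxy and its parent.
#' @param n_ref reference-panel size for the latent-genotype proxy
#'   construction.
#' @param window_kb inter-SNP spacing guarantee (positions of distinct
#'   instruments are placed further apart than this; proxies closer).
#' @param seed integer RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(k_snps = 3, k_med_snps = 7, k_out_snps = 0,
                       n_exp = 3301, n_med = 21758, n_out = 337199,
                       maf_range = c(0.1, 0.5), gamma_sd = 0.3,
                       theta_xm = 0.3249, theta_my = 0.00358,
                       theta_direct = 0.00092,
                       pleiotropy_mean = 0, pleiotropy_sd = 0,
                       ld_proxy_count = 0, ld_proxy_r2 = 0.8, n_ref = 10000,
                       window_kb = 10000, seed = 1) {
  stopifnot(k_snps >= 1, k_med_snps >= 0, k_out_snps >= 0,
            n_exp >= 10, n_med >= 10, n_out >= 10,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            gamma_sd > 0, ld_proxy_count >= 0,
            ld_proxy_r2 >= 0, ld_proxy_r2 < 1, window_kb > 0)
  structure(as.list(environment()), class = "sim_config")
}

# per-allele SE of a GWAS effect for a standardized trait
gwas_se <- function(maf, n) 1 / sqrt(2 * maf * (1 - maf) * n)

# rejection-sample a true effect until its expected GWAS p clears 5e-8;
# effects are returned as magnitudes, i.e. coded on the trait-increasing
# allele, so directional pleiotropy keeps its direction under the
# exposure-positive orientation the Egger regression applies
sample_instrument_effect <- function(gamma_sd, se, p_target = 5e-8,
                                     max_attempts = 1000) {
  z_needed <- stats::qnorm(p_target / 2, lower.tail = FALSE)
  for (i in seq_len(max_attempts)) {
    g <- abs(stats::rnorm(1, 0, gamma_sd))
    if (g / se > z_needed) return(g)
  }
  stopf(paste0("could not draw a genome-wide-significant instrument effect in %d ",
               "attempts (gamma_sd = %g is too small for se = %g)"),
        max_attempts, gamma_sd, se)
}

.allele_pairs <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                      c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))

#' Simulate GWAS summary statistics for the causal chain
#'
#' Draws, for every instrument, a MAF, a true effect (rejection-sampled to
#' guarantee genome-wide significance in its own GWAS), per-trait standard
#' errors (2 * maf * (1-maf) * n)^(-1/2), and observed effects from the
#' generating chain with independent normal noise. Exposure instruments
#' propagate to the mediator (times theta_xm) and outcome (times
#' theta_direct + theta_xm * theta_my, plus any pleiotropic direct effect);
#' mediator instruments propagate to the outcome (times theta_my).
#' Instruments are spaced further apart than the clumping window; optional
#' LD proxies are planted next to exposure instruments via a latent
#' reference-genotype construction so that their empirical r^2 is
#' meaningful.
#'
#' @param config a [sim_config()].
#' @return list of class `mr_simulation` with elements `exposure`,
#'   `mediator`, `outcome` (validated `mr_summary` datasets), `truth`
#'   (generating parameters, per-SNP true effects, instrument ids and the
#'   true mediated proportion), and `ld` (pairwise r^2 data.frame, or NULL
#'   when no proxies were requested).
#' @export
simulate_chain <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  theta_total <- config$theta_direct + config$theta_xm * config$theta_my

  draw_maf <- function(k) stats::runif(k, config$maf_range[1], config$maf_range[2])
  spacing <- config$window_kb * 1000 + 50000

  rows <- list(); ld_rows <- list()
  truth_effects <- list()
  add_snp <- function(id, chrom, pos, maf, eff_exp, eff_med, eff_out) {
    pair <- .allele_pairs[[sample.int(length(.allele_pairs), 1)]]
    list(snp = id, chrom = chrom, pos = pos,
         effect_allele = pair[1], other_allele = pair[2], eaf = maf,
         eff = c(exposure = eff_exp, mediator = eff_med, outcome = eff_out))
  }

  # exposure instruments (+ pleiotropic direct paths to the outcome)
  k <- config$k_snps
  maf_x <- draw_maf(k)
  gamma <- vapply(seq_len(k), function(j)
    sample_instrument_effect(config$gamma_sd, gwas_se(maf_x[j], config$n_exp)),
    numeric(1))
  alpha <- stats::rnorm(k, config$pleiotropy_mean, config$pleiotropy_sd)
  exposure_snps <- sprintf("rs1%06d", seq_len(k))
  for (j in seq_len(k)) {
    rows[[length(rows) + 1L]] <- add_snp(
      exposure_snps[j], "1", j * spacing, maf_x[j],
      gamma[j], config$theta_xm * gamma[j],
      theta_total * gamma[j] + alpha[j])
    if (config$ld_proxy_count > 0) {
      pr <- plant_proxies(exposure_snps[j], maf_x[j], config)
      for (i in seq_along(pr$ids)) {
        atten <- pr$atten[i]
        rows[[length(rows) + 1L]] <- add_snp(
          pr$ids[i], "1", j * spacing + i * 1000, pr$maf[i],
          atten * gamma[j], atten * config$theta_xm * gamma[j],
          atten * (theta_total * gamma[j] + alpha[j]))
      }
      ld_rows[[length(ld_rows) + 1L]] <- pr$ld
    }
  }

  # mediator-specific instruments
  km <- config$k_med_snps
  gamma_med <- numeric(0); mediator_snps <- character(0)
  if (km > 0) {
    maf_m <- draw_maf(km)
    gamma_med <- vapply(seq_len(km), function(j)
      sample_instrument_effect(config$gamma_sd, gwas_se(maf_m[j], config$n_med)),
      numeric(1))
    mediator_snps <- sprintf("rs2%06d", seq_len(km))
    for (j in seq_len(km))
      rows[[length(rows) + 1L]] <- add_snp(
        mediator_snps[j], "2", j * spacing, maf_m[j],
        0, gamma_med[j], config$theta_my * gamma_med[j])
  }

  # outcome-specific instruments (for reverse-direction calibration)
  ko <- config$k_out_snps
  gamma_out <- numeric(0); outcome_snps <- character(0)
  if (ko > 0) {
    maf_o <- draw_maf(ko)
    gamma_out <- vapply(seq_len(ko), function(j)
      sample_instrument_effect(config$gamma_sd, gwas_se(maf_o[j], config$n_out)),
      numeric(1))
    outcome_snps <- sprintf("rs3%06d", seq_len(ko))
    for (j in seq_len(ko))
      rows[[length(rows) + 1L]] <- add_snp(
        outcome_snps[j], "3", j * spacing, maf_o[j],
        0, 0, gamma_out[j])
  }

  base <- do.call(rbind, lapply(rows, function(r)
    data.frame(snp = r$snp, chrom = r$chrom, pos = r$pos,
               effect_allele = r$effect_allele, other_allele = r$other_allele,
               eaf = r$eaf, stringsAsFactors = FALSE)))
  eff <- do.call(rbind, lapply(rows, function(r) r$eff))

  make_gwas <- function(trait, n, trait_type) {
    se <- gwas_se(base$eaf, n)
    beta <- stats::rnorm(nrow(base), eff[, trait], se)
    p <- 2 * stats::pnorm(-abs(beta / se))
    p[p == 0] <- .Machine$double.xmin
    df <- cbind(base, data.frame(beta = beta, se = se, pvalue = p, n = n))
    summary_dataset(df, trait_id = trait, trait_type = trait_type, n_default = n)
  }
  exposure <- make_gwas("exposure", config$n_exp, "quantitative")
  mediator <- make_gwas("mediator", config$n_med, "quantitative")
  outcome <- make_gwas("outcome", config$n_out, "binary")

  truth <- list(
    theta_xm = config$theta_xm, theta_my = config$theta_my,
    theta_direct = config$theta_direct, theta_total = theta_total,
    proportion_mediated_pct = if (theta_total != 0)
      100 * config$theta_xm * config$theta_my / theta_total else NA_real_,
    gamma = stats::setNames(gamma, exposure_snps),
    gamma_med = stats::setNames(gamma_med, mediator_snps),
    gamma_out = stats::setNames(gamma_out, outcome_snps),
    alpha = stats::setNames(alpha, exposure_snps),
    exposure_snps = exposure_snps, mediator_snps = mediator_snps,
    outcome_snps = outcome_snps)

  ld <- if (length(ld_rows)) do.call(rbind, ld_rows) else NULL
  structure(list(exposure = exposure, mediator = mediator, outcome = outcome,
                 truth = truth, ld = ld, config = config),
            class = "mr_simulation")
}

# latent-genotype proxies: each proxy haplotype copies the parent allele
# with probability sqrt(target r2), else draws fresh, so dosage correlation
# approximates sqrt(r2) and r^2 the target. Returns attenuation factors
# (regression of parent dosage on proxy dosage) and the empirical r2 table.
plant_proxies <- function(parent_id, maf, config) {
  m <- config$ld_proxy_count
  n_ref <- config$n_ref
  c_copy <- sqrt(config$ld_proxy_r2)
  hap_parent <- matrix(stats::rbinom(2 * n_ref, 1, maf), ncol = 2)
  g_parent <- rowSums(hap_parent)
  ids <- sprintf("%s9%02d", sub("^rs", "rs9", parent_id), seq_len(m))
  dos <- matrix(0, n_ref, m + 1,
                dimnames = list(NULL, c(parent_id, ids)))
  dos[, 1] <- g_parent
  maf_pr <- atten <- numeric(m)
  for (i in seq_len(m)) {
    copy <- matrix(stats::runif(2 * n_ref) < c_copy, ncol = 2)
    fresh <- matrix(stats::rbinom(2 * n_ref, 1, maf), ncol = 2)
    hap <- ifelse(copy, hap_parent, fresh)
    dos[, i + 1] <- rowSums(hap)
    maf_pr[i] <- mean(dos[, i + 1]) / 2
    atten[i] <- stats::cov(dos[, 1], dos[, i + 1]) / stats::var(dos[, i + 1])
  }
  list(ids = ids, maf = pmin(pmax(maf_pr, 0.01), 0.99), atten = atten,
       ld = r2_from_dosages(dos))
}

#' Simulate the null chain (no causal paths)
#'
#' [simulate_chain()] with all three chain coefficients forced to zero;
#' instruments keep their own-trait effects. Used for type-I-error and
#' reverse-direction calibration.
#'
#' @param config a [sim_config()]; its theta values are overridden.
#' @return An `mr_simulation`, see [simulate_chain()].
#' @export
simulate_null <- function(config = sim_config()) {
  config$theta_xm <- 0; config$theta_my <- 0; config$theta_direct <- 0
  simulate_chain(config)
}

#' Write a simulation to disk
#'
#' Emits the three GWAS as TSV in the dialect [read_summary_stats()] reads,
#' the ground truth as a JSON sidecar, and the r^2 table (when present) as
#' TSV.
#'
#' @param sim an `mr_simulation`.
#' @param dir output directory (created if absent).
#' @return Named character vector of the files written, invisibly.
#' @export
simulation_to_dir <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(exposure = file.path(dir, "exposure.tsv"),
             mediator = file.path(dir, "mediator.tsv"),
             outcome = file.path(dir, "outcome.tsv"),
             truth = file.path(dir, "truth.json"))
  write_summary_stats(sim$exposure, files["exposure"])
  write_summary_stats(sim$mediator, files["mediator"])
  write_summary_stats(sim$outcome, files["outcome"])
  jsonlite::write_json(sim$truth, files["truth"], auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(sim$ld)) {
    files["ld"] <- file.path(dir, "ld_r2.tsv")
    utils::write.table(sim$ld, files["ld"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(files)
}
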