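#' Analysis configuration for the two-step study
#'
#' @param instrument an [instrument_config()].
#' @param n_boot bootstrap replicates for the median/mode estimators.
#' @param bandwidth_factor mode-estimator bandwidth multiplier.
#' @param penalty_k penalized-weighted-median constant.
#' @param seed master seed; every stochastic stage derives its stream from
#'   it, making the whole run reproducible.
#' @param alpha significance level used by the heterogeneity, pleiotropy
#'   and causal-effect flags.
#' @param palindrome_window EAF ambiguity window for palindromic SNPs.
#' @param exclude_snps rsIDs removed from every instrument set after
#'   clumping (e.g. a confounder-associated exclusion list).
#' @param exclude_exposure_instruments_in_step2 drop SNPs that are
#'   genome-wide significant for the exposure from the mediator's
#'   instrument set, so the mediator -> outcome estimate is not driven by
#'   exposure instruments acting through the exposure (default TRUE).
#' @param run_reverse,run_mediation stage toggles.
#' @return list of class `mr_config`.
#' @export
mr_config <- function(instrument = instrument_config(), n_boot = 1000,
                      bandwidth_factor = 1, penalty_k = 20, seed = 0,
                      alpha = 0.05, palindrome_window = c(0.42, 0.58),
                      exclude_snps = character(),
                      exclude_exposure_instruments_in_step2 = TRUE,
                      run_reverse = TRUE, run_mediation = TRUE) {
  structure(list(instrument = instrument, n_boot = n_boot,
                 bandwidth_factor = bandwidth_factor, penalty_k = penalty_k,
                 seed = seed, alpha = alpha,
                 palindrome_window = palindrome_window,
                 exclude_snps = exclude_snps,
                 exclude_exposure_instruments_in_step2 =
                   exclude_exposure_instruments_in_step2,
                 run_reverse = run_reverse, run_mediation = run_mediation),
            class = "mr_config")
}

#' Analyse one exposure-outcome pair end to end
#'
#' Instrument selection on the exposure, harmonization against the outcome,
#' the eight-estimator battery, and the sensitivity block (heterogeneity,
#' Egger intercept where k >= 3, leave-one-out). Degrades to a structured
#' not-estimable result instead of erroring when no instruments survive.
#'
#' @param exposure,outcome `mr_summary` datasets.
#' @param ld LD source for clumping (see [ld_lookup()]).
#' @param config an [mr_config()].
#' @param extra_exclude additional SNP ids excluded from the instrument set
#'   for this pair only.
#' @param pair_seed seed for this pair's bootstrap streams.
#' @return list of class `mr_pair`: `exposure_id`, `outcome_id`,
#'   `estimable`, and when estimable `instruments`, `harmonization`,
#'   `estimates`, `ivw`, `sensitivity` (`heterogeneity`, `egger_intercept`,
#'   `leave_one_out`), `scatter` and `forest` plot tables.
#' @export
analyse_pair <- function(exposure, outcome, ld = NULL, config = mr_config(),
                         extra_exclude = character(), pair_seed = config$seed) {
  ids <- list(exposure_id = attr(exposure, "trait_id") %||% "exposure",
              outcome_id = attr(outcome, "trait_id") %||% "outcome")
  sel <- select_instruments(exposure, ld, config$instrument,
                            exclude = c(config$exclude_snps, extra_exclude))
  if (length(sel$snps) == 0L)
    return(c(ids, list(estimable = FALSE,
                       reason = "no significant independent instruments",
                       instruments = sel$report)))
  h <- tryCatch(harmonize(exposure, outcome, sel$snps,
                          palindrome_window = config$palindrome_window),
                error = function(e) conditionMessage(e))
  if (is.character(h))
    return(c(ids, list(estimable = FALSE, reason = h, instruments = sel$report)))

  est <- mr_all(h, n_boot = config$n_boot, seed = pair_seed,
                bandwidth_factor = config$bandwidth_factor,
                penalty_k = config$penalty_k)
  ivw <- attr(est, "estimates")$ivw
  sens <- list(heterogeneity = if (nrow(h) >= 2) heterogeneity(h, config$alpha),
               egger_intercept = if (nrow(h) >= 3)
                 egger_intercept_test(h, config$alpha),
               leave_one_out = if (nrow(h) >= 2) leave_one_out(h))
  w <- wald_ratios(h)
  c(ids, list(
    estimable = TRUE,
    instruments = sel$report,
    harmonization = harmonization_report(h),
    h = h,
    estimates = est,
    ivw = ivw,
    sensitivity = sens,
    scatter = data.frame(snp = h$snp, beta_exp = h$beta_exp,
                         se_exp = h$se_exp, beta_out = h$beta_out,
                         se_out = h$se_out, stringsAsFactors = FALSE),
    forest = data.frame(snp = w$snp, ratio = w$ratio, se = w$se,
                        ci_low = w$ratio - Z975 * w$se,
                        ci_high = w$ratio + Z975 * w$se,
                        stringsAsFactors = FALSE)))
}

#' Run the full two-step mediation study
#'
#' Orchestrates the three forward pairwise analyses
#' (exposure -> mediator, exposure -> outcome, mediator -> outcome),
#' optional reverse-direction checks, and the mediation decomposition
#' (present only when all three forward pairs are estimable, from their IVW
#' estimates). Deterministic under a fixed `config$seed`.
#'
#' @param exposure,mediator,outcome `mr_summary` datasets (or file paths,
#'   read with the default column map).
#' @param ld LD source for clumping.
#' @param config an [mr_config()].
#' @return list of class `mr_study_report` with elements `pairs` (named
#'   list of `mr_pair` results, forward and reverse), `mediation`
#'   (`mr_mediation` or a skip record), `mediation_table`, and `config`.
#' @export
run_two_step <- function(exposure, mediator, outcome, ld = NULL,
                         config = mr_config()) {
  as_ds <- function(x, role, type) {
    if (is.character(x)) read_summary_stats(x, trait_id = role, trait_type = type)
    else x
  }
  exposure <- as_ds(exposure, "exposure", "quantitative")
  mediator <- as_ds(mediator, "mediator", "quantitative")
  outcome <- as_ds(outcome, "outcome", "binary")

  step2_exclude <- if (config$exclude_exposure_instruments_in_step2)
    select_by_pvalue(exposure, config$instrument$p_threshold) else character()

  pairs <- list()
  pairs$exposure_mediator <- analyse_pair(exposure, mediator, ld, config,
                                          pair_seed = config$seed + 11)
  pairs$exposure_outcome <- analyse_pair(exposure, outcome, ld, config,
                                         pair_seed = config$seed + 12)
  pairs$mediator_outcome <- analyse_pair(mediator, outcome, ld, config,
                                         extra_exclude = step2_exclude,
                                         pair_seed = config$seed + 13)
  if (config$run_reverse) {
    pairs$outcome_exposure <- analyse_pair(outcome, exposure, ld, config,
                                           pair_seed = config$seed + 21)
    pairs$outcome_mediator <- analyse_pair(outcome, mediator, ld, config,
                                           pair_seed = config$seed + 22)
    pairs$mediator_exposure <- analyse_pair(mediator, exposure, ld, config,
                                            extra_exclude = step2_exclude,
                                            pair_seed = config$seed + 23)
  }

  forward_ok <- all(vapply(pairs[c("exposure_mediator", "exposure_outcome",
                                   "mediator_outcome")],
                           function(p) isTRUE(p$estimable), logical(1)))
  mediation <- med_table <- NULL
  if (config$run_mediation && forward_ok) {
    mediation <- two_step_mediation(total = pairs$exposure_outcome$ivw,
                                    step1 = pairs$exposure_mediator$ivw,
                                    step2 = pairs$mediator_outcome$ivw)
    med_table <- mediation_table(mediation,
                                 total = pairs$exposure_outcome$ivw,
                                 step1 = pairs$exposure_mediator$ivw,
                                 step2 = pairs$mediator_outcome$ivw)
  } else if (config$run_mediation) {
    mediation <- list(skipped = TRUE,
                      reason = "not all forward pairs were estimable")
  } else {
    mediation <- list(skipped = TRUE, reason = "mediation disabled in config")
  }

  structure(list(pairs = pairs, mediation = mediation,
                 mediation_table = med_table, config = config),
            class = "mr_study_report")
}

fmt5 <- function(x) ifelse(is.na(x), NA, sprintf("%.5f", x))

format_estimates_table <- function(df) {
  out <- df
  for (col in c("beta", "se", "ci_low", "ci_high", "or", "or_low", "or_high"))
    out[[col]] <- fmt5(df[[col]])
  out$pvalue <- ifelse(is.na(df$pvalue), NA, sprintf("%.4g", df$pvalue))
  out
}

#' Serialize a study report to TSV files plus a JSON manifest
#'
#' Writes, per pair: the instrument report, harmonization log, estimates
#' table (effects and ORs at 5-decimal display precision), sensitivity
#' block and scatter/forest/leave-one-out plot tables; plus the one-row
#' mediation table; plus `manifest.json` listing every emitted file with
#' its MD5 checksum and the resolved configuration.
#'
#' @param report an `mr_study_report`.
#' @param outdir output directory (created if absent).
#' @return Character vector of files written, invisibly.
#' @export
render_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(outdir, 2) != 0) stopf("output directory not writable: %s", outdir)
  written <- character()
  emit <- function(df, name) {
    path <- file.path(outdir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, path)
  }

  all_estimates <- list()
  for (nm in names(report$pairs)) {
    p <- report$pairs[[nm]]
    emit(p$instruments, sprintf("instruments_%s.tsv", nm))
    if (!isTRUE(p$estimable)) next
    emit(p$harmonization, sprintf("harmonization_%s.tsv", nm))
    est <- cbind(pair = nm, format_estimates_table(p$estimates))
    all_estimates[[nm]] <- est
    emit(p$sensitivity$heterogeneity, sprintf("heterogeneity_%s.tsv", nm))
    if (!is.null(p$sensitivity$egger_intercept))
      emit(as.data.frame(p$sensitivity$egger_intercept),
           sprintf("egger_intercept_%s.tsv", nm))
    emit(p$sensitivity$leave_one_out, sprintf("leave_one_out_%s.tsv", nm))
    emit(p$scatter, sprintf("scatter_%s.tsv", nm))
    emit(p$forest, sprintf("forest_%s.tsv", nm))
  }
  emit(do.call(rbind, all_estimates), "estimates.tsv")

  mediation_section <- if (!is.null(report$mediation_table)) {
    emit(report$mediation_table, "mediation.tsv")
    list(present = TRUE, file = "mediation.tsv")
  } else {
    list(present = FALSE, skipped = TRUE,
         reason = report$mediation$reason %||% "unavailable")
  }

  manifest <- list(
    files = lapply(written, function(f)
      list(name = basename(f), md5 = unname(tools::md5sum(f)))),
    mediation = mediation_section,
    pairs = lapply(report$pairs, function(p)
      list(exposure = p$exposure_id, outcome = p$outcome_id,
           estimable = isTRUE(p$estimable),
           reason = if (!isTRUE(p$estimable)) p$reason)),
    config = resolved_config(report$config))
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(c(written, manifest_path))
}

resolved_config <- function(config) {
  cfg <- unclass(config)
  cfg$instrument <- unclass(cfg$instrument)
  cfg
}
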