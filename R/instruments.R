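#' Instrument-selection configuration
#'
#' Defaults follow the conventional genome-wide pipeline: significance
#' p < 5e-8 (strict), greedy LD clumping at r^2 < 0.001 within 10,000 kb,
#' and the F > 10 weak-instrument rule.
#'
#' @param p_threshold genome-wide significance cutoff (strict `<`).
#' @param r2_threshold pairwise LD r^2 above which the weaker SNP is clumped
#'   away.
#' @param window_kb clumping distance in kilobases.
#' @param f_threshold instruments with F below this are flagged weak.
#' @param r2_mode how per-SNP variance explained is computed: `"from-eaf"`
#'   uses 2*eaf*(1-eaf)*beta^2 (standardized quantitative trait),
#'   `"from-f"` uses t^2/(t^2+n-2); `"auto"` picks from-eaf when EAF is
#'   available and from-f otherwise.
#' @return list of class `instrument_config`.
#' @export
instrument_config <- function(p_threshold = 5e-8, r2_threshold = 0.001,
                              window_kb = 10000, f_threshold = 10,
                              r2_mode = c("auto", "from-eaf", "from-f")) {
  stopifnot(p_threshold > 0, p_threshold < 1,
            r2_threshold >= 0, r2_threshold <= 1,
            window_kb > 0, f_threshold >= 0)
  structure(list(p_threshold = p_threshold, r2_threshold = r2_threshold,
                 window_kb = window_kb, f_threshold = f_threshold,
                 r2_mode = match.arg(r2_mode)),
            class = "instrument_config")
}

#' Select genome-wide-significant SNPs
#'
#' @param dataset an `mr_summary` dataset.
#' @param p_threshold strict significance cutoff.
#' @return Character vector of SNP ids with p strictly below the threshold,
#'   ordered by ascending p (ties broken by SNP id).
#' @export
select_by_pvalue <- function(dataset, p_threshold = 5e-8) {
  if (nrow(dataset) == 0L) stopf("empty dataset")
  hits <- dataset[dataset$pvalue < p_threshold, c("snp", "pvalue")]
  hits$snp[order(hits$pvalue, hits$snp)]
}

#' Build an r-squared lookup from a pair table, matrix, or dosage matrix
#'
#' @param ld one of: a data.frame with columns `snp_a`, `snp_b`, `r2`;
#'   a square numeric matrix with SNP ids as dimnames; a path to a 3-column
#'   TSV of pairs; or `NULL` (no LD information — any in-window query
#'   errors).
#' @return A function `(a, b) -> r2` returning `NA` for unknown pairs
#'   (same-SNP queries return 1).
#' @export
ld_lookup <- function(ld) {
  if (is.null(ld)) return(function(a, b) if (a == b) 1 else NA_real_)
  if (is.character(ld) && length(ld) == 1L)
    ld <- utils::read.table(ld, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (is.matrix(ld)) {
    ids <- rownames(ld)
    if (is.null(ids) || !identical(ids, colnames(ld)))
      stopf("LD matrix needs identical SNP-id row and column names")
    return(function(a, b) {
      if (a == b) return(1)
      if (!(a %in% ids) || !(b %in% ids)) return(NA_real_)
      unname(ld[a, b])
    })
  }
  stopifnot(is.data.frame(ld), all(c("snp_a", "snp_b", "r2") %in% names(ld)))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  env <- new.env(parent = emptyenv(), size = nrow(ld) * 2L)
  for (i in seq_len(nrow(ld)))
    assign(key(ld$snp_a[i], ld$snp_b[i]), ld$r2[i], envir = env)
  function(a, b) {
    if (a == b) return(1)
    get0(key(a, b), envir = env, ifnotfound = NA_real_)
  }
}

#' Compute pairwise r-squared from a reference dosage matrix
#'
#' Squared Pearson correlation between SNP dosage columns (individuals in
#' rows, dosages in {0,1,2}).
#'
#' @param dosages numeric matrix, columns named by SNP id.
#' @return data.frame with columns `snp_a`, `snp_b`, `r2` for every pair.
#' @export
r2_from_dosages <- function(dosages) {
  stopifnot(is.matrix(dosages), !is.null(colnames(dosages)))
  cm <- suppressWarnings(stats::cor(dosages))^2
  ids <- colnames(dosages)
  pairs <- which(upper.tri(cm), arr.ind = TRUE)
  data.frame(snp_a = ids[pairs[, 1]], snp_b = ids[pairs[, 2]],
             r2 = cm[pairs], stringsAsFactors = FALSE)
}

#' Greedy LD clumping
#'
#' Repeatedly keeps the remaining SNP with the lowest p-value and removes
#' every remaining same-chromosome SNP within `window_kb` whose r^2 with it
#' is at or above `r2_threshold`. The retained set is pairwise independent
#' under the threshold. An in-window pair with no r^2 available is an error:
#' independence is never silently assumed.
#'
#' @param candidates data.frame with columns `snp`, `chrom`, `pos`,
#'   `pvalue` (e.g. a subset of an `mr_summary` dataset).
#' @param ld anything [ld_lookup()] accepts.
#' @param config an [instrument_config()].
#' @return Character vector of retained SNP ids, in selection order.
#' @export
ld_clump <- function(candidates, ld = NULL, config = instrument_config()) {
  need <- c("snp", "chrom", "pos", "pvalue")
  stopifnot(all(need %in% names(candidates)))
  if (nrow(candidates) == 0L) return(character())
  lk <- ld_lookup(ld)
  cand <- candidates[order(candidates$pvalue, candidates$snp), need]
  window_bp <- config$window_kb * 1000
  kept <- character()
  while (nrow(cand) > 0L) {
    top <- cand[1L, ]
    kept <- c(kept, top$snp)
    cand <- cand[-1L, , drop = FALSE]
    if (nrow(cand) == 0L) break
    in_window <- cand$chrom == top$chrom & abs(cand$pos - top$pos) <= window_bp
    if (any(in_window)) {
      r2 <- vapply(cand$snp[in_window], function(s) lk(top$snp, s), numeric(1))
      if (anyNA(r2))
        stopf("no r2 available for in-window pair(s): %s vs %s",
              top$snp, paste(cand$snp[in_window][is.na(r2)], collapse = ", "))
      drop <- in_window
      drop[in_window] <- r2 >= config$r2_threshold
      cand <- cand[!drop, , drop = FALSE]
    }
  }
  kept
}

#' Per-SNP variance explained (R^2)
#'
#' Two conventions: `from-eaf` gives R^2 = 2*eaf*(1-eaf)*beta^2, valid for a
#' standardized quantitative trait; `from-f` gives R^2 = t^2/(t^2 + n - 2)
#' with t = beta/se.
#'
#' @param beta,se,eaf,n per-SNP summary statistics (vectorized).
#' @param mode `"from-eaf"` or `"from-f"`.
#' @return Numeric vector of R^2 values.
#' @export
compute_r2 <- function(beta, se = NULL, eaf = NULL, n = NULL,
                       mode = c("from-eaf", "from-f")) {
  mode <- match.arg(mode)
  if (mode == "from-eaf") {
    if (is.null(eaf) || anyNA(eaf)) stopf("from-eaf mode requires non-missing eaf")
    2 * eaf * (1 - eaf) * beta^2
  } else {
    if (is.null(se) || is.null(n)) stopf("from-f mode requires se and n")
    t2 <- (beta / se)^2
    t2 / (t2 + n - 2)
  }
}

#' Instrument-strength F-statistic
#'
#' F = (n - 2) * R^2 / (1 - R^2) from the single-SNP exposure regression.
#' F below 10 conventionally flags a weak instrument.
#'
#' @param r2 variance explained, in `[0, 1)`.
#' @param n exposure-GWAS sample size (> 2).
#' @return F statistic (vectorized).
#' @export
f_statistic <- function(r2, n) {
  if (any(n <= 2)) stopf("F-statistic requires n > 2")
  if (any(r2 < 0 | r2 >= 1)) stopf("r2 must lie in [0, 1)")
  (n - 2) * r2 / (1 - r2)
}

#' Select and validate instruments for one exposure
#'
#' Runs the selection cascade — significance filter, optional exclusion
#' list, greedy LD clumping, F-statistic validation — and reports every
#' candidate SNP with its fate.
#'
#' @param dataset exposure `mr_summary` dataset.
#' @param ld LD source for clumping (see [ld_lookup()]).
#' @param config an [instrument_config()].
#' @param exclude SNP ids to remove after significance filtering (e.g. a
#'   confounder-associated list).
#' @return list with `snps` (selected instrument ids) and `report`
#'   (data.frame: snp, pvalue, r2_explained, f_stat, selected, reason).
#' @export
select_instruments <- function(dataset, ld = NULL, config = instrument_config(),
                               exclude = character()) {
  sig <- select_by_pvalue(dataset, config$p_threshold)
  reason <- setNames(rep("not-significant", nrow(dataset)), dataset$snp)
  reason[sig] <- "kept"
  excluded <- intersect(sig, exclude)
  reason[excluded] <- "excluded"
  sig <- setdiff(sig, excluded)

  if (length(sig)) {
    cand <- dataset[match(sig, dataset$snp), c("snp", "chrom", "pos", "pvalue")]
    kept <- ld_clump(cand, ld, config)
    reason[setdiff(sig, kept)] <- "clumped"
    sig <- kept
  }

  idx <- match(dataset$snp, dataset$snp)
  use_eaf <- switch(config$r2_mode,
                    "from-eaf" = TRUE,
                    "from-f" = FALSE,
                    "auto" = !anyNA(dataset$eaf))
  r2 <- if (use_eaf)
    compute_r2(dataset$beta, eaf = dataset$eaf, mode = "from-eaf")
  else
    compute_r2(dataset$beta, se = dataset$se, n = dataset$n, mode = "from-f")
  r2 <- pmin(r2, 1 - 1e-12)
  f <- f_statistic(r2, pmax(dataset$n, 3))

  weak <- dataset$snp[dataset$snp %in% sig][
    f[match(sig, dataset$snp)] < config$f_threshold]
  reason[weak] <- "weak-instrument"
  sig <- setdiff(sig, weak)

  report <- data.frame(snp = dataset$snp, pvalue = dataset$pvalue,
                       r2_explained = r2, f_stat = f,
                       selected = dataset$snp %in% sig,
                       reason = reason[dataset$snp],
                       stringsAsFactors = FALSE)
  report <- report[order(report$pvalue, report$snp), ]
  rownames(report) <- NULL
  list(snps = sig, report = report)
}
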