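#' Default column mapping for GWAS summary-statistic files
#'
#' Maps internal field names to the column headers most summary-statistic
#' distributions use. Override individual entries when reading files with a
#' different dialect, e.g. `default_column_map(snp = "rsid", pvalue = "pval")`.
#'
#' @param ... named overrides; names must be internal field names
#'   (`snp`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pvalue`, `n`).
#' @return Named character vector mapping internal fields to file columns.
#' @export
default_column_map <- function(...) {
  map <- c(snp = "SNP", chrom = "CHR", pos = "BP",
           effect_allele = "A1", other_allele = "A2",
           eaf = "EAF", beta = "BETA", se = "SE", pvalue = "P", n = "N")
  over <- c(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(map))
    if (length(bad)) stopf("unknown column-map field(s): %s", paste(bad, collapse = ", "))
    map[names(over)] <- over
  }
  map
}

.mandatory_fields <- c("snp", "effect_allele", "other_allele", "beta", "se", "pvalue")

#' Construct a validated summary-statistics dataset
#'
#' Applies the per-record invariants (positive SE, single-base alleles,
#' p in (0,1]) and drops violating rows with a per-reason count kept in the
#' `drop_log` attribute. Out-of-range effect-allele frequencies are set to
#' missing rather than dropping the record; missing per-record sample sizes
#' are back-filled with `n_default`.
#'
#' @param df data.frame with columns `snp`, `effect_allele`, `other_allele`,
#'   `beta`, `se`, `pvalue` and optionally `chrom`, `pos`, `eaf`, `n`.
#' @param trait_id label for the trait.
#' @param trait_type `"quantitative"` or `"binary"` (binary betas are
#'   log odds ratios).
#' @param n_default sample size used where a record has none.
#' @return A `mr_summary` data.frame with attributes `trait_id`,
#'   `trait_type`, `n_default`, `drop_log`.
#' @export
summary_dataset <- function(df, trait_id, trait_type = c("quantitative", "binary"),
                            n_default = NA_real_) {
  trait_type <- match.arg(trait_type)
  if (!is.data.frame(df) || nrow(df) == 0L) stopf("empty summary dataset for trait '%s'", trait_id)
  miss <- setdiff(.mandatory_fields, names(df))
  if (length(miss)) stopf("missing mandatory column(s): %s", paste(miss, collapse = ", "))
  for (f in c("chrom", "pos", "eaf", "n")) if (is.null(df[[f]])) df[[f]] <- NA
  df <- df[c("snp", "chrom", "pos", "effect_allele", "other_allele",
             "eaf", "beta", "se", "pvalue", "n")]
  df$snp <- as.character(df$snp)
  df$chrom <- as.character(df$chrom)
  for (f in c("pos", "eaf", "beta", "se", "pvalue", "n")) df[[f]] <- as.numeric(df[[f]])
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))

  drop_log <- c(bad_se = 0L, bad_beta = 0L, bad_allele = 0L, bad_pvalue = 0L,
                duplicate_snp = 0L)
  ok_allele <- df$effect_allele %in% c("A", "C", "G", "T") &
    df$other_allele %in% c("A", "C", "G", "T") &
    df$effect_allele != df$other_allele
  bad <- !ok_allele
  drop_log["bad_allele"] <- sum(bad)
  sel <- ok_allele
  bad_se <- !is.finite(df$se) | df$se <= 0
  drop_log["bad_se"] <- sum(bad_se & sel)
  sel <- sel & !bad_se
  bad_beta <- !is.finite(df$beta)
  drop_log["bad_beta"] <- sum(bad_beta & sel)
  sel <- sel & !bad_beta
  bad_p <- !is.finite(df$pvalue) | df$pvalue <= 0 | df$pvalue > 1
  drop_log["bad_pvalue"] <- sum(bad_p & sel)
  sel <- sel & !bad_p
  df <- df[sel, , drop = FALSE]

  dup <- duplicated(df$snp)
  drop_log["duplicate_snp"] <- sum(dup)
  df <- df[!dup, , drop = FALSE]
  if (nrow(df) == 0L) stopf("no valid records left for trait '%s' (drops: %s)",
                            trait_id, paste(names(drop_log), drop_log, sep = "=", collapse = ", "))

  df$eaf[!is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1)] <- NA_real_
  df$n[is.na(df$n)] <- n_default
  # soft check: p should agree with |beta/se| under a two-sided normal test;
  # compared in log space so extreme z-scores do not underflow
  lpz <- stats::pnorm(-abs(df$beta / df$se), log.p = TRUE) + log(2)
  # stored p-values pinned near 0 (underflow) carry no consistency signal
  inconsistent <- df$pvalue > 1e-300 & is.finite(lpz) &
    abs(lpz - log(df$pvalue)) > log(10)
  if (any(inconsistent))
    warnf("%d record(s) in '%s' have p-values inconsistent with beta/se by >10x",
          sum(inconsistent), trait_id)

  rownames(df) <- NULL
  structure(df, trait_id = trait_id, trait_type = trait_type,
            n_default = n_default, drop_log = drop_log,
            class = c("mr_summary", "data.frame"))
}

detect_delim <- function(path) {
  line <- readLines(path, n = 1L, warn = FALSE)
  if (length(line) == 0L) stopf("empty file: %s", path)
  if (grepl("\t", line)) "\t" else if (grepl(",", line)) "," else ""
}

#' Read GWAS summary statistics from delimited text
#'
#' The delimiter is auto-detected among tab, comma and whitespace; a header
#' row is required. Columns are located through `column_map`, so files with
#' arbitrary column order or naming are supported.
#'
#' @inheritParams summary_dataset
#' @param path file path.
#' @param column_map named mapping from internal fields to file columns,
#'   see [default_column_map()].
#' @return A validated `mr_summary` dataset (see [summary_dataset()]).
#' @export
read_summary_stats <- function(path, column_map = default_column_map(),
                               trait_id = basename(path),
                               trait_type = c("quantitative", "binary"),
                               n_default = NA_real_) {
  if (!file.exists(path)) stopf("summary-statistics file not found: %s", path)
  sep <- detect_delim(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0L) stopf("no data rows in %s", path)
  miss <- setdiff(column_map[.mandatory_fields], names(raw))
  if (length(miss)) stopf("mandatory column(s) absent from %s: %s", path,
                          paste(miss, collapse = ", "))
  df <- data.frame(snp = raw[[column_map[["snp"]]]], stringsAsFactors = FALSE)
  for (f in setdiff(names(column_map), "snp")) {
    col <- column_map[[f]]
    df[[f]] <- if (col %in% names(raw)) raw[[col]] else NA
  }
  summary_dataset(df, trait_id = trait_id, trait_type = match.arg(trait_type),
                  n_default = n_default)
}

#' Write a summary-statistics dataset as TSV
#'
#' Emits the same dialect [read_summary_stats()] reads with the default
#' column map.
#'
#' @param dataset an `mr_summary` dataset.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(dataset, path) {
  out <- as.data.frame(dataset)
  names(out) <- c("SNP", "CHR", "BP", "A1", "A2", "EAF", "BETA", "SE", "P", "N")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize exposure and outcome summary statistics to a common effect allele
#'
#' For every requested SNP present in both datasets the outcome effect is
#' re-expressed relative to the exposure's effect allele: direct matches are
#' kept, swapped alleles flip the outcome beta and EAF, strand-complementary
#' records are relabelled first. Palindromic (A/T, C/G) SNPs cannot be
#' resolved from allele labels; they are aligned by comparing which side of
#' 0.5 each EAF falls on, and dropped when either EAF lies inside the
#' ambiguity window (or is missing).
#'
#' @param exposure,outcome `mr_summary` datasets.
#' @param snp_ids SNPs to harmonize (default: every exposure SNP).
#' @param palindrome_window EAF interval around 0.5 inside which palindromic
#'   alignment is considered undecidable.
#' @return An `mr_harmonized` data.frame of retained SNPs with columns
#'   `snp`, `beta_exp`, `se_exp`, `eaf_exp`, `beta_out`, `se_out`, `eaf_out`,
#'   `action`; dropped SNPs (with reasons) are kept in the `dropped`
#'   attribute, trait labels in `exposure_id`/`outcome_id`.
#' @export
harmonize <- function(exposure, outcome, snp_ids = NULL,
                      palindrome_window = c(0.42, 0.58)) {
  stopifnot(length(palindrome_window) == 2L, palindrome_window[1] <= palindrome_window[2])
  if (is.null(snp_ids)) snp_ids <- exposure$snp
  if (!all(snp_ids %in% exposure$snp))
    stopf("snp_ids absent from exposure: %s",
          paste(utils::head(setdiff(snp_ids, exposure$snp), 5), collapse = ", "))
  ei <- match(snp_ids, exposure$snp)
  oi <- match(snp_ids, outcome$snp)

  n <- length(snp_ids)
  action <- character(n)
  beta_out <- se_out <- eaf_out <- rep(NA_real_, n)

  for (i in seq_len(n)) {
    ex <- exposure[ei[i], ]
    if (is.na(oi[i])) { action[i] <- "dropped-missing"; next }
    ou <- outcome[oi[i], ]
    a1 <- ex$effect_allele; a2 <- ex$other_allele
    b1 <- ou$effect_allele; b2 <- ou$other_allele
    pal <- is_palindromic(a1, a2)

    if (pal) {
      # labels cannot distinguish strands; both orders look compatible
      if (!((b1 == a1 && b2 == a2) || (b1 == a2 && b2 == a1) ||
            (b1 == COMPLEMENT[a1] && b2 == COMPLEMENT[a2]) ||
            (b1 == COMPLEMENT[a2] && b2 == COMPLEMENT[a1]))) {
        action[i] <- "dropped-mismatch"; next
      }
      f_exp <- ex$eaf
      f_out <- if (b1 == a1 || b1 == COMPLEMENT[a1]) ou$eaf else 1 - ou$eaf
      ambiguous <- function(f) is.na(f) ||
        (f > palindrome_window[1] && f < palindrome_window[2])
      if (ambiguous(f_exp) || ambiguous(f_out)) {
        action[i] <- "dropped-palindromic"; next
      }
      if ((f_exp < 0.5) == (f_out < 0.5)) {
        action[i] <- "kept"
        beta_out[i] <- ou$beta; eaf_out[i] <- f_out
      } else {
        action[i] <- "flipped"
        beta_out[i] <- -ou$beta; eaf_out[i] <- 1 - f_out
      }
      se_out[i] <- ou$se
      next
    }

    strand <- FALSE
    if (!((b1 %in% c(a1, a2)) && (b2 %in% c(a1, a2)))) {
      # try the opposite strand
      b1c <- COMPLEMENT[[b1]]; b2c <- COMPLEMENT[[b2]]
      if ((b1c %in% c(a1, a2)) && (b2c %in% c(a1, a2))) {
        b1 <- b1c; b2 <- b2c; strand <- TRUE
      } else { action[i] <- "dropped-mismatch"; next }
    }
    if (b1 == a1 && b2 == a2) {
      action[i] <- if (strand) "strand-corrected" else "kept"
      beta_out[i] <- ou$beta; eaf_out[i] <- ou$eaf
    } else if (b1 == a2 && b2 == a1) {
      action[i] <- if (strand) "strand-corrected" else "flipped"
      beta_out[i] <- -ou$beta
      eaf_out[i] <- if (is.na(ou$eaf)) NA_real_ else 1 - ou$eaf
    } else {
      action[i] <- "dropped-mismatch"; next
    }
    se_out[i] <- ou$se
  }

  keep <- !startsWith(action, "dropped")
  res <- data.frame(snp = snp_ids[keep],
                    beta_exp = exposure$beta[ei[keep]],
                    se_exp = exposure$se[ei[keep]],
                    eaf_exp = exposure$eaf[ei[keep]],
                    beta_out = beta_out[keep],
                    se_out = se_out[keep],
                    eaf_out = eaf_out[keep],
                    action = action[keep],
                    stringsAsFactors = FALSE)
  dropped <- data.frame(snp = snp_ids[!keep], action = action[!keep],
                        stringsAsFactors = FALSE)
  if (nrow(res) == 0L) {
    counts <- table(dropped$action)
    stopf("no SNPs retained after harmonization (%s)",
          paste(names(counts), counts, sep = ": ", collapse = ", "))
  }
  rownames(res) <- NULL
  structure(res,
            exposure_id = attr(exposure, "trait_id") %||% "exposure",
            outcome_id = attr(outcome, "trait_id") %||% "outcome",
            dropped = dropped,
            class = c("mr_harmonized", "data.frame"))
}

#' Harmonization report as a data.frame
#'
#' One row per input SNP (retained and dropped) with the action taken and,
#' for retained SNPs, the final harmonized effects.
#'
#' @param h an `mr_harmonized` set.
#' @return data.frame with columns `snp`, `action`, `beta_exp`, `se_exp`,
#'   `beta_out`, `se_out`.
#' @export
harmonization_report <- function(h) {
  kept <- data.frame(snp = h$snp, action = h$action,
                     beta_exp = h$beta_exp, se_exp = h$se_exp,
                     beta_out = h$beta_out, se_out = h$se_out,
                     stringsAsFactors = FALSE)
  dropped <- attr(h, "dropped")
  if (nrow(dropped)) {
    dropped <- data.frame(snp = dropped$snp, action = dropped$action,
                          beta_exp = NA_real_, se_exp = NA_real_,
                          beta_out = NA_real_, se_out = NA_real_,
                          stringsAsFactors = FALSE)
    kept <- rbind(kept, dropped)
  }
  kept
}
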