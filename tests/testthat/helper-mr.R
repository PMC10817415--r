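# shared fixtures, built in code

# minimal harmonized instrument set from effect vectors
h_set <- function(bx, by, sy, sx = rep(1e-6, length(bx)),
                  snp = sprintf("rs%03d", seq_along(bx))) {
  structure(
    data.frame(snp = snp, beta_exp = bx, se_exp = sx, eaf_exp = 0.3,
               beta_out = by, se_out = sy, eaf_out = 0.3, action = "kept",
               stringsAsFactors = FALSE),
    exposure_id = "X", outcome_id = "Y",
    dropped = data.frame(snp = character(), action = character(),
                         stringsAsFactors = FALSE),
    class = c("mr_harmonized", "data.frame"))
}

# random harmonized set for property tests
random_h <- function(k, seed) {
  set.seed(seed)
  h_set(bx = stats::runif(k, 0.2, 1) * sample(c(-1, 1), k, replace = TRUE),
        by = stats::rnorm(k, 0.1, 0.2),
        sy = stats::runif(k, 0.02, 0.2),
        sx = stats::runif(k, 0.01, 0.05))
}

# small summary dataset builder with sensible defaults
toy_dataset <- function(snp, beta, se, pvalue = NULL,
                        chrom = "1", pos = seq_along(snp) * 2e7,
                        ea = "A", oa = "G", eaf = 0.3, n = 10000,
                        trait_id = "trait", trait_type = "quantitative") {
  if (is.null(pvalue)) pvalue <- 2 * stats::pnorm(-abs(beta / se))
  # arbitrary p-values are a feature here; silence the consistency warning
  suppressWarnings(summary_dataset(
    data.frame(snp = snp, chrom = chrom, pos = pos,
               effect_allele = ea, other_allele = oa, eaf = eaf,
               beta = beta, se = se, pvalue = pvalue, n = n,
               stringsAsFactors = FALSE),
    trait_id = trait_id, trait_type = trait_type, n_default = n[1]))
}

# default-dialect summary-stat file on disk
write_toy_tsv <- function(df, path = tempfile(fileext = ".tsv"), sep = "\t") {
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

# exposure/outcome pair generated under a known causal effect, for
# estimator consistency checks
consistent_pair <- function(k, theta, noise, seed) {
  set.seed(seed)
  bx <- stats::runif(k, 0.3, 1)
  sx <- rep(noise / 3, k)
  sy <- rep(noise, k)
  h_set(bx = stats::rnorm(k, bx, sx), by = stats::rnorm(k, theta * bx, sy),
        sy = sy, sx = sx)
}
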