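# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures.

# A minimal valid sumstats data.frame; override any column via ...
make_sumstats_df <- function(n = 5, ...) {
  df <- data.frame(
    snp = sprintf("rs%d", seq_len(n)),
    chr = rep("9", n),
    pos = 104700000 + seq_len(n) * 1000,
    effect_allele = rep(c("A", "G", "C", "T", "A"), length.out = n),
    other_allele = rep(c("G", "A", "A", "C", "C"), length.out = n),
    eaf = seq(0.1, 0.45, length.out = n),
    beta = seq(-0.2, 0.2, length.out = n),
    se = rep(0.05, n),
    pval = rep(1e-8, n),
    n = rep(10000, n),
    stringsAsFactors = FALSE
  )
  over <- list(...)
  for (nm in names(over)) df[[nm]] <- over[[nm]]
  df
}

make_sumstats <- function(n = 5, trait_id = "trait", trait_type = "quantitative", ...) {
  mrpath::sumstats(make_sumstats_df(n, ...), trait_id = trait_id,
                   trait_type = trait_type)
}

# Build a harmonized set directly from effect vectors.
make_h <- function(beta_exp, beta_out, se_exp = rep(0.02, length(beta_exp)),
                   se_out = rep(1, length(beta_out)),
                   snp = sprintf("rs%d", seq_along(beta_exp))) {
  rows <- data.frame(snp = snp, chr = "9",
                     pos = 1e6 + seq_along(beta_exp) * 1000,
                     effect_allele = "A", other_allele = "G",
                     beta_exp = beta_exp, se_exp = se_exp,
                     beta_out = beta_out, se_out = se_out,
                     eaf_exp = 0.3, eaf_out = 0.3,
                     stringsAsFactors = FALSE)
  mrpath:::new_harmonized_set(rows, "exposure_test", "outcome_test")
}

# Harmonize the true instruments of a simulated triplet against one of
# its downstream tables, bypassing statistical selection (the truth file
# is the oracle for which SNPs are instruments).
harmonize_truth <- function(sim, against = c("outcome", "mediator")) {
  against <- match.arg(against)
  keep <- as.data.frame(sim$exposure)
  keep <- keep[keep$snp %in% sim$truth$instruments, ]
  ex <- mrpath::sumstats(keep, trait_id = "exposure_sim")
  mrpath::harmonize(ex, sim[[against]])
}
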