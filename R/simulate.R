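# Synthetic GWAS/eQTL summary-statistics generator with known ground
# truth, emulating a cis-eQTL exposure, a quantitative circulating-
# metabolite mediator, and a rare binary disease outcome.

NONPALINDROMIC_PAIRS <- list(c("A", "G"), c("A", "C"), c("T", "G"),
                             c("T", "C"), c("G", "A"), c("C", "A"),
                             c("G", "T"), c("C", "T"))
PALINDROMIC_PAIRS <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

#' Simulation scenario for the mediated causal chain
#'
#' Defines the study conditions for the generator: instrument counts,
#' GWAS sample sizes, the true path coefficients of the mediated chain
#' (exposure -> mediator -> outcome plus a direct path), instrument
#' strength, pleiotropy, LD-block structure and allele content. The
#' default path coefficients are calibrated so the true odds ratios of
#' the three legs are 0.917 (exposure -> mediator, per SD), 2.0499
#' (mediator -> outcome) and 0.4957 (total exposure -> outcome), with
#' GWAS sizes 31,684 (eQTL exposure), 118,000 (metabolite) and 317,252
#' (outcome, ~1\% cases).
#'
#' @param seed default seed carried in the scenario (overridable at
#'   generation time).
#' @param n_snp true cis instruments (default 30).
#' @param n_null_snp non-instrument cis SNPs (default 200).
#' @param gene_region list(chrom, start, end) for the target gene.
#' @param n_exp,n_med,n_out GWAS sample sizes for the three studies.
#' @param case_fraction case proportion of the binary outcome GWAS; scales
#'   the outcome SEs as 1/sqrt(2 n v p(1-p)).
#' @param beta1 true exposure -> mediator effect (log/SD scale).
#' @param beta2 true mediator -> outcome effect (log-odds per SD).
#' @param beta_direct true direct exposure -> outcome effect; the default
#'   makes the total effect equal log(0.4957).
#' @param instrument_strength c(z_min, z_max): per-instrument |Z| for the
#'   true effect relative to its SE is uniform on this range, so F-values
#'   fall in [z_min^2, z_max^2].
#' @param pleiotropy list(frac, mean, sd): fraction of instruments given
#'   direct (non-mediated) effects, drawn N(mean, sd) independently for
#'   the mediator and the outcome side.
#' @param ld_blocks list(block_size, r2): instruments are grouped into
#'   blocks of this size whose true effects and sampling errors are
#'   correlated at sqrt(r2); block size 1 means independent instruments.
#' @param palindrome_fraction fraction of SNPs given A/T or C/G alleles.
#' @param maf_range effect-allele frequencies are uniform on this range.
#' @param flip_fraction fraction of mediator/outcome rows reported on the
#'   swapped allele (beta negated, frequency complemented), exercising
#'   harmonization.
#' @param n_snp_med instruments for the mediator's own GWAS (used by
#'   \code{\link{simulate_mediation_study}}).
#' @return a \code{sim_scenario} list.
#' @export
sim_scenario <- function(seed = NULL,
                         n_snp = 30, n_null_snp = 200,
                         gene_region = list(chrom = "9", start = 104700000,
                                            end = 104850000),
                         n_exp = 31684, n_med = 118000, n_out = 317252,
                         case_fraction = 0.01,
                         beta1 = log(0.917), beta2 = log(2.0499),
                         beta_direct = log(0.4957) - log(0.917) * log(2.0499),
                         instrument_strength = c(z_min = 5, z_max = 9),
                         pleiotropy = list(frac = 0, mean = 0, sd = 0),
                         ld_blocks = list(block_size = 1, r2 = 0.8),
                         palindrome_fraction = 0.1,
                         maf_range = c(0.05, 0.5),
                         flip_fraction = 0.3,
                         n_snp_med = 30) {
  stopifnot(n_snp >= 1, n_null_snp >= 0, n_exp > 0, n_med > 0, n_out > 0,
            case_fraction > 0, case_fraction < 1,
            pleiotropy$frac >= 0, pleiotropy$frac <= 1,
            ld_blocks$block_size >= 1, ld_blocks$r2 >= 0, ld_blocks$r2 <= 1,
            palindrome_fraction >= 0, palindrome_fraction <= 1,
            length(maf_range) == 2, all(maf_range > 0), all(maf_range < 1))
  structure(list(seed = seed, n_snp = n_snp, n_null_snp = n_null_snp,
                 gene_region = gene_region, n_exp = n_exp, n_med = n_med,
                 n_out = n_out, case_fraction = case_fraction,
                 beta1 = beta1, beta2 = beta2, beta_direct = beta_direct,
                 instrument_strength = instrument_strength,
                 pleiotropy = pleiotropy, ld_blocks = ld_blocks,
                 palindrome_fraction = palindrome_fraction,
                 maf_range = maf_range, flip_fraction = flip_fraction,
                 n_snp_med = n_snp_med),
            class = "sim_scenario")
}

#' Scenario calibrated to the published drug-target analysis
#'
#' The default scenario with the allele-content nuisance switched off
#' (no palindromes, independent instruments), so that all 30 instruments
#' survive selection and the analyzed set size matches the published
#' exposure -> outcome analysis. True ORs for the three legs are 0.917,
#' 2.0499 and 0.4957; the implied true proportion mediated is
#' 100 * beta1 * beta2 / total = 8.86\%.
#'
#' @param seed optional default seed.
#' @return a \code{sim_scenario}.
#' @export
paper_like_scenario <- function(seed = NULL) {
  sim_scenario(seed = seed, palindrome_fraction = 0,
               ld_blocks = list(block_size = 1, r2 = 0.8))
}

# Per-SNP SE of a standardized-trait GWAS beta.
se_quant <- function(n, eaf) 1 / sqrt(2 * n * eaf * (1 - eaf))
# Log-odds SE for a binary GWAS with case fraction v.
se_binary <- function(n, v, eaf) 1 / sqrt(2 * n * v * eaf * (1 - eaf))

draw_alleles <- function(m, palindrome_fraction) {
  pal <- stats::runif(m) < palindrome_fraction
  pick <- function(pairs, k) {
    idx <- sample.int(length(pairs), k, replace = TRUE)
    do.call(rbind, pairs[idx])
  }
  ea <- character(m); oa <- character(m)
  if (any(pal)) {
    p <- pick(PALINDROMIC_PAIRS, sum(pal))
    ea[pal] <- p[, 1]; oa[pal] <- p[, 2]
  }
  if (any(!pal)) {
    p <- pick(NONPALINDROMIC_PAIRS, sum(!pal))
    ea[!pal] <- p[, 1]; oa[!pal] <- p[, 2]
  }
  data.frame(effect_allele = ea, other_allele = oa, palindromic = pal,
             stringsAsFactors = FALSE)
}

# Equicorrelated standard normals within blocks (corr = rho), iid across
# blocks; block 0 or NA means independent.
block_normals <- function(block, rho) {
  m <- length(block)
  z <- stats::rnorm(m)
  if (rho <= 0) return(z)
  for (b in unique(block[!is.na(block) & block > 0])) {
    idx <- which(block == b)
    if (length(idx) < 2) next
    z0 <- stats::rnorm(1)
    z[idx] <- sqrt(rho) * z0 + sqrt(1 - rho) * z[idx]
  }
  z
}

# Assemble one study's observed sumstats table, optionally reporting a
# fraction of rows on the swapped allele.
build_study_table <- function(snps, true_beta, se, n, trait_id, trait_type,
                              block, rho, flip_fraction) {
  eps <- block_normals(block, rho) * se
  beta <- true_beta + eps
  flip <- stats::runif(nrow(snps)) < flip_fraction
  df <- data.frame(snp = snps$snp, chr = snps$chr, pos = snps$pos,
                   effect_allele = ifelse(flip, snps$other_allele,
                                          snps$effect_allele),
                   other_allele = ifelse(flip, snps$effect_allele,
                                         snps$other_allele),
                   eaf = ifelse(flip, 1 - snps$eaf, snps$eaf),
                   beta = ifelse(flip, -beta, beta), se = se,
                   # floor against underflow for extreme z-scores
                   pval = pmax(2 * stats::pnorm(-abs(beta / se)),
                               .Machine$double.xmin),
                   n = n, stringsAsFactors = FALSE)
  sumstats(df, trait_id = trait_id, trait_type = trait_type)
}

make_cis_snps <- function(s) {
  m <- s$n_snp + s$n_null_snp
  gr <- s$gene_region
  pos_instr <- round(stats::runif(s$n_snp, gr$start, gr$end))
  pos_null <- if (s$n_null_snp > 0)
    round(stats::runif(s$n_null_snp, gr$start - 1.5e5, gr$end + 1.5e5))
  else numeric(0)
  al <- draw_alleles(m, s$palindrome_fraction)
  B <- s$ld_blocks$block_size
  block <- c(if (B > 1) rep(seq_len(ceiling(s$n_snp / B)), each = B)[seq_len(s$n_snp)]
             else rep(0L, s$n_snp),
             rep(0L, s$n_null_snp))
  pos <- c(pos_instr, pos_null)
  # co-locate LD-block members so they fall within the clumping window
  if (B > 1) for (b in unique(block[block > 0])) {
    idx <- which(block == b)
    pos[idx] <- pos[idx[1]] + c(0, round(stats::runif(length(idx) - 1, 1, 2e4)))
  }
  data.frame(snp = sprintf("rs9%06d", seq_len(m)), chr = gr$chrom, pos = pos,
             effect_allele = al$effect_allele, other_allele = al$other_allele,
             eaf = stats::runif(m, s$maf_range[1], s$maf_range[2]),
             palindromic = al$palindromic,
             is_instrument = c(rep(TRUE, s$n_snp), rep(FALSE, s$n_null_snp)),
             block = block, stringsAsFactors = FALSE)
}

ld_table_from_blocks <- function(snps, r2) {
  pairs <- list()
  for (b in unique(snps$block[snps$block > 0])) {
    ids <- snps$snp[snps$block == b]
    if (length(ids) < 2) next
    cmb <- utils::combn(ids, 2)
    pairs[[length(pairs) + 1]] <- data.frame(snp_a = cmb[1, ], snp_b = cmb[2, ],
                                             r2 = r2, stringsAsFactors = FALSE)
  }
  ld_table(if (length(pairs)) do.call(rbind, pairs) else
    data.frame(snp_a = character(), snp_b = character(), r2 = numeric()))
}

#' Simulate an exposure/mediator/outcome summary-statistics triplet
#'
#' Generates one realization of the mediated chain at the cis locus.
#' Per SNP: frequency ~ U(maf_range); SEs follow the standardized-trait
#' (exposure, mediator) and rare-binary (outcome) formulas at the
#' scenario's sample sizes; true instrument effects gamma_j have
#' |gamma/se| uniform on the instrument-strength range with random sign
#' (null SNPs get 0); the mediator's true effect is beta1 * gamma plus a
#' pleiotropy term, the outcome's is beta_direct * gamma + beta2 * (true
#' mediator effect) plus outcome-side pleiotropy. Observed betas add
#' study-specific noise, correlated within LD blocks at sqrt(r2); LD-block
#' members also share (attenuated) true effects, mimicking tagging. The
#' mediator and outcome tables report a fraction of rows on the swapped
#' allele so harmonization is exercised.
#'
#' @param s a \code{\link{sim_scenario}}.
#' @param seed RNG seed (defaults to the scenario's); same seed, same
#'   scenario gives byte-identical output.
#' @return list with \code{exposure}, \code{mediator}, \code{outcome}
#'   (\code{sumstats}), \code{ld} (\code{ld_table}) and \code{truth}
#'   (per-SNP truth data.frame plus true path coefficients and the true
#'   proportion mediated).
#' @export
simulate_triplet <- function(s, seed = s$seed) {
  stopifnot(inherits(s, "sim_scenario"))
  with_seed(seed, {
    snps <- make_cis_snps(s)
    m <- nrow(snps)
    se_x <- se_quant(s$n_exp, snps$eaf)
    se_m <- se_quant(s$n_med, snps$eaf)
    se_y <- se_binary(s$n_out, s$case_fraction, snps$eaf)

    zr <- s$instrument_strength
    z <- stats::runif(m, zr[["z_min"]], zr[["z_max"]]) *
      sample(c(-1, 1), m, replace = TRUE)
    gamma <- ifelse(snps$is_instrument, z * se_x, 0)
    # tagged signals: block members carry the lead effect attenuated by r
    rho <- sqrt(s$ld_blocks$r2)
    for (b in unique(snps$block[snps$block > 0])) {
      idx <- which(snps$block == b)
      if (length(idx) > 1) gamma[idx[-1]] <- rho * gamma[idx[1]]
    }

    # pleiotropic effects are directional relative to the exposure-
    # increasing allele (the convention under which a nonzero mean is
    # detectable as an Egger intercept), hence the sign(gamma) factor
    pleio <- s$pleiotropy
    has_pleio <- snps$is_instrument & stats::runif(m) < pleio$frac
    dir <- ifelse(gamma < 0, -1, 1)
    alpha_m <- ifelse(has_pleio, stats::rnorm(m, pleio$mean, pleio$sd), 0) * dir
    alpha_y <- ifelse(has_pleio, stats::rnorm(m, pleio$mean, pleio$sd), 0) * dir

    true_med <- s$beta1 * gamma + alpha_m
    true_out <- s$beta_direct * gamma + s$beta2 * true_med + alpha_y

    exposure <- build_study_table(snps, gamma, se_x, s$n_exp, "exposure_sim",
                                  "quantitative", snps$block, rho, 0)
    mediator <- build_study_table(snps, true_med, se_m, s$n_med,
                                  "mediator_sim", "quantitative", snps$block,
                                  rho, s$flip_fraction)
    outcome <- build_study_table(snps, true_out, se_y, s$n_out, "outcome_sim",
                                 "binary", snps$block, rho, s$flip_fraction)
    total <- s$beta_direct + s$beta1 * s$beta2
    truth <- list(per_snp = data.frame(snps,
                                       gamma = gamma, alpha_m = alpha_m,
                                       alpha_y = alpha_y,
                                       stringsAsFactors = FALSE),
                  beta1 = s$beta1, beta2 = s$beta2,
                  beta_direct = s$beta_direct, total = total,
                  proportion_pct = 100 * s$beta1 * s$beta2 / total,
                  instruments = snps$snp[snps$is_instrument],
                  seed = seed)
    list(exposure = exposure, mediator = mediator, outcome = outcome,
         ld = ld_table_from_blocks(snps, s$ld_blocks$r2), truth = truth)
  })
}

#' Simulate a full two-step mediation study
#'
#' Extends \code{\link{simulate_triplet}} with an independent instrument
#' set for the mediator's own GWAS (a second locus on another chromosome,
#' widely spaced, so it is independent of the cis locus), allowing both
#' mediation steps to be estimated: step 1 from the cis instruments
#' against the mediator, step 2 from the mediator's instruments against
#' the outcome (true per-SNP outcome effect beta2 * delta_j). The
#' exposure, mediator and outcome tables each cover the union of both
#' SNP sets, so the tables can also feed the MVMR design.
#'
#' @inheritParams simulate_triplet
#' @return the \code{simulate_triplet} list, with tables extended to the
#'   mediator-instrument SNPs and \code{truth$med_instruments} naming them.
#' @export
simulate_mediation_study <- function(s, seed = s$seed) {
  trip <- simulate_triplet(s, seed)
  with_seed(if (is.null(seed)) NULL else seed + 1000L, {
    k <- s$n_snp_med
    al <- draw_alleles(k, s$palindrome_fraction)
    snps <- data.frame(snp = sprintf("rs2%06d", seq_len(k)), chr = "2",
                       pos = 10e6 + seq_len(k) * 2e6,
                       effect_allele = al$effect_allele,
                       other_allele = al$other_allele,
                       eaf = stats::runif(k, s$maf_range[1], s$maf_range[2]),
                       palindromic = al$palindromic, is_instrument = TRUE,
                       block = 0L, stringsAsFactors = FALSE)
    se_x <- se_quant(s$n_exp, snps$eaf)
    se_m <- se_quant(s$n_med, snps$eaf)
    se_y <- se_binary(s$n_out, s$case_fraction, snps$eaf)
    zr <- s$instrument_strength
    delta <- stats::runif(k, zr[["z_min"]], zr[["z_max"]]) * se_m *
      sample(c(-1, 1), k, replace = TRUE)

    exp_b <- build_study_table(snps, 0, se_x, s$n_exp, "exposure_sim",
                               "quantitative", snps$block, 0, 0)
    med_b <- build_study_table(snps, delta, se_m, s$n_med, "mediator_sim",
                               "quantitative", snps$block, 0, s$flip_fraction)
    out_b <- build_study_table(snps, s$beta2 * delta, se_y, s$n_out,
                               "outcome_sim", "binary", snps$block, 0,
                               s$flip_fraction)
    bind <- function(a, b) sumstats(rbind(as.data.frame(a), as.data.frame(b)),
                                    trait_id = attr(a, "trait_id"),
                                    trait_type = attr(a, "trait_type"))
    trip$exposure <- bind(trip$exposure, exp_b)
    trip$mediator <- bind(trip$mediator, med_b)
    trip$outcome <- bind(trip$outcome, out_b)
    trip$truth$med_instruments <- snps$snp
    trip$truth$delta <- delta
    trip
  })
}

#' Simulate a battery of candidate mediator GWAS tables
#'
#' Emulates screening a panel of circulating metabolites: a shared cis
#' locus (exposure as in \code{simulate_triplet}) and one mediator table
#' per candidate, of which \code{n_true} have a real exposure -> mediator
#' effect with |beta1| uniform on \code{effect_range} and sign negative
#' with probability \code{prob_negative}; the rest are null.
#'
#' @param s a \code{\link{sim_scenario}}.
#' @param n_mediators number of candidate mediators (default 123).
#' @param n_true number with real effects (default 36).
#' @param effect_range range of |beta1| for true mediators.
#' @param prob_negative probability a true effect is negative.
#' @param seed RNG seed.
#' @return list: \code{exposure} (sumstats), \code{mediators} (named list
#'   of sumstats), \code{truth} (data.frame mediator, beta1),
#'   \code{instruments} (cis instrument ids).
#' @export
simulate_mediator_battery <- function(s, n_mediators = 123, n_true = 36,
                                      effect_range = c(0.06, 0.12),
                                      prob_negative = 29 / 35,
                                      seed = s$seed) {
  stopifnot(n_true <= n_mediators)
  with_seed(seed, {
    snps <- make_cis_snps(s)
    se_x <- se_quant(s$n_exp, snps$eaf)
    se_m <- se_quant(s$n_med, snps$eaf)
    zr <- s$instrument_strength
    z <- stats::runif(nrow(snps), zr[["z_min"]], zr[["z_max"]]) *
      sample(c(-1, 1), nrow(snps), replace = TRUE)
    gamma <- ifelse(snps$is_instrument, z * se_x, 0)
    exposure <- build_study_table(snps, gamma, se_x, s$n_exp, "exposure_sim",
                                  "quantitative", snps$block, 0, 0)
    beta1 <- numeric(n_mediators)
    true_idx <- sample.int(n_mediators, n_true)
    signs <- ifelse(stats::runif(n_true) < prob_negative, -1, 1)
    beta1[true_idx] <- signs * stats::runif(n_true, effect_range[1],
                                            effect_range[2])
    ids <- sprintf("metabolite_%03d", seq_len(n_mediators))
    mediators <- stats::setNames(lapply(seq_len(n_mediators), function(k) {
      build_study_table(snps, beta1[k] * gamma, se_m, s$n_med, ids[k],
                        "quantitative", snps$block, 0, s$flip_fraction)
    }), ids)
    list(exposure = exposure, mediators = mediators,
         truth = data.frame(mediator = ids, beta1 = beta1,
                            stringsAsFactors = FALSE),
         instruments = snps$snp[snps$is_instrument])
  })
}

#' Write a simulated dataset to a directory
#'
#' Emits exposure.tsv, mediator.tsv, outcome.tsv, ld.tsv and truth.json.
#'
#' @param sim a list from \code{\link{simulate_triplet}} or
#'   \code{\link{simulate_mediation_study}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_sumstats(sim$exposure, file.path(dir, "exposure.tsv"))
  write_sumstats(sim$mediator, file.path(dir, "mediator.tsv"))
  write_sumstats(sim$outcome, file.path(dir, "outcome.tsv"))
  utils::write.table(as.data.frame(sim$ld), file.path(dir, "ld.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$per_snp <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(sim$truth$per_snp, file.path(dir, "truth_per_snp.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
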