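# Ground-truth summary-statistics generator.

test_that("same seed gives byte-identical simulated files", {
  dir <- withr::local_tempdir()
  s <- sim_scenario(n_snp = 10, n_null_snp = 20)
  write_simulation(simulate_triplet(s, seed = 7), file.path(dir, "a"))
  write_simulation(simulate_triplet(s, seed = 7), file.path(dir, "b"))
  for (f in c("exposure.tsv", "mediator.tsv", "outcome.tsv", "ld.tsv",
              "truth.json")) {
    expect_identical(readLines(file.path(dir, "a", f)),
                     readLines(file.path(dir, "b", f)), label = f)
  }
  # and a different seed gives different data
  write_simulation(simulate_triplet(s, seed = 8), file.path(dir, "c"))
  expect_false(identical(readLines(file.path(dir, "a", "exposure.tsv")),
                         readLines(file.path(dir, "c", "exposure.tsv"))))
})

test_that("standard errors follow the stated sample-size formulas", {
  s <- paper_like_scenario()
  sim <- simulate_triplet(s, seed = 9)
  ex <- as.data.frame(sim$exposure)
  expect_equal(ex$se, 1 / sqrt(2 * s$n_exp * ex$eaf * (1 - ex$eaf)))
  md <- as.data.frame(sim$mediator)
  expect_equal(md$se, 1 / sqrt(2 * s$n_med * md$eaf * (1 - md$eaf)))
  ot <- as.data.frame(sim$outcome)
  expect_equal(ot$se, 1 / sqrt(2 * s$n_out * s$case_fraction *
                                 ot$eaf * (1 - ot$eaf)))
  # selected instruments are strong: F well above the weak cutoff
  keep <- ex[ex$snp %in% sim$truth$instruments, ]
  expect_gt(mean(f_statistic(keep$beta, keep$se)), 30)
})

test_that("palindrome fraction is realized and palindromes never survive selection", {
  s <- sim_scenario(n_snp = 30, n_null_snp = 200, palindrome_fraction = 0.1)
  sim <- simulate_triplet(s, seed = 23)
  ex <- as.data.frame(sim$exposure)
  n_pal <- sum(is_palindromic(ex$effect_allele, ex$other_allele))
  # ~Binomial(230, 0.1): stay within a generous +/-4 sd band of 23
  expect_gt(n_pal, 23 - 4 * sqrt(230 * 0.1 * 0.9))
  expect_lt(n_pal, 23 + 4 * sqrt(230 * 0.1 * 0.9))
  sel <- select_instruments(sim$exposure, ld = sim$ld)
  expect_false(any(is_palindromic(sel$kept$effect_allele,
                                  sel$kept$other_allele)))
})

test_that("downstream IVW recovers the true total effect within 3 SE", {
  s <- paper_like_scenario()
  sim <- simulate_triplet(s, seed = 25)
  est <- mr_ivw(harmonize_truth(sim, "outcome"))
  expect_lt(abs(est$beta - sim$truth$total), 3 * est$se)
  # and the exposure->mediator leg recovers beta1
  est1 <- mr_ivw(harmonize_truth(sim, "mediator"))
  expect_lt(abs(est1$beta - s$beta1), 3 * est1$se)
})

test_that("Monte-Carlo consistency: IVW is unbiased with well-calibrated SEs", {
  s <- paper_like_scenario()
  res <- t(vapply(1:300, function(i) {
    est <- mr_ivw(harmonize_truth(simulate_triplet(s, seed = 20000 + i),
                                  "outcome"))
    c(est$beta, est$se)
  }, numeric(2)))
  expect_lt(abs(mean(res[, 1]) - s$beta1 * s$beta2 - s$beta_direct), 0.02)
  # empirical spread of estimates matches the mean reported SE within 15%
  expect_lt(abs(sd(res[, 1]) - mean(res[, 2])) / sd(res[, 1]), 0.15)
})

test_that("LD blocks appear in the LD table and their truth is consistent", {
  s <- sim_scenario(n_snp = 12, n_null_snp = 0, palindrome_fraction = 0,
                    ld_blocks = list(block_size = 3, r2 = 0.8))
  sim <- simulate_triplet(s, seed = 29)
  expect_equal(nrow(sim$ld), 4 * choose(3, 2))
  expect_true(all(sim$ld$r2 == 0.8))
  # block members lie within the clump window of their lead
  per <- sim$truth$per_snp
  for (b in unique(per$block[per$block > 0])) {
    pos <- per$pos[per$block == b]
    expect_lt(max(pos) - min(pos), 1e5)
  }
  # paper-like truth: calibrated path coefficients and implied proportion
  t2 <- simulate_triplet(paper_like_scenario(), seed = 1)$truth
  expect_equal(t2$beta1, log(0.917))
  expect_equal(t2$total, log(0.4957))
  expect_equal(t2$proportion_pct, 8.8624, tolerance = 1e-4)
})

test_that("sparse directional pleiotropy raises the Egger intercept rejection rate", {
  s_pleio <- sim_scenario(palindrome_fraction = 0, n_null_snp = 0,
                          pleiotropy = list(frac = 0.3, mean = 0.15, sd = 0.02))
  s_null <- sim_scenario(palindrome_fraction = 0, n_null_snp = 0)
  reject <- function(s, seed) {
    h <- harmonize_truth(simulate_triplet(s, seed = seed), "outcome")
    mr_egger(h)$intercept$pval < 0.05
  }
  r_pleio <- mean(vapply(1:300, function(i) reject(s_pleio, 8000 + i),
                         logical(1)))
  r_null <- mean(vapply(1:300, function(i) reject(s_null, 8000 + i),
                        logical(1)))
  expect_gt(r_pleio, r_null)
})

test_that("scenario validation rejects impossible configurations", {
  expect_error(sim_scenario(n_snp = 0))
  expect_error(sim_scenario(maf_range = c(0, 0.5)))
  expect_error(sim_scenario(pleiotropy = list(frac = 2, mean = 0, sd = 0)))
})

test_that("the mediation study adds an independent mediator-instrument locus", {
  s <- paper_like_scenario()
  sim <- simulate_mediation_study(s, seed = 33)
  expect_length(sim$truth$med_instruments, 30)
  # mediator instruments reach genome-wide strength in the mediator table
  md <- as.data.frame(sim$mediator)
  bmd <- md[md$snp %in% sim$truth$med_instruments, ]
  expect_gt(mean(bmd$pval < 1e-5), 0.6)
  # and are null for the exposure
  ex <- as.data.frame(sim$exposure)
  bex <- ex[ex$snp %in% sim$truth$med_instruments, ]
  expect_gt(mean(bex$pval > 1e-5), 0.9)
  # step-2 IVW on the mediator's own instruments recovers beta2
  keep <- sumstats(bmd, trait_id = "mediator_sim")
  h2 <- harmonize(keep, sim$outcome)
  est2 <- mr_ivw(h2)
  expect_lt(abs(est2$beta - s$beta2), 3 * est2$se)
})
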