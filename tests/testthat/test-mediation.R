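# Two-step mediation, delta-method intervals, MVMR, mediator screening.

test_that("mediation decomposition handles the null mediator path and published table", {
  est <- function(beta, se) list(beta = beta, se = se)
  # beta1 = 0: no mediated effect, direct equals total
  m0 <- mediation_effect(est(0, 0.01), est(0.7, 0.3), est(-0.7, 0.28))
  expect_equal(m0$mediated, 0)
  expect_equal(m0$direct, -0.7)
  expect_equal(m0$proportion_pct, 0)

  # published mediation row: mediated -0.0730, total -0.7018 gives the
  # direct effect -0.6288 (exact identity) and proportion ~10.41%
  mt <- mediation_effect(est(-0.0730, 0.011), est(1, 1e-9),
                         est(-0.7018, 0.2859))
  expect_identical(mt$direct, -0.7018 - (-0.0730))
  expect_equal(mt$direct, -0.6288)
  expect_equal(mt$proportion_pct, 10.4071, tolerance = 0.05)

  expect_error(mediation_effect(est(1, 1), est(1, 1), est(0, 1)),
               class = "mrpath_config_error")
})

test_that("mediated + direct = total to machine precision for random inputs", {
  set.seed(77)
  for (i in 1:25) {
    m <- mediation_effect(list(beta = rnorm(1), se = runif(1, 0.01, 1)),
                          list(beta = rnorm(1), se = runif(1, 0.01, 1)),
                          list(beta = rnorm(1) + 1, se = runif(1, 0.01, 1)))
    expect_equal(m$mediated + m$direct, m$total, tolerance = 1e-12)
    expect_equal(sign(m$proportion_pct),
                 sign(m$mediated) * sign(m$total))
  }
})

test_that("delta-method proportion interval agrees with a Monte-Carlo oracle", {
  # effect sizes of the published analysis at the simulator's SE regime
  b1 <- log(0.917); se1 <- 0.016
  b2 <- log(2.0499); se2 <- 0.157
  tt <- log(0.4957); se_t <- 0.082
  m <- mediation_effect(list(beta = b1, se = se1), list(beta = b2, se = se2),
                        list(beta = tt, se = se_t))
  mc <- mrpath:::with_seed(4242, {
    d1 <- rnorm(1e5, b1, se1); d2 <- rnorm(1e5, b2, se2)
    dt <- rnorm(1e5, tt, se_t)
    quantile(100 * d1 * d2 / dt, c(0.025, 0.975))
  })
  width <- m$ci_high - m$ci_low
  # the exact sampling distribution of the ratio is right-skewed while
  # the delta interval is symmetric: widths agree closely, bounds to
  # within the skew allowance
  expect_lt(abs(width - (mc[[2]] - mc[[1]])), 0.1 * width)
  expect_lt(abs(m$ci_low - mc[[1]]), 0.15 * width)
  expect_lt(abs(m$ci_high - mc[[2]]), 0.15 * width)
})

test_that("MVMR equals the normal-equation oracle and nests univariable IVW", {
  # hand-built 4-SNP, 2-exposure system
  X <- cbind(e1 = c(0.05, 0.04, -0.03, 0.06), e2 = c(0.02, -0.05, 0.04, 0.01))
  by <- c(0.03, 0.01, -0.02, 0.05)
  se <- c(0.02, 0.03, 0.025, 0.015)
  res <- mvmr_ivw(X, by, se)
  W <- diag(1 / se^2)
  oracle <- solve(t(X) %*% W %*% X, t(X) %*% W %*% by)
  expect_equal(res$beta, unname(drop(oracle)), tolerance = 1e-10)
  expect_equal(res$exposure, c("e1", "e2"))

  # second exposure at noise level: first estimate ~ univariable IVW
  set.seed(5)
  bx1 <- runif(20, 0.03, 0.06)
  bx2 <- rnorm(20, 0, 1e-6)
  se_y <- rep(0.02, 20)
  by2 <- -0.7 * bx1 + rnorm(20, 0, se_y)
  uv <- mr_ivw(make_h(bx1, by2, se_out = se_y), random_effects = FALSE)
  mv <- mvmr_ivw(cbind(a = bx1, b = bx2), by2, se_y)
  expect_equal(mv$beta[1], uv$beta, tolerance = 1e-3)

  # collinear design errors; too few instruments errors
  expect_error(mvmr_ivw(cbind(bx1, 2 * bx1), by2, se_y),
               class = "mrpath_config_error")
  expect_error(mvmr_ivw(X[1:3, ], by[1:3], se[1:3]),
               class = "mrpath_config_error")
})

test_that("MVMR attenuates a fully mediated exposure toward zero", {
  # truth: no direct path; the mediator transmits the whole (large)
  # effect, so the univariable total is clearly nonzero
  s <- sim_scenario(beta_direct = 0, beta1 = -0.35, beta2 = 2.005,
                    palindrome_fraction = 0, n_null_snp = 0)
  sim <- simulate_mediation_study(s, seed = 61)
  mvh <- mvmr_harmonize(list(exposure = sim$exposure, mediator = sim$mediator),
                        sim$outcome,
                        snps = c(sim$truth$instruments,
                                 sim$truth$med_instruments))
  res <- mvmr_ivw(mvh)
  direct_row <- res[res$exposure == "exposure", ]
  med_row <- res[res$exposure == "mediator", ]
  # conditional exposure effect is near zero, mediator near beta2
  expect_lt(abs(direct_row$beta), 3 * direct_row$se)
  expect_lt(abs(med_row$beta - s$beta2), 3 * med_row$se)
  # while the univariable total effect is clearly negative
  uv <- mr_ivw(harmonize_truth(sim, "outcome"))
  expect_lt(uv$beta + 2 * uv$se, 0)
})

test_that("mediator screening filters on step-1 p and counts directions", {
  tab <- data.frame(mediator = c("m1", "m2", "m3"),
                    beta = c(0.2, -0.3, 0.1),
                    pval = c(0.5, 0.5, 0.5))
  expect_length(screen_mediators(tab)$selected, 0)
  expect_length(screen_mediators(tab, alpha = 1)$selected, 3)

  tab$pval <- c(0.01, 0.001, 0.2)
  scr <- screen_mediators(tab)
  expect_equal(scr$selected, c("m1", "m2"))
  expect_equal(scr$n_up, 1)
  expect_equal(scr$n_down, 1)

  # Bonferroni is stricter than no adjustment
  scr_b <- screen_mediators(tab, adjust = "bonferroni")
  expect_true(length(scr_b$selected) <= length(scr$selected))
})

test_that("screening recovers true mediators from a simulated battery", {
  s <- paper_like_scenario()
  bat <- simulate_mediator_battery(s, n_mediators = 123, n_true = 36,
                                   seed = 71)
  keep <- as.data.frame(bat$exposure)
  keep <- keep[keep$snp %in% bat$instruments, ]
  ex <- sumstats(keep, trait_id = "exposure_sim")
  step1 <- do.call(rbind, lapply(names(bat$mediators), function(id) {
    h <- harmonize(ex, bat$mediators[[id]])
    est <- mr_ivw(h)
    data.frame(mediator = id, beta = est$beta, pval = est$pval)
  }))
  scr <- screen_mediators(step1)
  truth_pos <- bat$truth$mediator[bat$truth$beta1 != 0]
  recovered <- mean(truth_pos %in% scr$selected)
  expect_gte(recovered, 0.90)
  # direction of recovered effects matches the truth
  sel_tab <- merge(scr$table[scr$table$selected, ], bat$truth, by = "mediator")
  sel_true <- sel_tab[sel_tab$beta1 != 0, ]
  expect_true(all(sign(sel_true$beta) == sign(sel_true$beta1)))
})
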