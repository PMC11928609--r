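# Univariable estimator suite.

test_that("Wald ratio matches hand arithmetic and handles the null", {
  e1 <- mr_wald_ratio(1, 0.1, 0.5, 0.1)
  expect_equal(e1$beta, 0.5)
  expect_equal(e1$se, 0.1)
  e2 <- mr_wald_ratio(-0.5, 0.05, 0.25, 0.1)
  expect_equal(e2$beta, -0.5)
  expect_equal(e2$se, 0.2)
  e3 <- mr_wald_ratio(0.4, 0.05, 0, 0.1)
  expect_equal(e3$beta, 0)
  expect_equal(e3$pval, 1)
  expect_error(mr_wald_ratio(0, 0.1, 0.5, 0.1), class = "mrpath_config_error")
})

test_that("IVW equals the hand-computed weighted solution; homogeneous sets have SE_RE = SE_FE", {
  h <- make_h(beta_exp = c(1, 2, 1), beta_out = c(1, 2, 3),
              se_out = c(1, 1, 1))
  est <- mr_ivw(h)
  expect_equal(est$beta, 8 / 6)

  # all Wald ratios identical: beta = r, Q = 0, RE does not inflate
  r <- 0.7
  h2 <- make_h(beta_exp = c(0.5, 1, 2), beta_out = r * c(0.5, 1, 2),
               se_out = c(0.3, 0.2, 0.4))
  fe <- mr_ivw(h2, random_effects = FALSE)
  re <- mr_ivw(h2, random_effects = TRUE)
  expect_equal(re$beta, r)
  expect_equal(re$se, fe$se)
  expect_equal(cochran_q(h2, re$beta)$q, 0, tolerance = 1e-12)

  h1 <- make_h(0.5, 0.2)
  expect_error(mr_ivw(h1), "wald", ignore.case = TRUE,
               class = "mrpath_config_error")
})

test_that("IVW equals the weighted-least-squares oracle to 1e-10 on random sets", {
  set.seed(101)
  for (i in 1:20) {
    L <- sample(3:40, 1)
    bx <- rnorm(L, 0, 0.05); by <- rnorm(L, 0, 0.1)
    se_y <- runif(L, 0.01, 0.5)
    h <- make_h(bx, by, se_out = se_y)
    est <- mr_ivw(h, random_effects = FALSE)
    oracle <- lm(by ~ 0 + bx, weights = 1 / se_y^2)
    expect_equal(est$beta, unname(coef(oracle)), tolerance = 1e-10)
    expect_equal(est$se,
                 unname(sqrt(1 / sum(bx^2 / se_y^2))), tolerance = 1e-10)
  }
})

test_that("Egger recovers a zero intercept on proportional data and a constant offset otherwise", {
  bx <- seq(0.02, 0.08, length.out = 10)
  h0 <- make_h(bx, 0.5 * bx, se_out = rep(0.02, 10))
  eg0 <- mr_egger(h0)
  expect_equal(eg0$intercept$intercept, 0, tolerance = 1e-12)
  expect_equal(eg0$slope$beta, mr_ivw(h0)$beta, tolerance = 1e-10)

  cc <- 0.03
  h1 <- make_h(bx, cc + 0.5 * bx, se_out = rep(0.02, 10))
  eg1 <- mr_egger(h1)
  expect_equal(eg1$intercept$intercept, cc, tolerance = 1e-10)
  expect_equal(eg1$slope$beta, 0.5, tolerance = 1e-10)

  expect_error(mr_egger(make_h(c(1, 2), c(1, 2))),
               class = "mrpath_config_error")
})

test_that("Egger intercept test has power against pervasive directional pleiotropy", {
  s1 <- sim_scenario(palindrome_fraction = 0, n_null_snp = 0,
                     pleiotropy = list(frac = 1, mean = 0.05, sd = 0.01))
  reject <- function(s, seed) {
    sim <- simulate_triplet(s, seed = seed)
    h <- harmonize_truth(sim, "outcome")
    mr_egger(h)$intercept$pval < 0.05
  }
  power <- mean(vapply(1:200, function(i) reject(s1, 7000 + i), logical(1)))
  expect_gt(power, 0.5)  # far above the nominal type-I level
})

test_that("weighted median matches quantile oracles and tolerates <50% invalid weight", {
  h <- make_h(beta_exp = c(1, 1, 1), beta_out = c(1, 2, 3),
              se_out = c(1, 1, 1))
  est <- mr_weighted_median(h, n_boot = 200, seed = 1)
  expect_equal(est$beta, 2)

  # nearly all weight on one SNP pulls the estimate to its ratio
  h2 <- make_h(beta_exp = c(1, 1, 1), beta_out = c(5, 1, 2),
               se_out = c(0.001, 10, 10))
  est2 <- mr_weighted_median(h2, n_boot = 200, seed = 1)
  expect_equal(est2$beta, 5, tolerance = 1e-6)

  # breakdown property: 30 valid + 12 invalid instruments (minority weight)
  set.seed(33)
  true_b <- -0.7
  bx <- runif(42, 0.03, 0.06)
  se_y <- rep(0.02, 42)
  by <- true_b * bx + rnorm(42, 0, se_y)
  by[31:42] <- by[31:42] + 0.15          # strongly pleiotropic minority
  h3 <- make_h(bx, by, se_exp = rep(0.005, 42), se_out = se_y)
  est3 <- mr_weighted_median(h3, n_boot = 500, seed = 9)
  expect_lt(abs(est3$beta - true_b), 3 * est3$se)
  expect_error(mr_weighted_median(make_h(c(1, 2), c(1, 2))),
               class = "mrpath_config_error")
})

test_that("mode estimators find the dominant ratio cluster", {
  # all ratios equal: estimate is that ratio (zero-bandwidth branch)
  h0 <- make_h(beta_exp = c(1, 2, 4), beta_out = 0.3 * c(1, 2, 4),
               se_out = c(1, 1, 1))
  est0 <- mr_mode(h0, n_boot = 100, seed = 2)
  expect_equal(est0$beta, 0.3, tolerance = 1e-12)

  # bimodal {0,0,0,5}: simple mode sits at the larger cluster
  h1 <- make_h(beta_exp = rep(1, 4), beta_out = c(0, 0.01, -0.01, 5),
               se_out = rep(1, 4))
  est1 <- mr_mode(h1, n_boot = 100, seed = 2)
  # grid-density oracle computed directly
  r <- h1$rows$beta_out / h1$rows$beta_exp
  bw <- 0.9 * min(sd(r), IQR(r) / 1.349) * 4^(-1 / 5)
  grid <- seq(min(r) - 3 * bw, max(r) + 3 * bw, length.out = 1000)
  dens <- sapply(grid, function(g) mean(dnorm(g, r, bw)))
  expect_equal(est1$beta, grid[which.max(dens)])
  expect_lt(abs(est1$beta), 0.5)

  # weighted variant with virtually all weight on the ratio-5 SNP
  h2 <- make_h(beta_exp = rep(1, 4), beta_out = c(0, 0.01, -0.01, 5),
               se_out = c(10, 10, 10, 0.001))
  est2 <- mr_mode(h2, weighted = TRUE, n_boot = 100, seed = 2)
  expect_equal(est2$beta, 5, tolerance = 0.1)
})

test_that("the suite dispatches on instrument count with the published row order", {
  h1 <- make_h(0.5, 0.25, se_out = 0.1)
  r1 <- mr_all_methods(h1)
  expect_equal(r1$method, "wald_ratio")

  h2 <- make_h(c(0.5, 0.6), c(0.25, 0.3), se_out = c(0.1, 0.1))
  r2 <- mr_all_methods(h2)
  expect_equal(r2$method, "ivw_re")

  s <- paper_like_scenario()
  sim <- simulate_triplet(s, seed = 3)
  h <- harmonize_truth(sim, "outcome")
  r5 <- mr_all_methods(h, n_boot = 300, seed = 4)
  expect_equal(r5$method, c("egger", "weighted_median", "ivw_re",
                            "simple_mode", "weighted_mode"))
  # homogeneous scenario: all five point estimates agree within 2 SE
  for (i in seq_len(5)) for (j in seq_len(5))
    expect_lt(abs(r5$beta[i] - r5$beta[j]),
              2 * (r5$se[i] + r5$se[j]))
})

test_that("estimators are sign-flip and scale equivariant", {
  s <- paper_like_scenario()
  sim <- simulate_triplet(s, seed = 12)
  h <- harmonize_truth(sim, "outcome")

  # flip the (bx, by) pair of the first five instruments
  h_flip <- h
  h_flip$rows$beta_exp[1:5] <- -h_flip$rows$beta_exp[1:5]
  h_flip$rows$beta_out[1:5] <- -h_flip$rows$beta_out[1:5]
  expect_equal(mr_ivw(h_flip)$beta, mr_ivw(h)$beta, tolerance = 1e-12)
  expect_equal(mr_egger(h_flip)$slope$beta, mr_egger(h)$slope$beta,
               tolerance = 1e-12)
  expect_equal(mr_weighted_median(h_flip, 50, seed = 5)$beta,
               mr_weighted_median(h, 50, seed = 5)$beta, tolerance = 1e-12)
  expect_equal(mr_mode(h_flip, n_boot = 50, seed = 5)$beta,
               mr_mode(h, n_boot = 50, seed = 5)$beta, tolerance = 1e-12)

  # rescaling the outcome side by c rescales every estimate by c
  cc <- 2.5
  h_scale <- h
  h_scale$rows$beta_out <- cc * h_scale$rows$beta_out
  h_scale$rows$se_out <- cc * h_scale$rows$se_out
  expect_equal(mr_ivw(h_scale)$beta, cc * mr_ivw(h)$beta, tolerance = 1e-12)
  expect_equal(mr_egger(h_scale)$slope$beta, cc * mr_egger(h)$slope$beta,
               tolerance = 1e-12)
  expect_equal(mr_weighted_median(h_scale, 50, seed = 5)$beta,
               cc * mr_weighted_median(h, 50, seed = 5)$beta,
               tolerance = 1e-9)
})
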