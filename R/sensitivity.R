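# Heterogeneity, pleiotropy and influence diagnostics.

#' Cochran's Q heterogeneity test
#'
#' Q = sum over SNPs of se_out^-2 * (beta_out - beta_hat * beta_exp)^2,
#' referred to a chi-square with df degrees of freedom, together with the
#' I^2 = max(0, (Q - df)/Q) * 100 heterogeneity percentage. df defaults to
#' L - 1 (IVW); pass L - 2 for residual heterogeneity about an Egger fit.
#'
#' @param h a \code{harmonized_set} with at least 2 SNPs.
#' @param beta_hat causal slope about which heterogeneity is measured.
#' @param df degrees of freedom (default L - 1).
#' @return a \code{heterogeneity_result}: list(q, df, pval, i2).
#' @export
cochran_q <- function(h, beta_hat, df = n_snp(h) - 1) {
  if (n_snp(h) < 2) stop_config("Cochran's Q needs >= 2 instruments")
  w <- 1 / h$rows$se_out^2
  q <- sum(w * (h$rows$beta_out - beta_hat * h$rows$beta_exp)^2)
  i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0
  structure(list(q = q, df = df,
                 pval = stats::pchisq(q, df, lower.tail = FALSE), i2 = i2),
            class = "heterogeneity_result")
}

# Leave-one-out fixed-effect IVW slopes for every SNP, O(L).
loo_fe_slopes <- function(bx, by, w) {
  sxy <- sum(w * bx * by); sxx <- sum(w * bx^2)
  (sxy - w * bx * by) / (sxx - w * bx^2)
}

#' MR-PRESSO global and outlier tests
#'
#' Residual-sum-of-squares resampling test for horizontal pleiotropy.
#' The observed statistic sums per-SNP contributions
#' d_j = se_out^-2 (beta_out_j - b_(-j) beta_exp_j)^2, where b_(-j) is the
#' leave-one-out fixed-effect IVW slope. Under the null, replicate data
#' are drawn as beta_exp* ~ N(beta_exp, se_exp) and
#' beta_out_j* ~ N(b_(-j) beta_exp_j, se_out_j), and the statistic is
#' recomputed identically. Monte-Carlo p-values use add-one smoothing,
#' (1 + count)/(n_sim + 1), so they are never zero; per-SNP p-values are
#' Bonferroni-multiplied by L and SNPs below \code{alpha} are flagged as
#' outliers. The optional distortion test compares the IVW shift caused
#' by removing the flagged outliers to shifts from removing random
#' same-size subsets.
#'
#' @param h a \code{harmonized_set} with at least 4 SNPs.
#' @param n_sim resampling replicates (>= 100; default 1000).
#' @param seed RNG seed; results are bit-reproducible given (seed, n_sim).
#' @param alpha outlier significance level on the adjusted per-SNP p.
#' @param distortion also run the distortion test (off by default).
#' @return a \code{presso_result}: list(rss_obs, global_pval,
#'   outlier_indices, per_snp_pvals, distortion_pval, n_sim, seed).
#' @export
mr_presso <- function(h, n_sim = 1000, seed = NULL, alpha = 0.05,
                      distortion = FALSE) {
  L <- n_snp(h)
  if (L < 4) stop_config("MR-PRESSO needs >= 4 instruments")
  if (n_sim < 100) stop_config("n_sim must be >= 100")
  rows <- h$rows
  w <- 1 / rows$se_out^2
  slopes_loo <- loo_fe_slopes(rows$beta_exp, rows$beta_out, w)
  d_obs <- w * (rows$beta_out - slopes_loo * rows$beta_exp)^2
  rss_obs <- sum(d_obs)

  sim <- with_seed(seed, {
    bx_star <- matrix(stats::rnorm(L * n_sim, rows$beta_exp, rows$se_exp), L)
    by_star <- matrix(stats::rnorm(L * n_sim, slopes_loo * rows$beta_exp,
                                   rows$se_out), L)
    sxy <- colSums(w * bx_star * by_star)
    sxx <- colSums(w * bx_star^2)
    sl_star <- (rep(sxy, each = L) - w * bx_star * by_star) /
      (rep(sxx, each = L) - w * bx_star^2)
    d_star <- w * (by_star - sl_star * bx_star)^2
    list(rss = colSums(d_star), d = d_star)
  })

  global_pval <- (1 + sum(sim$rss >= rss_obs)) / (n_sim + 1)
  per_raw <- (1 + rowSums(sim$d >= d_obs)) / (n_sim + 1)
  per_adj <- pmin(1, per_raw * L)
  outliers <- which(per_adj < alpha)

  distortion_pval <- NULL
  if (distortion && length(outliers) > 0 && length(outliers) < L - 1) {
    keep <- setdiff(seq_len(L), outliers)
    fe <- function(idx) sum(w[idx] * rows$beta_exp[idx] * rows$beta_out[idx]) /
      sum(w[idx] * rows$beta_exp[idx]^2)
    shift_obs <- abs(fe(seq_len(L)) - fe(keep))
    shifts <- with_seed(if (is.null(seed)) NULL else seed + 1L,
      vapply(seq_len(n_sim), function(i) {
        rnd <- sample(seq_len(L), length(outliers))
        abs(fe(seq_len(L)) - fe(setdiff(seq_len(L), rnd)))
      }, numeric(1)))
    distortion_pval <- (1 + sum(shifts >= shift_obs)) / (n_sim + 1)
  }

  structure(list(rss_obs = rss_obs, global_pval = global_pval,
                 outlier_indices = outliers, per_snp_pvals = per_adj,
                 distortion_pval = distortion_pval, n_sim = n_sim,
                 seed = seed),
            class = "presso_result")
}

#' Leave-one-out sensitivity analysis
#'
#' Recomputes the random-effects IVW estimate with each SNP removed in
#' turn, plus an "all" row for the full set. The \code{stable} attribute
#' is FALSE when any single drop flips the sign of the estimate or moves
#' its p-value across 0.05.
#'
#' @param h a \code{harmonized_set} with at least 3 SNPs.
#' @param level confidence level.
#' @return data.frame (dropped_snp, n_snp, beta, se, pval) with L + 1 rows
#'   and a logical \code{stable} attribute.
#' @export
leave_one_out <- function(h, level = 0.95) {
  L <- n_snp(h)
  if (L < 3) stop_config("leave-one-out needs >= 3 instruments")
  full <- mr_ivw(h, random_effects = TRUE, level = level)
  rows <- lapply(seq_len(L), function(j) {
    hj <- new_harmonized_set(h$rows[-j, , drop = FALSE], h$exposure_id,
                             h$outcome_id)
    est <- mr_ivw(hj, random_effects = TRUE, level = level)
    data.frame(dropped_snp = h$rows$snp[j], n_snp = est$n_snp,
               beta = est$beta, se = est$se, pval = est$pval,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(dropped_snp = "all", n_snp = full$n_snp,
                               beta = full$beta, se = full$se,
                               pval = full$pval, stringsAsFactors = FALSE))
  loo <- out[out$dropped_snp != "all", ]
  unstable <- any(sign(loo$beta) != sign(full$beta)) ||
    any((loo$pval < 0.05) != (full$pval < 0.05))
  attr(out, "stable") <- !unstable
  out
}

#' Funnel-plot data export
#'
#' Per-SNP Wald ratios against their precision (1/SE of the ratio,
#' i.e. |beta_exp|/se_out); asymmetry of this cloud about the pooled
#' estimate suggests directional pleiotropy.
#'
#' @param h a \code{harmonized_set}.
#' @return data.frame (snp, wald_ratio, precision).
#' @export
funnel_data <- function(h) {
  rows <- h$rows
  data.frame(snp = rows$snp, wald_ratio = rows$beta_out / rows$beta_exp,
             precision = abs(rows$beta_exp) / rows$se_out,
             stringsAsFactors = FALSE)
}

#' Sensitivity summary for one exposure-outcome pair
#'
#' Bundles Cochran's Q/I^2 about the IVW fit, the Egger intercept test and
#' the MR-PRESSO global p into one row shaped like the diagnostic columns
#' of a published MR table.
#'
#' @param h a \code{harmonized_set} (>= 4 SNPs for the PRESSO column).
#' @param n_sim,seed MR-PRESSO controls.
#' @return one-row data.frame (q, q_df, q_pval, i2, egger_intercept,
#'   egger_se, egger_pval, presso_global_p).
#' @export
sensitivity_summary <- function(h, n_sim = 1000, seed = NULL) {
  ivw <- mr_ivw(h)
  het <- cochran_q(h, ivw$beta)
  eg <- if (n_snp(h) >= 3) mr_egger(h)$intercept else
    list(intercept = NA_real_, se = NA_real_, pval = NA_real_)
  presso_p <- if (n_snp(h) >= 4)
    mr_presso(h, n_sim = n_sim, seed = seed)$global_pval else NA_real_
  data.frame(q = het$q, q_df = het$df, q_pval = het$pval, i2 = het$i2,
             egger_intercept = eg$intercept, egger_se = eg$se,
             egger_pval = eg$pval, presso_global_p = presso_p)
}
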