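# Univariable two-sample MR estimators: Wald ratio, IVW (fixed and
# multiplicative random effects), MR-Egger, weighted median, and
# mode-based estimators.

MR_METHODS <- c("wald_ratio", "ivw_fe", "ivw_re", "egger", "weighted_median",
                "simple_mode", "weighted_mode")

# One result row in the shape of a published MR table.
mr_estimate <- function(method, beta, se, pval, n_snp, level = 0.95) {
  beta <- unname(beta); se <- unname(se); pval <- unname(pval)
  orci <- beta_to_or(beta, se, level)
  structure(data.frame(method = method, n_snp = n_snp, beta = beta, se = se,
                       pval = pval, or = orci$or, ci_low = orci$ci_low,
                       ci_high = orci$ci_high, stringsAsFactors = FALSE,
                       row.names = NULL),
            class = c("mr_estimate", "data.frame"))
}

#' Wald ratio estimate from a single instrument
#'
#' beta = beta_out / beta_exp with the first-order standard error
#' se_out / |beta_exp|; the p-value is two-sided normal.
#'
#' @param beta_exp,se_exp SNP-exposure effect and SE.
#' @param beta_out,se_out SNP-outcome effect and SE.
#' @param level confidence level for the odds-ratio interval.
#' @return an \code{mr_estimate} row.
#' @export
mr_wald_ratio <- function(beta_exp, se_exp, beta_out, se_out, level = 0.95) {
  if (beta_exp == 0) stop_config("Wald ratio undefined: beta_exp = 0")
  beta <- beta_out / beta_exp
  se <- se_out / abs(beta_exp)
  mr_estimate("wald_ratio", beta, se, pval_normal(beta, se), 1L, level)
}

ivw_weights <- function(h) 1 / h$rows$se_out^2

#' Inverse-variance-weighted estimate
#'
#' Weighted zero-intercept regression of outcome on exposure betas with
#' weights 1/se_out^2 — the meta-analysis of per-SNP Wald ratios. The
#' random-effects variant (the default, and the primary method of the
#' pipeline) inflates the fixed-effect SE by max(1, sqrt(Q/(L-1)))
#' (multiplicative overdispersion, never credited below 1), so FE and RE
#' coincide when Cochran's Q is at or below its degrees of freedom.
#' P-values are two-sided normal.
#'
#' @param h a \code{harmonized_set} with at least 2 SNPs.
#' @param random_effects use the multiplicative random-effects SE.
#' @param level confidence level for the OR interval.
#' @return an \code{mr_estimate} row (method \code{ivw_re} or \code{ivw_fe}).
#' @export
mr_ivw <- function(h, random_effects = TRUE, level = 0.95) {
  L <- n_snp(h)
  if (L < 2)
    stop_config("IVW needs >= 2 instruments; use mr_wald_ratio for one SNP")
  w <- ivw_weights(h)
  bx <- h$rows$beta_exp; by <- h$rows$beta_out
  sxx <- sum(w * bx^2)
  beta <- sum(w * bx * by) / sxx
  se_fe <- sqrt(1 / sxx)
  if (random_effects) {
    q <- sum(w * (by - beta * bx)^2)
    se <- se_fe * max(1, sqrt(q / (L - 1)))
  } else se <- se_fe
  mr_estimate(if (random_effects) "ivw_re" else "ivw_fe",
              beta, se, pval_normal(beta, se), L, level)
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome betas on exposure betas with a
#' free intercept, after orienting every instrument so beta_exp >= 0.
#' A nonzero intercept indicates directional horizontal pleiotropy; the
#' slope is the pleiotropy-adjusted causal estimate. Standard errors carry
#' the multiplicative overdispersion factor max(1, sqrt(Q_resid/(L-2)))
#' and p-values use the t distribution with L-2 df.
#'
#' @param h a \code{harmonized_set} with at least 3 SNPs.
#' @param level confidence level for the OR interval.
#' @return list with \code{slope} (an \code{mr_estimate}) and
#'   \code{intercept} (an \code{egger_intercept}: intercept, se, pval).
#' @export
mr_egger <- function(h, level = 0.95) {
  L <- n_snp(h)
  if (L < 3) stop_config("MR-Egger needs >= 3 instruments")
  flip <- h$rows$beta_exp < 0
  bx <- abs(h$rows$beta_exp)
  by <- ifelse(flip, -h$rows$beta_out, h$rows$beta_out)
  w <- 1 / h$rows$se_out^2
  X <- cbind(intercept = 1, slope = bx)
  xtwx <- crossprod(X, w * X)
  coefs <- drop(solve(xtwx, crossprod(X, w * by)))
  resid <- by - drop(X %*% coefs)
  q_resid <- sum(w * resid^2)
  scale <- max(1, sqrt(q_resid / (L - 2)))
  ses <- sqrt(diag(solve(xtwx))) * scale
  slope <- mr_estimate("egger", coefs["slope"], ses["slope"],
                       pval_t(coefs["slope"], ses["slope"], L - 2), L, level)
  intercept <- structure(list(intercept = unname(coefs["intercept"]),
                              se = unname(ses["intercept"]),
                              pval = pval_t(coefs["intercept"], ses["intercept"], L - 2)),
                         class = "egger_intercept")
  list(slope = slope, intercept = intercept)
}

# Ratio estimates and their first-order inverse-variance weights.
ratio_estimates <- function(bx, by, se_out) {
  list(r = by / bx, w = bx^2 / se_out^2)
}

weighted_median_point <- function(r, w) {
  ord <- order(r)
  r <- r[ord]; w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(r[1])
  if (0.5 >= s[length(s)]) return(r[length(r)])
  stats::approx(s, r, xout = 0.5, ties = "ordered")$y
}

# Parametric bootstrap of any point estimator of (bx, by) pairs.
bootstrap_estimates <- function(h, point_fun, n_boot, seed) {
  rows <- h$rows
  L <- nrow(rows)
  with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(L, rows$beta_exp, rows$se_exp)
      by <- stats::rnorm(L, rows$beta_out, rows$se_out)
      point_fun(bx, by)
    }, numeric(1))
  })
}

#' Weighted-median estimator
#'
#' The weighted median of per-SNP ratio estimates, consistent when valid
#' instruments carry more than half the weight. Weights are inverse
#' first-order ratio variances (beta_exp^2/se_out^2) normalized to one;
#' the point estimate interpolates the weighted empirical quantile at 0.5.
#' The SE is the standard deviation over a parametric bootstrap that
#' redraws both exposure and outcome betas from their sampling normals.
#'
#' @param h a \code{harmonized_set} with at least 3 SNPs.
#' @param n_boot bootstrap replicates for the SE (default 1000).
#' @param seed RNG seed for the bootstrap (restores caller's RNG state).
#' @param level confidence level for the OR interval.
#' @return an \code{mr_estimate} row.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = NULL, level = 0.95) {
  if (n_snp(h) < 3) stop_config("weighted median needs >= 3 instruments")
  point <- function(bx, by) {
    re <- ratio_estimates(bx, by, h$rows$se_out)
    weighted_median_point(re$r, re$w)
  }
  beta <- point(h$rows$beta_exp, h$rows$beta_out)
  boots <- bootstrap_estimates(h, point, n_boot, seed)
  se <- stats::sd(boots)
  mr_estimate("weighted_median", beta, se, pval_normal(beta, se), n_snp(h),
              level)
}

mode_point <- function(r, w, bandwidth_factor) {
  w <- w / sum(w)
  L <- length(r)
  spread <- min(stats::sd(r), stats::IQR(r) / 1.349)
  bw <- bandwidth_factor * 0.9 * spread * L^(-1 / 5)
  if (!is.finite(bw) || bw <= 0) return(r[1])
  grid <- seq(min(r) - 3 * bw, max(r) + 3 * bw, length.out = 1000)
  dens <- vapply(grid, function(g) sum(w * stats::dnorm(g, r, bw)), numeric(1))
  grid[which.max(dens)]
}

#' Mode-based estimators (simple and weighted)
#'
#' The mode of the smoothed empirical density of per-SNP ratio estimates,
#' consistent when the largest group of instruments sharing a ratio is
#' valid (ZEMPA). A Gaussian kernel with the modified Silverman bandwidth
#' phi * 0.9 * min(sd, IQR/1.349) * L^(-1/5) is evaluated on a 1000-point
#' grid over [min(r) - 3h, max(r) + 3h]; the weighted variant scales each
#' kernel by the normalized inverse-variance weight. The SE is
#' 1.4826 * MAD over the same parametric bootstrap as the weighted median.
#' If all ratios coincide (zero bandwidth) that common ratio is returned.
#'
#' @param h a \code{harmonized_set} with at least 3 SNPs.
#' @param bandwidth_factor bandwidth multiplier phi (default 1).
#' @param weighted use inverse-variance kernel weights.
#' @param n_boot,seed parametric-bootstrap controls.
#' @param level confidence level for the OR interval.
#' @return an \code{mr_estimate} row (\code{simple_mode} or \code{weighted_mode}).
#' @export
mr_mode <- function(h, bandwidth_factor = 1, weighted = FALSE, n_boot = 1000,
                    seed = NULL, level = 0.95) {
  if (n_snp(h) < 3) stop_config("mode estimators need >= 3 instruments")
  point <- function(bx, by) {
    re <- ratio_estimates(bx, by, h$rows$se_out)
    w <- if (weighted) re$w else rep(1, length(re$r))
    mode_point(re$r, w, bandwidth_factor)
  }
  beta <- point(h$rows$beta_exp, h$rows$beta_out)
  boots <- bootstrap_estimates(h, point, n_boot, seed)
  se <- stats::mad(boots)
  mr_estimate(if (weighted) "weighted_mode" else "simple_mode",
              beta, se, pval_normal(beta, se), n_snp(h), level)
}

#' Run the full univariable estimator suite
#'
#' Mirrors the standard published layout: with one instrument only the
#' Wald ratio is computed; with two, IVW only; with three or more, all
#' five methods in the order MR-Egger, weighted median, IVW, simple mode,
#' weighted mode.
#'
#' @param h a \code{harmonized_set}.
#' @param n_boot,seed bootstrap controls passed to median/mode estimators.
#' @param level confidence level.
#' @return data.frame of \code{mr_estimate} rows.
#' @export
mr_all_methods <- function(h, n_boot = 1000, seed = NULL, level = 0.95) {
  L <- n_snp(h)
  if (L < 1) stop_empty("no instruments")
  if (L == 1) {
    r <- h$rows
    return(mr_wald_ratio(r$beta_exp, r$se_exp, r$beta_out, r$se_out, level))
  }
  if (L == 2) return(mr_ivw(h, random_effects = TRUE, level = level))
  seeds <- if (is.null(seed)) rep(list(NULL), 3) else as.list(seed + 0:2)
  out <- rbind(mr_egger(h, level)$slope,
        mr_weighted_median(h, n_boot, seeds[[1]], level),
        mr_ivw(h, random_effects = TRUE, level = level),
        mr_mode(h, weighted = FALSE, n_boot = n_boot, seed = seeds[[2]],
                level = level),
        mr_mode(h, weighted = TRUE, n_boot = n_boot, seed = seeds[[3]],
                level = level))
  rownames(out) <- NULL
  out
}
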