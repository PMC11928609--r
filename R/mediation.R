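# Two-step mediation decomposition and multivariable (MVMR) adjustment.

get_beta_se <- function(x) {
  if (inherits(x, "mr_estimate") || is.data.frame(x))
    list(beta = x$beta[1], se = x$se[1])
  else list(beta = x[["beta"]], se = x[["se"]])
}

#' Two-step MR mediation decomposition
#'
#' Product-of-coefficients mediation on the log scale: the mediated effect
#' is beta1 * beta2 (exposure -> mediator, mediator -> outcome), the direct
#' effect is total - mediated by subtraction, and the proportion mediated
#' is 100 * mediated / total. Variances are propagated by the delta method
#' with zero cross-covariances (the three estimates come from separate
#' two-sample contrasts):
#' var(mediated) = beta1^2 var(beta2) + beta2^2 var(beta1), and
#' var(prop) = (100/total)^2 var(mediated)
#'           + (100 * mediated / total^2)^2 var(total).
#' The proportion interval is the normal (delta) interval.
#'
#' @param step1 exposure -> mediator estimate (an \code{mr_estimate} row or
#'   list with \code{beta}, \code{se}).
#' @param step2 mediator -> outcome estimate, same forms.
#' @param total exposure -> outcome total-effect estimate, same forms.
#' @param level confidence level for the proportion interval.
#' @return a \code{mediation_result} list: beta1/se1, beta2/se2,
#'   total/se_total, mediated/se_mediated, direct, proportion_pct with
#'   ci_low/ci_high and se.
#' @export
mediation_effect <- function(step1, step2, total, level = 0.95) {
  s1 <- get_beta_se(step1); s2 <- get_beta_se(step2); tt <- get_beta_se(total)
  if (tt$beta == 0) stop_config("proportion mediated undefined: total effect is 0")
  mediated <- s1$beta * s2$beta
  var_med <- s1$beta^2 * s2$se^2 + s2$beta^2 * s1$se^2
  direct <- tt$beta - mediated
  prop <- 100 * mediated / tt$beta
  var_prop <- (100 / tt$beta)^2 * var_med +
    (100 * mediated / tt$beta^2)^2 * tt$se^2
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(beta1 = s1$beta, se1 = s1$se, beta2 = s2$beta, se2 = s2$se,
                 total = tt$beta, se_total = tt$se,
                 mediated = mediated, se_mediated = sqrt(var_med),
                 direct = direct,
                 proportion_pct = prop, se_proportion = sqrt(var_prop),
                 ci_low = prop - z * sqrt(var_prop),
                 ci_high = prop + z * sqrt(var_prop), level = level),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("Mediated %.4f  Direct %.4f  Total %.4f\n",
              x$mediated, x$direct, x$total))
  cat(sprintf("Proportion mediated %.4f%% (%.4f ~ %.4f)\n",
              x$proportion_pct, x$ci_low, x$ci_high))
  invisible(x)
}

#' Harmonize several exposures and one outcome onto shared instruments
#'
#' Builds the multivariable design: SNPs present in every table are
#' aligned to the first exposure's effect allele (sign-flipping swapped
#' alleles, dropping incompatible ones) across all exposures and the
#' outcome.
#'
#' @param exposures named list of \code{sumstats} tables (>= 2).
#' @param outcome a \code{sumstats} table.
#' @param snps optional SNP ids to restrict to (e.g. the union of the
#'   per-exposure instrument selections).
#' @return list with \code{beta_exp} (L x k matrix), \code{se_exp}
#'   (L x k), \code{beta_out}, \code{se_out}, \code{snp}.
#' @export
mvmr_harmonize <- function(exposures, outcome, snps = NULL) {
  stopifnot(length(exposures) >= 2, inherits(outcome, "sumstats"))
  ids <- names(exposures) %||% paste0("exposure", seq_along(exposures))
  ref <- exposures[[1]]
  common <- Reduce(intersect, c(lapply(exposures, function(t) t$snp),
                                list(outcome$snp)))
  if (!is.null(snps)) common <- intersect(common, snps)
  if (length(common) < 2) stop_empty("fewer than 2 shared SNPs across tables")

  align <- function(tbl, refrows) {
    m <- tbl[match(refrows$snp, tbl$snp), ]
    same <- m$effect_allele == refrows$effect_allele &
      m$other_allele == refrows$other_allele
    swapped <- m$effect_allele == refrows$other_allele &
      m$other_allele == refrows$effect_allele
    list(beta = ifelse(same, m$beta, ifelse(swapped, -m$beta, NA)),
         se = m$se)
  }
  refrows <- ref[match(common, ref$snp), ]
  aligned <- lapply(exposures, align, refrows = refrows)
  out_al <- align(outcome, refrows)
  ok <- Reduce(`&`, lapply(aligned, function(a) !is.na(a$beta))) &
    !is.na(out_al$beta)
  if (sum(ok) < 2) stop_empty("fewer than 2 allele-compatible shared SNPs")
  list(beta_exp = do.call(cbind, stats::setNames(
         lapply(aligned, function(a) a$beta[ok]), ids)),
       se_exp = do.call(cbind, stats::setNames(
         lapply(aligned, function(a) a$se[ok]), ids)),
       beta_out = out_al$beta[ok], se_out = out_al$se[ok],
       snp = refrows$snp[ok])
}

#' Multivariable IVW regression
#'
#' Weighted multiple regression of outcome betas on the exposure-beta
#' columns without intercept, weights 1/se_out^2, giving each exposure's
#' effect conditional on the others. SEs carry the multiplicative
#' overdispersion factor max(1, sqrt(Q_resid/(L - k))); p-values are
#' two-sided normal.
#'
#' @param mv either the list returned by \code{\link{mvmr_harmonize}} or a
#'   numeric matrix of exposure betas (L x k, with column names).
#' @param beta_out,se_out outcome betas/SEs (when \code{mv} is a matrix).
#' @param level confidence level.
#' @return data.frame with one row per exposure: exposure, n_snp, beta,
#'   se, pval, or, ci_low, ci_high.
#' @export
mvmr_ivw <- function(mv, beta_out = NULL, se_out = NULL, level = 0.95) {
  if (is.list(mv) && !is.null(mv$beta_exp)) {
    X <- as.matrix(mv$beta_exp); by <- mv$beta_out; se <- mv$se_out
  } else {
    X <- as.matrix(mv); by <- beta_out; se <- se_out
  }
  L <- nrow(X); k <- ncol(X)
  if (L <= k + 1)
    stop_config("MVMR needs more instruments than exposures + 1")
  if (qr(X)$rank < k)
    stop_config("singular MVMR design: exposure betas are collinear")
  w <- 1 / se^2
  xtwx <- crossprod(X, w * X)
  coefs <- drop(solve(xtwx, crossprod(X, w * by)))
  resid <- by - drop(X %*% coefs)
  scale <- max(1, sqrt(sum(w * resid^2) / (L - k)))
  ses <- sqrt(diag(solve(xtwx))) * scale
  orci <- beta_to_or(coefs, ses, level)
  data.frame(exposure = colnames(X) %||% paste0("exposure", seq_len(k)),
             n_snp = L, beta = unname(coefs), se = unname(ses),
             pval = pval_normal(coefs, ses), or = orci$or,
             ci_low = orci$ci_low, ci_high = orci$ci_high,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Screen candidate mediators on their step-1 association
#'
#' Keeps mediators whose exposure -> mediator estimate is significant at
#' \code{alpha} and reports the split of effect directions. No multiplicity
#' correction is applied by default; Bonferroni or Benjamini-Hochberg can
#' be requested.
#'
#' @param step1_results data.frame with columns \code{mediator},
#'   \code{beta}, \code{pval} (one row per candidate).
#' @param alpha significance level (default 0.05).
#' @param adjust multiplicity adjustment: "none" (default), "bonferroni"
#'   or "BH".
#' @return list: \code{selected} mediator ids, \code{n_up}/\code{n_down}
#'   counts of positive/negative selected effects, and the annotated
#'   \code{table}.
#' @export
screen_mediators <- function(step1_results, alpha = 0.05,
                             adjust = c("none", "bonferroni", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(all(c("mediator", "beta", "pval") %in% names(step1_results)))
  p <- if (adjust == "none") step1_results$pval else
    stats::p.adjust(step1_results$pval, method = adjust)
  sel <- !is.na(p) & p < alpha
  tab <- step1_results
  tab$p_screen <- p
  tab$selected <- sel
  list(selected = step1_results$mediator[sel],
       n_up = sum(sel & step1_results$beta > 0),
       n_down = sum(sel & step1_results$beta < 0),
       table = tab)
}
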