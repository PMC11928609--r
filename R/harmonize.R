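# Allele harmonization of exposure and outcome summary statistics.

EXCLUSION_REASONS <- c("pval", "weak_instrument", "cis_window", "ld_clump",
                       "maf", "palindrome", "exclusion_list",
                       "allele_mismatch", "presso_outlier",
                       "missing_in_outcome")

new_provenance <- function(snp = character(), reason = character()) {
  stopifnot(all(reason %in% EXCLUSION_REASONS))
  data.frame(snp = as.character(snp), reason = as.character(reason),
             stringsAsFactors = FALSE)
}

new_harmonized_set <- function(rows, exposure_id, outcome_id,
                               provenance = new_provenance()) {
  stopifnot(is.data.frame(rows),
            all(c("snp", "beta_exp", "se_exp", "beta_out", "se_out",
                  "eaf_exp", "eaf_out") %in% names(rows)),
            !anyDuplicated(rows$snp),
            all(rows$se_exp > 0), all(rows$se_out > 0))
  rownames(rows) <- NULL
  structure(list(exposure_id = exposure_id, outcome_id = outcome_id,
                 rows = rows, provenance = provenance),
            class = "harmonized_set")
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat("Harmonized set:", x$exposure_id, "->", x$outcome_id, "\n")
  cat("  SNPs:", nrow(x$rows), "  excluded:", nrow(x$provenance), "\n")
  invisible(x)
}

#' Number of instruments in a harmonized set
#' @param h a \code{harmonized_set}.
#' @return integer SNP count.
#' @export
n_snp <- function(h) nrow(h$rows)

#' Is an allele pair palindromic?
#'
#' A/T and C/G pairs read the same on both strands, so effect alleles
#' cannot be matched across studies from allele codes alone.
#'
#' @param effect_allele,other_allele character vectors of single-base alleles.
#' @return logical vector.
#' @examples
#' is_palindromic(c("A", "A", "G"), c("T", "G", "C"))
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  a <- toupper(effect_allele); b <- toupper(other_allele)
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
}

#' Harmonize exposure and outcome summary statistics to a shared effect allele
#'
#' Intersects the two tables on SNP id and aligns outcome effects to the
#' exposure's effect allele: when the outcome lists the same alleles the
#' row passes through; when effect/other are swapped the outcome beta is
#' sign-flipped and its frequency complemented; incompatible allele pairs
#' are dropped with reason \code{allele_mismatch}, and exposure SNPs
#' absent from the outcome with reason \code{missing_in_outcome}.
#' Harmonizing an already-aligned pair of tables is a no-op.
#'
#' @param exposure,outcome \code{sumstats} tables.
#' @param provenance optional prior exclusion log (e.g. from
#'   \code{\link{select_instruments}}) carried into the result.
#' @return a \code{harmonized_set}.
#' @export
harmonize <- function(exposure, outcome, provenance = NULL) {
  stopifnot(inherits(exposure, "sumstats"), inherits(outcome, "sumstats"))
  prov <- provenance %||% new_provenance()
  idx <- match(exposure$snp, outcome$snp)
  missing <- is.na(idx)
  if (any(missing))
    prov <- rbind(prov, new_provenance(exposure$snp[missing], rep("missing_in_outcome", sum(missing))))
  ex <- exposure[!missing, , drop = FALSE]
  out <- outcome[idx[!missing], , drop = FALSE]

  same <- ex$effect_allele == out$effect_allele & ex$other_allele == out$other_allele
  swapped <- ex$effect_allele == out$other_allele & ex$other_allele == out$effect_allele
  mism <- !(same | swapped)
  if (any(mism))
    prov <- rbind(prov, new_provenance(ex$snp[mism], rep("allele_mismatch", sum(mism))))

  keep_ex <- ex[!mism, , drop = FALSE]
  keep_out <- out[!mism, , drop = FALSE]
  sw <- swapped[!mism]
  beta_out <- ifelse(sw, -keep_out$beta, keep_out$beta)
  eaf_out <- ifelse(sw, 1 - keep_out$eaf, keep_out$eaf)

  if (nrow(keep_ex) == 0)
    stop_empty("no SNPs remain after harmonization")

  rows <- data.frame(snp = keep_ex$snp, chr = keep_ex$chr, pos = keep_ex$pos,
                     effect_allele = keep_ex$effect_allele,
                     other_allele = keep_ex$other_allele,
                     beta_exp = keep_ex$beta, se_exp = keep_ex$se,
                     beta_out = beta_out, se_out = keep_out$se,
                     eaf_exp = keep_ex$eaf, eaf_out = eaf_out,
                     stringsAsFactors = FALSE)
  new_harmonized_set(rows,
                     exposure_id = attr(exposure, "trait_id"),
                     outcome_id = attr(outcome, "trait_id"),
                     provenance = prov)
}
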