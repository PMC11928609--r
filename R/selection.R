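# Instrument selection: significance, strength, cis-window, MAF,
# exclusion list, palindrome and LD-clumping filters.

#' Instrument-selection configuration
#'
#' Thresholds follow the conventional drug-target cis-MR recipe:
#' association p < 1e-5, F > 10 against weak instruments, a +/-100 kb
#' cis window around the target gene, LD pruning at r^2 = 0.3 within
#' 100 kb, MAF > 0.01, palindromic SNPs removed, and an optional
#' user-supplied rsID exclusion list standing in for confounder lookups.
#'
#' @param p_threshold association p-value cutoff (keep p < this).
#' @param f_threshold weak-instrument F cutoff (keep F > this).
#' @param cis_window_bp half-width of the cis window around the gene.
#' @param ld_r2 clumping threshold; SNP pairs at or above this r^2 within
#'   \code{ld_window_bp} are pruned to the smaller p-value.
#' @param ld_window_bp clumping window in base pairs.
#' @param maf_min minor-allele-frequency floor, in (0, 0.5).
#' @param drop_palindromes drop A/T and C/G SNPs.
#' @param exclusion_list character vector of rsIDs to remove.
#' @param strict_maf if TRUE, SNPs lacking a frequency fail the MAF filter;
#'   by default they pass with a warning.
#' @return a \code{selection_config} list.
#' @export
selection_config <- function(p_threshold = 1e-5, f_threshold = 10,
                             cis_window_bp = 1e5, ld_r2 = 0.3,
                             ld_window_bp = 1e5, maf_min = 0.01,
                             drop_palindromes = TRUE,
                             exclusion_list = character(),
                             strict_maf = FALSE) {
  stopifnot(p_threshold > 0, f_threshold > 0, cis_window_bp > 0,
            ld_r2 > 0, ld_r2 <= 1, ld_window_bp > 0,
            maf_min > 0, maf_min < 0.5)
  structure(list(p_threshold = p_threshold, f_threshold = f_threshold,
                 cis_window_bp = cis_window_bp, ld_r2 = ld_r2,
                 ld_window_bp = ld_window_bp, maf_min = maf_min,
                 drop_palindromes = drop_palindromes,
                 exclusion_list = as.character(exclusion_list),
                 strict_maf = strict_maf),
            class = "selection_config")
}

#' Instrument-strength F-statistic
#'
#' The single-SNP approximation F = (beta/se)^2; F > 10 is the usual
#' weak-instrument cutoff.
#'
#' @param beta,se per-SNP effect and standard error (se > 0).
#' @return numeric vector of F statistics.
#' @examples
#' f_statistic(0.1, 0.03)  # 11.11
#' @export
f_statistic <- function(beta, se) {
  if (any(se <= 0)) stop_config("se must be > 0")
  (beta / se)^2
}

#' Read a pairwise LD table
#'
#' Expects a TSV with columns \code{snp_a}, \code{snp_b}, \code{r2}.
#' The table is treated as symmetric; absent pairs are taken as r^2 = 0
#' and self-pairs as r^2 = 1.
#'
#' @param path TSV path.
#' @return data.frame of class \code{ld_table}.
#' @export
read_ld_table <- function(path) {
  if (!file.exists(path)) stop_config(paste0("LD table not found: ", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("snp_a", "snp_b", "r2") %in% names(df)))
    stop_config("LD table must have columns snp_a, snp_b, r2")
  ld_table(df)
}

#' Construct an LD table from a data.frame
#' @param df data.frame with columns \code{snp_a}, \code{snp_b}, \code{r2}.
#' @return the validated data.frame with class \code{ld_table}.
#' @export
ld_table <- function(df = data.frame(snp_a = character(), snp_b = character(),
                                     r2 = numeric())) {
  stopifnot(all(c("snp_a", "snp_b", "r2") %in% names(df)),
            all(df$r2 >= 0 & df$r2 <= 1))
  structure(df[c("snp_a", "snp_b", "r2")], class = c("ld_table", "data.frame"))
}

#' Look up pairwise r^2 values
#' @param ld an \code{ld_table} (or NULL for no LD information).
#' @param a,b SNP id vectors (recycled).
#' @return numeric vector of r^2; 1 on self-pairs, 0 for unlisted pairs.
#' @export
ld_lookup <- function(ld, a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n); b <- rep_len(as.character(b), n)
  out <- ifelse(a == b, 1, 0)
  if (is.null(ld) || nrow(ld) == 0) return(out)
  key <- function(x, y) paste(x, y, sep = "\r")
  map <- stats::setNames(ld$r2, key(ld$snp_a, ld$snp_b))
  hit1 <- map[key(a, b)]; hit2 <- map[key(b, a)]
  r2 <- ifelse(is.na(hit1), hit2, hit1)
  ifelse(a == b, 1, ifelse(is.na(r2), 0, r2))
}

# Greedy clump: survivors sorted by ascending p (ties by chr, pos, snp);
# keep a SNP iff r2 < ld_r2 with every already-kept SNP within the window.
clump_snps <- function(df, ld, ld_r2, ld_window_bp) {
  ord <- order(df$pval, df$chr, df$pos, df$snp)
  df <- df[ord, , drop = FALSE]
  kept <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    prior <- which(kept)
    near <- prior[!is.na(df$chr[prior]) & !is.na(df$chr[i]) &
                    df$chr[prior] == df$chr[i] &
                    !is.na(df$pos[prior]) & !is.na(df$pos[i]) &
                    abs(df$pos[prior] - df$pos[i]) <= ld_window_bp]
    if (length(near) == 0) { kept[i] <- TRUE; next }
    r2 <- ld_lookup(ld, df$snp[i], df$snp[near])
    kept[i] <- all(r2 < ld_r2)
  }
  df$snp[!kept]
}

#' Select instrumental variables from an exposure table
#'
#' Applies the filters in a fixed, logged order: (1) association p-value,
#' (2) F-statistic, (3) cis window (when \code{gene_region} is given),
#' (4) MAF, (5) exclusion list, (6) palindromes, (7) greedy LD clumping.
#' Every removal is recorded with its reason, so
#' \code{nrow(exposure) == nrow(kept) + nrow(provenance)}.
#'
#' @param exposure a \code{sumstats} table (needs \code{pval} populated).
#' @param cfg a \code{\link{selection_config}}.
#' @param ld an \code{ld_table} or NULL (no LD pruning possible).
#' @param gene_region optional list/vector with \code{chrom}, \code{start},
#'   \code{end}: the cis filter keeps SNPs on \code{chrom} within
#'   \code{cis_window_bp} of [start, end].
#' @return list with \code{kept} (a \code{sumstats} table) and
#'   \code{provenance} (data.frame of snp, reason).
#' @export
select_instruments <- function(exposure, cfg = selection_config(), ld = NULL,
                               gene_region = NULL) {
  stopifnot(inherits(exposure, "sumstats"))
  if (nrow(exposure) == 0) stop_empty("exposure table is empty")
  df <- as.data.frame(exposure)
  prov <- new_provenance()
  drop <- function(df, bad, reason) {
    if (any(bad))
      prov <<- rbind(prov, new_provenance(df$snp[bad], rep(reason, sum(bad))))
    df[!bad, , drop = FALSE]
  }

  if (all(is.na(df$pval)))
    stop_config("p-value column required for instrument selection")
  df <- drop(df, is.na(df$pval) | df$pval >= cfg$p_threshold, "pval")
  if (nrow(df) > 0)
    df <- drop(df, f_statistic(df$beta, df$se) <= cfg$f_threshold,
               "weak_instrument")
  if (!is.null(gene_region) && nrow(df) > 0) {
    gr <- as.list(gene_region)
    lo <- as.numeric(gr$start) - cfg$cis_window_bp
    hi <- as.numeric(gr$end) + cfg$cis_window_bp
    out_cis <- is.na(df$chr) | is.na(df$pos) |
      df$chr != as.character(gr$chrom) | df$pos < lo | df$pos > hi
    df <- drop(df, out_cis, "cis_window")
  }
  if (nrow(df) > 0) {
    maf <- pmin(df$eaf, 1 - df$eaf)
    miss <- is.na(maf)
    if (any(miss) && !cfg$strict_maf)
      warning(sum(miss), " SNP(s) lack eaf; passing the MAF filter unchecked")
    fail_maf <- ifelse(miss, cfg$strict_maf, maf < cfg$maf_min)
    df <- drop(df, fail_maf, "maf")
  }
  if (nrow(df) > 0)
    df <- drop(df, df$snp %in% cfg$exclusion_list, "exclusion_list")
  if (cfg$drop_palindromes && nrow(df) > 0)
    df <- drop(df, is_palindromic(df$effect_allele, df$other_allele),
               "palindrome")
  if (nrow(df) > 0) {
    clumped <- clump_snps(df, ld, cfg$ld_r2, cfg$ld_window_bp)
    df <- drop(df, df$snp %in% clumped, "ld_clump")
  }
  if (nrow(df) == 0)
    stop_empty("no instruments survive selection")
  kept <- sumstats(df, trait_id = attr(exposure, "trait_id"),
                   trait_type = attr(exposure, "trait_type"))
  list(kept = kept, provenance = prov)
}

#' Remove MR-PRESSO outliers from a harmonized set
#'
#' Drops the rows flagged by \code{\link{mr_presso}}, preserving the order
#' of the remaining rows and logging each removal with reason
#' \code{presso_outlier}.
#'
#' @param h a \code{harmonized_set}.
#' @param presso a \code{presso_result} computed on \code{h}.
#' @return the pruned \code{harmonized_set}.
#' @export
remove_presso_outliers <- function(h, presso) {
  stopifnot(inherits(h, "harmonized_set"), inherits(presso, "presso_result"))
  idx <- presso$outlier_indices
  if (length(idx) == 0) return(h)
  if (length(idx) >= nrow(h$rows))
    stop_empty("MR-PRESSO flagged every instrument as an outlier")
  prov <- rbind(h$provenance,
                new_provenance(h$rows$snp[idx], rep("presso_outlier", length(idx))))
  new_harmonized_set(h$rows[-idx, , drop = FALSE], h$exposure_id, h$outcome_id,
                     prov)
}
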