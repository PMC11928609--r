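# Summary-statistics data model and TSV I/O.
#
# A summary-statistics table is a plain data.frame with the canonical
# columns below plus attributes trait_id / trait_type, class "sumstats".
# Betas are log-odds for binary traits and SD units for quantitative ones.

CANONICAL_COLS <- c("snp", "chr", "pos", "effect_allele", "other_allele",
                    "eaf", "beta", "se", "pval", "n")
REQUIRED_COLS  <- c("snp", "effect_allele", "other_allele", "beta", "se")
NUMERIC_COLS   <- c("pos", "eaf", "beta", "se", "pval", "n")
VALID_ALLELES  <- c("A", "C", "G", "T")

#' Construct a summary-statistics table
#'
#' Validates and normalises a data.frame of per-SNP GWAS/eQTL association
#' statistics into the canonical layout used throughout the package.
#' Alleles are uppercased; indels (multi-base alleles) and rows violating
#' basic invariants (non-positive SE, p outside (0,1], frequency outside
#' (0,1), duplicate SNP ids) are rejected with an error unless
#' \code{drop_invalid = TRUE}, in which case they are dropped and counted
#' in the \code{parse_report} attribute.
#'
#' @param df data.frame containing at least \code{snp}, \code{effect_allele},
#'   \code{other_allele}, \code{beta}, \code{se}; optionally \code{chr},
#'   \code{pos}, \code{eaf}, \code{pval}, \code{n}.
#' @param trait_id character label for the trait (e.g. a GWAS accession).
#' @param trait_type \code{"quantitative"} or \code{"binary"}.
#' @param drop_invalid drop offending rows instead of erroring.
#' @return a \code{sumstats} data.frame with attributes \code{trait_id},
#'   \code{trait_type} and \code{parse_report} (named counts of dropped rows).
#' @export
sumstats <- function(df, trait_id = "trait", trait_type = c("quantitative", "binary"),
                     drop_invalid = FALSE) {
  trait_type <- match.arg(trait_type)
  if (!is.data.frame(df)) stop_config("`df` must be a data.frame")
  missing_cols <- setdiff(REQUIRED_COLS, names(df))
  if (length(missing_cols) > 0)
    stop_config(paste0("missing required column(s): ",
                       paste(missing_cols, collapse = ", ")))
  for (col in setdiff(CANONICAL_COLS, names(df))) df[[col]] <- NA
  df <- df[CANONICAL_COLS]
  df$snp <- as.character(df$snp)
  df$chr <- as.character(df$chr)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele  <- toupper(as.character(df$other_allele))
  for (col in NUMERIC_COLS) df[[col]] <- suppressWarnings(as.numeric(df[[col]]))

  drop_reasons <- character(nrow(df))
  bad_num <- is.na(df$beta) | is.na(df$se) | df$se <= 0
  drop_reasons[bad_num] <- "bad_beta_se"
  bad_allele <- !(df$effect_allele %in% VALID_ALLELES) |
    !(df$other_allele %in% VALID_ALLELES) |
    df$effect_allele == df$other_allele
  drop_reasons[bad_allele & drop_reasons == ""] <- "bad_allele"
  bad_p <- !is.na(df$pval) & (df$pval <= 0 | df$pval > 1)
  drop_reasons[bad_p & drop_reasons == ""] <- "bad_pval"
  bad_eaf <- !is.na(df$eaf) & (df$eaf <= 0 | df$eaf >= 1)
  drop_reasons[bad_eaf & drop_reasons == ""] <- "bad_eaf"
  dup <- duplicated(df$snp)
  drop_reasons[dup & drop_reasons == ""] <- "duplicate_snp"

  bad <- drop_reasons != ""
  if (any(bad) && !drop_invalid)
    stop_config(paste0("invalid summary-statistics rows (", sum(bad), "): ",
                       paste(unique(drop_reasons[bad]), collapse = ", "),
                       "; use drop_invalid = TRUE to drop them"))
  report <- table(factor(drop_reasons[bad],
                         levels = c("bad_beta_se", "bad_allele", "bad_pval",
                                    "bad_eaf", "duplicate_snp")))
  df <- df[!bad, , drop = FALSE]
  rownames(df) <- NULL
  structure(df,
            trait_id = trait_id, trait_type = trait_type,
            parse_report = c(as.list(report), n_dropped = sum(bad)),
            class = c("sumstats", "data.frame"))
}

#' Read a summary-statistics TSV
#'
#' Reads a tab-delimited table of per-SNP associations. Non-canonical
#' headers are handled through \code{dialect}, a named character vector
#' mapping canonical names to the file's column names, e.g.
#' \code{c(snp = "rsid", pval = "p")}. Rows with non-numeric beta/se or
#' se <= 0 (and other invariant violations) are dropped and counted in
#' the returned table's \code{parse_report} attribute.
#'
#' @param path path to a TSV file.
#' @param dialect named character vector, canonical name -> file column name.
#' @inheritParams sumstats
#' @return a \code{sumstats} table.
#' @export
read_sumstats <- function(path, dialect = NULL, trait_id = basename(path),
                          trait_type = c("quantitative", "binary")) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop_config(paste0("file not found: ", path))
  df <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                      colClasses = "character"),
    error = function(e) stop_config(paste0("empty or unreadable input file: ",
                                           path)))
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      src <- dialect[[canon]]
      if (!src %in% names(df))
        stop_config(paste0("dialect column not found in file: ", src))
      names(df)[names(df) == src] <- canon
    }
  }
  missing_cols <- setdiff(REQUIRED_COLS, names(df))
  if (length(missing_cols) > 0)
    stop_config(paste0("missing required column(s) in ", path, ": ",
                       paste(missing_cols, collapse = ", ")))
  sumstats(df, trait_id = trait_id, trait_type = trait_type,
           drop_invalid = TRUE)
}

#' Write a summary-statistics TSV
#'
#' Writes the canonical-header TSV; missing values become empty cells so
#' that \code{read_sumstats(write_sumstats(x))} round-trips field-for-field.
#'
#' @param table a \code{sumstats} table.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_sumstats <- function(table, path) {
  stopifnot(inherits(table, "sumstats"))
  df <- as.data.frame(table)[CANONICAL_COLS]
  for (col in NUMERIC_COLS)
    df[[col]] <- ifelse(is.na(df[[col]]), "",
                        format(df[[col]], digits = 17, trim = TRUE, scientific = NA))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Odds ratio with Wald confidence interval from a log-odds effect
#'
#' @param beta log-odds effect estimate(s).
#' @param se standard error(s), > 0.
#' @param level confidence level in (0,1); 0.95 by default.
#' @return data.frame with columns \code{or}, \code{ci_low}, \code{ci_high}.
#' @examples
#' beta_to_or(log(2), 0.1)
#' @export
beta_to_or <- function(beta, se, level = 0.95) {
  if (any(se <= 0)) stop_config("se must be > 0")
  if (level <= 0 || level >= 1) stop_config("level must be in (0,1)")
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(or = exp(beta), ci_low = exp(beta - z * se),
             ci_high = exp(beta + z * se))
}
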