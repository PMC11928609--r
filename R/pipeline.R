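# End-to-end pipelines chaining selection, harmonization, estimation and
# diagnostics, with TSV outputs and a JSON run manifest.

#' Load and validate a pipeline run configuration
#'
#' Configurations are plain lists (or YAML files deserializing to one)
#' with paths to the input tables plus options. Required fields depend on
#' the pipeline; referenced paths are checked at validation time.
#'
#' @param config a named list or path to a YAML file.
#' @param required character vector of required fields.
#' @return the validated config list.
#' @export
load_run_config <- function(config, required = c("exposure", "outcome", "out_dir")) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop_config(paste0("config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_config("config must be a list or YAML file path")
  for (field in required)
    if (is.null(config[[field]]))
      stop_config(paste0("config field missing: ", field))
  for (field in intersect(c("exposure", "outcome", "ld", "exclusion_list_file"),
                          names(config)))
    if (is.character(config[[field]]) && !file.exists(config[[field]]))
      stop_config(paste0("config path for '", field, "' does not exist: ",
                         config[[field]]))
  if (!is.null(config$mediators))
    for (p in unlist(config$mediators))
      if (!file.exists(p))
        stop_config(paste0("mediator table does not exist: ", p))
  config
}

selection_from_config <- function(config) {
  sel <- config$selection %||% list()
  excl <- sel$exclusion_list %||% character()
  if (!is.null(config$exclusion_list_file))
    excl <- union(excl, readLines(config$exclusion_list_file, warn = FALSE))
  do.call(selection_config, utils::modifyList(sel, list(exclusion_list = excl)))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_manifest <- function(out_dir, config, seed, counts, inputs) {
  inputs <- Filter(function(p) is.character(p) && file.exists(p), inputs)
  checksums <- vapply(inputs, function(p) unname(tools::md5sum(p)),
                      character(1))
  manifest <- list(package = "mrpath",
                   version = as.character(utils::packageVersion("mrpath")),
                   seed = seed, config = config, counts = counts,
                   input_md5 = as.list(checksums),
                   effect_scale = "log-odds (binary traits) / SD units (quantitative)")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
}

# Shared core: read, select, harmonize, PRESSO-prune one exposure/outcome
# pair. Returns the pruned harmonized set plus stage counts.
prepare_pair <- function(exposure, outcome, cfg, ld = NULL, gene_region = NULL,
                         n_sim = 1000, seed = NULL, presso_prune = TRUE) {
  sel <- select_instruments(exposure, cfg, ld = ld, gene_region = gene_region)
  h <- harmonize(sel$kept, outcome, provenance = sel$provenance)
  presso <- NULL
  if (presso_prune && n_snp(h) >= 4) {
    presso <- mr_presso(h, n_sim = n_sim, seed = seed)
    h <- remove_presso_outliers(h, presso)
  }
  list(h = h, presso = presso,
       counts = list(input = nrow(exposure), selected = nrow(sel$kept),
                     harmonized = n_snp(h) + length(presso$outlier_indices %||% integer()),
                     analyzed = n_snp(h)))
}

#' Univariable MR pipeline
#'
#' Full exposure -> outcome analysis: instrument selection, harmonization,
#' MR-PRESSO outlier removal, the five-method estimator suite, and the
#' sensitivity battery (Q/I^2, Egger intercept, PRESSO global p,
#' leave-one-out, funnel export). Writes estimates.tsv, sensitivity.tsv,
#' loo.tsv, funnel.tsv, provenance.tsv and manifest.json to
#' \code{config$out_dir}.
#'
#' Config fields: \code{exposure}, \code{outcome} (TSV paths or
#' \code{sumstats} tables), \code{out_dir}; optional \code{ld} (TSV path),
#' \code{gene_region} (list chrom/start/end), \code{selection} (list of
#' \code{\link{selection_config}} arguments), \code{exclusion_list_file},
#' \code{seed}, \code{n_boot}, \code{n_sim}, \code{dialect_exposure},
#' \code{dialect_outcome}.
#'
#' @param config list or YAML path (see Details).
#' @return invisibly, a list with the harmonized set, estimates and
#'   sensitivity tables.
#' @export
run_uvmr_pipeline <- function(config) {
  config <- load_run_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  n_boot <- config$n_boot %||% 1000L
  n_sim <- config$n_sim %||% 1000L

  exposure <- if (inherits(config$exposure, "sumstats")) config$exposure else
    read_sumstats(config$exposure, dialect = config$dialect_exposure)
  outcome <- if (inherits(config$outcome, "sumstats")) config$outcome else
    read_sumstats(config$outcome, dialect = config$dialect_outcome,
                  trait_type = "binary")
  ld <- if (!is.null(config$ld)) read_ld_table(config$ld) else NULL

  prep <- prepare_pair(exposure, outcome, selection_from_config(config),
                       ld = ld, gene_region = config$gene_region,
                       n_sim = n_sim, seed = seed)
  h <- prep$h

  est <- mr_all_methods(h, n_boot = n_boot, seed = seed + 10L)
  est <- cbind(exposure = h$exposure_id, outcome = h$outcome_id, est,
               stringsAsFactors = FALSE)
  sens <- cbind(exposure = h$exposure_id, outcome = h$outcome_id,
                sensitivity_summary(h, n_sim = n_sim, seed = seed + 20L),
                stringsAsFactors = FALSE)
  loo <- if (n_snp(h) >= 3) leave_one_out(h) else NULL

  write_tsv(est, file.path(out_dir, "estimates.tsv"))
  write_tsv(sens, file.path(out_dir, "sensitivity.tsv"))
  if (!is.null(loo)) write_tsv(loo, file.path(out_dir, "loo.tsv"))
  write_tsv(funnel_data(h), file.path(out_dir, "funnel.tsv"))
  write_tsv(h$provenance, file.path(out_dir, "provenance.tsv"))
  write_manifest(out_dir, config[setdiff(names(config), c("exposure", "outcome"))],
                 seed, prep$counts,
                 Filter(is.character, config[c("exposure", "outcome", "ld")]))
  invisible(list(harmonized = h, estimates = est, sensitivity = sens,
                 loo = loo, counts = prep$counts))
}

#' Two-step mediation pipeline with MVMR adjustment
#'
#' Step 1 estimates the exposure's effect on every candidate mediator from
#' the exposure's instruments; mediators significant at \code{alpha} are
#' screened through; step 2 estimates each surviving mediator's effect on
#' the outcome from the mediator's own instruments; the total effect is
#' the exposure -> outcome IVW; the mediated effect, direct effect and
#' delta-method proportion interval follow, one row per surviving
#' mediator. Finally the exposure and the top mediator (smallest step-2 p)
#' enter a multivariable IVW. Writes step1.tsv, step2.tsv, mediation.tsv,
#' mvmr.tsv and manifest.json.
#'
#' Config fields: \code{exposure}, \code{outcome}, \code{mediators}
#' (named list/vector of TSV paths or \code{sumstats}), \code{out_dir};
#' optional \code{gene_region}, \code{selection}, \code{ld}, \code{alpha},
#' \code{seed}, \code{n_boot}, \code{n_sim}, \code{screen_adjust}.
#'
#' @param config list or YAML path.
#' @return invisibly, a list with step1/step2 tables, the mediation table
#'   and the MVMR table (NULL when no mediator survives screening).
#' @export
run_mediation_pipeline <- function(config) {
  config <- load_run_config(config, required = c("exposure", "outcome",
                                                 "mediators", "out_dir"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  n_boot <- config$n_boot %||% 1000L
  n_sim <- config$n_sim %||% 1000L
  alpha <- config$alpha %||% 0.05
  cfg <- selection_from_config(config)
  ld <- if (!is.null(config$ld)) read_ld_table(config$ld) else NULL

  load_tbl <- function(x, type = "quantitative", id = NULL)
    if (inherits(x, "sumstats")) x else
      read_sumstats(x, trait_type = type,
                    trait_id = id %||% basename(as.character(x)))
  exposure <- load_tbl(config$exposure)
  outcome <- load_tbl(config$outcome, type = "binary")
  med_list <- config$mediators
  med_ids <- names(med_list) %||% vapply(med_list, function(p)
    basename(as.character(p)), character(1))
  mediators <- stats::setNames(
    lapply(seq_along(med_list), function(i)
      load_tbl(med_list[[i]], id = med_ids[i])), med_ids)

  # exposure instruments, used for the total effect and every step 1
  sel <- select_instruments(exposure, cfg, ld = ld,
                            gene_region = config$gene_region)
  h_total <- harmonize(sel$kept, outcome, provenance = sel$provenance)
  if (n_snp(h_total) >= 4) {
    pr <- mr_presso(h_total, n_sim = n_sim, seed = seed)
    h_total <- remove_presso_outliers(h_total, pr)
  }
  total <- if (n_snp(h_total) >= 2) mr_ivw(h_total) else {
    r <- h_total$rows
    mr_wald_ratio(r$beta_exp, r$se_exp, r$beta_out, r$se_out)
  }

  step1 <- do.call(rbind, lapply(med_ids, function(id) {
    h1 <- harmonize(sel$kept, mediators[[id]])
    est <- if (n_snp(h1) >= 2) mr_ivw(h1) else {
      r <- h1$rows
      mr_wald_ratio(r$beta_exp, r$se_exp, r$beta_out, r$se_out)
    }
    cbind(mediator = id, est, stringsAsFactors = FALSE)
  }))
  scr <- screen_mediators(step1, alpha = alpha,
                          adjust = config$screen_adjust %||% "none")

  step2 <- NULL; mediation <- NULL; mvmr <- NULL
  if (length(scr$selected) > 0) {
    step2_rows <- list(); med_rows <- list()
    for (id in scr$selected) {
      sel2 <- tryCatch(select_instruments(mediators[[id]], cfg, ld = ld),
                       mrpath_empty_result = function(e) NULL)
      if (is.null(sel2)) next
      h2 <- tryCatch(harmonize(sel2$kept, outcome, provenance = sel2$provenance),
                     mrpath_empty_result = function(e) NULL)
      if (is.null(h2)) next
      if (n_snp(h2) >= 4) {
        pr2 <- mr_presso(h2, n_sim = n_sim, seed = seed + 30L)
        h2 <- remove_presso_outliers(h2, pr2)
      }
      est2 <- if (n_snp(h2) >= 2) mr_ivw(h2) else {
        r <- h2$rows
        mr_wald_ratio(r$beta_exp, r$se_exp, r$beta_out, r$se_out)
      }
      step2_rows[[id]] <- cbind(mediator = id, est2, stringsAsFactors = FALSE)
      med <- mediation_effect(step1[step1$mediator == id, ], est2, total)
      med_rows[[id]] <- data.frame(mediator = id,
                                   mediating_effect = med$mediated,
                                   direct_effect = med$direct,
                                   total_effect = med$total,
                                   proportion_pct = med$proportion_pct,
                                   ci_low = med$ci_low, ci_high = med$ci_high,
                                   stringsAsFactors = FALSE)
    }
    step2 <- if (length(step2_rows)) do.call(rbind, step2_rows)
    mediation <- if (length(med_rows)) do.call(rbind, med_rows)

    if (!is.null(step2) && nrow(step2) > 0) {
      top <- step2$mediator[which.min(step2$pval)]
      mv_snps <- union(sel$kept$snp,
                       select_instruments(mediators[[top]], cfg, ld = ld)$kept$snp)
      mvh <- tryCatch(
        mvmr_harmonize(stats::setNames(list(exposure, mediators[[top]]),
                                       c(h_total$exposure_id, top)),
                       outcome, snps = mv_snps),
        mrpath_empty_result = function(e) NULL)
      if (!is.null(mvh) && nrow(mvh$beta_exp) > ncol(mvh$beta_exp) + 1)
        mvmr <- cbind(adjustment = top, outcome = h_total$outcome_id,
                      mvmr_ivw(mvh), stringsAsFactors = FALSE)
    }
  } else {
    warning("no mediator passed step-1 screening; mediation table is empty")
  }

  write_tsv(step1, file.path(out_dir, "step1.tsv"))
  write_tsv(step2 %||% step1[0, ], file.path(out_dir, "step2.tsv"))
  write_tsv(mediation %||% data.frame(), file.path(out_dir, "mediation.tsv"))
  if (!is.null(mvmr)) write_tsv(mvmr, file.path(out_dir, "mvmr.tsv"))
  counts <- list(mediators = length(mediators),
                 screened_in = length(scr$selected),
                 screened_up = scr$n_up, screened_down = scr$n_down,
                 mediation_rows = nrow(mediation %||% data.frame()))
  write_manifest(out_dir,
                 config[setdiff(names(config),
                                c("exposure", "outcome", "mediators"))],
                 seed, counts, list())
  invisible(list(total = total, step1 = step1, screen = scr, step2 = step2,
                 mediation = mediation, mvmr = mvmr, counts = counts))
}
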