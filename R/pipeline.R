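#' Assemble a pipeline configuration
#'
#' A plain list validated here; can also be read from a YAML file by
#' [run_pipeline()]. Exactly one data source is used: a simulation block, or
#' paths to marker and phenotype files.
#'
#' @param sim a [sim_config()] (or list of its arguments) to generate
#'   synthetic data, or NULL to read files.
#' @param markers_file path to a marker CSV (or `.vcf`/`.vcf.gz`); used when
#'   `sim` is NULL.
#' @param pheno_file path to a tidy phenotype CSV with columns genotype,
#'   location, year, maturity_group, is_check, yield.
#' @param thresholds a [class_thresholds()].
#' @param protocol a [cv_protocol()].
#' @param models list of [model_spec()]s to evaluate.
#' @param decision_threshold discard threshold on the low-class probability.
#' @param msi_mode `"all"` or `"observed"` (see [compute_msi()]).
#' @param fit_opts a [fa1_control()].
#' @param max_missing QC missingness cutoff.
#' @param impute_opts list of [impute_markers()] settings (`max_iter`, `tol`,
#'   `ntree`).
#' @param seed integer seed propagated to every stochastic stage.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), markers_file = NULL,
                            pheno_file = NULL,
                            thresholds = class_thresholds(),
                            protocol = cv_protocol(),
                            models = list(model_spec("elastic_net_multinomial"),
                                          model_spec("random_forest")),
                            decision_threshold = 0.70, msi_mode = "all",
                            fit_opts = fa1_control(), max_missing = 0.20,
                            impute_opts = list(max_iter = 10, tol = 0, ntree = 100),
                            seed = 1) {
  if (is.null(sim) && (is.null(markers_file) || is.null(pheno_file)))
    stop("either a `sim` block or both `markers_file` and `pheno_file` are required")
  if (!is.null(sim) && !inherits(sim, "sim_config")) sim <- do.call(sim_config, sim)
  structure(list(sim = sim, markers_file = markers_file, pheno_file = pheno_file,
                 thresholds = thresholds, protocol = protocol, models = models,
                 decision_threshold = decision_threshold, msi_mode = msi_mode,
                 fit_opts = fit_opts, max_missing = max_missing,
                 impute_opts = impute_opts, seed = seed),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full advancement-decision pipeline
#'
#' Sequences simulate (optional) -> marker QC -> imputation -> GRM -> FA1
#' genomic mixed model -> check model -> selection index -> repeated-CV
#' classification (per model) -> evaluation -> probability-threshold
#' decisions, writing every documented artifact plus a reproducibility
#' manifest (config, seed, file checksums) into `out`. Any stage failure
#' halts with the stage name; artifacts of completed stages are retained.
#'
#' @param config a [pipeline_config()], a plain list of its arguments, or the
#'   path to a YAML file holding them.
#' @param out output directory.
#' @return a `pipeline_run` list with the key in-memory objects and the
#'   manifest path.
#' @export
run_pipeline <- function(config = pipeline_config(), out) {
  if (is.character(config) && length(config) == 1) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a YAML config requires the 'yaml' package")
    config <- do.call(pipeline_config, yaml::read_yaml(config))
  }
  if (!inherits(config, "pipeline_config")) config <- do.call(pipeline_config, config)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log <- file.path(out, "pipeline.log")
  note <- function(...) cat(sprintf(...), "\n", file = log, append = TRUE, sep = "")
  artifacts <- character(0)
  keep <- function(p) { artifacts <<- c(artifacts, p); p }

  if (!is.null(config$sim)) {
    cfg <- config$sim
    cfg$seed <- config$seed
    markers_raw <- stage("simulate", simulate_markers(cfg))
    trials <- stage("simulate", simulate_trials(markers_raw, cfg))
    pheno <- trials$pheno
    stage("simulate", write_simdata(markers_raw, trials, out))
    keep(file.path(out, "markers.csv")); keep(file.path(out, "pheno.csv"))
    note("simulate: %d genotypes, %d markers, %d records",
         nrow(markers_raw), ncol(markers_raw), nrow(pheno))
  } else {
    trials <- NULL
    markers_raw <- stage("read", {
      if (grepl("\\.vcf(\\.gz)?$", config$markers_file))
        read_markers_vcf(config$markers_file, major_allele = TRUE)
      else read_markers_csv(config$markers_file)
    })
    pheno <- stage("read", utils::read.csv(config$pheno_file, stringsAsFactors = FALSE))
    need <- c("genotype", "location", "yield", "maturity_group", "is_check")
    if (!all(need %in% names(pheno)))
      stop("phenotype file must have columns: ", paste(need, collapse = ", "))
  }

  markers_qc <- stage("qc", qc_filter(markers_raw, config$max_missing))
  write_removal_log(markers_qc, keep(file.path(out, "qc_removal_log.tsv")))
  note("qc: %d of %d markers retained", ncol(markers_qc), ncol(markers_raw))

  io <- config$impute_opts
  markers_imp <- stage("impute", impute_markers(
    markers_qc, max_iter = io$max_iter %||% 10, tol = io$tol %||% 0,
    seed = config$seed, ntree = io$ntree %||% 100))
  write_markers_csv(markers_imp, keep(file.path(out, "markers_imputed.csv")))
  note("impute: %d cells filled in %d passes", sum(is.na(markers_qc)),
       attr(markers_imp, "impute_iterations") %||% 0L)

  line_ids <- unique(pheno$genotype[!pheno$is_check])
  line_ids <- intersect(rownames(markers_imp), line_ids)
  grm <- stage("grm", compute_grm(markers_imp[line_ids, ]))
  write_grm_csv(grm, keep(file.path(out, "grm.csv")))

  fit <- stage("fit-gxe", fa1_gblup(pheno[!pheno$is_check, ], grm, config$fit_opts))
  gblups <- stage("fit-gxe", predict(fit))
  write_gblups_csv(gblups, keep(file.path(out, "gblups.csv")))
  keep(file.path(out, "gblups_mask.csv"))
  writeLines(utils::capture.output(print(summary(fit))),
             keep(file.path(out, "fit_summary.txt")))
  note("fit-gxe: logLik %.2f after %d iterations (converged: %s)",
       fit$loglik, fit$n_iter, fit$converged)

  checkref <- stage("check-model", fit_check_model(pheno[pheno$is_check, ], config$fit_opts))
  utils::write.csv(as.data.frame(checkref), keep(file.path(out, "check_reference.csv")),
                   row.names = FALSE)

  mg_map <- stage("msi", {
    mg <- tapply(pheno$maturity_group, pheno$genotype, function(m) m[1])
    stats::setNames(as.vector(mg), names(mg))
  })
  msi <- stage("msi", compute_msi(gblups, checkref, mg_map, config$thresholds,
                                  mode = config$msi_mode))
  write_msi_csv(msi, keep(file.path(out, "msi.csv")))
  note("msi: classes %s", paste(capture_props(msi$yield_class), collapse = ", "))

  pca <- stage("pca", pca_markers(markers_imp[line_ids, ], k = 2))

  cv_list <- list(); decisions <- NULL
  for (spec in config$models) {
    tag <- if (spec$family == "elastic_net_multinomial") "glmnet" else "rf"
    preds <- stage(paste0("classify-", tag),
                   run_repeated_cv(markers_imp[line_ids, ], msi, spec, config$protocol))
    write_cv_csv(preds, keep(file.path(out, paste0("cv_predictions_", tag, ".csv"))))
    decisions <- stage(paste0("decide-", tag),
                       apply_decision_rule(preds, config$decision_threshold))
    stage(paste0("evaluate-", tag),
          write_evaluation_csv(out, preds, prefix = tag, decisions = decisions))
    div <- stage(paste0("evaluate-", tag), diversity_diagnostic(pca, decisions))
    writeLines(utils::capture.output(print(div)),
               keep(file.path(out, paste0(tag, "_diversity.txt"))))
    cv_list[[tag]] <- preds
    note("classify-%s: pooled accuracy %.3f, discard fraction %.2f", tag,
         mean(preds$true_class == preds$predicted_class),
         attr(decisions, "discard_fraction"))
  }

  manifest <- list(
    package = "yieldclass",
    version = as.character(utils::packageVersion("yieldclass")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = config$seed,
    config = rapply(unclass(config), unclass, how = "replace"),
    checksums = as.list(tools::md5sum(artifacts[file.exists(artifacts)])))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE, digits = NA)

  structure(list(fit = fit, gblups = gblups, check_reference = checkref,
                 msi = msi, cv = cv_list, decisions = decisions, pca = pca,
                 out = out, manifest = file.path(out, "manifest.json")),
            class = "pipeline_run")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

capture_props <- function(f) {
  tab <- table(f)
  sprintf("%s %.0f%%", names(tab), 100 * tab / sum(tab))
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("pipeline_run: artifacts in", x$out, "\n")
  print(x$msi)
  for (tag in names(x$cv)) print(x$cv[[tag]])
  invisible(x)
}
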