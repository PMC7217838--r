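# End-to-end orchestration: (simulate | ingest) -> windows/k-mers ->
# binding calls -> per-patient loads -> dichotomization -> cohort
# statistics, writing every intermediate and a machine-readable run
# manifest so a run is reproducible from its output directory alone.

#' Pipeline configuration
#'
#' Exactly one of `simulate` (with a [cohortConfig()]) or `input_dir`
#' (a directory laid out as written by [writeCohort()]) must be active.
#'
#' @param simulate logical; simulate the cohort instead of reading one.
#' @param cohort_config a [cohortConfig()] (simulate mode).
#' @param input_dir directory with `proteins.fasta`, `variants.tsv`,
#'   `genotypes.tsv`, `phenotypes.csv` (ingest mode).
#' @param length_set k-mer lengths.
#' @param thresholds a [binderThresholds()].
#' @param counting_mode load counting mode, see
#'   [computeSelfAntigenLoad()].
#' @param predictor `"surrogate"` or `"external"`.
#' @param binding_table_path NetMHC-style TSV (external predictor).
#' @param cutoff_mode `"roc_youden"` or a fixed numeric cutoff.
#' @param seed integer seed (simulate mode; overrides the one inside
#'   `cohort_config` when given).
#' @return validated list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(simulate = TRUE, cohort_config = cohortConfig(),
                           input_dir = NULL, length_set = 8:14,
                           thresholds = binderThresholds(),
                           counting_mode = "unique_peptide",
                           predictor = "surrogate",
                           binding_table_path = NULL,
                           cutoff_mode = "roc_youden", seed = NULL) {
  if (simulate == !is.null(input_dir))
    stop("exactly one of simulate or input_dir must be active")
  if (!is.null(input_dir) && !dir.exists(input_dir))
    stop("input_dir does not exist: ", input_dir)
  if (!identical(cutoff_mode, "roc_youden") && !is.numeric(cutoff_mode))
    stop("cutoff_mode must be \"roc_youden\" or a numeric cutoff")
  if (!is.null(binding_table_path) && !file.exists(binding_table_path))
    stop("binding_table_path does not exist: ", binding_table_path)
  if (simulate && !is.null(seed)) cohort_config$seed <- as.integer(seed)
  structure(list(simulate = simulate, cohort_config = cohort_config,
                 input_dir = input_dir, length_set = length_set,
                 thresholds = thresholds, counting_mode = counting_mode,
                 predictor = predictor,
                 binding_table_path = binding_table_path,
                 cutoff_mode = cutoff_mode),
            class = "PipelineConfig")
}

#' Run the full self-antigen load pipeline
#'
#' Stages: acquire cohort (simulate or ingest), extract mutant windows
#' and enumerate k-mers, predict binding, aggregate per-patient loads,
#' dichotomize (ROC/Youden or fixed cutoff), and run the cohort
#' statistics (group summary table, logistic regression, ROC points,
#' carrier contrasts are left to the caller). All intermediates are
#' written under `output_dir` together with `manifest.json` recording
#' the configuration, seed, package version and per-stage record
#' counts. Rerunning with the same config reproduces identical outputs.
#'
#' @param config a [pipelineConfig()].
#' @param output_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return (invisibly) list of class `PipelineReport`: `profiles`
#'   (per-patient covariates + load + high_load), `roc`, `table1`,
#'   `logistic`, `cutoff`, `manifest`.
#' @export
runPipeline <- function(config = pipelineConfig(), output_dir,
                        quiet = FALSE) {
  if (!inherits(config, "PipelineConfig"))
    stop("config must be built with pipelineConfig()")
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[pipeline] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  say("stage 1/5: cohort")
  cohort <- stage("cohort", {
    if (config$simulate) simulateCohort(config$cohort_config)
    else readCohort(config$input_dir)
  })
  writeCohort(cohort, file.path(output_dir, "inputs"))

  say("stage 2/5: peptides")
  pep <- stage("peptides", buildPeptideSet(variants(cohort),
                                           proteins(cohort),
                                           length_set = config$length_set))
  writePeptideTsv(pep, file.path(output_dir, "peptides.tsv"))

  say("stage 3/5: binding (", nrow(pep$kmers), " k-mers)")
  calls <- stage("binding", {
    bt <- if (!is.null(config$binding_table_path))
      readNetmhcTable(config$binding_table_path, config$thresholds)
    predictBinding(pep, genotypes(cohort), predictor = config$predictor,
                   binding_table = bt, thresholds = config$thresholds)
  })
  write.table(calls, file.path(output_dir, "binding_calls.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  say("stage 4/5: load")
  ph <- phenotypes(cohort)
  loads <- stage("load", selfAntigenLoads(calls, sample_ids = ph$sample_id,
                                          counting_mode = config$counting_mode))
  profiles <- merge(ph, loads, by = "sample_id", sort = FALSE)

  say("stage 5/5: statistics")
  roc <- stage("roc", rocAndCutoff(profiles$self_antigen_load,
                                   profiles$onset_group))
  cutoff <- if (identical(config$cutoff_mode, "roc_youden"))
    roc$chosen_cutoff else as.numeric(config$cutoff_mode)
  profiles$high_load <- dichotomizeLoad(profiles$self_antigen_load, cutoff)
  write.csv(profiles, file.path(output_dir, "patient_loads.csv"),
            row.names = FALSE, quote = FALSE)
  rocTab <- data.frame(threshold = roc$thresholds,
                       sensitivity = roc$sensitivity,
                       specificity = roc$specificity, youden = roc$youden)
  write.csv(rocTab, file.path(output_dir, "roc_points.csv"),
            row.names = FALSE, quote = FALSE)
  t1 <- stage("table1", table1Summary(profiles))
  write.csv(cbind(characteristic = rownames(t1), as.data.frame(t1)),
            file.path(output_dir, "group_summary.csv"), row.names = FALSE)
  logit <- stage("logistic", fitLogistic(profiles))
  write.csv(logit$table, file.path(output_dir, "adjusted_odds_ratios.csv"),
            row.names = FALSE, quote = FALSE)

  manifest <- list(
    package = "SelfAntigenLoad",
    version = as.character(packageVersion("SelfAntigenLoad")),
    simulate = config$simulate,
    seed = if (config$simulate) cohort@seed else NA,
    length_set = config$length_set,
    thresholds = unclass(config$thresholds),
    counting_mode = config$counting_mode,
    predictor = config$predictor,
    cutoff_mode = config$cutoff_mode,
    cutoff = cutoff,
    auc = roc$auc,
    counts = list(proteins = length(proteins(cohort)),
                  variants = nrow(variants(cohort)),
                  samples = nrow(ph),
                  kmers = nrow(pep$kmers),
                  binding_calls = nrow(calls))
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("done; cutoff = ", cutoff, ", AUC = ", round(roc$auc, 3))
  invisible(structure(list(profiles = profiles, roc = roc, table1 = t1,
                           logistic = logit, cutoff = cutoff,
                           manifest = manifest, cohort = cohort),
                      class = "PipelineReport"))
}

#' @export
print.PipelineReport <- function(x, ...) {
  cat("Self-antigen load pipeline report\n")
  cat("  samples: ", nrow(x$profiles), "; cutoff: load > ", x$cutoff,
      "; AUC = ", round(x$roc$auc, 3), "\n\n", sep = "")
  print(x$table1)
  cat("\n")
  print(x$logistic)
  invisible(x)
}
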