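default_pipeline_config <- function() {
  list(
    cohort1_expression = NULL, cohort1_clinical = NULL,
    cohort2_expression = NULL, cohort2_clinical = NULL,
    gene_list = NULL, reference = NULL,
    horizon = 1, time_unit = "as-supplied", horizon_unit = NULL,
    seed = 1L, mad_threshold = 0.5, min_freq = 0.2, max_freq = 0.8,
    screen_alpha = 0.05, n_folds = 10, n_perm = 200,
    outdir = NULL
  )
}

#' Run the full gene-pair signature workflow
#'
#' Executes the stages in order: gene filtering (presence + MAD in both
#' cohorts), pair scoring and candidate selection, signature training
#' (screen, LASSO-Cox, ROC cutoff) on cohort 1, frozen-cutoff validation on
#' cohort 2, then (when a reference matrix is configured) immune
#' deconvolution of cohort 1 with risk-group comparison and risk-score
#' correlation. Any stage failure halts with the stage name attached;
#' re-running with identical config and inputs reproduces identical output
#' checksums.
#'
#' @param config A named list, or path to a YAML file, with fields
#'   `cohort1_expression`, `cohort1_clinical`, `cohort2_expression`,
#'   `cohort2_clinical`, `gene_list` (file paths), optional `reference`,
#'   and parameters `horizon`, `time_unit`, `seed`, `mad_threshold`,
#'   `min_freq`, `max_freq`, `screen_alpha`, `n_folds`, `n_perm`, `outdir`.
#' @param seed Optional override of `config$seed`.
#' @param outdir Optional override of `config$outdir` (default: tempdir).
#' @return A `run_manifest`: config snapshot, seed, per-stage counts and
#'   md5 checksums of every written artifact. Also written to
#'   `<outdir>/manifest.json`.
#' @export
run_pipeline <- function(config, seed = NULL, outdir = NULL) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort_config(paste0("config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort_config("config must be a named list or a YAML path")
  cfg <- utils::modifyList(default_pipeline_config(), config)
  if (!is.null(seed)) cfg$seed <- seed
  if (!is.null(outdir)) cfg$outdir <- outdir
  cfg$outdir <- cfg$outdir %||% file.path(tempdir(), "pairhazard_run")
  cfg$seed <- as.integer(cfg$seed)

  # validate before any compute
  required_files <- c("cohort1_expression", "cohort1_clinical",
                      "cohort2_expression", "cohort2_clinical", "gene_list")
  for (field in required_files) {
    if (is.null(cfg[[field]])) abort_config(paste0("config field missing: ", field))
    if (!file.exists(cfg[[field]])) {
      abort_config(sprintf("config field '%s': file not found: %s", field, cfg[[field]]))
    }
  }
  if (!is.null(cfg$reference) && !file.exists(cfg$reference)) {
    abort_config(sprintf("config field 'reference': file not found: %s", cfg$reference))
  }
  if (!is.numeric(cfg$horizon) || cfg$horizon <= 0) {
    abort_config("config field 'horizon' must be a positive number")
  }
  if (!is.null(cfg$horizon_unit) && !identical(cfg$horizon_unit, cfg$time_unit)) {
    abort_config(sprintf(
      "unit mismatch: horizon is in '%s' but survival times are declared '%s'",
      cfg$horizon_unit, cfg$time_unit))
  }
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)

  stages <- list()
  out_paths <- character(0)
  stage <- function(name, counts, outputs) {
    rlang::inform(sprintf("[%s] %s", name,
                          paste(names(counts), unlist(counts), sep = "=", collapse = " ")))
    stages[[name]] <<- list(counts = counts, outputs = outputs)
    out_paths <<- c(out_paths, outputs)
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      ph_abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
               "ph_stage_error", stage = name, parent = e)
    })
  }
  pth <- function(file) file.path(cfg$outdir, file)

  # inputs
  expr1 <- run_stage("read", read_expression(cfg$cohort1_expression))
  clin1 <- run_stage("read", read_clinical(cfg$cohort1_clinical, time_unit = cfg$time_unit))
  expr2 <- run_stage("read", read_expression(cfg$cohort2_expression))
  clin2 <- run_stage("read", read_clinical(cfg$cohort2_clinical, time_unit = cfg$time_unit))
  candidates <- run_stage("read", read_gene_list(cfg$gene_list))

  # filter-genes
  flt <- run_stage("filter-genes",
                   filter_genes(candidates, expr1, expr2, mad_threshold = cfg$mad_threshold))
  readr::write_tsv(flt$report, pth("filter_report.tsv"), progress = FALSE)
  write_gene_list(flt$retained, pth("retained_genes.txt"))
  stage("filter-genes",
        list(genes_in = flt$input_count, genes_out = length(flt$retained)),
        pth(c("filter_report.tsv", "retained_genes.txt")))

  # score-pairs
  pm1 <- run_stage("score-pairs", build_pair_matrix(expr1, flt$retained))
  pm2 <- run_stage("score-pairs", build_pair_matrix(expr2, flt$retained))
  cand <- run_stage("score-pairs",
                    select_candidate_pairs(pm1, pm2, cfg$min_freq, cfg$max_freq))
  readr::write_tsv(cand$pairs1, pth("pair_scores_cohort1.tsv"), progress = FALSE)
  readr::write_tsv(cand$pairs2, pth("pair_scores_cohort2.tsv"), progress = FALSE)
  stage("score-pairs",
        list(pairs_all = nrow(pm1), pairs_candidate = length(cand$pair)),
        pth(c("pair_scores_cohort1.tsv", "pair_scores_cohort2.tsv")))

  # train
  trained <- run_stage("train",
                       train_signature(cand$pairs1, clin1, alpha = cfg$screen_alpha,
                                       n_folds = cfg$n_folds, seed = cfg$seed,
                                       horizon = cfg$horizon))
  write_signature(trained$model, pth("signature.json"))
  readr::write_tsv(trained$screen, pth("screen.tsv"), progress = FALSE)
  readr::write_tsv(trained$profile, pth("risk_training.tsv"), progress = FALSE)
  stage("train",
        list(pairs_screened = sum(trained$screen$passed),
             pairs_selected = nrow(trained$model$pairs),
             cutoff = trained$model$cutoff),
        pth(c("signature.json", "screen.tsv", "risk_training.tsv")))

  # validate
  val <- run_stage("validate", validate_signature(trained$model, cand$pairs2, clin2))
  readr::write_tsv(val$profile, pth("risk_validation.tsv"), progress = FALSE)
  readr::write_tsv(glance(val), pth("validation_summary.tsv"), progress = FALSE)
  readr::write_tsv(val$auc, pth("validation_auc.tsv"), progress = FALSE)
  stage("validate",
        list(n_high = unname(val$group_sizes["high"]),
             n_low = unname(val$group_sizes["low"])),
        pth(c("risk_validation.tsv", "validation_summary.tsv", "validation_auc.tsv")))

  # deconv + correlate (optional)
  if (!is.null(cfg$reference)) {
    ref <- run_stage("deconv", read_reference(cfg$reference))
    dec <- run_stage("deconv",
                     deconvolve(expr1, ref, n_perm = cfg$n_perm, seed = cfg$seed))
    readr::write_tsv(dec, pth("deconvolution.tsv"), progress = FALSE)
    stage("deconv", list(n_samples = nrow(dec), n_cell_types = length(deconv_cell_types(dec))),
          pth("deconvolution.tsv"))

    cmp <- run_stage("correlate", compare_groups(dec, trained$profile))
    cors <- run_stage("correlate", correlate_with_score(dec, trained$profile))
    readr::write_tsv(cmp, pth("group_comparison.tsv"), progress = FALSE)
    readr::write_tsv(cors, pth("score_correlation.tsv"), progress = FALSE)
    stage("correlate", list(n_cell_types = nrow(cmp)),
          pth(c("group_comparison.tsv", "score_correlation.tsv")))
  }

  input_files <- unlist(cfg[required_files])
  if (!is.null(cfg$reference)) input_files <- c(input_files, cfg$reference)
  manifest <- structure(list(
    tool = "pairhazard",
    version = as.character(utils::packageVersion("pairhazard")),
    seed = cfg$seed,
    config = cfg,
    input_checksums = as.list(tools::md5sum(input_files)),
    stages = purrr::map(stages, function(s) {
      list(counts = s$counts, checksums = as.list(tools::md5sum(s$outputs)))
    })
  ), class = "run_manifest")
  jsonlite::write_json(unclass(manifest), pth("manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("pairhazard run (version %s, seed %d)\n", x$version, x$seed))
  for (nm in names(x$stages)) {
    cnt <- x$stages[[nm]]$counts
    cat(sprintf("  %-12s %s\n", nm,
                paste(names(cnt), unlist(cnt), sep = "=", collapse = " ")))
  }
  invisible(x)
}
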