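# End-to-end orchestration: screening runs once on the training split, then
# each requested experiment (diversity indices, two-dimensional counts,
# multidimensional presence, core selection) writes its tables under one
# report directory. Stages are file-composable so partial reruns and
# inspection are possible; the numbered scripts under analysis/ drive them.

default_pipeline_config <- function() {
  list(
    seed = 1L,
    cohort_dir = NULL,            # NULL: simulate with generator defaults
    experiments = c("indices", "two_dim", "multidim", "core_selection"),
    cutoffs = c(0.1, 1e-2, 1e-3, 1e-4),
    screen_cutoff = 1e-2,         # associated set used by the feature builders
    classifiers = c("logistic", "lda", "svm_linear", "svm_poly",
                    "naive_bayes", "decision_tree", "random_forest",
                    "gbdt", "xgboost_like"),
    rfecv_estimator = "adaboost",
    core_classifier = "svm_linear",
    exclusion_tolerance = 0
  )
}

#' Run the full screening/classification pipeline
#'
#' Loads (or simulates) a cohort, screens associated clonotypes on the
#' training split across the cutoff ladder, then runs the selected
#' experiments and writes their tables plus a machine-readable run manifest
#' under `out_dir`.
#'
#' @param config named list overriding the defaults (seed, cohort_dir,
#'   experiments, cutoffs, screen_cutoff, classifiers, rfecv_estimator,
#'   core_classifier, exclusion_tolerance), or a path to a YAML file with
#'   those fields.
#' @param out_dir report directory (created).
#' @return invisibly, a list with the in-memory results (`screen`, one entry
#'   per experiment, `paths`).
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  bad <- setdiff(names(config), names(default_pipeline_config()))
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(default_pipeline_config(), config)
  unknown_exp <- setdiff(cfg$experiments,
                         c("indices", "two_dim", "multidim", "core_selection"))
  if (length(unknown_exp))
    stop("unknown experiment(s): ", paste(unknown_exp, collapse = ", "),
         call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cohort <- if (is.null(cfg$cohort_dir)) {
    generate_cohort(generator_config(seed = cfg$seed))
  } else {
    read_cohort(file.path(cfg$cohort_dir, "manifest.tsv"))
  }
  train <- cohort$train; test <- cohort$test
  results <- list()

  # one shared screening pass over the cutoff ladder
  full <- screen(train, cutoff = max(cfg$cutoffs))
  results$screen <- full
  utils::write.table(full, file.path(out_dir, "screen.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ladder <- lapply(cfg$cutoffs, function(ct) {
    if (ct >= 1) full$key else full$key[full$p_value < ct]
  })
  names(ladder) <- format(cfg$cutoffs, scientific = TRUE, trim = TRUE)
  jsonlite::write_json(
    list(cutoffs = cfg$cutoffs, n_keys = vapply(ladder, length, integer(1))),
    file.path(out_dir, "screen_summary.json"), auto_unbox = TRUE
  )
  associated <- full$key[full$p_value < cfg$screen_cutoff]

  run_bank <- function(tr_fm, te_fm, tag) {
    tab <- classify_bank(tr_fm, te_fm, cfg$classifiers, seed = cfg$seed)
    utils::write.table(tab, file.path(out_dir, paste0(tag, "_metrics.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tab
  }

  if ("indices" %in% cfg$experiments) {
    tr <- diversity_feature_table(train)
    te <- diversity_feature_table(test)
    write_matrix(tr, file.path(out_dir, "indices_train.tsv"))
    write_matrix(te, file.path(out_dir, "indices_test.tsv"))
    panel <- importance_panel(tr, seed = cfg$seed)
    imp <- data.frame(feature = names(panel$aggregate$sum_of_importance),
                      sum_of_importance = panel$aggregate$sum_of_importance,
                      sum_of_ranks = panel$aggregate$sum_of_ranks,
                      row.names = NULL)
    utils::write.table(imp, file.path(out_dir, "indices_importance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$indices <- list(metrics = run_bank(tr, te, "indices"),
                            importance = panel)
  }

  if (length(associated) == 0 &&
      any(c("two_dim", "multidim", "core_selection") %in% cfg$experiments)) {
    warning("no clonotypes passed the screen at cutoff ", cfg$screen_cutoff,
            "; sequence-based experiments skipped", call. = FALSE)
  } else {
    if ("two_dim" %in% cfg$experiments) {
      tr <- two_dim_feature_table(train, associated)
      te <- two_dim_feature_table(test, associated)
      write_matrix(tr, file.path(out_dir, "two_dim_train.tsv"))
      write_matrix(te, file.path(out_dir, "two_dim_test.tsv"))
      results$two_dim <- list(metrics = run_bank(tr, te, "two_dim"))
    }
    if ("multidim" %in% cfg$experiments) {
      tr <- presence_matrix(train, associated)
      te <- presence_matrix(test, associated)
      write_matrix(tr, file.path(out_dir, "multidim_train.tsv"))
      write_matrix(te, file.path(out_dir, "multidim_test.tsv"))
      results$multidim <- list(metrics = run_bank(tr, te, "multidim"))
    }
    if ("core_selection" %in% cfg$experiments) {
      tr <- presence_matrix(train, associated)
      te <- presence_matrix(test, associated)
      sel <- rfecv_select(tr, clf_spec(cfg$rfecv_estimator, seed = cfg$seed),
                          seed = cfg$seed)
      core <- backward_exclusion(tr, te, sel$selected_keys,
                                 clf_spec(cfg$core_classifier,
                                          seed = cfg$seed),
                                 tolerance = cfg$exclusion_tolerance,
                                 seed = cfg$seed)
      writeLines(core$selected_keys, file.path(out_dir, "core_keys.txt"))
      jsonlite::write_json(
        list(rfecv_dimension = length(sel$selected_keys),
             rfecv_keys = sel$selected_keys,
             core_keys = core$selected_keys,
             core_trace = core$trace,
             final_auc = core$final_eval$auc,
             final_accuracy = core$final_eval$accuracy,
             final_sensitivity = core$final_eval$sensitivity,
             final_specificity = core$final_eval$specificity),
        file.path(out_dir, "core_selection.json"), auto_unbox = TRUE,
        digits = NA
      )
      results$core_selection <- list(rfecv = sel, core = core)
    }
  }

  jsonlite::write_json(
    list(seed = cfg$seed, experiments = cfg$experiments,
         cutoffs = cfg$cutoffs, screen_cutoff = cfg$screen_cutoff,
         classifiers = cfg$classifiers,
         cohort = if (is.null(cfg$cohort_dir)) "simulated" else cfg$cohort_dir,
         package_version = as.character(utils::packageVersion("tcrscreen"))),
    file.path(out_dir, "run_manifest.json"), auto_unbox = TRUE
  )
  results$paths <- list.files(out_dir, full.names = TRUE)
  invisible(results)
}
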