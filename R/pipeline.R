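# End-to-end derivation pipeline: simulate (or read) -> score -> label ->
# derive candidate trees/rules -> select -> validity panel -> bootstrap.
# Every artifact is written as structured text next to a resolved copy of
# the configuration, so a rerun with the same config is byte-identical.

#' Screen predictors by bagged-tree Gini importance
#'
#' Rule derivation in practice is two-stage: an automatic run over all
#' predictors, then restriction to a small eligible candidate set before
#' the final fit.  This function automates the restriction: it grows trees
#' on \code{B} bootstrap resamples of the rows, accumulates each
#' predictor's node-size-weighted Gini decrease
#' (\code{\link{treeImportance}}), and returns the \code{n_items} highest
#' ranked predictors.  Bagging stabilizes the ranking, which from a single
#' full-sample tree is noisy.
#'
#' @param data Data frame of predictor columns (ordinal 0-4).
#' @param outcome Labels \code{poor} / \code{satisfactory}.
#' @param predictors Predictor column names to rank.
#' @param control \code{\link{treeControl}} used for the screening trees.
#' @param n_items Number of predictors to keep (default 5, the size of a
#'   bedside questionnaire).
#' @param B Number of bootstrap trees (default 25).
#' @param seed Seed for the resampling.
#' @return Character vector of the selected predictors (importance order),
#'   with the full importance vector in attribute \code{"importance"}.
#' @export
screenItems <- function(data, outcome, predictors,
                        control = treeControl(), n_items = 5, B = 25, seed = 1) {
  n <- nrow(data)
  imp <- stats::setNames(numeric(length(predictors)), predictors)
  with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      tr <- growTree(data[idx, , drop = FALSE], outcome[idx], predictors, control)
      imp <- imp + treeImportance(tr)
    }
  })
  ranked <- sort(imp, decreasing = TRUE)
  structure(names(ranked)[seq_len(min(n_items, length(ranked)))],
    importance = ranked
  )
}

#' Derive a prediction rule from labelled patient data
#'
#' Optionally screens the predictor set down to \code{n_items} candidates
#' (\code{\link{screenItems}}), then grows one full-sample Gini tree per
#' candidate depth, flattens each into a sequential rule, scores each
#' candidate's training validity, and applies the sensitivity-first
#' selection policy (\code{\link{selectRule}}).  The candidate ladder over
#' depths operationalizes the simplicity dimension of the selection
#' policy: shallower trees yield rules with fewer questions.
#'
#' @param data Data frame of predictor columns (ordinal 0-4).
#' @param outcome Labels \code{poor} / \code{satisfactory}.
#' @param predictors Predictor column names.
#' @param depths Candidate maximum depths (default \code{1:6}).
#' @param control Base \code{\link{treeControl}}; its \code{max_depth} is
#'   overridden per candidate.
#' @param min_specificity Selection floor (default 0.70).
#' @param n_items When non-\code{NULL}, screen the predictors down to this
#'   many items before the final full-sample fits (default 5).
#' @param screen_B,screen_seed Bootstrap settings for the screening stage.
#' @return List with \code{rule} (selected), \code{tree} (its source
#'   tree), \code{candidates} (per-depth list of rule, tree, report),
#'   \code{selected} (winning candidate index) and \code{items} (the
#'   screened predictor set).
#' @export
deriveRule <- function(data, outcome, predictors, depths = 1:6,
                       control = treeControl(
                         min_parent = 20, min_child = 10,
                         min_decrease = 1e-3, max_depth = 6,
                         class_weights = c(poor = 4, satisfactory = 1)
                       ),
                       min_specificity = 0.70,
                       n_items = 5, screen_B = 25, screen_seed = 1) {
  if (!is.null(n_items) && n_items < length(predictors)) {
    predictors <- screenItems(data, outcome, predictors,
      control = control, n_items = n_items, B = screen_B, seed = screen_seed
    )
  }
  candidates <- lapply(depths, function(d) {
    ctl <- control
    ctl$max_depth <- d
    tree <- growTree(data, outcome, predictors, ctl)
    rule <- flattenTree(tree, name = sprintf("depth-%d candidate", d))
    pred <- applyRule(rule, data)
    report <- validityReport(confusion(outcome, pred))
    list(rule = rule, tree = tree, report = report)
  })
  rule <- selectRule(candidates, min_specificity = min_specificity)
  sel <- attr(rule, "candidate")
  list(
    rule = rule, tree = candidates[[sel]]$tree,
    candidates = candidates, selected = sel, items = predictors
  )
}

#' Pipeline configuration
#'
#' @param out_dir Directory for run artifacts (created if needed).
#' @param cohort_path Optional existing cohort CSV (long format, see
#'   \code{\link{readCohort}}); when \code{NULL} a synthetic cohort is
#'   generated from \code{sim}.
#' @param sim A \code{\link{syntheticConfig}} used when simulating.
#' @param depths,min_specificity,control Passed to \code{\link{deriveRule}}.
#' @param bootstrap_B,bootstrap_level Bootstrap settings.
#' @param seed Master seed; the bootstrap seed is derived from it.
#' @param strict Strict (\code{>}) quintile labelling (default TRUE).
#' @param min_present WOMAC missing-item tolerance (default 0.8).
#' @return List of class \code{pipeline_config}.
#' @export
pipelineConfig <- function(out_dir, cohort_path = NULL,
                           sim = syntheticConfig(),
                           depths = 1:6,
                           control = treeControl(
                             min_parent = 20, min_child = 10,
                             min_decrease = 1e-3, max_depth = 6,
                             class_weights = c(poor = 4, satisfactory = 1)
                           ),
                           min_specificity = 0.70,
                           bootstrap_B = 1000, bootstrap_level = 0.95,
                           seed = 1, strict = TRUE, min_present = 0.8) {
  structure(
    list(
      out_dir = out_dir, cohort_path = cohort_path, sim = sim,
      depths = depths, control = control, min_specificity = min_specificity,
      bootstrap_B = bootstrap_B, bootstrap_level = bootstrap_level,
      seed = as.integer(seed), strict = strict, min_present = min_present
    ),
    class = "pipeline_config"
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full derivation pipeline
#'
#' Executes simulate/read -> score -> label -> derive -> validate ->
#' report, writing each artifact under \code{config$out_dir}:
#' \code{cohort.csv} (+ truth sidecar when simulated), \code{scored.csv},
#' \code{labelled.csv}, \code{tree.json}, \code{rule.json},
#' \code{validity.json}, \code{bootstrap.json}, \code{pipeline_log.txt}
#' and \code{resolved_config.json}.  Any stage failure halts with a
#' stage-tagged error.  Outputs are a pure function of the inputs and the
#' seed: rerunning with an identical config reproduces identical files.
#'
#' @param config A \code{\link{pipelineConfig}}.
#' @return Invisibly, a list with the main in-memory artifacts
#'   (\code{cohort}, \code{scores}, \code{labelling}, \code{derivation},
#'   \code{report}, \code{bootstrap}, \code{files}).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(config$out_dir, f)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  note("womacpr %s pipeline, master seed %d", as.character(utils::packageVersion("womacpr")), config$seed)

  cohort_df <- stage("simulate", {
    if (is.null(config$cohort_path)) {
      sim <- config$sim
      sim$seed <- config$seed
      cohort <- generateCohort(sim)
      emitCohort(cohort, path("cohort.csv"), path("cohort_truth.csv"))
      note("simulate: generated n = %d patients (seed %d)", sim$n, sim$seed)
      readCohort(path("cohort.csv"))
    } else {
      df <- readCohort(config$cohort_path)
      note("read: %d rows from %s", nrow(df), config$cohort_path)
      df
    }
  })

  scores <- stage("score", {
    s <- scoreCohort(cohort_df, min_present = config$min_present)
    utils::write.csv(s, path("scored.csv"), row.names = FALSE, quote = FALSE)
    note(
      "score: %d patient-timepoints scored, %d invalid",
      nrow(s), sum(!s$valid)
    )
    s
  })

  labelling <- stage("label", {
    six <- scores[scores$timepoint == "six_month", ]
    cutoff <- quintileCutoff(six$total)
    lab <- labelOutcomes(six$total, cutoff, strict = config$strict)
    writeLabelledCohort(six$id, six$total, lab, path("labelled.csv"))
    note(
      "label: cutoff %.2f, %d/%d poor outcomes", cutoff, lab$n_poor, lab$n
    )
    list(ids = six$id, labelling = lab)
  })

  derivation <- stage("derive", {
    base <- cohort_df[cohort_df$timepoint == "baseline", ]
    base <- base[match(labelling$ids, base$id), ]
    d <- deriveRule(
      base, labelling$labelling$labels, womacItems(),
      depths = config$depths, control = config$control,
      min_specificity = config$min_specificity,
      screen_seed = config$seed + 2L
    )
    writeTree(d$tree, path("tree.json"))
    writeRule(d$rule, path("rule.json"))
    note(
      "derive: %d candidates, selected depth index %d (%d questions, items: %s)",
      length(d$candidates), d$selected, nQuestions(d$rule),
      paste(ruleItems(d$rule), collapse = ", ")
    )
    d
  })

  report <- stage("report", {
    base <- cohort_df[cohort_df$timepoint == "baseline", ]
    base <- base[match(labelling$ids, base$id), ]
    pred <- applyRule(derivation$rule, base)
    rep <- validityReport(confusion(labelling$labelling$labels, pred))
    writeReport(rep, path("validity.json"))
    note(
      "report: Se %.3f, Sp %.3f, AUC %.3f",
      rep["sensitivity", "estimate"], rep["specificity", "estimate"],
      rep["auc", "estimate"]
    )
    list(report = rep, predicted = pred)
  })

  boot <- stage("validate", {
    b <- bootstrapValidate(
      labelling$labelling$labels, report$predicted,
      B = config$bootstrap_B, level = config$bootstrap_level,
      seed = config$seed + 1L
    )
    writeBootstrapResult(b, path("bootstrap.json"))
    undef <- sum(b$n_undefined)
    note(
      "validate: B = %d bootstrap resamples, %d undefined metric-resamples",
      attr(b, "B"), undef
    )
    b
  })

  resolved <- list(
    format = "womacpr_pipeline_config", version = 1L,
    package_version = as.character(utils::packageVersion("womacpr")),
    seed = config$seed,
    depths = config$depths, min_specificity = config$min_specificity,
    bootstrap_B = config$bootstrap_B, bootstrap_level = config$bootstrap_level,
    strict = config$strict, min_present = config$min_present,
    control = unclass(config$control)[c("min_parent", "min_child", "max_depth", "min_decrease")],
    class_weights = as.list(config$control$class_weights),
    simulated = is.null(config$cohort_path),
    sim = if (is.null(config$cohort_path)) {
      c(
        unclass(config$sim)[c(
          "n", "baseline_latent_mean", "baseline_latent_sd", "item_noise_sd",
          "improvement_mean", "improvement_sd", "rule_effect",
          "target_se", "target_sp", "outcome_prob"
        )],
        list(thresholds = config$sim$thresholds)
      )
    }
  )
  jsonlite::write_json(resolved, path("resolved_config.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  note("config: resolved configuration written (md5 %s)", unname(tools::md5sum(path("resolved_config.json"))))
  writeLines(log_lines, path("pipeline_log.txt"))

  invisible(list(
    cohort = cohort_df, scores = scores, labelling = labelling$labelling,
    derivation = derivation, report = report$report, bootstrap = boot,
    files = list.files(config$out_dir, full.names = TRUE)
  ))
}
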