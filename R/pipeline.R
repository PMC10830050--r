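#' Default pipeline configuration
#'
#' One declarative list with a section per stage; any section can be
#' overridden, and a stage can be skipped by supplying its input
#' explicitly (e.g. `responses` to skip simulation). Readable from YAML or
#' JSON via [read_pipeline_config()].
#'
#' @param seed master seed for every stochastic stage.
#' @return nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    synth = list(),                     # synth_config() overrides
    qc = list(),                        # default_qc_rules() overrides
    standardize = list(respondent_level = TRUE),
    factors = list(n_meta = NULL),      # NULL: score the shipped ten factors
    segment = list(k = 7, central_fraction = 0.02, n_runs = 20,
                   move_threshold = TRUE),
    profile = list(variables = NULL),   # NULL: demographics + outcomes
    validate = list(refusal_outcome = "out_vax_refuse")
  )
}

#' Read a pipeline configuration file
#'
#' @param path YAML (`.yaml`/`.yml`) or JSON configuration file mirroring
#'   [default_pipeline_config()].
#' @return configuration list merged over the defaults.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  modifyList(default_pipeline_config(), cfg)
}

#' Run the full segmentation pipeline
#'
#' Executes simulate (optional) -> respondent screening -> dual-mode
#' standardization -> factor scoring -> hybrid segmentation (with QDA
#' allocation of the booster sample) -> profile tables -> predictive
#' validation, and returns all stage outputs plus a run manifest recording
#' parameters, seeds and output digests. Deterministic given the
#' configuration (including its seed).
#'
#' @param config configuration list (see [default_pipeline_config()]).
#' @param responses optional [response_matrix] to analyse instead of
#'   simulating (skips the synth stage).
#' @param truth optional truth table accompanying `responses` (enables the
#'   recovery diagnostics).
#' @param out_dir optional directory; when given, all tabular outputs and
#'   the manifest are written there as CSV/JSON.
#' @return list of class `pipeline_result` with components `responses`,
#'   `truth`, `qc`, `standardized`, `factor_models`, `scores`,
#'   `segmentation`, `booster`, `labels`, `profile`, `validation`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         responses = NULL, truth = NULL, out_dir = NULL) {
  config <- modifyList(default_pipeline_config(), config)
  seed <- config$seed
  stages <- list()
  t0 <- Sys.time()

  # -- simulate ------------------------------------------------------------
  if (is.null(responses)) {
    sc <- do.call(synth_config, modifyList(list(seed = seed), config$synth))
    gen <- generate_population(sc)
    responses <- gen$responses
    truth <- gen$truth
    stages$synth <- list(n = sc$n_respondents, seed = seed)
  }

  # -- qc ------------------------------------------------------------------
  rules <- modifyList(default_qc_rules(responses$likert_levels), config$qc)
  qc <- qc_screen(responses, rules)
  X <- qc$responses
  stages$qc <- c(rules, qc$report[c("n_before", "n_after", "n_removed")])

  # -- standardize ---------------------------------------------------------
  Z <- standardize_responses(X, config$standardize$respondent_level)
  stages$standardize <- list(
    respondent_level = config$standardize$respondent_level,
    diagnostics = standardization_diagnostics(Z)[
      c("max_abs_mean", "max_abs_sd_minus_1")])

  # -- factors -------------------------------------------------------------
  models <- if (!is.null(config$factors$models)) config$factors$models
  else default_factor_models(compute_alpha = Z)
  scores <- score_factors(Z, models)
  if (!is.null(config$factors$n_meta)) {
    meta <- build_meta_factors(scores, config$factors$n_meta)
    scores <- meta$scores
    models <- c(models, meta$models)
  }
  stages$factors <- list(
    n_factors = ncol(scores),
    alphas = vapply(models, function(m)
      if (is.null(m$alpha)) NA_real_ else m$alpha, numeric(1)))

  # -- segment (core + telephone; booster allocated by QDA) ---------------
  is_booster <- X$sample_source == "booster"
  F_core <- scores[!is_booster, , drop = FALSE]
  segcfg <- config$segment
  seg <- build_segments(F_core, k = segcfg$k,
                        central_fraction = segcfg$central_fraction,
                        n_runs = segcfg$n_runs, seed = seed,
                        move_threshold = isTRUE(segcfg$move_threshold))
  labels <- stats::setNames(rep(NA_character_, nrow(scores)),
                            rownames(scores))
  labels[!is_booster] <- seg$labels
  booster <- NULL
  if (any(is_booster)) {
    booster <- qda_allocate(F_core, seg$labels,
                            scores[is_booster, , drop = FALSE])
    labels[is_booster] <- booster$labels_new
  }
  stages$segment <- list(k = segcfg$k, stability = seg$stability,
                         n_moved = seg$n_moved,
                         move_threshold = seg$model$move_threshold,
                         qda_training_accuracy =
                           if (!is.null(booster)) booster$training_accuracy,
                         seed = seed)

  # -- profile -------------------------------------------------------------
  prof_data <- cbind(
    if (!is.null(X$demographics)) X$demographics,
    if (!is.null(X$outcomes)) X$outcomes)
  vars <- config$profile$variables
  if (is.null(vars)) vars <- names(prof_data)
  seg_levels <- seg$model$segment_names
  seg_factor <- factor(labels, levels = seg_levels)
  profile <- if (length(vars))
    build_profile_table(prof_data, seg_factor, vars, weights = X$weights)
  stages$profile <- list(n_variables = length(vars))

  # -- validate ------------------------------------------------------------
  validation <- NULL
  if (!is.null(X$outcomes) &&
      all(protective_behaviour_items() %in% names(X$outcomes))) {
    pscore <- protective_score(X$outcomes[protective_behaviour_items()])
    demo <- X$demographics[c("gender", "ethnicity", "education", "income",
                             "age")]
    glm_tab <- fit_type3_anova(pscore, seg_factor, demo)
    wald <- NULL
    refusal <- config$validate$refusal_outcome
    if (refusal %in% names(X$outcomes) &&
        length(unique(X$outcomes[[refusal]])) > 1)
      wald <- fit_logistic_wald(X$outcomes[[refusal]], seg_factor, demo)
    validation <- list(
      glm_table = glm_tab, wald = wald,
      comparison = predictor_comparison_report(glm_tab, wald))
    stages$validate <- list(
      segment_eta2 = validation$comparison$segment_eta2,
      demographics_eta2 = validation$comparison$demographics_eta2)
  }

  # -- recovery diagnostics (synthetic runs only) --------------------------
  recovery <- NULL
  if (!is.null(truth)) {
    idx <- match(names(labels), truth$respondent_id)
    recovery <- list(
      ari = mclust::adjustedRandIndex(labels, truth$true_segment[idx]))
    stages$recovery <- recovery
  }

  result <- structure(
    list(responses = responses, truth = truth, qc = qc$report,
         standardized = Z, factor_models = models, scores = scores,
         segmentation = seg, booster = booster, labels = labels,
         profile = profile, validation = validation, recovery = recovery,
         manifest = NULL),
    class = "pipeline_result")

  manifest <- list(
    package_version = as.character(utils::packageVersion("audseg")),
    config_digest = content_digest(jsonlite::toJSON(
      config[setdiff(names(config), "factors")], auto_unbox = TRUE,
      force = TRUE)),
    seed = seed, stages = stages,
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- write_pipeline_outputs(result, labels, out_dir)
    manifest$outputs <- lapply(files, function(f)
      list(path = basename(f), digest = file_digest(f)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
  }
  result$manifest <- manifest
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("  respondents analysed: ", length(x$labels), " (",
      x$qc$n_removed, " removed in screening)\n", sep = "")
  cat("  factors scored: ", ncol(x$scores), "\n", sep = "")
  cat("  segments: ", paste(x$segmentation$model$segment_names,
                            collapse = ", "), "\n", sep = "")
  cat("  k-means stability (mean pairwise ARI): ",
      round(x$segmentation$stability, 3), "\n", sep = "")
  if (!is.null(x$booster))
    cat("  QDA training accuracy: ",
        round(x$booster$training_accuracy, 3), "\n", sep = "")
  if (!is.null(x$recovery))
    cat("  recovery ARI vs ground truth: ", round(x$recovery$ari, 3),
        "\n", sep = "")
  if (!is.null(x$validation))
    cat("  segment eta2 = ",
        round(x$validation$comparison$segment_eta2, 3),
        ", combined demographics eta2 = ",
        round(x$validation$comparison$demographics_eta2, 3), "\n", sep = "")
  invisible(x)
}

write_pipeline_outputs <- function(result, labels, out_dir) {
  files <- character()
  p <- function(name) file.path(out_dir, name)
  files <- c(files, write_responses(result$responses, p("responses.csv")))
  if (!is.null(result$truth)) {
    utils::write.csv(result$truth, p("truth.csv"), row.names = FALSE)
    files <- c(files, p("truth.csv"))
  }
  jsonlite::write_json(result$qc, p("qc_report.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  files <- c(files, p("qc_report.json"))
  sc <- data.frame(respondent_id = rownames(result$scores),
                   unclass(result$scores), check.names = FALSE)
  utils::write.csv(sc, p("factor_scores.csv"), row.names = FALSE)
  files <- c(files, p("factor_scores.csv"))
  files <- c(files, write_factor_models(result$factor_models,
                                        p("factor_models.json")))
  asg <- data.frame(respondent_id = names(labels), segment = labels,
                    stringsAsFactors = FALSE)
  d <- dist_to_centroids(result$scores,
                         result$segmentation$model$centroids)
  asg <- cbind(asg, as.data.frame(d))
  utils::write.csv(asg, p("assignments.csv"), row.names = FALSE)
  files <- c(files, p("assignments.csv"))
  model <- result$segmentation$model
  jsonlite::write_json(
    list(k = model$k, segment_names = model$segment_names,
         central_segment_id = model$central_segment_id,
         move_threshold = model$move_threshold,
         centroids = as.data.frame(model$centroids)),
    p("segment_model.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
  files <- c(files, p("segment_model.json"))
  if (!is.null(result$profile))
    files <- c(files, write_profile_table(result$profile,
                                          p("profile.csv")))
  if (!is.null(result$validation)) {
    utils::write.csv(as.data.frame(result$validation$glm_table),
                     p("glm_table.csv"), row.names = FALSE)
    files <- c(files, p("glm_table.csv"))
    if (!is.null(result$validation$wald)) {
      utils::write.csv(as.data.frame(result$validation$wald),
                       p("wald_report.csv"), row.names = FALSE)
      files <- c(files, p("wald_report.csv"))
    }
  }
  files
}

content_digest <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(x), tmp)
  unname(tools::md5sum(tmp))
}

file_digest <- function(path) unname(tools::md5sum(path))
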