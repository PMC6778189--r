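#' Default pipeline configuration
#'
#' A small, fast demonstration configuration: a tiny image cohort with a
#' planted mean drift, modest discretization, and a fixed 2-feature
#' model. Every stochastic stage has a fixed seed, so reruns are
#' bit-identical.
#'
#' @return Nested list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function() {
  list(cohort = list(n_good = 2, n_bad = 2, n_fractions = 6,
                     volume_shape = c(16, 16, 9),
                     planted = data.frame(feature = "mean",
                                          slope_good = -2, slope_bad = 0),
                     patient_sd = 0.01, noise_sd = 3, seed = 11),
       features = list(G = 16, window = c(-200, 400), d = 1),
       screen = list(alpha = 0.05, spearman_threshold = 0.9,
                     mslr_nr = 50, seed = 21),
       som = list(grid = c(2, 2), epochs = 10, seed = 31),
       classify = list(combo = c("fo_mean", "fo_std"), seed = 41))
}

#' Run the delta-radiomics pipeline end to end
#'
#' Orchestrates simulate -> extract -> delta -> screen -> SOM ->
#' classify from one configuration list, writing every intermediate
#' artifact (CSV/JSON), a log and a reproducibility manifest (config
#' hash, seeds, package version) into `out_dir`. Stages are pure
#' functions of their inputs and seeds, so a rerun with the same
#' configuration reproduces every output bit-identically; a rerun also
#' regenerates any deleted intermediate. Errors abort with the stage
#' name, leaving earlier artifacts in place.
#'
#' Real (non-synthetic) studies enter at the feature-table stage: the
#' pipeline consumes already-registered volume/mask pairs, and rigid or
#' deformable registration is assumed done upstream.
#'
#' @param config Configuration list as in [default_pipeline_config()];
#'   missing entries fall back to the defaults.
#' @param out_dir Output directory.
#' @return Invisibly, a list with the main stage results (`cohort`,
#'   `features`, `drf`, `screen`, `som`, `model`, `cv`).
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = tempfile("deltarad_run")) {
  def <- default_pipeline_config()
  for (nm in names(def)) {
    config[[nm]] <- utils::modifyList(def[[nm]], config[[nm]] %||% list())
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "pipeline.log")
  logmsg <- function(...) cat(sprintf(...), "\n", sep = "",
                              file = logf, append = TRUE)
  cat("", file = logf)
  stage <- function(name, expr) {
    logmsg("[%s] start", name)
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    logmsg("[%s] done", name)
    out
  }

  cc <- config$cohort
  cohort <- stage("simulate", generate_cohort(cohort_spec(
    n_good = cc$n_good, n_bad = cc$n_bad, n_fractions = cc$n_fractions,
    volume_shape = cc$volume_shape,
    planted_features = cc$planted,
    patient_sd = cc$patient_sd, noise_sd = cc$noise_sd, seed = cc$seed)))

  fc <- config$features
  features <- stage("extract", extract_feature_table(
    cohort, G = fc$G, window = fc$window, d = fc$d))
  write.csv(features, file.path(out_dir, "features.csv"),
            row.names = FALSE)
  jsonlite::write_json(fc, file.path(out_dir, "features_config.json"),
                       auto_unbox = TRUE)

  drf <- stage("delta", weekly_drf(compute_drf(features)))
  write.csv(drf$drf, file.path(out_dir, "drf.csv"), row.names = FALSE)
  write.csv(drf$weekly, file.path(out_dir, "drf_weekly.csv"),
            row.names = FALSE)

  sc <- config$screen
  screen <- stage("screen", drf_screen(
    drf, cohort$labels, motion = cohort$motion, scanner = cohort$scanner,
    alpha = sc$alpha, spearman_threshold = sc$spearman_threshold,
    mslr_nr = sc$mslr_nr, seed = sc$seed))
  write.csv(screen$report, file.path(out_dir, "screening_report.csv"),
            row.names = FALSE)
  jsonlite::write_json(list(alpha = screen$alpha,
                            candidates = screen$candidates),
                       file.path(out_dir, "candidates.json"),
                       auto_unbox = TRUE)

  sm <- config$som
  slopes <- stage("som", {
    sl <- drf_slopes(drf)
    som <- som_train(sl, grid = sm$grid, epochs = sm$epochs,
                     seed = sm$seed)
    wp <- som_weight_planes(som)
    write.csv(as.data.frame(som$weights),
              file.path(out_dir, "som_weights.csv"), row.names = FALSE)
    list(som = som, planes = wp)
  })

  cl <- config$classify
  combo <- cl$combo
  samples <- cbind(data.frame(patient = drf$drf$patient,
                              stringsAsFactors = FALSE),
                   drf$drf[, drf$features, drop = FALSE])
  cv <- stage("classify", loo_cv(samples, cohort$labels, combo,
                                 seed = cl$seed))
  model <- train_response_classifier(samples,
              cohort$labels[as.character(samples$patient)],
              combo = combo, seed = cl$seed)
  write.csv(cv$scores, file.path(out_dir, "cv_scores.csv"),
            row.names = FALSE)
  jsonlite::write_json(list(auc = cv$auc, accuracy = cv$accuracy,
                            accuracy_patient = cv$accuracy_patient),
                       file.path(out_dir, "cv_metrics.json"),
                       auto_unbox = TRUE, digits = NA)

  cfg_file <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, cfg_file, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_file)),
    package_version = as.character(utils::packageVersion("deltarad")),
    seeds = list(cohort = cc$seed, screen = sc$seed, som = sm$seed,
                 classify = cl$seed))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  logmsg("[pipeline] complete")
  invisible(list(cohort = cohort, features = features, drf = drf,
                 screen = screen, som = slopes, model = model, cv = cv,
                 out_dir = out_dir))
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the [run_pipeline()] structure.
#' @return Configuration list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$cohort$planted))
    cfg$cohort$planted <- as.data.frame(cfg$cohort$planted)
  cfg
}
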