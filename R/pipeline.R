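#' Run the full psychotype-atlas pipeline
#'
#' Chains the package end to end: (optionally) simulate a cohort, refuse any
#' training partition containing depressed subjects, train the map on the
#' training items, map the test cohort, build the per-cell overlay, cluster
#' the codebook, pick the depression-hotspot and mental-stability endpoint
#' cells, trace the weighted shortest path between them and rank the
#' attitude changes along it — plus, when enabled, the age / well-being
#' predictors and the elastic-net relative-importance comparison.
#'
#' @param cohort A cohort tibble, or `NULL` to generate one from `spec`.
#' @param spec A [cohort_spec()] used when `cohort` is `NULL`.
#' @param som A [som_config()].
#' @param n_clusters Codebook clusters to cut.
#' @param top_k Features per direction in the recommendation ranking.
#' @param predictors Logical: also train the age and well-being predictors
#'   and run the elastic-net importance analysis (slower).
#' @param predictor_cfg Base [predictor_config()] settings used for both
#'   tasks when `predictors = TRUE` (the task field is set per model).
#' @param out_dir Optional directory; when given, cohort CSV, map JSON,
#'   overlay/cluster/path JSON and a run manifest are written there.
#' @param seed Global seed propagated to every stage.
#' @return A list of class `atlas_pipeline` with every stage's artifact.
#' @export
run_pipeline <- function(cohort = NULL, spec = NULL, som = som_config(),
                         n_clusters = 3, top_k = 5, predictors = FALSE,
                         predictor_cfg = NULL, out_dir = NULL, seed = 1L) {
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tic <- Sys.time()
    value <- tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage `%s` failed: %s", name,
                    conditionMessage(e)))
    })
    message(sprintf("[psychatlas] stage=%s seed=%d elapsed=%.2fs",
                    name, seed, as.numeric(Sys.time() - tic, units = "secs")))
    value
  }

  cohort <- stage("cohort", {
    if (is.null(cohort)) {
      spec <- spec %||% cohort_spec(seed = seed)
      generate_cohort(spec)
    } else cohort
  })
  stage("validate", validate_cohort(cohort, require_clean_train = TRUE))

  train <- cohort[cohort$split == "train", ]
  test <- cohort[cohort$split == "test", ]
  som$seed <- som$seed %||% seed
  model <- stage("train_som", train_som(cohort_items(train), som))
  assignments <- stage("map_test", map_cohort(model, test))
  overlay <- stage("overlay", cell_overlay(assignments, test, wave = 2))
  clusters <- stage("cluster", cluster_codebook(model, n_clusters))
  stats <- stage("cluster_stats", cluster_stats(clusters, overlay))
  endpoints <- stage("endpoints", select_endpoints(overlay))
  path <- stage("path", shortest_path(som_graph(model),
                                      endpoints$hotspot$cell,
                                      endpoints$stable$cell))
  changes <- stage("recommendations", rank_feature_changes(path, k = top_k))

  predictor_fits <- importance <- NULL
  if (predictors) {
    base <- predictor_cfg %||% predictor_config(seed = seed)
    age_cfg <- base; age_cfg$task <- "age"; age_cfg$l2_coefficient <- 1e-6
    wb_cfg <- base; wb_cfg$task <- "wellbeing6"; wb_cfg$l2_coefficient <- 1e-7
    predictor_fits <- list(
      age = stage("predict_age", train_predictor(cohort, age_cfg)),
      wellbeing = stage("predict_wellbeing", train_predictor(cohort, wb_cfg))
    )
    pred_wb <- stage("predict_test_wb",
                     as.matrix(predict(predictor_fits$wellbeing, test)))
    importance <- stage("en_importance", purrr::map(1:6, function(k) {
      en_importance(test, pred_wb, k, seed = seed)
    }))
  }

  result <- structure(
    list(cohort = cohort, model = model, assignments = assignments,
         overlay = overlay, clusters = clusters, cluster_stats = stats,
         endpoints = endpoints, path = path, recommendations = changes,
         predictors = predictor_fits, importance = importance,
         seed = seed),
    class = "atlas_pipeline"
  )

  if (!is.null(out_dir)) {
    stage("write", {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_cohort(cohort, file.path(out_dir, "cohort.csv"))
      save_som(model, file.path(out_dir, "som.json"))
      jsonlite::write_json(overlay, file.path(out_dir, "overlay.json"),
                           digits = NA, auto_unbox = TRUE)
      jsonlite::write_json(as_tibble(clusters),
                           file.path(out_dir, "clusters.json"),
                           digits = NA, auto_unbox = TRUE)
      readr::write_csv(stats, file.path(out_dir, "cluster_stats.csv"),
                       progress = FALSE)
      jsonlite::write_json(
        list(cells = path$cells, coords = path$coords,
             total_length = path$total_length),
        file.path(out_dir, "path.json"), digits = NA, auto_unbox = TRUE)
      readr::write_csv(path$trajectories,
                       file.path(out_dir, "trajectories.csv"),
                       progress = FALSE)
      manifest <- list(
        package = "psychatlas",
        package_version = as.character(utils::packageVersion("psychatlas")),
        r_version = R.version.string,
        seed = seed,
        som_seed = model$config$seed,
        created = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
        stages = c("cohort", "validate", "train_som", "map_test", "overlay",
                   "cluster", "cluster_stats", "endpoints", "path",
                   "recommendations",
                   if (predictors) c("predict_age", "predict_wellbeing",
                                     "en_importance"))
      )
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
    })
  }
  result
}

#' @export
print.atlas_pipeline <- function(x, ...) {
  cat("<atlas_pipeline>\n")
  print(glance(x$model))
  cat(sprintf("  path: %d cells, length %.4f (hotspot cell %d -> stable cell %d)\n",
              length(x$path$cells), x$path$total_length,
              x$endpoints$hotspot$cell, x$endpoints$stable$cell))
  invisible(x)
}
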