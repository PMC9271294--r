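#' Map a cohort onto a trained SOM
#'
#' Assigns every subject to the best-matching unit of its questionnaire item
#' vector.  Each profile matches exactly one cell; a cell may collect many
#' profiles.
#'
#' @param model A `som_model` trained on the cohort's item features.
#' @param cohort A cohort tibble whose `item_*` columns match the model's
#'   `feature_names`.
#' @return A tibble with one row per subject: `subject_id`, `cell`, `row`,
#'   `col`, `distance`; the grid layout travels along in the `"grid"`
#'   attribute.
#' @export
map_cohort <- function(model, cohort) {
  items <- cohort_items(cohort)
  if (!identical(colnames(items), model$feature_names)) {
    abort("cohort item columns do not match the model's feature names.")
  }
  hit <- find_bmu(model, items)
  out <- dplyr::bind_cols(tibble(subject_id = cohort$subject_id), hit)
  attr(out, "grid") <- model$grid
  out
}

#' Aggregate per-cell metadata over a mapped cohort
#'
#' For each map cell, counts the depressed and non-depressed subjects mapped
#' there, their depression odds (depressed / non-depressed), percent male, and
#' mean well-being for the chosen wave.  Cells with no mapped subjects are
#' flagged `occupied = FALSE` (the "NA" cells of the atlas).  Odds are raw
#' count ratios: 0 when no depressed subject maps to the cell, and `Inf`
#' (flagged via `odds_capped`) when depressed subjects map to a cell with no
#' non-depressed ones.
#'
#' @param assignments Output of [map_cohort()] (or any tibble with
#'   `subject_id` and `cell`, plus a `"grid"` attribute or `grid` argument).
#' @param cohort The cohort the assignments were computed from.
#' @param wave Which well-being wave to average per cell: 2 (follow-up,
#'   default) or 1 (baseline).
#' @param grid Optional grid layout tibble (`cell`, `row`, `col`); defaults
#'   to the attribute left by [map_cohort()].
#' @return A tibble of class `cell_overlay`, one row per grid cell: counts,
#'   `depression_odds`, `odds_capped`, `n_male`, `pct_male`,
#'   `mean_wb_1` ... `mean_wb_6`, `occupied`.
#' @export
cell_overlay <- function(assignments, cohort, wave = 2, grid = NULL) {
  if (nrow(cohort) == 0) abort("`cohort` is empty.")
  grid <- grid %||% attr(assignments, "grid")
  if (is.null(grid)) abort("no grid layout: pass `grid` or use `map_cohort()` output.")
  if (!all(cohort$subject_id %in% assignments$subject_id)) {
    abort("`assignments` do not cover the cohort.")
  }
  wbc <- wb_cols(wave)
  joined <- dplyr::inner_join(assignments[c("subject_id", "cell")],
                              cohort, by = "subject_id")
  per_cell <- joined |>
    dplyr::group_by(.data$cell) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_depressed = sum(.data$depressed),
      n_nondepressed = sum(!.data$depressed),
      n_male = sum(.data$sex == "male"),
      dplyr::across(dplyr::all_of(wbc), mean,
                    .names = "mean_wb_{seq_along(wbc)}"),
      .groups = "drop"
    )
  out <- dplyr::left_join(grid, per_cell, by = "cell") |>
    dplyr::mutate(
      dplyr::across(c("n", "n_depressed", "n_nondepressed", "n_male"),
                    ~ dplyr::coalesce(.x, 0L)),
      occupied = .data$n > 0,
      depression_odds = dplyr::case_when(
        .data$n_nondepressed > 0 ~ .data$n_depressed / .data$n_nondepressed,
        .data$n_depressed > 0 ~ Inf,
        TRUE ~ NA_real_
      ),
      odds_capped = .data$n_nondepressed == 0 & .data$n_depressed > 0,
      pct_male = dplyr::if_else(.data$n > 0, 100 * .data$n_male / .data$n,
                                NA_real_)
    ) |>
    dplyr::relocate("occupied", .after = dplyr::last_col())
  class(out) <- unique(c("cell_overlay", class(out)))
  attr(out, "wave") <- wave
  out
}

#' Cluster the codebook into psychotypes
#'
#' Agglomerative hierarchical clustering of the per-cell codebook vectors
#' (complete linkage, Euclidean distance), with the dendrogram cut to exactly
#' `n_clusters`.  Labels are the raw dendrogram-cut labels; [cluster_stats()]
#' re-indexes them by descending depression odds so that cluster 1 is always
#' the depression-prone psychotype.
#'
#' @param model A trained `som_model`.
#' @param n_clusters Number of clusters to cut, between 2 and the number of
#'   cells.
#' @return A tibble with one row per cell: `cell`, `row`, `col`, `cluster`;
#'   linkage and metric recorded as attributes.
#' @export
cluster_codebook <- function(model, n_clusters = 3) {
  m <- n_cells(model)
  if (n_clusters < 2 || n_clusters > m) {
    abort(sprintf("`n_clusters` must be between 2 and %d.", m))
  }
  hc <- hclust(dist(model$codebook, method = "euclidean"), method = "complete")
  out <- dplyr::mutate(model$grid,
                       cluster = as.integer(cutree(hc, k = n_clusters)))
  attr(out, "linkage") <- "complete"
  attr(out, "metric") <- "euclidean"
  attr(out, "hclust") <- hc
  class(out) <- unique(c("som_clusters", class(out)))
  out
}

#' Per-cluster summary statistics
#'
#' Aggregates a [cell_overlay()] over a [cluster_codebook()] partition:
#' number of cells, summed depressed / non-depressed counts, depression odds
#' computed from the summed counts, percent male among mapped subjects, and
#' subject-weighted mean well-being per dimension — plus a `"Total"` row.
#' Clusters are re-indexed 1..k by descending depression odds, so cluster 1
#' is the depression-prone psychotype.
#'
#' @param clusters Output of [cluster_codebook()] (cell-to-cluster tibble).
#' @param overlay Output of [cell_overlay()] built on the same grid.
#' @return A tibble with one row per cluster plus a totals row: `cluster`,
#'   `n_cells`, `n_depressed`, `n_nondepressed`, `depression_odds`,
#'   `pct_male`, `mean_wb_1` ... `mean_wb_6` (when present in the overlay).
#' @export
cluster_stats <- function(clusters, overlay) {
  joined <- dplyr::inner_join(overlay, clusters[c("cell", "cluster")], by = "cell")
  if (nrow(joined) != nrow(overlay)) {
    abort("`clusters` and `overlay` do not describe the same grid.")
  }
  wb_means <- grep("^mean_wb_\\d$", names(overlay), value = TRUE)
  joined$.w <- joined$n # subject weights for well-being means
  summarise_part <- function(df) {
    dplyr::summarise(
      df,
      n_cells = dplyr::n(),
      n_depressed = sum(.data$n_depressed),
      n_nondepressed = sum(.data$n_nondepressed),
      n_male = sum(.data$n_male),
      n = sum(.data$n),
      dplyr::across(dplyr::all_of(wb_means),
                    ~ if (sum(.data$.w[!is.na(.x)]) > 0) {
                        sum(.x * .data$.w, na.rm = TRUE) /
                          sum(.data$.w[!is.na(.x)])
                      } else NA_real_),
      .groups = "drop"
    )
  }
  per_cluster <- summarise_part(dplyr::group_by(joined, .data$cluster))
  finish <- function(df) {
    dplyr::mutate(
      df,
      depression_odds = dplyr::case_when(
        .data$n_nondepressed > 0 ~ .data$n_depressed / .data$n_nondepressed,
        .data$n_depressed > 0 ~ Inf,
        TRUE ~ NA_real_
      ),
      pct_male = dplyr::if_else(.data$n > 0, 100 * .data$n_male / .data$n,
                                NA_real_)
    )
  }
  per_cluster <- finish(per_cluster)
  # depression-prone cluster first: re-index by descending odds (NA last,
  # ties by descending depressed count, then original label)
  ord <- order(-dplyr::coalesce(per_cluster$depression_odds, -Inf),
               -per_cluster$n_depressed, per_cluster$cluster)
  relabel <- setNames(seq_along(ord), per_cluster$cluster[ord])
  per_cluster <- per_cluster[ord, ]
  per_cluster$cluster <- as.character(seq_along(ord))
  total <- finish(summarise_part(joined))
  total$cluster <- "Total"
  out <- dplyr::bind_rows(per_cluster, total) |>
    dplyr::select("cluster", "n_cells", "n_depressed", "n_nondepressed",
                  "depression_odds", "pct_male",
                  dplyr::all_of(wb_means))
  attr(out, "relabel") <- relabel
  out
}

#' Correlate cell depression odds with cell mean well-being
#'
#' Across occupied cells with defined, finite odds, correlates the
#' depression odds with the per-cell mean well-being of each dimension
#' (Spearman rank correlation — odds are heavy-tailed — with a two-sided
#' p-value).  A significantly negative correlation across dimensions is what
#' licenses using depression odds as a well-being proxy on the map.
#'
#' @param overlay A [cell_overlay()].
#' @param dimensions Which of the six well-being dimensions to test.
#' @param method Correlation type passed to [stats::cor.test()].
#' @return A tibble: `dimension`, `estimate`, `p_value`, `n_cells`, `note`
#'   (`"degenerate"` when either variable is constant, with `NA` estimate).
#' @export
odds_wellbeing_correlation <- function(overlay, dimensions = 1:6,
                                       method = "spearman") {
  use <- dplyr::filter(overlay, .data$occupied,
                       is.finite(.data$depression_odds))
  if (nrow(use) < 3) abort("fewer than 3 occupied cells with defined odds.")
  purrr::map_dfr(dimensions, function(k) {
    colk <- paste0("mean_wb_", k)
    y <- use[[colk]]
    ok <- is.finite(y)
    x <- use$depression_odds[ok]
    y <- y[ok]
    if (length(x) < 3 || sd(x) == 0 || sd(y) == 0) {
      return(tibble(dimension = k, estimate = NA_real_, p_value = NA_real_,
                    n_cells = length(x), note = "degenerate"))
    }
    ct <- suppressWarnings(cor.test(x, y, method = method,
                                    alternative = "two.sided", exact = FALSE))
    tibble(dimension = k, estimate = unname(ct$estimate),
           p_value = ct$p.value, n_cells = length(x), note = NA_character_)
  })
}
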