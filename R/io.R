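#' Read and write cohort tables
#'
#' Cohort CSVs use a fixed header (`subject_id`, `item_01` ... `item_NN`,
#' `age`, `sex`, `wb1_1` ... `wb1_6`, `wb2_1` ... `wb2_6`, `depressed`,
#' `split`).  Reading validates the schema and reports offending columns by
#' name; a write-then-read round trip is value-identical.
#'
#' @param path File path.
#' @param cohort A cohort tibble.
#' @return `read_cohort()` returns a validated cohort tibble;
#'   `write_cohort()` returns `path` invisibly.
#' @export
read_cohort <- function(path) {
  # base parser: correctly-rounded doubles, so write/read round-trips exactly
  raw <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  validate_cohort(raw)
  raw$depressed <- as.logical(raw$depressed)
  new_cohort_tbl(raw)
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  out <- dplyr::mutate(as_tibble(cohort),
                       dplyr::across(dplyr::where(is.double),
                                     ~ sprintf("%.17g", .x)))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

SOM_SERIAL_VERSION <- "1"

#' Save and load trained maps
#'
#' JSON serialization of a `som_model`, preserving the codebook at full
#' numeric precision so best-matching-unit lookups are identical before and
#' after a round trip.  Files carry a format version; a mismatch is refused.
#'
#' @param model A `som_model`.
#' @param path File path (JSON).
#' @return `load_som()` returns the `som_model`; `save_som()` returns `path`
#'   invisibly.
#' @export
save_som <- function(model, path) {
  if (!inherits(model, "som_model")) abort("`model` must be a `som_model`.")
  payload <- list(
    format = "psychatlas_som", version = SOM_SERIAL_VERSION,
    config = unclass(model$config),
    codebook = model$codebook,
    codebook_init = model$codebook_init,
    feature_names = model$feature_names,
    center = model$center, scale = model$scale,
    training_log = model$training_log,
    epochs = model$epochs, converged = model$converged
  )
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_som
#' @export
load_som <- function(path) {
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e) {
                        abort(sprintf("cannot parse SOM file `%s`: %s",
                                      path, conditionMessage(e)))
                      })
  if (!identical(payload$format, "psychatlas_som")) {
    abort(sprintf("`%s` is not a serialized map.", path))
  }
  if (!identical(as.character(payload$version), SOM_SERIAL_VERSION)) {
    abort(sprintf("SOM file version `%s` does not match supported version `%s`.",
                  payload$version, SOM_SERIAL_VERSION))
  }
  cfg <- payload$config
  config <- som_config(width = cfg$width, height = cfg$height,
                       sigma0 = cfg$sigma0,
                       learning_rate0 = cfg$learning_rate0,
                       n_iterations_per_epoch = cfg$n_iterations_per_epoch,
                       max_epochs = cfg$max_epochs,
                       convergence_tol = cfg$convergence_tol,
                       patience = cfg$patience, seed = cfg$seed)
  structure(
    list(config = config,
         codebook = as.matrix(payload$codebook),
         codebook_init = as.matrix(payload$codebook_init),
         feature_names = payload$feature_names,
         center = setNames(as.numeric(payload$center), payload$feature_names),
         scale = setNames(as.numeric(payload$scale), payload$feature_names),
         grid = grid_coords(config$width, config$height),
         training_log = as_tibble(payload$training_log),
         epochs = payload$epochs,
         converged = payload$converged),
    class = "som_model"
  )
}
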