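#' Specify a synthetic midlife cohort
#'
#' Builds the parameter object consumed by [generate_cohort()].  The defaults
#' reproduce the cohort geometry of the MIDUS-style study design this package
#' targets: a training partition of 2718 subjects containing no depressed
#' individuals and a test partition of 394 depressed plus 779 non-depressed
#' subjects, each subject described by 32 bounded Likert-type item scores,
#' chronological age, sex, and six baseline (wave-1) and six follow-up
#' (wave-2) psychological well-being scores on the Ryff dimensions.
#'
#' The generator plants recoverable structure so every downstream stage of the
#' atlas is testable:
#' * the population varies along a latent mood/adaptivity trait (the unit
#'   direction of `depression_shift`): a broad main mode plus a smaller
#'   depression-prone psychotype mode (12% of subjects) further along the
#'   axis, so a map trained on non-depressed people still contains a
#'   depression-prone region;
#' * depressed subjects are shifted in item space by `depression_shift`;
#' * follow-up well-being is a fixed nonlinear (logistic-link) function of the
#'   items, `wellbeing_link`, plus Gaussian noise of sd `noise_sd`;
#' * baseline well-being mixes the same item signal with an independent
#'   right-skewed (reflected-Beta) component, so it is a noisy proxy of the
#'   planted signal;
#' * a subset of items drifts linearly with age (`age_link`), making
#'   psychological age predictable from the questionnaire.
#'
#' @param n_train Number of training subjects (all non-depressed).
#' @param n_test_depressed,n_test_nondepressed Test-partition composition.
#' @param n_items Number of questionnaire items.
#' @param item_scale Length-2 numeric, the closed bounds of the item (and
#'   well-being) scale.  Values are clipped into this range.
#' @param depression_shift Per-item mean shift applied to depressed subjects;
#'   recycled scalar or length-`n_items` vector.  Its unit direction also
#'   defines the latent mood/adaptivity trait axis (see `trait_sd`).
#' @param trait_sd Standard deviation, in item units, of the latent
#'   mood/adaptivity trait along which the non-depressed population varies;
#'   the trait axis is the unit vector of `depression_shift`, so depressed
#'   subjects sit in the extreme tail of the same axis rather than in a
#'   detached blob.  Set to 0 for independent items.
#' @param wellbeing_link 6 x `n_items` coefficient matrix of the planted
#'   item-to-follow-up-well-being mapping, or `NULL` for the built-in default.
#' @param age_link Per-item loading of standardized age on item means;
#'   recycled scalar or length-`n_items` vector.
#' @param noise_sd Standard deviation of the Gaussian noise added to
#'   follow-up well-being before clipping.
#' @param item_sd Within-group item standard deviation before clipping.
#' @param seed Integer seed; a single global seed from which every subsystem
#'   draws its own stream, so regeneration is bit-identical.
#'
#' @return A list of class `cohort_spec`.
#' @seealso [generate_cohort()]
#' @export
#' @examples
#' spec <- cohort_spec(n_train = 200, n_test_depressed = 40,
#'                     n_test_nondepressed = 80, seed = 1)
#' cohort <- generate_cohort(spec)
#' dplyr::count(cohort, split, depressed)
cohort_spec <- function(n_train = 2718,
                        n_test_depressed = 394,
                        n_test_nondepressed = 779,
                        n_items = 32,
                        item_scale = c(1, 7),
                        depression_shift = NULL,
                        wellbeing_link = NULL,
                        age_link = NULL,
                        trait_sd = 1.5,
                        noise_sd = 0.5,
                        item_sd = 1.2,
                        seed = 1L) {
  for (fld in c("n_train", "n_test_depressed", "n_test_nondepressed", "n_items")) {
    v <- get(fld)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 1 || v != floor(v)) {
      abort(sprintf("`%s` must be a positive integer count.", fld))
    }
  }
  if (!is.numeric(item_scale) || length(item_scale) != 2 ||
      !(item_scale[1] < item_scale[2])) {
    abort("`item_scale` must be numeric length 2 with min < max (degenerate scale).")
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1 || noise_sd < 0) {
    abort("`noise_sd` must be a non-negative real.")
  }
  if (!is.numeric(trait_sd) || length(trait_sd) != 1 || trait_sd < 0) {
    abort("`trait_sd` must be a non-negative real.")
  }
  if (!is.numeric(item_sd) || length(item_sd) != 1 || item_sd <= 0) {
    abort("`item_sd` must be a positive real.")
  }
  depression_shift <- depression_shift %||% default_depression_shift(n_items)
  depression_shift <- rep_len(as.numeric(depression_shift), n_items)
  age_link <- age_link %||% default_age_link(n_items)
  age_link <- rep_len(as.numeric(age_link), n_items)
  wellbeing_link <- wellbeing_link %||% default_wellbeing_link(n_items)
  wellbeing_link <- as.matrix(wellbeing_link)
  if (nrow(wellbeing_link) != 6 || ncol(wellbeing_link) != n_items) {
    abort("`wellbeing_link` must be a 6 x n_items coefficient matrix.")
  }
  structure(
    list(
      n_train = as.integer(n_train),
      n_test_depressed = as.integer(n_test_depressed),
      n_test_nondepressed = as.integer(n_test_nondepressed),
      n_items = as.integer(n_items),
      item_scale = as.numeric(item_scale),
      depression_shift = depression_shift,
      wellbeing_link = wellbeing_link,
      age_link = age_link,
      trait_sd = trait_sd,
      noise_sd = noise_sd,
      item_sd = item_sd,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

# Depressed subjects sit lower on the adaptive items (first 12) and higher on
# the maladaptive block (last quarter); middle items carry no depression signal.
default_depression_shift <- function(n_items) {
  shift <- numeric(n_items)
  n_ad <- min(12L, n_items)
  shift[seq_len(n_ad)] <- -0.8
  if (n_items >= 4) {
    mal <- seq.int(n_items - max(1L, n_items %/% 4) + 1L, n_items)
    shift[mal] <- 0.8
  }
  shift
}

# Standardized age loads on a middle block of items, away from the
# depression-shifted blocks, so age and depression signals stay separable.
default_age_link <- function(n_items) {
  link <- numeric(n_items)
  blk <- intersect(13:20, seq_len(n_items))
  if (length(blk) == 0) blk <- seq_len(min(4L, n_items))
  link[blk] <- 0.8
  link
}

# Each well-being dimension loads positively on staggered adaptive items and
# negatively on the maladaptive tail; fixed pattern, identical across seeds.
default_wellbeing_link <- function(n_items) {
  L <- matrix(0, 6, n_items)
  n_ad <- min(12L, n_items)
  mal <- if (n_items >= 4) seq.int(n_items - max(1L, n_items %/% 4) + 1L, n_items) else integer()
  for (k in 1:6) {
    ad <- ((k - 1L) * 2L + 0:5) %% n_ad + 1L
    L[k, ad] <- L[k, ad] + 0.22
    L[k, ad[1]] <- L[k, ad[1]] + 0.18 # dimension-specific emphasis item
    if (length(mal) > 0) {
      mk <- mal[(k - 1L) %% length(mal) + 1L]
      L[k, mal] <- L[k, mal] - 0.08
      L[k, mk] <- L[k, mk] - 0.14
    }
  }
  L
}

#' Names of the questionnaire item columns
#'
#' @param n_items Number of items.
#' @return Character vector `item_01`, `item_02`, ...
#' @export
item_cols <- function(n_items = 32) sprintf("item_%02d", seq_len(n_items))

wb_cols <- function(wave) sprintf("wb%d_%d", wave, 1:6)

# Deterministic per-subsystem sub-seeds from the single global seed.
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(2147483646L, n)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Planted nonlinear link: logistic squash of a linear item combination,
# mapped onto the score range.
planted_wellbeing <- function(items, spec) {
  centers <- item_centers(spec)
  z <- sweep(items, 2, centers) %*% t(spec$wellbeing_link)
  lo <- spec$item_scale[1]
  hi <- spec$item_scale[2]
  lo + (hi - lo) * stats::plogis(0.9 * z)
}

item_centers <- function(spec) {
  seq(spec$item_scale[1] + 0.35 * diff(spec$item_scale),
      spec$item_scale[1] + 0.65 * diff(spec$item_scale),
      length.out = spec$n_items)
}

#' Generate a seeded synthetic cohort
#'
#' Draws a cohort table from a [cohort_spec()].  Items are truncated-normal
#' (Gaussian draws clipped to the item scale) around per-item centers, with
#' the depressed subpopulation shifted by `depression_shift` and a planted
#' linear age drift on the `age_link` items.  Follow-up well-being is the
#' planted nonlinear function of the items plus Gaussian noise; baseline
#' well-being mixes the same signal with an independent right-skewed
#' (reflected-Beta(5, 1.5)) component.  Ages are uniform on 25-74 and sex is
#' Bernoulli with 40% male.  All scores are clipped to the declared scale.
#'
#' The training partition never contains depressed subjects.  Regenerating
#' with the same spec (same seed) is bit-identical.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble of class `cohort_tbl` with columns `subject_id`,
#'   `item_01` ... `item_NN`, `age`, `sex`, `wb1_1` ... `wb1_6`,
#'   `wb2_1` ... `wb2_6`, `depressed`, `split`; the generating spec is kept in
#'   the `"spec"` attribute.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) abort("`spec` must be a `cohort_spec`.")
  seeds <- derive_seeds(spec$seed, 5L)
  n <- spec$n_train + spec$n_test_depressed + spec$n_test_nondepressed
  lo <- spec$item_scale[1]
  hi <- spec$item_scale[2]

  split <- rep(c("train", "test"),
               c(spec$n_train, spec$n_test_depressed + spec$n_test_nondepressed))
  depressed <- rep(c(FALSE, TRUE, FALSE),
                   c(spec$n_train, spec$n_test_depressed, spec$n_test_nondepressed))

  set.seed(seeds[1]) # demographics stream
  age <- runif(n, 25, 74)
  sex <- ifelse(runif(n) < 0.40, "male", "female")

  set.seed(seeds[2]) # item stream
  z_age <- (age - 49.5) / 14.15
  mu <- matrix(item_centers(spec), n, spec$n_items, byrow = TRUE) +
    outer(z_age, spec$age_link) +
    outer(as.numeric(depressed), spec$depression_shift)
  shift_norm <- sqrt(sum(spec$depression_shift^2))
  if (spec$trait_sd > 0 && shift_norm > 0) {
    # latent mood/adaptivity axis along the unit direction of the depression
    # shift: most subjects sit in a broad main mode, a minority occupies a
    # depression-prone psychotype mode further along the axis, and depressed
    # subjects are additionally mean-shifted into that vulnerable region
    vulnerable <- runif(n) < 0.12
    trait <- ifelse(vulnerable, rnorm(n, mean = 2.8, sd = 0.5), rnorm(n))
    mu <- mu + outer(trait * spec$trait_sd, spec$depression_shift / shift_norm)
  }
  items <- clip(mu + matrix(rnorm(n * spec$n_items, sd = spec$item_sd),
                            n, spec$n_items), lo, hi)
  colnames(items) <- item_cols(spec$n_items)

  g <- planted_wellbeing(items, spec)

  set.seed(seeds[3]) # baseline well-being stream
  skew <- matrix(lo + (hi - lo) * rbeta(n * 6, 5, 1.5), n, 6)
  wb1 <- clip(0.55 * g + 0.45 * skew, lo, hi)
  colnames(wb1) <- wb_cols(1)

  set.seed(seeds[4]) # follow-up noise stream
  wb2 <- clip(g + matrix(rnorm(n * 6, sd = spec$noise_sd), n, 6), lo, hi)
  colnames(wb2) <- wb_cols(2)

  out <- tibble(
    subject_id = sprintf("S%05d", seq_len(n)),
    as_tibble(items),
    age = age,
    sex = sex,
    as_tibble(wb1),
    as_tibble(wb2),
    depressed = depressed,
    split = split
  )
  new_cohort_tbl(out, spec = spec)
}

new_cohort_tbl <- function(x, spec = NULL) {
  structure(x, spec = spec, class = unique(c("cohort_tbl", class(x))))
}

#' Extract the questionnaire item matrix from a cohort
#'
#' @param cohort A cohort tibble.
#' @return Numeric matrix, subjects x items.
#' @export
cohort_items <- function(cohort) {
  cols <- grep("^item_\\d+$", names(cohort), value = TRUE)
  if (length(cols) == 0) abort("cohort has no `item_*` columns.")
  m <- as.matrix(cohort[cols])
  storage.mode(m) <- "double"
  m
}

#' Validate a cohort table against the fixed schema
#'
#' Checks column presence, item numeric-ness, sex coding, well-being bounds
#' and the no-depressed-in-training constraint.
#'
#' @param cohort A data frame.
#' @param n_items Expected number of items.
#' @param require_clean_train Refuse cohorts whose training partition contains
#'   depressed subjects (the atlas is trained on non-depressed people only).
#' @return The cohort, invisibly, if valid; otherwise an error naming the
#'   offending column.
#' @export
validate_cohort <- function(cohort, n_items = NULL, require_clean_train = FALSE) {
  items_present <- grep("^item_\\d+$", names(cohort), value = TRUE)
  n_items <- n_items %||% length(items_present)
  required <- c("subject_id", item_cols(n_items), "age", "sex",
                wb_cols(1), wb_cols(2), "depressed", "split")
  missing <- setdiff(required, names(cohort))
  if (length(missing) > 0) {
    abort(sprintf("cohort is missing required column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  for (col in c(item_cols(n_items), "age", wb_cols(1), wb_cols(2))) {
    if (!is.numeric(cohort[[col]])) {
      abort(sprintf("cohort column `%s` must be numeric.", col))
    }
  }
  if (anyNA(cohort[required])) abort("cohort contains missing values.")
  bad_sex <- setdiff(unique(cohort$sex), c("male", "female"))
  if (length(bad_sex) > 0) {
    abort(sprintf("cohort column `sex` has unknown code(s): %s",
                  paste(bad_sex, collapse = ", ")))
  }
  bad_split <- setdiff(unique(cohort$split), c("train", "test"))
  if (length(bad_split) > 0) {
    abort(sprintf("cohort column `split` has unknown code(s): %s",
                  paste(bad_split, collapse = ", ")))
  }
  if (require_clean_train && any(cohort$depressed & cohort$split == "train")) {
    abort("training partition contains depressed subjects; the map is trained on non-depressed people only.")
  }
  invisible(cohort)
}
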