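# Cross-validated decoding of spatial location from multivoxel patterns:
# a linear nu-SVR (LIBSVM via e1071, C = 1, nu = 0.5, untuned) is trained
# on the audiovisual congruent conditions of the training runs and decodes
# every condition of the held-out run.

#' Scale voxel response patterns
#'
#' `"pattern"` min-max scales each pattern (one run x condition vector)
#' to `[0, 1]` across its voxels; `"voxel"` scales each voxel across
#' patterns; `"roi"` applies one global min-max to the whole matrix;
#' `"none"` leaves the amplitudes untouched.
#'
#' @param patterns An `avbci_patterns` object.
#' @param method Scaling rule.
#' @return The patterns object with `x` rescaled.
#' @export
scale_patterns <- function(patterns,
                           method = c("pattern", "voxel", "roi", "none")) {
  method <- match.arg(method)
  patterns$x <- scale_matrix(patterns$x, method)
  patterns$scaling <- method
  patterns
}

scale_matrix <- function(x, method, stats = NULL) {
  minmax <- function(v, lo, hi) {
    if (hi - lo == 0) abort("constant pattern/voxel cannot be scaled.")
    (v - lo) / (hi - lo)
  }
  switch(method,
    none = x,
    pattern = t(apply(x, 1, function(r) minmax(r, min(r), max(r)))),
    voxel = {
      lo <- stats$lo %||% apply(x, 2, min)
      hi <- stats$hi %||% apply(x, 2, max)
      if (any(hi - lo == 0)) abort("constant pattern/voxel cannot be scaled.")
      sweep(sweep(x, 2, lo), 2, hi - lo, `/`)
    },
    roi = minmax(x, stats$lo %||% min(x), stats$hi %||% max(x))
  )
}

#' Leave-one-run-out decoding of spatial location
#'
#' Per cross-validation fold, fits the regression on the congruent
#' patterns of the training runs (labels = the common stimulus location,
#' all attention x report conditions included) and predicts a continuous
#' location for every condition of the held-out run.  Scaling statistics
#' that pool across patterns (`"voxel"`, `"roi"`) are computed on the
#' training runs only and applied to the test run, so no information
#' crosses folds; `"pattern"` scaling is per pattern and fold-safe by
#' construction.
#'
#' @param patterns An `avbci_patterns` object (unscaled).
#' @param cost,nu LIBSVM nu-SVR hyperparameters (fixed, not tuned).
#' @param scaling Pattern scaling rule, see [scale_patterns()].
#' @return A tibble of class `avbci_decoded`: one row per run x
#'   condition with the decoded continuous location (`decoded`, degrees)
#'   and the fold id.
#' @export
cross_validated_decode <- function(patterns, cost = 1, nu = 0.5,
                                   scaling = c("pattern", "voxel", "roi",
                                               "none")) {
  scaling <- match.arg(scaling)
  stopifnot(inherits(patterns, "avbci_patterns"))
  meta <- patterns$meta
  runs <- sort(unique(meta$run))
  if (length(runs) < 2) abort("need at least 2 runs for cross-validation.")

  out <- purrr::map_dfr(runs, function(test_run) {
    tr <- meta$run != test_run
    te <- !tr
    stats <- switch(scaling,
      voxel = list(lo = apply(patterns$x[tr, , drop = FALSE], 2, min),
                   hi = apply(patterns$x[tr, , drop = FALSE], 2, max)),
      roi = list(lo = min(patterns$x[tr, ]), hi = max(patterns$x[tr, ])),
      NULL
    )
    xtr <- scale_matrix(patterns$x[tr, , drop = FALSE], scaling, stats)
    xte <- scale_matrix(patterns$x[te, , drop = FALSE], scaling, stats)
    cong <- meta$aloc[tr] == meta$vloc[tr]
    model <- e1071::svm(
      x = xtr[cong, , drop = FALSE], y = meta$aloc[tr][cong],
      type = "nu-regression", kernel = "linear", cost = cost, nu = nu,
      scale = FALSE
    )
    meta[te, ] |>
      mutate(decoded = unname(predict(model, xte)), fold = test_run)
  })
  class(out) <- c("avbci_decoded", class(out))
  out
}

#' Group-level decoding accuracy for congruent conditions
#'
#' Per participant, the Pearson correlation between true and decoded
#' locations on audiovisual congruent conditions is Fisher-z transformed
#' (capped at `atanh(1 - 1e-15)` for perfect decoding); the z values are
#' tested against zero with a one-tailed sign-permutation test and the
#' inverse-transformed mean and CI are reported.
#'
#' @param decoded A tibble binding [cross_validated_decode()] outputs with
#'   a `participant` column.
#' @param ... Passed to [sign_permutation_test()] (e.g. `seed`).
#' @return A list of class `avbci_accuracy`: per-participant tibble
#'   (`r`, `z`), group mean correlation (inverse-transformed mean z) with
#'   CI, and the permutation test result.
#' @export
decoding_accuracy <- function(decoded, ...) {
  per <- decoded |>
    filter(.data$aloc == .data$vloc) |>
    group_by(.data$participant) |>
    summarise(r = cor(.data$aloc, .data$decoded), .groups = "drop")
  if (anyNA(per$r)) {
    warn("zero-variance decoded values: correlation undefined for some participants.")
  }
  cap <- 1 - 1e-15
  per$z <- atanh(pmin(pmax(per$r, -cap), cap))
  test <- sign_permutation_test(per$z[!is.na(per$z)], tails = "one", ...)
  structure(
    list(
      per_participant = per,
      mean_r = tanh(mean(per$z, na.rm = TRUE)),
      ci_r = tanh(c(test$ci_low, test$ci_high)),
      test = test
    ),
    class = "avbci_accuracy"
  )
}

#' @export
print.avbci_accuracy <- function(x, ...) {
  cat("<avbci decoding accuracy> mean r =", round(x$mean_r, 3),
      "[", round(x$ci_r[1], 3), ",", round(x$ci_r[2], 3), "],",
      "one-tailed p =", signif(x$test$p_value, 3), "\n")
  invisible(x)
}
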