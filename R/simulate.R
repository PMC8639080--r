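# Synthetic data generators: discrete localisation responses from any
# observer model in the 2 x 3 space, plausible observer populations, and
# multivoxel patterns with a known audiovisual encoding weight.

#' Simulate discrete localisation responses
#'
#' Fills the `response` column of a trial table by drawing internal
#' samples, computing the observer's final estimate of the reported
#' modality, and pressing the nearest button.  Draws are taken from
#' per-participant substreams of `seed`, so adding participants leaves
#' earlier participants' responses unchanged.
#'
#' @param design A trial table from [make_design()].
#' @param params An [observer_params()] object.
#' @param seed Master seed for the internal-sample draws.
#' @param lapse_rate Probability of replacing a response with a uniformly
#'   random button (default 0: trials with confused responses are assumed
#'   excluded upstream, as in standard cleaning).
#' @param locations Button locations; defaults to the design locations.
#' @return The trial table with `response` filled (degrees, one of the
#'   button locations).
#' @export
simulate_observer <- function(design, params, seed = 1, lapse_rate = 0,
                              locations = NULL) {
  stopifnot(inherits(params, "avbci_observer_params"))
  if (nrow(design) == 0) abort("`design` is empty.")
  if (lapse_rate < 0 || lapse_rate > 1) abort("`lapse_rate` must be in [0, 1].")
  locations <- sort(locations %||% unique(c(design$aloc, design$vloc)))

  design |>
    group_by(.data$participant) |>
    group_modify(function(d, key) {
      n <- nrow(d)
      draws <- with_seed(derive_seed(seed, "observer", key$participant), {
        z <- matrix(rnorm(2 * n), ncol = 2)
        lap <- if (lapse_rate > 0) {
          list(hit = runif(n) < lapse_rate,
               btn = sample(locations, n, replace = TRUE))
        } else {
          NULL
        }
        list(z = z, lap = lap)
      })
      s <- sigma_at(params, d$attention, d$report)
      x_a <- d$aloc + s$sa * draws$z[, 1]
      x_v <- d$vloc + s$sv * draws$z[, 2]
      est <- final_estimates(x_a, x_v, params, d$attention, d$report)
      e <- ifelse(d$report == "A", est$s_final_a, est$s_final_v)
      resp <- nearest_button(e, locations)
      if (!is.null(draws$lap)) resp[draws$lap$hit] <- draws$lap$btn[draws$lap$hit]
      d$response <- resp
      d
    }) |>
    ungroup() |>
    select(names(design))
}

#' Draw a plausible observer population
#'
#' Samples per-participant true parameters for simulation studies
#' (parameter/model recovery).  Ranges reflect typical audiovisual
#' localisation fits: auditory noise of a few degrees and clearly larger
#' than visual noise, a broad central prior, and an intermediate
#' common-cause prior.  For `att_free` variants the modality attended is
#' generated as more precise (sigma_A smaller under auditory attention,
#' sigma_V smaller under visual attention); `rep_free` variants analogously
#' tie sigma to the reported modality.
#'
#' @param n Number of participants.
#' @param variant Model variant generating the data.
#' @param seed Seed.
#' @return A list of `n` [observer_params()] objects.
#' @export
sample_observer_population <- function(n, variant = "BCI-att_free", seed = 1) {
  row <- VARIANTS[VARIANTS$variant == variant, ]
  if (nrow(row) == 0) abort(paste0("unknown model variant: ", variant))
  lv <- scheme_levels(row$scheme)
  purrr::map(seq_len(n), function(i) {
    with_seed(derive_seed(seed, "population", variant, i), {
      base_a <- runif(1, 3.5, 7)
      base_v <- runif(1, 1, 2.5)
      # attended (or reported) modality is the more precise one
      gain <- runif(2, 1.3, 1.8)
      sa <- switch(row$scheme,
        none = base_a,
        att = c(attA = base_a, attV = base_a * gain[1]),
        rep = c(repA = base_a, repV = base_a * gain[1]),
        att_rep = c(attA.repA = base_a, attA.repV = base_a * runif(1, 1, 1.2),
                    attV.repA = base_a * gain[1],
                    attV.repV = base_a * gain[1] * runif(1, 1, 1.2))
      )
      sv <- switch(row$scheme,
        none = base_v,
        att = c(attA = base_v * gain[2], attV = base_v),
        rep = c(repA = base_v * gain[2], repV = base_v),
        att_rep = c(attA.repA = base_v * gain[2],
                    attA.repV = base_v * gain[2] * runif(1, 1, 1.2),
                    attV.repA = base_v * runif(1, 1, 1.2), attV.repV = base_v)
      )
      observer_params(
        variant,
        sigma_a = sa, sigma_v = sv,
        sigma_p = runif(1, 9, 16),
        p_common = if (row$inference == "BCI") runif(1, 0.45, 0.75) else NULL
      )
    })
  })
}

#' Simulate multivoxel response patterns with a known audiovisual weight
#'
#' Generates one pattern per run x condition whose spatial encoding mixes
#' the auditory and visual locations with a fixed ground-truth weight:
#' the effective location is `s* = weight * vloc + (1 - weight) * aloc`
#' and voxel `v` responds `slope_v * s* + baseline_v + noise`.  The same
#' generative law applies to congruent and incongruent cells.
#'
#' @param weight Ground-truth visual weight in `[0, 1]`.
#' @param noise_sd Gaussian amplitude noise s.d. (same units as the
#'   baselines).
#' @param n_voxels Number of voxels (at least 2).
#' @param spec A [design_spec()]; its locations and cue levels define the
#'   36 conditions and its `n_runs` the number of patterns per condition.
#' @param tuning_slopes Optional per-voxel slopes; drawn `N(0, 1)` if
#'   `NULL` (must not be all zero).
#' @param baselines Optional per-voxel baselines; drawn `N(0, 10)` if
#'   `NULL`.
#' @param roi Label for the synthetic region.
#' @param seed Seed.
#' @return An object of class `avbci_patterns`: a list with `meta` (tibble
#'   of run x condition rows), `x` (patterns x voxels matrix), `roi`,
#'   `ground_truth_weight`, `noise_sd`, `locations`.
#' @export
simulate_voxel_patterns <- function(weight, noise_sd, n_voxels = 100,
                                    spec = design_spec(n_runs = 7),
                                    tuning_slopes = NULL, baselines = NULL,
                                    roi = "synthetic", seed = 1) {
  if (weight < 0 || weight > 1) abort("`weight` must lie in [0, 1].")
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  if (n_voxels < 2) abort("`n_voxels` must be at least 2.")
  with_seed(derive_seed(seed, "voxels", roi), {
    tuning_slopes <- tuning_slopes %||% rnorm(n_voxels)
    baselines <- baselines %||% rnorm(n_voxels, 0, 10)
    if (length(tuning_slopes) != n_voxels || length(baselines) != n_voxels) {
      abort("`tuning_slopes`/`baselines` must have length `n_voxels`.")
    }
    if (all(tuning_slopes == 0)) abort("tuning slopes must not be all zero.")
    meta <- tidyr::expand_grid(run = seq_len(spec$n_runs),
                               design_cells(spec)) |>
      mutate(s_star = weight * .data$vloc + (1 - weight) * .data$aloc)
    x <- outer(meta$s_star, tuning_slopes) +
      matrix(baselines, nrow(meta), n_voxels, byrow = TRUE) +
      matrix(rnorm(nrow(meta) * n_voxels, 0, noise_sd), nrow(meta), n_voxels)
    structure(
      list(meta = meta, x = x, roi = roi, ground_truth_weight = weight,
           noise_sd = noise_sd, locations = spec$locations),
      class = "avbci_patterns"
    )
  })
}

#' @export
print.avbci_patterns <- function(x, ...) {
  cat("<avbci voxel patterns> roi:", x$roi, "\n")
  cat("  ", nrow(x$x), "patterns x", ncol(x$x), "voxels;",
      "ground-truth weight", x$ground_truth_weight,
      "; noise sd", x$noise_sd, "\n")
  invisible(x)
}

#' Read / write voxel-pattern sets as delimited text
#'
#' One row per run x condition: the metadata columns (`run`, `aloc`,
#' `vloc`, `attention`, `report`, `s_star`), the set-level fields (`roi`,
#' `ground_truth_weight`, `noise_sd`, repeated), then one `v<j>` column
#' per voxel.
#'
#' @param patterns An `avbci_patterns` object.
#' @param path CSV file path.
#' @return `write_patterns` returns `path` invisibly; `read_patterns` the
#'   reconstructed `avbci_patterns` object.
#' @export
write_patterns <- function(patterns, path) {
  stopifnot(inherits(patterns, "avbci_patterns"))
  x <- patterns$x
  colnames(x) <- paste0("v", seq_len(ncol(x)))
  df <- bind_cols(
    patterns$meta,
    tibble(roi = patterns$roi,
           ground_truth_weight = patterns$ground_truth_weight %||% NA_real_,
           noise_sd = patterns$noise_sd %||% NA_real_),
    as_tibble(x)
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_patterns
#' @export
read_patterns <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  vcols <- grep("^v[0-9]+$", names(df), value = TRUE)
  meta_cols <- setdiff(names(df), c(vcols, "roi", "ground_truth_weight",
                                    "noise_sd"))
  structure(
    list(
      meta = as_tibble(df[meta_cols]),
      x = as.matrix(df[vcols]),
      roi = df$roi[1],
      ground_truth_weight = df$ground_truth_weight[1],
      noise_sd = df$noise_sd[1],
      locations = sort(unique(c(df$aloc, df$vloc)))
    ),
    class = "avbci_patterns"
  )
}
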