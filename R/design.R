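# Factorial ventriloquist design: 3 (auditory location) x 3 (visual
# location) x 2 (prestimulus attention) x 2 (poststimulus report), discrete
# 3-button responses at the stimulus locations.

#' Specify a factorial audiovisual localisation design
#'
#' @param locations Numeric vector of source azimuths in degrees visual
#'   angle, symmetric about 0.  Default `c(-9, 0, 9)`.
#' @param attention_levels,report_levels Factor levels for the prestimulus
#'   attention and poststimulus report cues.
#' @param n_trials_per_condition Trials per design cell per run.
#' @param n_runs Number of runs.
#' @param seed Integer seed controlling trial-order randomisation.
#' @return An object of class `avbci_design_spec`.
#' @export
#' @examples
#' design_spec(n_trials_per_condition = 6, n_runs = 14)
design_spec <- function(locations = c(-9, 0, 9),
                        attention_levels = c("A", "V"),
                        report_levels = c("A", "V"),
                        n_trials_per_condition = 6,
                        n_runs = 14,
                        seed = 1L) {
  locations <- sort(as.numeric(locations))
  if (length(locations) < 2 || anyDuplicated(locations)) {
    abort("`locations` must be at least two distinct azimuths.")
  }
  if (max(abs(locations + rev(locations))) > 1e-9) {
    abort("`locations` must be symmetric about 0.")
  }
  if (n_trials_per_condition < 1 || n_trials_per_condition %% 1 != 0) {
    abort("`n_trials_per_condition` must be a positive integer.")
  }
  if (n_runs < 1 || n_runs %% 1 != 0) {
    abort("`n_runs` must be a positive integer.")
  }
  structure(
    list(
      locations = locations,
      attention_levels = attention_levels,
      report_levels = report_levels,
      n_trials_per_condition = as.integer(n_trials_per_condition),
      n_runs = as.integer(n_runs),
      seed = as.integer(seed)
    ),
    class = "avbci_design_spec"
  )
}

#' @export
print.avbci_design_spec <- function(x, ...) {
  cat("<avbci design spec>\n")
  cat("  locations:", paste(x$locations, collapse = ", "), "deg\n")
  cat("  attention:", paste(x$attention_levels, collapse = "/"),
      " report:", paste(x$report_levels, collapse = "/"), "\n")
  cat("  ", x$n_trials_per_condition, "trials/cell x ",
      length(x$locations)^2 * length(x$attention_levels) *
        length(x$report_levels), "cells x ", x$n_runs, "runs\n")
  invisible(x)
}

# All design cells (conditions) of a spec, in canonical order.
design_cells <- function(spec) {
  tidyr::expand_grid(
    attention = spec$attention_levels,
    report = spec$report_levels,
    aloc = spec$locations,
    vloc = spec$locations
  )
}

#' Instantiate a balanced trial table (responses empty)
#'
#' Builds the long-format trial table for one or more participants: every
#' (auditory location, visual location, attention, report) cell occurs
#' `n_trials_per_condition` times in every run, pseudo-randomised within
#' run by the spec seed.
#'
#' @param spec A [design_spec()].
#' @param n_participants Number of participants to lay out.
#' @return A tibble with columns `participant`, `run`, `trial`, `aloc`,
#'   `vloc`, `attention`, `report`, `valid` (precue matches postcue) and
#'   `response` (all `NA`, to be filled by [simulate_observer()]).
#' @export
#' @examples
#' make_design(design_spec(n_trials_per_condition = 1, n_runs = 1))
make_design <- function(spec, n_participants = 1) {
  stopifnot(inherits(spec, "avbci_design_spec"))
  if (n_participants < 1) abort("`n_participants` must be positive.")
  cells <- design_cells(spec)
  run_block <- cells[rep(seq_len(nrow(cells)), spec$n_trials_per_condition), ]
  purrr::map_dfr(seq_len(n_participants), function(p) {
    purrr::map_dfr(seq_len(spec$n_runs), function(r) {
      ord <- with_seed(
        derive_seed(spec$seed, "design", p, r),
        sample.int(nrow(run_block))
      )
      run_block[ord, ] |>
        mutate(
          participant = p, run = r, trial = dplyr::row_number(),
          .before = 1
        )
    })
  }) |>
    mutate(valid = .data$attention == .data$report, response = NA_real_)
}
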