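# Simulation-based multinomial likelihood.  Predicted button probabilities
# per design cell come from the C++ kernel fed with a fixed standard-normal
# draw matrix (common random numbers), so the log likelihood is an exactly
# deterministic function of the parameters for a given seed.

#' Tabulate response counts per design cell
#'
#' @param trials One participant's trial table with responses filled.
#' @param locations Button locations; defaults to the stimulus locations
#'   present in the table.
#' @return An object of class `avbci_counts`: cells tibble, a buttons x
#'   cells count matrix, and the total trial count `n`.
#' @export
condition_counts <- function(trials, locations = NULL) {
  if (anyNA(trials$response)) abort("responses contain missing values.")
  if (length(unique(trials$participant)) > 1) {
    abort("`trials` must contain a single participant.")
  }
  locations <- sort(locations %||% unique(c(trials$aloc, trials$vloc)))
  if (!all(trials$response %in% locations)) {
    abort("responses outside the button locations.")
  }
  cells <- trials |>
    distinct(.data$attention, .data$report, .data$aloc, .data$vloc) |>
    arrange(.data$attention, .data$report, .data$aloc, .data$vloc)
  key_of <- function(a, r, al, vl) paste(a, r, al, vl, sep = "|")
  idx <- match(
    key_of(trials$attention, trials$report, trials$aloc, trials$vloc),
    key_of(cells$attention, cells$report, cells$aloc, cells$vloc)
  )
  btn <- match(trials$response, locations)
  counts <- matrix(0, length(locations), nrow(cells))
  for (i in seq_along(idx)) counts[btn[i], idx[i]] <- counts[btn[i], idx[i]] + 1
  structure(
    list(cells = cells, counts = counts, locations = locations,
         n = nrow(trials)),
    class = "avbci_counts"
  )
}

#' @export
print.avbci_counts <- function(x, ...) {
  cat("<avbci response counts>", x$n, "trials,", nrow(x$cells), "cells,",
      length(x$locations), "buttons\n")
  invisible(x)
}

# Fixed standard-normal draw matrices (n_sim x cells, auditory and visual).
crn_draws <- function(n_sim, n_cells, seed) {
  with_seed(seed, list(
    za = matrix(rnorm(n_sim * n_cells), n_sim, n_cells),
    zv = matrix(rnorm(n_sim * n_cells), n_sim, n_cells)
  ))
}

# Predicted probabilities for every cell given a draw matrix.
cell_probs <- function(params, cells, z, locations) {
  s <- sigma_at(params, cells$attention, cells$report)
  cell_response_probs_cpp(
    za = z$za, zv = z$zv,
    aloc = cells$aloc, vloc = cells$vloc, sa = s$sa, sv = s$sv,
    report_a = cells$report == "A",
    sp = params$sigma_p, mup = params$mu_p, pc = params$p_common,
    forced_fusion = params$inference == "FF", buttons = locations
  )
}

#' Simulation-based multinomial log likelihood
#'
#' Sums, over design cells, the observed button counts times the log of
#' the model-predicted button probabilities.  The multinomial coefficient
#' is omitted (constant in the parameters), and probabilities are floored
#' at `floor_p` before the log to guard against zero simulated mass.
#'
#' @param params An [observer_params()] object.
#' @param counts A [condition_counts()] object.
#' @param n_sim Simulated internal-sample pairs per cell.
#' @param seed Seed for the common-random-number draws.
#' @param z Optional precomputed draws from the internal CRN generator;
#'   when fitting, one matrix is drawn per fit and reused across all
#'   parameter evaluations.
#' @param floor_p Probability floor.
#' @return The log likelihood (a scalar, `<= 0` up to the omitted
#'   multinomial constant).
#' @export
log_likelihood <- function(params, counts, n_sim = 10000, seed = 1,
                           z = NULL, floor_p = 1e-6) {
  stopifnot(inherits(counts, "avbci_counts"))
  z <- z %||% crn_draws(n_sim, nrow(counts$cells), seed)
  p <- cell_probs(params, counts$cells, z, counts$locations)
  multinomial_loglik_cpp(p, counts$counts, floor_p)
}

# Log likelihood of the guessing null model: uniform over the buttons.
null_loglik <- function(counts) {
  -counts$n * log(length(counts$locations))
}
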