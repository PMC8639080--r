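# Simulation studies with known ground truth: parameter recovery for one
# variant and model recovery (confusion matrix) across the 2 x 3 space.

#' Parameter-recovery study
#'
#' Draws a plausible observer population, simulates each participant's
#' responses under the generating variant, refits that variant, and pairs
#' true with recovered parameters.
#'
#' @param n_participants Number of simulated observers.
#' @param variant Generating (and fitted) model variant.
#' @param spec Design; the default gives 84 trials per cell (6 per run x
#'   14 runs).
#' @param n_sim,maxit,grid Fitting settings, see [fit_model()].
#' @param seed Master seed.
#' @return A tibble with one row per participant x parameter: `term`,
#'   `true`, `recovered`, plus the fit's `logL` and `r2_scaled`.
#' @export
parameter_recovery_study <- function(n_participants = 12,
                                     variant = "BCI-att_free",
                                     spec = design_spec(
                                       n_trials_per_condition = 6,
                                       n_runs = 14
                                     ),
                                     n_sim = 10000, maxit = 300,
                                     grid = NULL, seed = 1) {
  pop <- sample_observer_population(n_participants, variant,
                                    seed = derive_seed(seed, "pop"))
  design <- make_design(spec, n_participants = n_participants)
  purrr::map_dfr(seq_len(n_participants), function(p) {
    trials <- simulate_observer(filter(design, .data$participant == p),
                                pop[[p]], seed = derive_seed(seed, "sim"))
    fit <- fit_model(trials, variant, n_sim = n_sim, maxit = maxit,
                     grid = grid, seed = derive_seed(seed, "fit", p))
    true_tbl <- tibble(
      term = tidy(fit)$term,
      true = {
        tp <- pop[[p]]
        unname(c(tp$sigma_a, tp$sigma_v, tp$sigma_p,
                 if (tp$inference == "BCI") tp$p_common))
      }
    )
    tidy(fit) |>
      rename(recovered = "estimate") |>
      left_join(true_tbl, by = "term") |>
      mutate(participant = p, logL = fit$logL, r2_scaled = fit$r2_scaled,
             .before = 1)
  })
}

#' Model-recovery study (confusion matrix)
#'
#' For each generating variant, simulates a participant sample, fits all
#' candidate variants to every participant, and runs random-effects model
#' selection.  The confusion matrix of protected exceedance probabilities
#' shows how reliably the pipeline re-identifies the generating model.
#'
#' @param generating Variants that generate data (default: all six).
#' @param candidates Variants fitted to each dataset (default: all six).
#' @param n_participants Participants per generating condition.
#' @param spec Design (default 84 trials/cell).
#' @param n_sim,maxit,grid Fitting settings; the defaults trade a little
#'   likelihood resolution for runtime, which simulation checks show does
#'   not change the selected model.
#' @param bms_samples Dirichlet draws for exceedance probabilities.
#' @param seed Master seed.
#' @return A list: `confusion` (tibble generating x candidate with pEP),
#'   `selected` (tibble of the top-pEP model per generating condition),
#'   and `fits` (the per-condition fit tables).
#' @export
model_recovery_study <- function(generating = model_variants()$variant,
                                 candidates = model_variants()$variant,
                                 n_participants = 12,
                                 spec = design_spec(
                                   n_trials_per_condition = 6, n_runs = 14
                                 ),
                                 n_sim = 1500, maxit = 150,
                                 grid = list(
                                   sigma_a = c(3, 8), sigma_v = c(1, 2.5),
                                   sigma_p = c(10, 25),
                                   p_common = c(0.3, 0.6)
                                 ),
                                 bms_samples = 1e5, seed = 1) {
  design <- make_design(spec, n_participants = n_participants)
  res <- purrr::map(generating, function(g) {
    pop <- sample_observer_population(n_participants, g,
                                      seed = derive_seed(seed, "pop", g))
    trials <- purrr::map_dfr(seq_len(n_participants), function(p) {
      simulate_observer(filter(design, .data$participant == p), pop[[p]],
                        seed = derive_seed(seed, "sim", g))
    })
    fits <- fit_participants(trials, variants = candidates, n_sim = n_sim,
                             maxit = maxit, grid = grid,
                             seed = derive_seed(seed, "fit", g))
    bms <- rfx_bms(evidence_matrix(fits), n_samples = bms_samples,
                   seed = derive_seed(seed, "bms", g))
    list(generating = g, fits = fits, bms = bms)
  })
  confusion <- purrr::map_dfr(res, function(r) {
    tidy(r$bms) |> mutate(generating = r$generating, .before = 1)
  })
  selected <- confusion |>
    group_by(.data$generating) |>
    slice_max(.data$pep, n = 1, with_ties = FALSE) |>
    ungroup() |>
    select("generating", selected = "model", "pep")
  list(confusion = confusion, selected = selected,
       fits = setNames(purrr::map(res, "fits"), generating))
}
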