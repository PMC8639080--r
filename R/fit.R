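# Maximum-likelihood fitting of the six observer models: a coarse grid
# search in transformed parameter space (log sigma, logit P_common)
# initialises a Nelder-Mead simplex refinement of the simulation-based
# multinomial likelihood under common random numbers.

theta_names <- function(variant) {
  row <- VARIANTS[VARIANTS$variant == variant, ]
  lv <- scheme_levels(row$scheme)
  nm <- c(paste0("log_sigma_a.", lv), paste0("log_sigma_v.", lv), "log_sigma_p")
  if (row$inference == "BCI") nm <- c(nm, "logit_p_common")
  nm
}

theta_to_params <- function(theta, variant) {
  row <- VARIANTS[VARIANTS$variant == variant, ]
  lv <- scheme_levels(row$scheme)
  nl <- length(lv)
  observer_params(
    variant,
    sigma_a = setNames(exp(theta[seq_len(nl)]), lv),
    sigma_v = setNames(exp(theta[nl + seq_len(nl)]), lv),
    sigma_p = exp(theta[2 * nl + 1]),
    p_common = if (row$inference == "BCI") plogis(theta[2 * nl + 2]) else NULL
  )
}

params_to_theta <- function(params) {
  th <- c(log(params$sigma_a), log(params$sigma_v), log(params$sigma_p))
  if (params$inference == "BCI") th <- c(th, qlogis(params$p_common))
  setNames(th, theta_names(params$variant))
}

default_fit_grid <- function() {
  list(sigma_a = c(2, 4, 8, 16), sigma_v = c(0.5, 1, 2, 4),
       sigma_p = c(5, 10, 20, 40), p_common = c(0.2, 0.5, 0.8))
}

# Grid of starting points: factorial over base values, each expanded to
# equal values across the variant's conditioning levels.
grid_starts <- function(variant, grid) {
  row <- VARIANTS[VARIANTS$variant == variant, ]
  g <- expand.grid(sigma_a = grid$sigma_a, sigma_v = grid$sigma_v,
                   sigma_p = grid$sigma_p,
                   p_common = if (row$inference == "BCI") grid$p_common else 1)
  nl <- length(scheme_levels(row$scheme))
  t(apply(g, 1, function(r) {
    th <- c(rep(log(r[["sigma_a"]]), nl), rep(log(r[["sigma_v"]]), nl),
            log(r[["sigma_p"]]))
    if (row$inference == "BCI") th <- c(th, qlogis(r[["p_common"]]))
    th
  }))
}

#' Fit one observer model to one participant's responses
#'
#' Maximises the simulation-based multinomial log likelihood over the
#' variant's free parameters.  A fixed standard-normal draw matrix is
#' generated once per fit and reused across all parameter evaluations
#' (common random numbers), so the surface is deterministic and the
#' returned optimum is exactly reproducible from the seed.
#'
#' @param trials One participant's trial table (responses filled).
#' @param variant Model variant code (see [model_variants()]).
#' @param n_sim Simulated internal-sample pairs per design cell per
#'   likelihood evaluation.
#' @param seed Seed for the common-random-number draws.
#' @param grid Named list of grid values for the initialisation search
#'   (defaults to [default_fit_grid()]); the factorial over base values is
#'   evaluated and the best point starts the simplex.
#' @param maxit Maximum Nelder-Mead iterations.
#' @param floor_p Probability floor inside the likelihood.
#' @param locations Button locations (default: stimulus locations found in
#'   the trials).
#' @return An object of class `avbci_fit` carrying the fitted
#'   [observer_params()], `logL`, `logL_null`, scaled R-squared, the three
#'   information-criterion variants from [bic_scores()], convergence
#'   metadata and the seed.
#' @export
fit_model <- function(trials, variant, n_sim = 10000, seed = 1, grid = NULL,
                      maxit = 500, floor_p = 1e-6, locations = NULL) {
  counts <- condition_counts(trials, locations = locations)
  fit_counts(counts, variant, n_sim = n_sim, seed = seed, grid = grid,
             maxit = maxit, floor_p = floor_p)
}

#' @rdname fit_model
#' @param counts A [condition_counts()] object (alternative entry point).
#' @export
fit_counts <- function(counts, variant, n_sim = 10000, seed = 1, grid = NULL,
                       maxit = 500, floor_p = 1e-6) {
  stopifnot(inherits(counts, "avbci_counts"))
  row <- VARIANTS[VARIANTS$variant == variant, ]
  if (nrow(row) == 0) abort(paste0("unknown model variant: ", variant))
  grid <- modifyList(default_fit_grid(), grid %||% list())
  # the draw seed depends on the fit seed only, not the variant, so all
  # variants fitted to the same data share one draw matrix and their log
  # likelihoods are directly comparable (common Monte-Carlo noise)
  z <- crn_draws(n_sim, nrow(counts$cells), derive_seed(seed, "crn"))

  negll <- function(theta) {
    if (any(!is.finite(theta))) return(1e10)
    p <- theta_to_params(theta, variant)
    -log_likelihood(p, counts, z = z, floor_p = floor_p)
  }

  starts <- grid_starts(variant, grid)
  grid_vals <- apply(starts, 1, negll)
  best <- which.min(grid_vals)

  opt <- optim(starts[best, ], negll, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-9))
  # keep the better of grid optimum and simplex output (non-convergence
  # falls back to best-so-far rather than failing)
  if (opt$value > grid_vals[best]) {
    opt <- list(par = starts[best, ], value = grid_vals[best],
                convergence = 1L, counts = opt$counts)
  }

  params <- theta_to_params(opt$par, variant)
  logL <- -opt$value
  l0 <- null_loglik(counts)
  fit <- structure(
    list(
      params = params, variant = variant, k = row$k,
      logL = logL, logL_null = l0, n = counts$n,
      n_sim = n_sim, seed = seed, floor_p = floor_p,
      converged = opt$convergence == 0,
      n_grid_evals = nrow(starts),
      n_optim_evals = unname(opt$counts["function"]),
      counts = counts
    ),
    class = "avbci_fit"
  )
  fit$r2_scaled <- goodness_of_fit(fit)
  ic <- bic_scores(fit)
  fit$bic <- ic$bic
  fit$log_evidence <- ic$log_evidence
  fit$bic_conventional <- ic$bic_conventional
  fit
}

#' Scaled coefficient of determination of a fit
#'
#' `R2 = 1 - exp(-(2/n) (l(beta) - l(0)))` against the uniform-guessing
#' null model, divided by its maximum attainable value
#' `max(R2) = 1 - exp((2/n) l(0))` reached under perfect prediction of the
#' discrete responses.
#'
#' @param fit An `avbci_fit` object.
#' @return The scaled R-squared (can be negative if the model underfits
#'   the null; not clipped).
#' @export
goodness_of_fit <- function(fit) {
  r2 <- 1 - exp(-(2 / fit$n) * (fit$logL - fit$logL_null))
  r2_max <- 1 - exp((2 / fit$n) * fit$logL_null)
  r2 / r2_max
}

#' Information criteria of a fit
#'
#' Returns three conventions side by side: `bic` as printed in the source
#' convention `-ln L + k ln n`; `log_evidence = logL - (k/2) ln n`, the
#' Schwarz approximation to the log model evidence used for group-level
#' model selection; and the textbook `bic_conventional = -2 logL + k ln n`.
#' All three rank models identically.
#'
#' @param fit An `avbci_fit` object.
#' @return A one-row tibble with the three criteria.
#' @export
bic_scores <- function(fit) {
  tibble(
    bic = -fit$logL + fit$k * log(fit$n),
    log_evidence = fit$logL - (fit$k / 2) * log(fit$n),
    bic_conventional = -2 * fit$logL + fit$k * log(fit$n)
  )
}

#' @export
print.avbci_fit <- function(x, ...) {
  cat("<avbci fit> ", x$variant, ": logL = ", round(x$logL, 2),
      ", scaled R2 = ", round(x$r2_scaled, 3),
      ", k = ", x$k, ", n = ", x$n,
      if (!x$converged) "  [not converged: best-so-far]", "\n", sep = "")
  invisible(x)
}

#' @export
tidy.avbci_fit <- function(x, ...) {
  p <- x$params
  tibble(
    term = c(paste0("sigma_a.", names(p$sigma_a)),
             paste0("sigma_v.", names(p$sigma_v)), "sigma_p",
             if (p$inference == "BCI") "p_common"),
    estimate = unname(c(p$sigma_a, p$sigma_v, p$sigma_p,
                        if (p$inference == "BCI") p$p_common))
  )
}

#' @export
glance.avbci_fit <- function(x, ...) {
  tibble(
    variant = x$variant, k = x$k, n = x$n, logL = x$logL,
    logL_null = x$logL_null, r2_scaled = x$r2_scaled, bic = x$bic,
    log_evidence = x$log_evidence, converged = x$converged,
    n_sim = x$n_sim, seed = x$seed
  )
}

#' Fit a set of model variants to every participant
#'
#' @param trials A multi-participant trial table.
#' @param variants Character vector of variant codes (default: all six).
#' @param ... Passed to [fit_model()].
#' @return A tibble with one row per participant x variant, the fit object
#'   in a list column plus its [glance()] summaries.
#' @export
fit_participants <- function(trials, variants = model_variants()$variant,
                             ...) {
  purrr::map_dfr(sort(unique(trials$participant)), function(p) {
    tp <- filter(trials, .data$participant == p)
    purrr::map_dfr(variants, function(v) {
      f <- fit_model(tp, v, ...)
      bind_cols(tibble(participant = p, variant = v, fit = list(f)),
                glance(f)[-1])
    })
  })
}

#' Participants x models log-evidence matrix
#'
#' @param fit_tbl Output of [fit_participants()].
#' @return A numeric matrix (participants x models) of the log-evidence
#'   approximations, ready for [rfx_bms()].
#' @export
evidence_matrix <- function(fit_tbl) {
  wide <- fit_tbl |>
    select("participant", "variant", "log_evidence") |>
    tidyr::pivot_wider(names_from = "variant", values_from = "log_evidence")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$participant
  m
}

#' Group-level model-comparison summary table
#'
#' One row per model variant: across-participant mean (and SEM) of the
#' fitted parameters and scaled R-squared, the summed log evidence
#' relative to a reference model (`rel_bic`, reference minus model so the
#' reference is 0 and smaller is better), and, when a [rfx_bms()] result
#' is supplied, the protected exceedance probabilities.
#'
#' @param fit_tbl Output of [fit_participants()].
#' @param bms Optional `avbci_bms` object for the same fits.
#' @param reference Reference variant for `rel_bic`.
#' @return A tibble with one row per variant.
#' @export
model_comparison_table <- function(fit_tbl, bms = NULL,
                                   reference = "BCI-att_free") {
  sums <- fit_tbl |>
    group_by(.data$variant) |>
    summarise(
      k = .data$k[1],
      mean_r2_scaled = mean(.data$r2_scaled),
      sem_r2_scaled = sd(.data$r2_scaled) / sqrt(dplyr::n()),
      sum_log_evidence = sum(.data$log_evidence),
      mean_p_common = mean(purrr::map_dbl(.data$fit, ~ .x$params$p_common)),
      mean_sigma_p = mean(purrr::map_dbl(.data$fit, ~ .x$params$sigma_p)),
      .groups = "drop"
    )
  if (!reference %in% sums$variant) {
    abort(paste0("reference variant not fitted: ", reference))
  }
  ref <- sums$sum_log_evidence[sums$variant == reference]
  sums <- mutate(sums, rel_bic = .env$ref - .data$sum_log_evidence)
  if (!is.null(bms)) {
    sums <- left_join(sums, tidy(bms)[c("model", "pep")],
                      by = c(variant = "model"))
  }
  arrange(sums, .data$rel_bic)
}
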