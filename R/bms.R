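# Random-effects Bayesian model selection at the group level: variational
# Dirichlet posterior over model frequencies, exceedance probabilities by
# Monte-Carlo (exact regularised-incomplete-beta form for two models),
# Bayesian omnibus risk by free-energy comparison against the null model
# of equal frequencies, and protected exceedance probabilities.

#' Random-effects Bayesian model selection
#'
#' Treats the model generating each participant's data as a random effect
#' with population frequencies `r ~ Dirichlet(alpha0)`.  The variational
#' posterior over frequencies is iterated to convergence from the
#' participants x models log-evidence matrix; exceedance probabilities are
#' the posterior probabilities that each model is the most frequent; the
#' Bayesian omnibus risk (BOR) is the posterior probability of the null
#' hypothesis that all frequencies are equal, computed from the free
#' energies `F1` (random-effects model) and `F0` (null):
#' `BOR = 1 / (1 + exp(F1 - F0))`.
#'
#' @param evidence Participants x models matrix of log evidences (finite;
#'   e.g. from [evidence_matrix()]).
#' @param alpha0 Symmetric Dirichlet prior count (default 1).
#' @param n_samples Dirichlet draws for the exceedance probabilities.
#' @param tol,max_iter Variational convergence controls (max change in
#'   alpha, iteration cap).
#' @param ep_method `"auto"` uses the exact regularised-incomplete-beta
#'   form when there are two models and Dirichlet sampling otherwise;
#'   `"sampling"` and `"exact"` force one route (exact requires two
#'   models).
#' @param seed Seed for the Dirichlet sampling.
#' @return An object of class `avbci_bms`: `alpha`, `expected_freq`,
#'   `ep`, `bor`, `pep`, plus iteration metadata.
#' @export
rfx_bms <- function(evidence, alpha0 = 1, n_samples = 1e6, tol = 1e-6,
                    max_iter = 1e4,
                    ep_method = c("auto", "sampling", "exact"), seed = 1) {
  ep_method <- match.arg(ep_method)
  evidence <- as.matrix(evidence)
  if (any(!is.finite(evidence))) abort("log evidences must be finite.")
  n <- nrow(evidence)
  k <- ncol(evidence)
  if (n < 2 || k < 2) abort("need at least 2 participants and 2 models.")
  models <- colnames(evidence) %||% paste0("model", seq_len(k))

  alpha <- rep(alpha0, k)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # responsibilities: softmax of evidence plus E[log r_k]
    u <- sweep(evidence, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    u <- exp(u - apply(u, 1, max))
    z <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(z)
    delta <- max(abs(alpha_new - alpha))
    alpha <- alpha_new
    if (delta < tol || iter >= max_iter) break
  }
  ef <- alpha / sum(alpha)

  use_exact <- ep_method == "exact" || (ep_method == "auto" && k == 2)
  if (use_exact && k != 2) abort("exact exceedance requires exactly 2 models.")
  ep <- if (use_exact) {
    p1 <- 1 - pbeta(0.5, alpha[1], alpha[2])
    c(p1, 1 - p1)
  } else {
    with_seed(derive_seed(seed, "bms-ep"), {
      g <- matrix(rgamma(n_samples * k, shape = rep(alpha, each = n_samples)),
                  n_samples, k)
      tabulate(max.col(g), nbins = k) / n_samples
    })
  }

  # free energy of the variational solution (alpha0 symmetric)
  elr <- digamma(alpha) - digamma(sum(alpha))
  f1 <- sum(z * evidence) + sum((alpha0 - 1) * elr) +
    lgamma(k * alpha0) - k * lgamma(alpha0) -
    sum(z * log(pmax(z, 1e-300))) + sum(z %*% elr) -
    (lgamma(sum(alpha)) - sum(lgamma(alpha)) + sum((alpha - 1) * elr))
  # null model: frequencies fixed and equal; exact log evidence
  f0 <- sum(apply(evidence, 1, function(e) {
    m <- max(e)
    m + log(mean(exp(e - m)))
  }))
  bor <- 1 / (1 + exp(f1 - f0))

  structure(
    list(
      models = models, alpha = setNames(alpha, models),
      expected_freq = setNames(ef, models), ep = setNames(ep, models),
      bor = bor, pep = setNames(protected_ep(ep, bor), models),
      n_participants = n, n_samples = n_samples, iterations = iter,
      converged = iter < max_iter, seed = seed
    ),
    class = "avbci_bms"
  )
}

#' Protected exceedance probabilities
#'
#' Shrinks exceedance probabilities toward chance in proportion to the
#' Bayesian omnibus risk: `pEP = EP * (1 - BOR) + BOR / K`.
#'
#' @param ep Vector of exceedance probabilities (sums to 1).
#' @param bor Bayesian omnibus risk in `[0, 1]`.
#' @return Vector of protected exceedance probabilities (sums to 1).
#' @export
#' @examples
#' protected_ep(c(0.9, 0.1), bor = 0.2)
protected_ep <- function(ep, bor) {
  if (abs(sum(ep) - 1) > 1e-6) abort("`ep` must sum to 1.")
  if (bor < 0 || bor > 1) abort("`bor` must lie in [0, 1].")
  ep * (1 - bor) + bor / length(ep)
}

#' @export
print.avbci_bms <- function(x, ...) {
  cat("<avbci random-effects model selection> ", x$n_participants,
      " participants, ", length(x$models), " models\n", sep = "")
  cat("  BOR =", signif(x$bor, 3), "\n")
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.avbci_bms <- function(x, ...) {
  tibble(
    model = x$models, alpha = unname(x$alpha),
    expected_freq = unname(x$expected_freq), ep = unname(x$ep),
    pep = unname(x$pep)
  )
}

#' @export
glance.avbci_bms <- function(x, ...) {
  tibble(
    n_participants = x$n_participants, n_models = length(x$models),
    bor = x$bor, best_model = x$models[which.max(x$pep)],
    best_pep = max(x$pep), iterations = x$iterations,
    converged = x$converged
  )
}
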