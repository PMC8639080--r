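# Group-level nonparametric inference: exhaustive sign-permutation tests
# on per-participant effects and factorial contrasts on weight tables.

#' Sign-permutation test of a group mean
#'
#' Builds the null distribution of the across-participant mean under all
#' `2^n` assignments of signs to the participant effects (exhaustive when
#' `2^n <= 2^20`, e.g. 4,096 assignments at n = 12; Monte-Carlo with a
#' seed otherwise).  The observed assignment is part of the enumeration,
#' so p-values never reach 0.  The effect size is the observed mean minus
#' the mean of the null distribution; its 95% CI is a bias-corrected
#' percentile bootstrap over participants.
#'
#' @param effects Numeric vector of per-participant effects (n >= 2).
#' @param tails `"two"` (default) or `"one"` (positive direction).
#' @param exhaustive Force exhaustive enumeration or Monte-Carlo;
#'   `NULL` picks exhaustive whenever `2^n <= 2^20`.
#' @param n_perm Monte-Carlo permutation count (ignored when exhaustive).
#' @param seed Seed for Monte-Carlo permutation and the bootstrap.
#' @param ci Compute the bootstrap CI (disable in tight loops).
#' @param n_boot Bootstrap resamples.
#' @param conf_level CI coverage.
#' @return An object of class `avbci_perm` with `observed`, `p_value`,
#'   `effect_size`, `ci_low`, `ci_high`, `n_permutations`, `tails`.
#' @export
#' @examples
#' sign_permutation_test(c(0.2, 0.5, 0.1, 0.4), tails = "one")
sign_permutation_test <- function(effects, tails = c("two", "one"),
                                  exhaustive = NULL, n_perm = 10000,
                                  seed = 1, ci = TRUE, n_boot = 10000,
                                  conf_level = 0.95) {
  tails <- match.arg(tails)
  n <- length(effects)
  if (n < 2) abort("need at least 2 participants.")
  exhaustive <- exhaustive %||% (n <= 20)
  if (exhaustive && n > 20) abort("exhaustive enumeration limited to n <= 20.")
  obs <- mean(effects)

  null_means <- if (exhaustive) {
    # enumerate sign assignments in chunks to bound memory at large n
    total <- 2^n
    chunk <- min(total, 2^14)
    unlist(lapply(seq(0, total - 1, by = chunk), function(from) {
      idx <- from + seq_len(min(chunk, total - from)) - 1
      signs <- 1 - 2 * ((outer(idx, 0:(n - 1), function(i, b) {
        i %/% 2^b
      })) %% 2)
      as.vector(signs %*% effects) / n
    }))
  } else {
    with_seed(derive_seed(seed, "perm"), {
      signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
      signs[1, ] <- 1 # observed assignment included
      as.vector(signs %*% effects) / n
    })
  }

  p <- if (tails == "two") {
    mean(abs(null_means) >= abs(obs) - 1e-12)
  } else {
    mean(null_means >= obs - 1e-12)
  }
  if (all(effects == 0)) {
    warn("all effects are zero; p = 1.")
    p <- 1
  }
  es <- obs - mean(null_means)

  ci_low <- ci_high <- NA_real_
  if (ci) {
    boot <- with_seed(derive_seed(seed, "boot"), {
      idx <- matrix(sample.int(n, n_boot * n, replace = TRUE), n_boot, n)
      rowMeans(matrix(effects[idx], n_boot, n))
    })
    # bias-corrected percentile interval
    z0 <- qnorm(pmin(pmax(mean(boot < obs), 1 / n_boot), 1 - 1 / n_boot))
    a <- (1 - conf_level) / 2
    probs <- pnorm(2 * z0 + qnorm(c(a, 1 - a)))
    q <- quantile(boot, probs, names = FALSE, type = 7)
    ci_low <- q[1] - mean(null_means)
    ci_high <- q[2] - mean(null_means)
  }

  structure(
    list(
      observed = obs, p_value = p, tails = tails,
      n_permutations = length(null_means), exhaustive = exhaustive,
      effect_size = es, ci_low = ci_low, ci_high = ci_high, n = n
    ),
    class = "avbci_perm"
  )
}

#' @export
print.avbci_perm <- function(x, ...) {
  cat("<avbci sign-permutation test> n =", x$n, ",",
      x$n_permutations, if (x$exhaustive) "(exhaustive)" else "(Monte-Carlo)",
      "assignments\n")
  cat("  ", x$tails, "-tailed p = ", signif(x$p_value, 4),
      ", effect size = ", round(x$effect_size, 4), sep = "")
  if (!is.na(x$ci_low)) {
    cat(" [", round(x$ci_low, 4), ", ", round(x$ci_high, 4), "]", sep = "")
  }
  cat("\n")
  invisible(x)
}

# canonical +/- coding of the 2 x 2 x 2 weight-table factors; V and high
# disparity carry the positive sign
factor_codes <- function(w) {
  list(
    attention = ifelse(w$attention == "V", 1, -1),
    report = ifelse(w$report == "V", 1, -1),
    disparity = ifelse(w$disparity == max(w$disparity), 1,
                       ifelse(w$disparity == min(w$disparity), -1, 0))
  )
}

#' Per-participant factorial contrasts on a weight table
#'
#' Computes, for each participant, a weighted sum over the 2 (attention) x
#' 2 (report) x 2 (disparity) cells.  Named effects use +/- coding with V
#' and high disparity positive, scaled by 1/4 so that a main effect is the
#' plain mean difference (e.g. report effect = mean over attention x
#' disparity of repV - repA).  A custom contrast can be given as a data
#' frame of cells and weights (summing to 0).
#'
#' @param weights An `avbci_weights` table (complete 2 x 2 x 2 per
#'   participant).
#' @param effect One of `"attention"`, `"report"`, `"disparity"`,
#'   `"attention:report"`, `"attention:disparity"`, `"report:disparity"`,
#'   `"attention:report:disparity"`, or a data frame with columns
#'   `attention`, `report`, `disparity`, `weight`.
#' @return A tibble with `participant` and `effect` columns (one row per
#'   participant), ready for [sign_permutation_test()].
#' @export
factorial_contrasts <- function(weights, effect = "report") {
  cells_per <- weights |> count(.data$participant)
  if (any(cells_per$n != 8)) abort("weight table incomplete: need 2 x 2 x 2 cells per participant.")

  if (is.data.frame(effect)) {
    if (abs(sum(effect$weight)) > 1e-9) abort("contrast weights must sum to 0.")
    w <- weights |>
      left_join(effect, by = c("attention", "report", "disparity"))
    if (anyNA(w$weight)) abort("contrast does not cover all cells.")
  } else {
    codes <- factor_codes(weights)
    parts <- strsplit(effect, ":", fixed = TRUE)[[1]]
    if (!all(parts %in% names(codes))) {
      abort(paste0("unknown effect: ", effect))
    }
    w <- weights
    w$weight <- Reduce(`*`, codes[parts]) / 4
  }
  w |>
    group_by(.data$participant) |>
    summarise(effect = sum(.data$w * .data$weight), .groups = "drop")
}

#' Permutation tests for all factorial effects of a weight table
#'
#' Runs [factorial_contrasts()] plus [sign_permutation_test()] for the
#' three main effects and all interactions.
#'
#' @param weights An `avbci_weights` table.
#' @param tails,seed Passed to [sign_permutation_test()].
#' @return A tibble with one row per effect: p-value, effect size, CI.
#' @export
weight_effects_table <- function(weights, tails = "two", seed = 1) {
  effects <- c("attention", "report", "disparity", "attention:report",
               "attention:disparity", "report:disparity",
               "attention:report:disparity")
  purrr::map_dfr(effects, function(e) {
    v <- factorial_contrasts(weights, e)$effect
    t <- sign_permutation_test(v, tails = tails, seed = seed)
    tibble(effect = e, observed = t$observed, p_value = t$p_value,
           effect_size = t$effect_size, ci_low = t$ci_low,
           ci_high = t$ci_high, n_permutations = t$n_permutations)
  })
}
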