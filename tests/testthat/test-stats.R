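# Sign-permutation inference and factorial contrasts.

test_that("n = 12 enumerates exactly 4,096 sign assignments", {
  t <- sign_permutation_test(rnorm(12), ci = FALSE)
  expect_equal(t$n_permutations, 4096)
  expect_true(t$exhaustive)
})

test_that("the exhaustive p-value matches brute-force enumeration", {
  x <- c(1, 2, 3, 4)
  # independent oracle: all 16 assignments via expand.grid
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 4)))
  null <- signs %*% x / 4
  p_one <- mean(null >= mean(x))
  p_two <- mean(abs(null) >= abs(mean(x)))
  expect_equal(sign_permutation_test(x, tails = "one", ci = FALSE)$p_value,
               p_one)
  expect_equal(sign_permutation_test(x, tails = "two", ci = FALSE)$p_value,
               p_two)
  expect_equal(sign_permutation_test(x, ci = FALSE)$n_permutations, 16)
})

test_that("degenerate and directional cases behave as specified", {
  expect_warning(t0 <- sign_permutation_test(rep(0, 6), ci = FALSE), "zero")
  expect_equal(t0$p_value, 1)
  expect_equal(t0$effect_size, 0)
  # one-tailed p is at most the two-tailed p for correctly signed effects
  x <- c(0.5, 0.2, 0.9, 0.4, 0.3)
  p1 <- sign_permutation_test(x, tails = "one", ci = FALSE)$p_value
  p2 <- sign_permutation_test(x, tails = "two", ci = FALSE)$p_value
  expect_lte(p1, p2)
  # permuting participant order changes nothing
  t_a <- sign_permutation_test(x, ci = FALSE)
  t_b <- sign_permutation_test(rev(x), ci = FALSE)
  expect_equal(t_a$p_value, t_b$p_value)
  expect_equal(t_a$effect_size, t_b$effect_size)
})

test_that("Monte-Carlo mode is seeded and includes the observed assignment", {
  x <- rnorm(25, 0.1)
  t1 <- sign_permutation_test(x, exhaustive = FALSE, n_perm = 2000, seed = 4,
                              ci = FALSE)
  t2 <- sign_permutation_test(x, exhaustive = FALSE, n_perm = 2000, seed = 4,
                              ci = FALSE)
  expect_identical(t1$p_value, t2$p_value)
  expect_gte(t1$p_value, 1 / 2000)
})

test_that("null p-values are uniform up to permutation discreteness", {
  set.seed(91)
  ps <- replicate(400, sign_permutation_test(rnorm(12), ci = FALSE)$p_value)
  ks <- max(abs(sort(ps) - seq_along(ps) / length(ps)))
  expect_lt(ks, 0.08) # 400 draws; the acceptance suite runs 2,000
})

test_that("effect-size CI brackets the observed mean for clear effects", {
  set.seed(13)
  x <- rnorm(12, 0.5, 0.2)
  t <- sign_permutation_test(x, seed = 3)
  expect_true(t$ci_low < mean(x) && mean(x) < t$ci_high)
  expect_lt(t$p_value, 0.05)
})

make_weight_table <- function(fn, n = 5) {
  tidyr::expand_grid(participant = seq_len(n), attention = c("A", "V"),
                     report = c("A", "V"), disparity = c(9, 18)) |>
    dplyr::mutate(w = fn(attention, report, disparity))
}

test_that("factorial contrasts recover planted cell structure", {
  w0 <- make_weight_table(function(a, r, d) 0.5)
  for (e in c("attention", "report", "report:disparity")) {
    expect_equal(factorial_contrasts(w0, e)$effect, rep(0, 5))
  }
  w1 <- make_weight_table(function(a, r, d) ifelse(r == "V", 0.8, 0.6))
  expect_equal(factorial_contrasts(w1, "report")$effect, rep(0.2, 5))
  expect_equal(factorial_contrasts(w1, "attention")$effect, rep(0, 5))
  # custom contrast: must cover cells and sum to zero
  cust <- tidyr::expand_grid(attention = c("A", "V"), report = c("A", "V"),
                             disparity = c(9, 18)) |>
    dplyr::mutate(weight = ifelse(report == "V", 1 / 4, -1 / 4))
  expect_equal(factorial_contrasts(w1, cust)$effect, rep(0.2, 5))
  expect_error(factorial_contrasts(w1, dplyr::mutate(cust, weight = 1)),
               "sum to 0")
  expect_error(factorial_contrasts(w1[-1, ], "report"), "incomplete")
  expect_error(factorial_contrasts(w1, "colour"), "unknown effect")
})

test_that("interaction contrasts detect a planted report-by-disparity pattern", {
  set.seed(17)
  w <- make_weight_table(function(a, r, d) {
    0.5 + 0.03 * (a == "V") +
      ifelse(r == "V", 1, -1) * ifelse(d == 18, 0.2, 0.1) +
      rnorm(length(a), 0, 0.01)
  }, n = 8)
  expect_true(all(factorial_contrasts(w, "report:disparity")$effect > 0))
  expect_lt(abs(mean(factorial_contrasts(w, "attention:disparity")$effect)),
            0.02)
  tbl <- weight_effects_table(w, seed = 5)
  expect_equal(nrow(tbl), 7)
  expect_lt(tbl$p_value[tbl$effect == "report"], 0.05)
  expect_lt(tbl$p_value[tbl$effect == "report:disparity"], 0.05)
})
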