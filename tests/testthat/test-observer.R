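# The observer model: causal-structure posterior, component estimates,
# model-averaged readout, and predicted button distributions.

test_that("common-cause posterior respects prior dominance and symmetry", {
  x <- c(-12, -3, 0, 4, 9)
  y <- c(5, 0, -2, 8, -9)
  expect_equal(posterior_common(x, y, bci_params(p_common = 1)), rep(1, 5))
  expect_equal(posterior_common(x, y, bci_params(p_common = 0)), rep(0, 5))
  # equal sigmas and a central prior make the posterior exchangeable
  p <- bci_params(sigma_a = 3, sigma_v = 3)
  expect_equal(posterior_common(x, y, p), posterior_common(y, x, p))
})

test_that("common-cause posterior matches brute-force integration over sources", {
  # independent oracle: integrate the generative model over the source
  # locations numerically instead of using the closed-form convolutions
  sa <- 4; sv <- 2; sp <- 10; pc <- 0.5; xa <- 5; xv <- -5
  l1 <- stats::integrate(function(s) {
    dnorm(xa, s, sa) * dnorm(xv, s, sv) * dnorm(s, 0, sp)
  }, -Inf, Inf, rel.tol = 1e-12)$value
  l2 <- stats::integrate(function(s) dnorm(xa, s, sa) * dnorm(s, 0, sp),
                         -Inf, Inf, rel.tol = 1e-12)$value *
    stats::integrate(function(s) dnorm(xv, s, sv) * dnorm(s, 0, sp),
                     -Inf, Inf, rel.tol = 1e-12)$value
  oracle <- l1 * pc / (l1 * pc + l2 * (1 - pc))
  got <- posterior_common(xa, xv, bci_params(pc, sa, sv, sp))
  expect_equal(got, oracle, tolerance = 1e-6)
})

test_that("component estimates are reliability-weighted combinations", {
  p_flat <- bci_params(sigma_a = 2, sigma_v = 2, sigma_p = 1e9)
  est <- component_estimates(6, -2, p_flat)
  expect_equal(est$s_fused, (6 - 2) / 2, tolerance = 1e-12)
  expect_equal(est$s_seg_a, 6, tolerance = 1e-6)
  # x_A = 9, x_V = 0, sigma_A = 3, sigma_V = 1, flat prior -> 0.9
  est2 <- component_estimates(9, 0, bci_params(sigma_a = 3, sigma_v = 1,
                                               sigma_p = 1e9))
  expect_equal(est2$s_fused, 0.9, tolerance = 1e-6)
})

test_that("shrinking visual noise strictly increases the visual weight", {
  grad <- function(sv) {
    p <- bci_params(sigma_a = 4, sigma_v = sv, sigma_p = 12)
    e1 <- component_estimates(0, 1e-4, p)$s_fused
    e0 <- component_estimates(0, 0, p)$s_fused
    (e1 - e0) / 1e-4
  }
  svs <- c(4, 2, 1, 0.5)
  expect_true(all(diff(sapply(svs, grad)) > 0))
  # and the gradient equals the closed-form relative reliability
  p <- bci_params(sigma_a = 4, sigma_v = 2, sigma_p = 12)
  expect_equal(grad(2), (1 / 4) / (1 / 16 + 1 / 4 + 1 / 144),
               tolerance = 1e-6)
})

test_that("model averaging interpolates between fusion and segregation", {
  p1 <- bci_params(p_common = 1)
  e1 <- final_estimates(5, -5, p1)
  expect_equal(e1$s_final_a, e1$s_fused)
  expect_equal(e1$s_final_v, e1$s_fused)
  p0 <- bci_params(p_common = 0)
  e0 <- final_estimates(5, -5, p0)
  expect_equal(e0$s_final_a, e0$s_seg_a)
  expect_equal(e0$s_final_v, e0$s_seg_v)
  # convexity: the final estimate lies between segregation and fusion
  set.seed(4)
  xa <- rnorm(500, 0, 10); xv <- rnorm(500, 0, 10)
  e <- final_estimates(xa, xv, bci_params(p_common = 0.6))
  expect_true(all(e$s_final_a >= pmin(e$s_fused, e$s_seg_a) - 1e-12))
  expect_true(all(e$s_final_a <= pmax(e$s_fused, e$s_seg_a) + 1e-12))
  expect_true(all(e$p_c1 >= 0 & e$p_c1 <= 1))
})

test_that("BCI with P_common = 1 reproduces forced fusion exactly", {
  set.seed(11)
  xa <- rnorm(1e4, 0, 12)
  xv <- rnorm(1e4, 0, 12)
  bci <- final_estimates(xa, xv, bci_params(p_common = 1))
  ff <- final_estimates(xa, xv, ff_params())
  expect_equal(max(abs(bci$s_final_a - ff$s_final_a)), 0, tolerance = 1e-12)
  expect_equal(max(abs(bci$s_final_v - ff$s_final_v)), 0, tolerance = 1e-12)
})

test_that("expected causal posterior weakly decreases with disparity", {
  p <- bci_att_params()
  mean_pc1 <- sapply(c(0, 9, 18), function(disp) {
    u <- (seq_len(201) - 0.5) / 201
    g <- tidyr::expand_grid(xa = -disp / 2 + 4.5 * qnorm(u),
                            xv = disp / 2 + 1.5 * qnorm(u))
    mean(posterior_common(g$xa, g$xv, p, attention = "A"))
  })
  expect_true(all(diff(mean_pc1) < 0))
})

test_that("predicted response distributions are proper and certain when noise-free", {
  cond <- list(aloc = 9, vloc = 9, attention = "A", report = "A")
  p0 <- bci_params(sigma_a = 1e-6, sigma_v = 1e-6, sigma_p = 12)
  for (m in c("simulation", "quadrature")) {
    pr <- predict_response_probs(p0, cond, method = m, n_sim = 2000,
                                 grid_n = 51)
    expect_equal(pr$prob[pr$button == 9], 1)
  }
  # normalisation across all 36 cells, both methods
  cells <- avbci:::design_cells(tiny_spec())
  p <- bci_att_params()
  for (i in seq_len(nrow(cells))) {
    s <- predict_response_probs(p, cells[i, ], n_sim = 500, seed = i)
    q <- predict_response_probs(p, cells[i, ], method = "quadrature",
                                grid_n = 41)
    expect_equal(sum(s$prob), 1, tolerance = 1e-12)
    expect_equal(sum(q$prob), 1, tolerance = 1e-12)
    expect_true(all(s$prob >= 0) && all(q$prob >= 0))
  }
})

test_that("simulation and quadrature routes agree within Monte-Carlo error", {
  p <- bci_att_params()
  cond <- list(aloc = -9, vloc = 9, attention = "V", report = "A")
  sim <- predict_response_probs(p, cond, n_sim = 10000, seed = 2)
  quad <- predict_response_probs(p, cond, method = "quadrature", grid_n = 501)
  tol <- 3 * sqrt(quad$prob * (1 - quad$prob) / 10000) + 2 / 10000
  expect_true(all(abs(sim$prob - quad$prob) <= tol))
})

test_that("parameter constructors validate the variant structure", {
  expect_error(observer_params("BCI-att_fixed", sigma_a = -1, sigma_v = 1,
                               sigma_p = 10, p_common = 0.5), "positive")
  expect_error(observer_params("BCI-att_fixed", sigma_a = 1, sigma_v = 1,
                               sigma_p = 10), "p_common")
  expect_error(observer_params("nope", 1, 1, 1), "unknown")
  expect_error(
    observer_params("BCI-att_free", sigma_a = c(a = 1, b = 2),
                    sigma_v = 1, sigma_p = 10, p_common = 0.5),
    "named"
  )
  # free-parameter counts across the model space: 3, 5, 5, 9, 4, 6
  expect_equal(model_variants()$k, c(3L, 5L, 5L, 9L, 4L, 6L))
})
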