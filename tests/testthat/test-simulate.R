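# Synthetic data: observer responses and voxel patterns.

test_that("noise-free segregating observer reports the true location", {
  p <- bci_params(p_common = 0, sigma_a = 1e-6, sigma_v = 1e-6, sigma_p = 12)
  d <- make_design(tiny_spec(trials = 2))
  tr <- simulate_observer(d, p, seed = 3)
  truth <- ifelse(tr$report == "A", tr$aloc, tr$vloc)
  expect_equal(tr$response, truth)
})

test_that("symmetric fusion of opposite locations lands on the centre button", {
  p <- observer_params("FF-att_fixed-rep_fixed", sigma_a = 2, sigma_v = 2,
                       sigma_p = 1e9)
  tr <- simulate_observer(one_condition_trials(500, aloc = -9, vloc = 9), p,
                          seed = 5, locations = c(-9, 0, 9))
  expect_true(mean(tr$response == 0) > 0.95)
})

test_that("empirical response proportions converge to the analytic oracle", {
  p <- bci_att_params()
  cond <- list(aloc = -9, vloc = 9, attention = "A", report = "A")
  n <- 1e5
  tr <- simulate_observer(
    one_condition_trials(n, cond$aloc, cond$vloc, cond$attention,
                         cond$report),
    p, seed = 9, locations = c(-9, 0, 9)
  )
  emp <- as.numeric(table(factor(tr$response, c(-9, 0, 9)))) / n
  quad <- predict_response_probs(p, cond, method = "quadrature",
                                 grid_n = 501)$prob
  tol <- 3 * sqrt(quad * (1 - quad) / n) + 2 / n
  expect_true(all(abs(emp - quad) <= tol))
})

test_that("attention enters only through sigma: valid and invalid precues match", {
  # with attention-fixed sigmas the simulator has no switching cost, so
  # (attA, repA) and (attV, repA) responses are identical in distribution
  p <- bci_params()
  quad <- function(att) {
    predict_response_probs(p, list(aloc = -9, vloc = 0, attention = att,
                                   report = "A"),
                           method = "quadrature", grid_n = 301)$prob
  }
  expect_identical(quad("A"), quad("V"))
  n <- 2e4
  valid <- simulate_observer(one_condition_trials(n, -9, 0, "A", "A"), p,
                             seed = 12, locations = c(-9, 0, 9))
  invalid <- simulate_observer(one_condition_trials(n, -9, 0, "V", "A"), p,
                               seed = 13, locations = c(-9, 0, 9))
  pv <- as.numeric(table(factor(valid$response, c(-9, 0, 9)))) / n
  pi_ <- as.numeric(table(factor(invalid$response, c(-9, 0, 9)))) / n
  # two independent estimates: the difference has twice the variance
  expect_true(all(abs(pv - pi_) <= 3 * sqrt(2 * pv * (1 - pv) / n) + 6 / n))
})

test_that("simulation is deterministic and stable under added participants", {
  p <- bci_att_params()
  d2 <- make_design(tiny_spec(trials = 2), n_participants = 2)
  d3 <- make_design(tiny_spec(trials = 2), n_participants = 3)
  t2 <- simulate_observer(d2, p, seed = 21)
  t3 <- simulate_observer(d3, p, seed = 21)
  expect_identical(t2, dplyr::filter(t3, participant <= 2))
  expect_identical(t2, simulate_observer(d2, p, seed = 21))
})

test_that("observer simulation rejects invalid inputs", {
  expect_error(
    observer_params("BCI-att_fixed", sigma_a = 0, sigma_v = 1, sigma_p = 5,
                    p_common = 0.5),
    "positive"
  )
  p <- bci_params()
  expect_error(simulate_observer(one_condition_trials(0, 0, 0), p), "empty")
  expect_error(simulate_observer(one_condition_trials(5, 0, 0), p,
                                 lapse_rate = 2), "lapse")
})

test_that("voxel patterns are exactly linear in the effective location", {
  spec <- tiny_spec(runs = 2)
  pat <- simulate_voxel_patterns(0.3, noise_sd = 0, n_voxels = 5,
                                 spec = spec, seed = 2)
  # amplitude = slope * s_star + baseline: regress and check residuals
  for (v in 1:5) {
    res <- residuals(lm(pat$x[, v] ~ pat$meta$s_star))
    expect_lt(max(abs(res)), 1e-9)
  }
})

test_that("pure visual coding duplicates congruent patterns at matching vloc", {
  pat <- simulate_voxel_patterns(1, noise_sd = 0, n_voxels = 8,
                                 spec = tiny_spec(runs = 1), seed = 4)
  m <- pat$meta
  incong <- which(m$aloc == -9 & m$vloc == 9 & m$attention == "A" &
                    m$report == "A")[1]
  cong <- which(m$aloc == 9 & m$vloc == 9 & m$attention == "A" &
                  m$report == "A")[1]
  expect_equal(pat$x[incong, ], pat$x[cong, ])

  # weight 0.5 with opposite locations reproduces the central pattern
  pat5 <- simulate_voxel_patterns(0.5, noise_sd = 0, n_voxels = 8,
                                  spec = tiny_spec(runs = 1), seed = 4)
  m5 <- pat5$meta
  i <- which(m5$aloc == -9 & m5$vloc == 9)[1]
  j <- which(m5$aloc == 0 & m5$vloc == 0)[1]
  expect_equal(pat5$x[i, ], pat5$x[j, ])
})

test_that("voxel-pattern generator validates its arguments", {
  expect_error(simulate_voxel_patterns(0.5, noise_sd = -1), "non-negative")
  expect_error(simulate_voxel_patterns(2, noise_sd = 1), "\\[0, 1\\]")
  expect_error(simulate_voxel_patterns(0.5, 1, n_voxels = 1), "at least 2")
  expect_error(
    simulate_voxel_patterns(0.5, 1, n_voxels = 3,
                            tuning_slopes = c(0, 0, 0)),
    "all zero"
  )
})

test_that("voxel-pattern sets round-trip through CSV", {
  pat <- simulate_voxel_patterns(0.4, 0.3, n_voxels = 4,
                                 spec = tiny_spec(runs = 2), seed = 6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_patterns(pat, path)
  back <- read_patterns(path)
  expect_equal(back$meta, pat$meta)
  expect_equal(unname(back$x), unname(pat$x))
  expect_equal(back$ground_truth_weight, 0.4)
  expect_equal(back$locations, pat$locations)
})
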