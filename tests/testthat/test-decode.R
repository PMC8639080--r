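# Cross-validated SVR decoding and decoding accuracy.

test_that("pattern scaling maps each pattern onto [0, 1]", {
  pat <- simulate_voxel_patterns(0.5, 1, n_voxels = 3,
                                 spec = tiny_spec(runs = 2), seed = 1)
  pat$x[1, ] <- c(2, 4, 6)
  sc <- scale_patterns(pat)
  expect_equal(sc$x[1, ], c(0, 0.5, 1))
  expect_true(all(sc$x >= 0 & sc$x <= 1))
  # idempotent on an already-normalised pattern
  expect_equal(scale_patterns(sc)$x[1, ], sc$x[1, ])
  pat$x[2, ] <- 5
  expect_error(scale_patterns(pat), "constant")
})

test_that("noise-free visual patterns decode congruent locations perfectly", {
  pat <- simulate_voxel_patterns(1, noise_sd = 0, n_voxels = 30,
                                 spec = tiny_spec(runs = 4), seed = 3)
  # affine (per-voxel) scaling keeps the code linear: r = 1
  dec <- cross_validated_decode(pat, scaling = "voxel")
  cong <- dplyr::filter(dec, aloc == vloc)
  expect_gt(cor(cong$aloc, cong$decoded), 1 - 1e-9)
  # per-pattern normalisation bends the code slightly but keeps ordering
  decp <- cross_validated_decode(pat, scaling = "pattern")
  congp <- dplyr::filter(decp, aloc == vloc)
  expect_gt(cor(congp$aloc, congp$decoded), 0.98)
  grp <- tapply(congp$decoded, congp$aloc, mean)
  expect_true(all(diff(grp[order(as.numeric(names(grp)))]) > 0))
})

test_that("the midpoint pattern decodes to the centre", {
  pat <- simulate_voxel_patterns(0.5, noise_sd = 0, n_voxels = 30,
                                 spec = tiny_spec(runs = 3), seed = 4)
  dec <- cross_validated_decode(pat, scaling = "voxel")
  mid <- dplyr::filter(dec, aloc == -9, vloc == 9)
  ctr <- dplyr::filter(dec, aloc == 0, vloc == 0)
  expect_equal(mean(mid$decoded), mean(ctr$decoded), tolerance = 1e-6)
})

test_that("every condition is decoded exactly once per fold", {
  pat <- simulate_voxel_patterns(0.7, 1, n_voxels = 20,
                                 spec = tiny_spec(runs = 5), seed = 5)
  dec <- cross_validated_decode(pat)
  expect_equal(nrow(dec), nrow(pat$meta))
  expect_true(all(dec$fold == dec$run))
  expect_equal(dplyr::count(dec, run)$n, rep(36, 5))
})

test_that("the trained model never sees the held-out run", {
  pat <- simulate_voxel_patterns(0.6, 0.5, n_voxels = 15,
                                 spec = tiny_spec(runs = 3), seed = 6)
  dec1 <- cross_validated_decode(pat)
  # corrupt the test run's patterns for fold 1 only: other folds' outputs,
  # which trained on that run, change; fold 1 predictions change only
  # through its inputs, not its model
  pat2 <- pat
  swap <- which(pat$meta$run == 1)
  pat2$x[swap, ] <- pat$x[rev(swap), ]
  dec2 <- cross_validated_decode(pat2)
  f1 <- dec1$decoded[dec1$fold == 1]
  f2 <- dec2$decoded[dec2$fold == 1]
  expect_equal(sort(f1), sort(f2), tolerance = 1e-9)
})

test_that("decoding degrades monotonically with pattern noise", {
  rs <- sapply(c(0.1, 3, 30), function(ns) {
    mean(sapply(1:5, function(rep) {
      pat <- simulate_voxel_patterns(1, noise_sd = ns, n_voxels = 40,
                                     spec = tiny_spec(runs = 3),
                                     seed = 100 * rep + ns)
      dec <- cross_validated_decode(pat)
      cong <- dplyr::filter(dec, aloc == vloc)
      cor(cong$aloc, cong$decoded)
    }))
  })
  expect_true(all(diff(rs) < 0))
})

test_that("group decoding accuracy tests Fisher-z correlations against zero", {
  dec <- purrr::map_dfr(1:6, function(p) {
    pat <- simulate_voxel_patterns(1, noise_sd = 2, n_voxels = 30,
                                   spec = tiny_spec(runs = 3), seed = p)
    cross_validated_decode(pat) |> dplyr::mutate(participant = p)
  })
  acc <- decoding_accuracy(dec, seed = 2)
  expect_lt(acc$test$p_value, 0.05)
  expect_gt(acc$mean_r, 0.5)
  expect_true(acc$ci_r[1] <= acc$mean_r)
  # perfect decoding is capped, not infinite
  dperf <- dplyr::tibble(participant = rep(1:3, each = 3),
                         aloc = rep(c(-9, 0, 9), 3),
                         vloc = rep(c(-9, 0, 9), 3),
                         decoded = rep(c(-9, 0, 9), 3))
  accp <- decoding_accuracy(dperf, seed = 3)
  expect_true(is.finite(accp$test$observed))
  expect_equal(accp$mean_r, 1, tolerance = 1e-9)
})

test_that("fewer than two runs is an error", {
  pat <- simulate_voxel_patterns(0.5, 1, n_voxels = 5,
                                 spec = tiny_spec(runs = 1), seed = 9)
  expect_error(cross_validated_decode(pat), "2 runs")
})
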