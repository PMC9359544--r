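test_that("taper mask equals the direct Gaussian formula everywhere", {
  sk <- skeleton_model(cbind(1:7, 2:8))
  cfg <- taper_config(sigma = 2, temporal_scale = 5, spatial_scale = 1)
  gap <- gap_spec(3, 11, 20)
  q <- taper_mask(gap, 40, sk, cfg)
  expect_equal(dim(q), c(40, 8))

  for (i in c(1, 10, 11, 15, 20, 21, 40)) {
    for (j in 1:8) {
      dt <- if (i >= 11 && i <= 20) 0 else min(abs(i - 11), abs(i - 20)) / 5
      ds <- abs(j - 3) / 1                       # chain: hops = index gap
      expect_equal(q[i, j], exp(-(dt^2 + ds^2) / 4), tolerance = 1e-12)
    }
  }

  # inside the gap at the gap marker the mask is exactly one
  expect_equal(q[11:20, 3], rep(1, 10))
  # a cell whose combined scaled distance is exactly sigma gives exp(-1)
  expect_equal(q[11, 5], exp(-1), tolerance = 1e-12)   # ds = 2 = sigma
})

test_that("taper decays monotonically in time and along the skeleton", {
  sk <- skeleton_model(cbind(1:9, 2:10))
  q <- taper_mask(gap_spec(5, 41, 60), 100, sk, taper_config())
  # away from the interval in either temporal direction
  expect_true(all(diff(q[60:100, 5]) <= 0))
  expect_true(all(diff(q[41:1, 5]) <= 0))
  # away from the gap marker at any fixed frame
  expect_true(all(diff(q[50, 5:10]) <= 0))
  expect_true(all(diff(q[1, 5:1]) <= 0))
  expect_true(all(q > 0 & q <= 1))
})

test_that("expand_taper replicates marker weights over x,y,z columns", {
  q <- matrix(c(1, 0.5, 0.2, 0.1), 2, 2)
  e <- expand_taper(q)
  expect_equal(dim(e), c(2, 6))
  expect_equal(e[, 1:3], q[, c(1, 1, 1)])
  expect_equal(e[, 4:6], q[, c(2, 2, 2)])
})

test_that("the combined mask is normalised to a maximum of exactly one", {
  su <- lowrank_setup(n_markers = 8, window = 60, n_train = 2, noise_sd = 0.05)
  g1 <- fit_lwpca(su$train, list(gap_spec(2, 10, 50)), su$skeleton, k = 3)
  expect_equal(max(g1$qbar), 1)
  g3 <- fit_lwpca(su$train, list(gap_spec(2, 10, 50), gap_spec(5, 1, 30),
                                 gap_spec(7, 30, 60)), su$skeleton, k = 3)
  expect_equal(max(g3$qbar), 1)
  expect_true(all(g3$qbar > 0 & g3$qbar <= 1))
})

test_that("an infinite window reduces the tapered fit to the plain one", {
  su <- lowrank_setup(noise_sd = 0.1)
  gaps <- list(gap_spec(2, 11, 90), gap_spec(6, 31, 100))
  wf <- fit_wpca(su$train, gaps, k = 4)
  lf <- fit_lwpca(su$train, gaps, su$skeleton,
                  taper = taper_config(sigma = Inf), k = 4)
  for (g in 1:2) {
    expect_equal(lf$projectors[[g]], wf$projectors[[g]], tolerance = 1e-6)
  }
  expect_equal(lf$alpha, wf$alpha, tolerance = 1e-6)

  gapped <- apply_gaps(su$test, gaps)
  expect_equal(reconstruct(lf, gapped)$values, reconstruct(wf, gapped)$values,
               tolerance = 1e-6)
})

test_that("tapering never increases the stacked energy", {
  su <- lowrank_setup(n_markers = 8, window = 60, n_train = 2, noise_sd = 0.1)
  dm <- demean(su$train)
  stacked <- do.call(rbind, lapply(dm$samples, `[[`, "values"))
  q <- expand_taper(taper_mask(gap_spec(4, 20, 40), 60, su$skeleton,
                               taper_config()))
  masked <- do.call(rbind, lapply(dm$samples,
                                  function(s) s$values * q))
  ev_full <- pca_subspace(stacked, k = 5)$eigenvalues_all
  ev_masked <- pca_subspace(masked, k = 5)$eigenvalues_all
  expect_lte(sum(ev_masked), sum(ev_full))
  expect_true(all(colSums(masked^2) <= colSums(stacked^2) + 1e-12))
})

test_that("a narrow window makes the mask predominantly near zero", {
  # full-body geometry: 400 frames, 41 markers, one central 20-frame gap
  sk <- skeleton_model(cbind(1:40, 2:41))
  q <- taper_mask(gap_spec(21, 191, 210), 400, sk, taper_config(sigma = 1))
  expect_gt(mean(q < 0.01), 0.5)
})

test_that("tapering beats the global fit under a distant erratic marker", {
  errs <- sapply(1:20, function(s) {
    cfg <- synth_config(n_markers = 10, m_frames = 5 * 80, latent_rank = 4,
                        noise_sd = 0.05, seed = 300 + s,
                        burst = list(marker = 9, start = 1, end = 400,
                                     amplitude = 5, frequency = 0.2))
    gen <- generate_motion(cfg)
    wins <- make_training_windows(gen$sample, window = 80)
    gaps <- list(gap_spec(2, 1, 80))
    gapped <- apply_gaps(wins[[5]], gaps)
    c(wpca = mse(reconstruct(fit_wpca(wins[1:4], gaps, k = 4), gapped),
                 wins[[5]], gapped),
      lwpca = mse(reconstruct(fit_lwpca(wins[1:4], gaps, gen$skeleton,
                                        taper = taper_config(sigma = 3),
                                        k = 4), gapped),
                  wins[[5]], gapped))
  })
  expect_lte(mean(errs["lwpca", ]), mean(errs["wpca", ]))
  expect_lte(var(errs["lwpca", ]), var(errs["wpca", ]))
})
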