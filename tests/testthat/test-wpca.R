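test_that("build_gap_groups returns one aligned basis pair per gap", {
  su <- lowrank_setup(n_markers = 6, window = 60, n_train = 2, noise_sd = 0.05)
  gaps <- list(gap_spec(1, 10, 40), gap_spec(4, 20, 55), gap_spec(6, 5, 30))
  gg <- build_gap_groups(su$train, gaps, k = 4)
  expect_length(gg$groups, 3)
  for (grp in gg$groups) {
    expect_equal(dim(grp$mapping), c(4, 4))
    expect_equal(grp$basis$k, gg$U$k)
  }
})

test_that("a gap on a constant marker leaves subspace and mapping unchanged", {
  set.seed(9)
  v <- matrix(rnorm(50 * 12), 50, 12)
  v[, 4:6] <- rep(c(3, -1, 2), each = 50)        # marker 2 constant
  s <- motion_sample(v)
  gg <- build_gap_groups(list(s), list(gap_spec(2, 10, 40)), k = 3)
  expect_identical(gg$groups[[1]]$basis$basis, gg$U$basis)
  expect_equal(gg$groups[[1]]$mapping, diag(3), tolerance = 1e-8)
})

test_that("duplicated training samples give the same fit as one", {
  su <- lowrank_setup(n_markers = 6, window = 50, n_train = 1, noise_sd = 0.1)
  gaps <- list(gap_spec(3, 5, 45))
  one <- fit_wpca(su$train[1], gaps, k = 3)
  dup <- fit_wpca(rep(su$train[1], 3), gaps, k = 3)
  expect_equal(one$projectors, dup$projectors, tolerance = 1e-8)
  expect_equal(one$alpha, dup$alpha, tolerance = 1e-8)
})

test_that("residual eigenvalue flooring follows the threshold rule", {
  w <- mocapfill:::delta_weights(c(4, 0.01), threshold = 0.1,
                                 threshold_type = "absolute")
  expect_equal(w$weights, c(0.25, 10))

  wr <- mocapfill:::delta_weights(c(100, 0.05), threshold = 1e-3,
                                  threshold_type = "relative")
  expect_equal(wr$weights, c(1 / 100, 1 / 0.1))   # floor = 0.1

  expect_error(mocapfill:::delta_weights(c(1, 2), threshold = -1), "positive")
})

test_that("zero residual floors every eigenvalue to a uniform weight", {
  # an exactly zero residual spectrum floors everywhere: uniform weights
  w0 <- mocapfill:::delta_weights(rep(0, 5))
  expect_equal(max(w0$weights), min(w0$weights))
  expect_true(all(is.finite(w0$weights)))

  # noiseless low-rank data with a full-window gap: per-gap reconstruction
  # of the training set is exact, so the accumulated residual vanishes
  su <- lowrank_setup(noise_sd = 0)
  gg <- build_gap_groups(su$train, list(gap_spec(3, 1, 100)), k = 4)
  w <- residual_weight_matrix(gg)
  expect_lt(max(w$delta), 1e-18)
})

test_that("weights match an independent eigensolver on the residual", {
  su <- lowrank_setup(noise_sd = 0.2)
  gaps <- list(gap_spec(2, 10, 90), gap_spec(5, 30, 100))
  gg <- build_gap_groups(su$train, gaps, k = 4)
  w <- residual_weight_matrix(gg, delta_threshold = 1e-12)

  b <- 0
  for (grp in gg$groups) {
    proj <- grp$basis$basis %*% grp$mapping %*% t(gg$U$basis)
    for (i in seq_along(gg$centered)) {
      b <- b + (gg$centered[[i]] - grp$gapped[[i]] %*% proj)
    }
  }
  delta_oracle <- eigen(crossprod(b), symmetric = TRUE)$values
  expect_equal(w$delta, delta_oracle, tolerance = 1e-8 * max(delta_oracle))
  keep <- delta_oracle > 1e-12 * max(delta_oracle)
  expect_equal(w$weights[keep], 1 / delta_oracle[keep],
               tolerance = 1e-8)
})

test_that("solve_alpha returns 1 for an exactly reconstructable single gap", {
  su <- lowrank_setup(noise_sd = 0)
  gaps <- list(gap_spec(3, 1, 100))
  fit <- fit_wpca(su$train, gaps, k = 4)
  expect_equal(fit$alpha, 1, tolerance = 1e-6)
})

test_that("unit weights reduce solve_alpha to ordinary least squares", {
  set.seed(12)
  full <- lapply(1:2, function(i) matrix(rnorm(15 * 9), 15, 9))
  gapped <- lapply(full, function(a) { a[2:10, 1:3] <- 0; a })
  projectors <- lapply(1:2, function(g) matrix(rnorm(81), 9, 9) / 9)
  alpha <- solve_alpha(full, gapped, projectors, rep(1, 9))

  # independent OLS: vectorise the two regressors
  x <- cbind(as.vector(do.call(rbind, lapply(gapped, `%*%`, projectors[[1]]))),
             as.vector(do.call(rbind, lapply(gapped, `%*%`, projectors[[2]]))))
  y <- as.vector(do.call(rbind, full))
  expect_equal(alpha, unname(stats::lm.fit(x, y)$coefficients),
               tolerance = 1e-8)
})

test_that("alpha is invariant to global rescaling of the weights", {
  set.seed(13)
  full <- lapply(1:2, function(i) matrix(rnorm(15 * 9), 15, 9))
  gapped <- lapply(full, function(a) { a[2:10, 4:6] <- 0; a })
  projectors <- lapply(1:2, function(g) matrix(rnorm(81), 9, 9) / 9)
  w <- runif(9, 0.1, 4)
  expect_equal(solve_alpha(full, gapped, projectors, w),
               solve_alpha(full, gapped, projectors, 1000 * w),
               tolerance = 1e-8)
})

test_that("the normal-equation solution dominates naive coefficient guesses", {
  set.seed(14)
  for (rep in 1:5) {
    ng <- sample(2:3, 1)
    full <- lapply(1:2, function(i) matrix(rnorm(20 * 12), 20, 12))
    gapped <- lapply(full, function(a) { a[3:18, 1:6] <- 0; a })
    projectors <- lapply(seq_len(ng), function(g)
      matrix(rnorm(144), 12, 12) / 12)
    w <- runif(12, 0.2, 2)
    alpha <- solve_alpha(full, gapped, projectors, w)
    obj <- function(a) alpha_objective(a, full, gapped, projectors, w)
    expect_lte(obj(alpha), obj(rep(0, ng)) + 1e-8)
    expect_lte(obj(alpha), obj(rep(1 / ng, ng)) + 1e-8)
  }
})

test_that("fully masked projections raise a degenerate-system error", {
  full <- list(matrix(rnorm(12), 4, 3))
  gapped <- list(matrix(0, 4, 3))
  expect_error(solve_alpha(full, gapped, list(diag(3)), rep(1, 3)),
               "degenerate")
})

test_that("reconstruct only touches missing entries and fills the mask", {
  su <- lowrank_setup(noise_sd = 0.05)
  gaps <- list(gap_spec(4, 20, 80))
  fit <- fit_wpca(su$train, gaps, k = 4)

  # a test sample with nothing missing passes through unchanged
  expect_equal(reconstruct(fit, su$test)$values, su$test$values)

  gapped <- apply_gaps(su$test, gaps)
  filled <- reconstruct(fit, gapped)
  expect_true(all(filled$mask == 1))
  obs <- gapped$mask == 1
  expect_equal(filled$values[obs], gapped$values[obs])
  expect_false(identical(filled$values[!obs], gapped$values[!obs]))
})

test_that("noiseless in-span motion with a whole-window gap is recovered exactly", {
  su <- lowrank_setup(noise_sd = 0)
  gaps <- list(gap_spec(3, 1, 100))
  gapped <- apply_gaps(su$test, gaps)
  filled <- reconstruct(fit_wpca(su$train, gaps, k = 4), gapped)
  expect_lt(rel_gap_mse(filled, su, gapped), 1e-6)
})

test_that("recovery error shrinks on average as the training set grows", {
  ks <- 1:8
  res <- sapply(1:60, function(s) {
    gen <- generate_motion(synth_config(n_markers = 8, m_frames = 9 * 50,
                                        latent_rank = 4, noise_sd = 0.2,
                                        seed = 100 + s))
    wins <- make_training_windows(gen$sample, window = 50)
    test <- wins[[9]]
    gaps <- simulate_gaps(50, 8, "single", gap_length = 50, seed = 200 + s)
    gapped <- apply_gaps(test, gaps)
    sapply(ks, function(K) {
      fit <- fit_wpca(wins[seq_len(K)], gaps, k = 4)
      mse(reconstruct(fit, gapped), test, gapped)
    })
  })
  curve <- rowMeans(res)
  expect_true(all(diff(curve) <= 0))
})
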