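test_that("frame-space and coordinate-space spectra coincide", {
  set.seed(21)
  for (dims in list(c(12, 30), c(30, 12), c(20, 20))) {
    a <- matrix(rnorm(prod(dims)), dims[1], dims[2])
    ev_frames <- eigen(tcrossprod(a), symmetric = TRUE)$values
    ev_coords <- eigen(crossprod(a), symmetric = TRUE)$values
    r <- min(dims)
    expect_equal(ev_frames[1:r], ev_coords[1:r],
                 tolerance = 1e-6 * ev_frames[1])
  }
})

test_that("fit_frame_recovery enforces its contracts", {
  su <- lowrank_setup(n_markers = 6, window = 40, n_train = 2, noise_sd = 0.05)
  expect_error(fit_frame_recovery(su$train, list()), "at least one")
  expect_error(fit_frame_recovery(su$train, frame_gap_spec(1, 40)),
               "nothing to condition on")
  expect_error(fit_frame_recovery(su$train, list(gap_spec(1, 5, 7))),
               "frame_gap_spec")

  model <- fit_frame_recovery(su$train, frame_gap_spec(10, 13), k = 4)
  expect_length(model$weights$weights, 4)         # one weight per missing frame
  expect_length(model$alpha, 4)
  for (h in model$h) expect_equal(h, t(h), tolerance = 1e-8)

  # recovering a sample with a different gap pattern is refused
  wrong <- apply_gaps(su$test, frame_gap_spec(20, 23))
  expect_error(recover_frames(model, wrong), "mismatch")
})

test_that("representable noiseless frames are recovered exactly", {
  # windows of shared global sinusoids span a 2 * latent_rank frame space;
  # with k at that rank and no tapering the regression is exact
  su <- lowrank_setup(noise_sd = 0)
  for (fg in list(frame_gap_spec(40, 40), frame_gap_spec(40, 42))) {
    gapped <- apply_gaps(su$test, fg)
    model <- fit_frame_recovery(su$train, fg,
                                taper = taper_config(sigma = Inf), k = 8)
    expect_lt(rel_gap_mse(recover_frames(model, gapped), su, gapped), 1e-6)
  }
})

test_that("frame coefficients match a derivative-free minimiser", {
  su <- lowrank_setup(n_markers = 6, window = 50, n_train = 2, noise_sd = 0.1)
  fg <- frame_gap_spec(17, 18)
  model <- fit_frame_recovery(su$train, fg, k = 5)

  centered <- demean(su$train)$samples
  a <- do.call(cbind, lapply(centered, `[[`, "values"))
  obs <- setdiff(seq_len(50), model$frames)
  a1 <- a[obs, , drop = FALSE]
  a2 <- a[model$frames, , drop = FALSE]
  fmats <- lapply(model$operators, function(o) o %*% a1)
  w <- model$weights$weights
  obj <- function(al) {
    r <- a2 - Reduce(`+`, Map(`*`, al, fmats))
    sum((w * r) * r)
  }
  fitted <- stats::optim(c(0, 0), obj, method = "Nelder-Mead",
                         control = list(reltol = 1e-14, maxit = 5000))
  expect_equal(model$alpha, fitted$par, tolerance = 1e-5)
  expect_lte(obj(model$alpha), fitted$value + 1e-10)
})

test_that("constant motion is restored verbatim", {
  frame <- rnorm(12)
  const <- motion_sample(matrix(frame, 30, 12, byrow = TRUE))
  model <- fit_frame_recovery(list(const, const), frame_gap_spec(10, 12))
  gapped <- apply_gaps(const, frame_gap_spec(10, 12))
  out <- recover_frames(model, gapped)
  expect_equal(out$values, const$values, tolerance = 1e-8)
})

test_that("recovery improves with the retained frame dimension", {
  res <- sapply(1:10, function(s) {
    gen <- generate_motion(synth_config(n_markers = 8, m_frames = 4 * 80,
                                        latent_rank = 4, noise_sd = 0,
                                        seed = 800 + s))
    wins <- make_training_windows(gen$sample, window = 80)
    fg <- simulate_gaps(80, 8, "frames", count = 3, seed = 900 + s)
    gapped <- apply_gaps(wins[[4]], fg)
    sapply(c(1, 2, 4, 8), function(k) {
      model <- fit_frame_recovery(wins[1:3], fg,
                                  taper = taper_config(sigma = Inf), k = k)
      mse(recover_frames(model, gapped), wins[[4]], gapped)
    })
  })
  expect_true(all(diff(rowMeans(res)) <= 0))
})

test_that("error grows with gap length and beats zero-order hold", {
  ftr <- sapply(1:20, function(s) {
    gen <- generate_motion(synth_config(n_markers = 10, m_frames = 4 * 100,
                                        latent_rank = 4, noise_sd = 0.05,
                                        seed = 600 + s))
    wins <- make_training_windows(gen$sample, window = 100)
    sapply(c(3, 6, 9, 12), function(G) {
      fg <- simulate_gaps(100, 10, "frames", count = G, seed = 700 + s)
      gapped <- apply_gaps(wins[[4]], fg)
      model <- fit_frame_recovery(wins[1:3], fg,
                                  taper = taper_config(sigma = 3,
                                                       temporal_scale = 30),
                                  k = 4)
      c(mse(recover_frames(model, gapped), wins[[4]], gapped),
        mse(zoh_fill(gapped, wins[[4]], fg[[1]]), wins[[4]], gapped))
    })
  })
  fr <- rowMeans(ftr)
  method <- fr[c(1, 3, 5, 7)]
  zoh <- fr[c(2, 4, 6, 8)]
  expect_true(all(diff(method) >= 0))
  expect_true(all(method < zoh))
})

test_that("frame_gap_fraction reproduces the protocol percentages", {
  expect_equal(frame_gap_fraction(frame_gap_spec(100, 102), 400), 0.75)
  expect_equal(frame_gap_fraction(frame_gap_spec(1, 12), 400), 3)
  expect_equal(frame_gap_fraction(list(), 400), 0)
  # overlapping runs count distinct frames once
  expect_equal(frame_gap_fraction(list(frame_gap_spec(1, 6),
                                       frame_gap_spec(4, 9)), 100), 9)
})
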