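#' Mean squared recovery error over missing entries
#'
#' The squared Frobenius norm of the reconstruction error restricted to the
#' originally missing entries, divided by the *count of missing entries*
#' (not the frame count).
#'
#' @param reconstructed,ground_truth `motion_sample`s (or plain matrices) of
#'   the same shape.
#' @param missing which entries were missing: a 0/1 matrix (1 = missing), a
#'   gapped `motion_sample` (its zero-mask entries), or a list of gap specs.
#' @return non-negative scalar.
#' @examples
#' truth <- motion_sample(matrix(1:12, 4, 3 * 1))
#' rec <- truth; rec$values[2, 1] <- rec$values[2, 1] + 2
#' mse(rec, truth, list(gap_spec(1, 2, 2)))  # 4 / 3 (3 missing coords)
#' @export
mse <- function(reconstructed, ground_truth, missing) {
  rv <- sample_values(reconstructed)
  gv <- sample_values(ground_truth)
  if (!identical(dim(rv), dim(gv))) {
    stopf("reconstruction and ground truth shapes differ")
  }
  miss <- missing_matrix(missing, dim(rv))
  count <- sum(miss)
  if (count == 0) stopf("no missing entries: the recovery error is undefined")
  sum(((rv - gv) * miss)^2) / count
}

missing_matrix <- function(missing, dims) {
  if (inherits(missing, "motion_sample")) {
    miss <- 1 - missing$mask
  } else if (is.matrix(missing)) {
    miss <- missing
    if (!all(miss %in% c(0, 1))) stopf("'missing' matrix must be 0/1")
  } else {
    miss <- matrix(0, dims[1], dims[2])
    for (gap in as_gap_list(missing)) {
      cols <- if (inherits(gap, "gap_spec")) marker_cols(gap$marker) else
        seq_len(dims[2])
      miss[gap$start:gap$end, cols] <- 1
    }
  }
  if (!identical(dim(miss), as.integer(dims))) {
    stopf("'missing' shape does not match the samples")
  }
  miss
}

#' Baseline gap fillers
#'
#' Two training-free references: `"linear"` interpolates each missing
#' coordinate linearly in time (nearest observed value beyond the ends);
#' `"pca"` is the classical self-PCA imputation of the test sample alone --
#' mean-fill, project onto the top-`k` principal components, replace the
#' missing entries, iterate to convergence.
#'
#' @param test a gapped `motion_sample`.
#' @param method `"linear"` or `"pca"`.
#' @param k,var_fraction component rule for `"pca"`.
#' @param tol,max_iter convergence controls for `"pca"`.
#' @return the filled `motion_sample` (all-ones mask); observed entries are
#'   untouched.
#' @export
baseline_fill <- function(test, method = c("linear", "pca"), k = NULL,
                          var_fraction = 0.95, tol = 1e-6, max_iter = 100) {
  method <- match.arg(method)
  stopifnot(inherits(test, "motion_sample"))
  if (all(test$mask == 0)) stopf("fully missing sample cannot be filled")
  out <- test
  if (method == "linear") {
    for (j in seq_len(ncol(test$values))) {
      obs <- which(test$mask[, j] == 1)
      gap <- which(test$mask[, j] == 0)
      if (length(gap) == 0L) next
      if (length(obs) == 0L) {
        stopf("column %d has no observed frames: linear interpolation impossible", j)
      }
      out$values[gap, j] <- approx(obs, test$values[obs, j], xout = gap,
                                   rule = 2)$y
    }
  } else {
    x <- test$values
    miss <- test$mask == 0
    mu0 <- colSums(x * test$mask) / pmax(colSums(test$mask), 1)
    x[miss] <- matrix(mu0, nrow(x), ncol(x), byrow = TRUE)[miss]
    scale_ref <- max(abs(x), 1e-12)
    for (iter in seq_len(max_iter)) {
      mu <- colMeans(x)
      xc <- sweep(x, 2L, mu)
      basis <- pca_subspace(xc, k = k, var_fraction = var_fraction)$basis
      recon <- xc %*% basis %*% t(basis)
      recon <- sweep(recon, 2L, mu, `+`)
      change <- max(abs(recon[miss] - x[miss])) / scale_ref
      x[miss] <- recon[miss]
      if (change < tol) break
    }
    out$values <- out$values * test$mask + x * miss
  }
  out$mask[] <- 1
  out
}

#' Run repeated gap-recovery trials
#'
#' The standard evaluation protocol: a long synthetic sequence is cut into
#' non-overlapping windows, the last window is the test take and the others
#' the training set; each trial draws a fresh random gap placement, corrupts
#' the test window, fits/applies the requested method, and records the mean
#' squared error over the missing entries.  The final figure of merit is the
#' arithmetic mean over trials.
#'
#' @param method `"wpca"`, `"lwpca"`, `"frames"`, `"linear"` or `"pca"`.
#' @param config a [synth_config()]; `m_frames` must cover
#'   `(n_train + 1) * window` frames.
#' @param protocol,n_gaps,gap_length gap placement, see [simulate_gaps()]
#'   (`protocol = "frames"` requires `method = "frames"` and vice versa).
#' @param window frames per window (default 400).
#' @param n_train training windows (default 5).
#' @param trials number of repetitions (default 50).
#' @param seed master seed; trial `t` uses `seed + t` for gap placement.
#' @param skeleton optional `skeleton_model`; defaults to the generator's.
#' @param taper,k,var_fraction,delta_threshold passed to the fitters.
#' @return a `data.frame` with columns `trial`, `seed`, `method`,
#'   `protocol`, `mse`, carrying `mean`, `sd` and `boxplot` (five-number
#'   stats) attributes; see [summarize_trials()].
#' @export
run_trials <- function(method = c("wpca", "lwpca", "frames", "linear", "pca"),
                       config = synth_config(), protocol = "single",
                       n_gaps = 1, gap_length = NULL, window = 400,
                       n_train = 5, trials = 50, seed = 1, skeleton = NULL,
                       taper = taper_config(), k = NULL, var_fraction = 0.95,
                       delta_threshold = 1e-3) {
  method <- match.arg(method)
  if ((protocol == "frames") != (method == "frames")) {
    stopf("the whole-frame protocol and the 'frames' method go together")
  }
  gen <- generate_motion(config)
  if (config$m_frames < (n_train + 1) * window) {
    stopf("config generates %d frames; %d needed for %d training + 1 test window",
          config$m_frames, (n_train + 1) * window, n_train)
  }
  wins <- make_training_windows(gen$sample, window, count = n_train + 1)
  train <- wins[seq_len(n_train)]
  test <- wins[[n_train + 1]]
  skeleton <- skeleton %||% gen$skeleton
  n <- n_markers(test)

  errs <- numeric(trials)
  seeds <- seed + seq_len(trials)
  for (t in seq_len(trials)) {
    gaps <- simulate_gaps(window, n, protocol, count = n_gaps,
                          gap_length = gap_length, seed = seeds[t])
    gapped <- apply_gaps(test, gaps)
    filled <- switch(method,
      wpca = reconstruct(
        fit_wpca(train, gaps, k = k, var_fraction = var_fraction,
                 delta_threshold = delta_threshold), gapped),
      lwpca = reconstruct(
        fit_lwpca(train, gaps, skeleton, taper = taper, k = k,
                  var_fraction = var_fraction,
                  delta_threshold = delta_threshold), gapped),
      frames = recover_frames(
        fit_frame_recovery(train, gaps, taper = taper, k = k,
                           var_fraction = var_fraction,
                           delta_threshold = delta_threshold), gapped),
      linear = baseline_fill(gapped, "linear"),
      pca = baseline_fill(gapped, "pca", k = k,
                          var_fraction = var_fraction)
    )
    errs[t] <- mse(filled, test, gapped)
  }
  report <- data.frame(trial = seq_len(trials), seed = seeds,
                       method = method, protocol = protocol, mse = errs,
                       stringsAsFactors = FALSE)
  attr(report, "mean") <- mean(errs)
  attr(report, "sd") <- if (trials > 1) sd(errs) else NA_real_
  attr(report, "boxplot") <- grDevices::boxplot.stats(errs)$stats
  report
}

#' Summarise a trial report
#'
#' @param report output of [run_trials()].
#' @return list with `mean`, `sd` and `boxplot` (lower whisker, hinges,
#'   median, upper whisker).
#' @export
summarize_trials <- function(report) {
  list(mean = mean(report$mse),
       sd = if (nrow(report) > 1) sd(report$mse) else NA_real_,
       boxplot = grDevices::boxplot.stats(report$mse)$stats)
}

#' Write a trial report to CSV or JSON
#'
#' @param report output of [run_trials()].
#' @param path output path (`.csv` or `.json`).
#' @return `invisible(path)`.
#' @export
write_trial_report <- function(report, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(
      list(trials = report, summary = summarize_trials(report)),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(report, path, row.names = FALSE)
  }
  invisible(path)
}
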