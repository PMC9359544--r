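#' Fit a whole-frame recovery model
#'
#' When entire frames are dropped (e.g. removed because of jitter), the
#' marker-space regression has nothing to condition on, but the correlation
#' *between frames* still does: the Gram matrix `A %*% t(A)` of the
#' horizontally concatenated training samples defines a frame-space
#' eigenbasis, and a frame whose row is missing can be predicted from the
#' observed rows through that basis.  Each missing frame is treated as one
#' gap with its own temporal-only Gaussian taper (rows weighted by
#' `exp(-(dt/ts)^2 / sigma^2)`), giving per-gap frame bases for the complete
#' and row-zeroed stacks, an eigenspace mapping between them, and one
#' combination coefficient per missing frame, solved by weighted least
#' squares exactly as in the marker-space method (the weight matrix here is
#' sized by the number of missing frames, from the eigenvalues of
#' `B %*% t(B)`).
#'
#' Rows of the row-zeroed stack's eigenbasis vanish at the missing frames
#' (they carry no data), so the missing-row block of each per-gap basis is
#' obtained from the complete-data basis via the eigenspace mapping; the
#' resulting predictor is the usual observed-to-missing row regression
#' expressed in the gapped basis.
#'
#' @param training list of complete `motion_sample`s sharing the same
#'   frame count `m` (they are concatenated along columns).
#' @param frame_gaps a `frame_gap_spec` or list of them; every frame inside
#'   any interval counts as one gap.
#' @param taper a [taper_config()] (only `sigma` and `temporal_scale` are
#'   used; there is no spatial term for whole frames).
#' @param k,var_fraction retained frame-space dimension rule; `k` is capped
#'   at the number of observed frames (with a warning).
#' @param delta_threshold,threshold_type weight-matrix floor, as in
#'   [residual_weight_matrix()].
#' @return an object of class `frame_recovery_model`.
#' @seealso [recover_frames()], [frame_gap_fraction()]
#' @export
fit_frame_recovery <- function(training, frame_gaps, taper = taper_config(),
                               k = NULL, var_fraction = 0.95,
                               delta_threshold = 1e-3,
                               threshold_type = c("relative", "absolute")) {
  threshold_type <- match.arg(threshold_type)
  if (inherits(training, "motion_sample")) training <- list(training)
  frame_gaps <- as_gap_list(frame_gaps)
  if (length(frame_gaps) == 0L) {
    stopf("need at least one missing frame to fit a frame-recovery model")
  }
  dm <- demean(training)
  centered <- lapply(dm$samples, `[[`, "values")
  m <- nrow(centered[[1]])
  for (fg in frame_gaps) {
    if (!inherits(fg, "frame_gap_spec")) {
      stopf("frame recovery expects frame_gap_spec gaps")
    }
    check_gap(fg, m, 1L)
  }
  frames <- sort(unique(unlist(lapply(frame_gaps, function(g) g$start:g$end))))
  ng <- length(frames)
  if (ng >= m) stopf("all %d frames missing: nothing to condition on", m)
  obs <- setdiff(seq_len(m), frames)

  a <- do.call(cbind, centered)               # m x 3nK
  atil <- a
  atil[frames, ] <- 0

  ev <- svd(a, nu = 0, nv = 0)$d^2
  k0 <- frame_space_k(ev, k, var_fraction, max_k = length(obs))

  global <- frame_gap_operator(a, atil, rep(1, m), k0, frames, obs)
  b <- a[frames, , drop = FALSE] - global$operator %*% a[obs, , drop = FALSE]
  delta <- svd(b, nu = 0, nv = 0)$d^2
  if (length(delta) < ng) delta <- c(delta, rep(0, ng - length(delta)))
  weights <- delta_weights(delta, delta_threshold, threshold_type)

  ops <- vector("list", ng)
  hs <- vector("list", ng)
  for (g in seq_len(ng)) {
    q <- exp(-((seq_len(m) - frames[g]) / taper$temporal_scale)^2 /
               taper$sigma^2)
    og <- frame_gap_operator(a, atil, q, k0, frames, obs)
    ops[[g]] <- og$operator
    hs[[g]] <- og$h
  }

  fmats <- lapply(ops, function(o) o %*% a[obs, , drop = FALSE])
  a2 <- a[frames, , drop = FALSE]
  w <- weights$weights
  mmat <- matrix(0, ng, ng)
  bvec <- numeric(ng)
  for (g in seq_len(ng)) {
    fw <- fmats[[g]] * w
    bvec[g] <- sum(fw * a2)
    for (h in seq_len(g)) {
      v <- sum(fw * fmats[[h]])
      mmat[g, h] <- v
      mmat[h, g] <- v
    }
  }
  alpha <- as.numeric(solve_psd(mmat, bvec))

  structure(
    list(frames = frames, operators = ops, h = hs, alpha = alpha,
         weights = weights, column_means = dm$means, k = k0,
         m = m, n_coords = ncol(centered[[1]]), taper = taper),
    class = "frame_recovery_model"
  )
}

frame_space_k <- function(ev, k, var_fraction, max_k) {
  rank <- max(1L, sum(sqrt(ev) > length(ev) * .Machine$double.eps *
                        sqrt(max(ev, 1e-300))))
  if (is.null(k)) {
    total <- sum(ev)
    k <- if (total == 0) 1L else which(cumsum(ev) / total >= var_fraction)[1]
    k <- min(k, rank)
  } else {
    if (!is_count(k) || k < 1) stopf("'k' must be a positive integer")
    if (k > rank) {
      warning(sprintf("requested k = %d exceeds numerical rank %d; using k = %d",
                      k, rank, rank), call. = FALSE)
      k <- rank
    }
  }
  if (k > max_k) {
    warning(sprintf("k = %d exceeds the %d observed frames; using k = %d",
                    k, max_k, max_k), call. = FALSE)
    k <- max_k
  }
  as.integer(k)
}

# frame-space regression operator for one taper: weight rows of the
# complete and row-zeroed stacks, extract k-dimensional frame bases from
# their Gram matrices (left singular vectors), map the gapped basis onto
# the complete one, and compose the observed-rows -> missing-rows predictor.
frame_gap_operator <- function(a, atil, q, k, frames, obs) {
  va <- fix_signs(svd(q * a, nu = k, nv = 0)$u)
  vt <- fix_signs(svd(q * atil, nu = k, nv = 0)$u)
  tg <- least_squares(vt, va)                        # va ~ vt %*% tg
  vt1 <- vt[obs, , drop = FALSE]
  va2 <- va[frames, , drop = FALSE]
  gram <- crossprod(vt %*% tg)                       # t(T) (Vt' Vt) T
  core <- solve_psd(gram, t(tg) %*% t(vt1))          # k x n_obs
  h <- tg %*% solve_psd(gram, t(tg))                 # symmetric by construction
  list(operator = va2 %*% core, h = h)
}

#' @export
print.frame_recovery_model <- function(x, ...) {
  cat(sprintf("Frame-recovery model: %d missing frame(s) of %d, k = %d\n",
              length(x$frames), x$m, x$k))
  invisible(x)
}

#' Recover wholly missing frames of a test sample
#'
#' The test sample must carry exactly the frame gaps the model was fitted
#' with (same positions).  Observed rows are centered with the stored
#' training means and pushed through the fitted frame-space regressors; the
#' missing rows are replaced by the weighted combination, means restored.
#'
#' @param model a `frame_recovery_model`.
#' @param test a `motion_sample` whose mask marks the same frames as wholly
#'   missing.
#' @return the filled `motion_sample` (all-ones mask).
#' @export
recover_frames <- function(model, test) {
  stopifnot(inherits(model, "frame_recovery_model"),
            inherits(test, "motion_sample"))
  if (nrow(test$values) != model$m) {
    stopf("test has %d frames but the model was fitted on %d",
          nrow(test$values), model$m)
  }
  test_frames <- sort(unique(unlist(lapply(frame_gaps_from_mask(test),
                                           function(g) g$start:g$end))))
  if (!identical(test_frames, model$frames)) {
    stopf("gap-pattern mismatch: test misses frames [%s], model was fitted for [%s]",
          paste(test_frames, collapse = ","),
          paste(model$frames, collapse = ","))
  }
  means <- model$column_means
  if (ncol(test$values) != length(means)) {
    stopf("test has %d coordinate columns but the model was fitted on %d",
          ncol(test$values), length(means))
  }
  centered <- center_sample(test, means)$values
  obs <- setdiff(seq_len(model$m), model$frames)
  m1 <- centered[obs, , drop = FALSE]
  est <- Reduce(`+`, Map(function(al, op) al * (op %*% m1),
                         model$alpha, model$operators))
  out <- test
  out$values[model$frames, ] <- sweep(est, 2L, means, `+`)
  out$mask[] <- 1
  out
}

#' Percentage of frames missing
#'
#' @param frame_gaps a `frame_gap_spec` or list of them.
#' @param m total frame count.
#' @return `100 * (number of distinct missing frames) / m`.
#' @examples
#' frame_gap_fraction(frame_gap_spec(100, 102), 400)  # 0.75
#' @export
frame_gap_fraction <- function(frame_gaps, m) {
  frame_gaps <- as_gap_list(frame_gaps)
  if (length(frame_gaps) == 0L) return(0)
  frames <- unique(unlist(lapply(frame_gaps, function(g) {
    check_gap(g, m, 1L)
    g$start:g$end
  })))
  100 * length(frames) / m
}
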