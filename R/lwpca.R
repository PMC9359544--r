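#' Taper mask configuration
#'
#' The locally weighted variant multiplies the data by a Gaussian mask
#' centered on each gap, `Q = exp(-d^2 / sigma^2)`, where `d` combines the
#' temporal distance (frames to the gap interval) and the spatial distance
#' (shortest path to the gap marker on the skeleton graph).  Frames and
#' skeleton hops are incommensurate units, so both are made dimensionless
#' before the Euclidean combination: `temporal_scale` frames and
#' `spatial_scale` skeleton-distance units each map to one unit of
#' distance.  `sigma` is then the dimensionless Gaussian window; `Inf`
#' disables tapering (mask identically 1), recovering the untapered method.
#'
#' @param sigma positive Gaussian window size (default 3; `Inf` allowed).
#' @param temporal_scale frames per unit distance (default 10).
#' @param spatial_scale skeleton-distance units per unit distance
#'   (default 1).
#' @return an object of class `taper_config`.
#' @export
taper_config <- function(sigma = 3, temporal_scale = 10, spatial_scale = 1) {
  for (nm in c("sigma", "temporal_scale", "spatial_scale")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0) {
      stopf("'%s' must be a positive scalar", nm)
    }
  }
  structure(list(sigma = sigma, temporal_scale = temporal_scale,
                 spatial_scale = spatial_scale), class = "taper_config")
}

#' @export
print.taper_config <- function(x, ...) {
  cat(sprintf("Taper: sigma = %g, temporal scale = %g frames, spatial scale = %g\n",
              x$sigma, x$temporal_scale, x$spatial_scale))
  invisible(x)
}

#' Gaussian spatio-temporal taper mask for one gap
#'
#' For cell (frame `i`, marker `j`) the temporal distance is 0 inside the
#' gap interval and the distance to its nearest endpoint outside; the
#' spatial distance is the skeleton shortest path from marker `j` to the gap
#' marker.  Both are scaled by the configured unit lengths and combined as
#' `Q[i, j] = exp(-(dt^2 + ds^2) / sigma^2)`, so `Q = 1` on the gap itself
#' and decays smoothly away from it in both time and body topology.
#'
#' @param gap a `gap_spec`.
#' @param m number of frames.
#' @param skeleton a `skeleton_model` covering all markers.
#' @param config a [taper_config()].
#' @return an `m` x `n` matrix with entries in (0, 1].
#' @seealso [expand_taper()] to replicate marker columns to x,y,z triples.
#' @export
taper_mask <- function(gap, m, skeleton, config = taper_config()) {
  stopifnot(inherits(gap, "gap_spec"), inherits(skeleton, "skeleton_model"),
            inherits(config, "taper_config"))
  n <- length(skeleton$markers)
  check_gap(gap, m, n)
  frames <- seq_len(m)
  dt <- pmax(gap$start - frames, frames - gap$end, 0) / config$temporal_scale
  ds <- skeleton_distances(skeleton, gap$marker) / config$spatial_scale
  d2 <- outer(dt^2, ds^2, `+`)
  q <- exp(-d2 / config$sigma^2)
  q
}

#' Expand an m x n taper mask to coordinate columns
#'
#' Each marker's mask value applies equally to its x, y and z columns.
#'
#' @param q an `m` x `n` taper mask.
#' @return an `m` x `3n` matrix.
#' @export
expand_taper <- function(q) {
  q[, rep(seq_len(ncol(q)), each = 3L), drop = FALSE]
}

#' Fit a locally weighted PCA gap regressor
#'
#' The tapered variant of [fit_wpca()]: for each gap, both the complete
#' stack and that gap's gap-group stack are multiplied elementwise by the
#' gap's taper mask before subspace extraction, so the per-gap bases (and
#' the mapping between them) describe the motion *near* the gap rather than
#' the whole body.  The residual accumulated for the weight matrix is
#' likewise tapered per gap, and the coefficient solve masks the residual by
#' the normalised sum of all gap masks.  Tapering makes the effective
#' covariance sparse (entries far from every gap are shrunk towards zero),
#' which suppresses the influence of distant, possibly erratic markers.
#'
#' With `sigma = Inf` every mask is identically 1 and the fit coincides
#' with [fit_wpca()] exactly.
#'
#' @inheritParams fit_wpca
#' @param skeleton a `skeleton_model` consistent with the samples' markers.
#' @param taper a [taper_config()].
#' @return an object of class `c("lwpca_fit", "mocap_fit")`, usable with
#'   [reconstruct()].
#' @export
fit_lwpca <- function(training, gaps, skeleton, taper = taper_config(),
                      k = NULL, var_fraction = 0.95, delta_threshold = 1e-3,
                      threshold_type = c("relative", "absolute")) {
  threshold_type <- match.arg(threshold_type)
  stopifnot(inherits(skeleton, "skeleton_model"))
  if (inherits(training, "motion_sample")) training <- list(training)
  gaps <- as_gap_list(gaps)
  if (length(gaps) == 0L) stopf("need at least one gap")
  dm <- demean(training)
  centered <- lapply(dm$samples, `[[`, "values")
  m <- nrow(centered[[1]])
  n <- ncol(centered[[1]]) %/% 3L
  if (length(skeleton$markers) != n) {
    stopf("skeleton has %d markers but samples have %d",
          length(skeleton$markers), n)
  }
  for (gap in gaps) check_gap(gap, m, n)

  # k is fixed once, on the untapered complete stack, so every per-gap
  # basis pair shares the same dimension
  stacked <- do.call(rbind, centered)
  k0 <- pca_subspace(stacked, k = k, var_fraction = var_fraction)$k

  qmasks <- lapply(gaps, taper_mask, m = m, skeleton = skeleton,
                   config = taper)
  qexp <- lapply(qmasks, expand_taper)
  groups <- vector("list", length(gaps))
  projectors <- vector("list", length(gaps))
  for (g in seq_along(gaps)) {
    qe <- qexp[[g]]
    masked_full <- lapply(centered, `*`, qe)
    gapped <- lapply(centered, zero_gap_cells, gaps = gaps[g])
    masked_gap <- lapply(gapped, `*`, qe)
    ug_full <- pca_subspace(do.call(rbind, masked_full), k = k0)
    ug_gap <- pca_subspace(do.call(rbind, masked_gap), k = k0)
    # the taper enters through the bases (tapered covariances) only; the
    # mapping is fit on the raw samples so that applying the composite
    # operator to a raw test sample is consistent
    tg <- eigen_mapping(centered, ug_full, gapped, ug_gap)
    groups[[g]] <- list(basis = ug_gap, basis_full = ug_full, mapping = tg,
                        gapped = gapped)
    projectors[[g]] <- ug_gap$basis %*% tg %*% t(ug_full$basis)
  }

  # tapered residual -> weight matrix
  b <- 0
  for (g in seq_along(gaps)) {
    s <- 0
    for (i in seq_along(centered)) {
      s <- s + (centered[[i]] - groups[[g]]$gapped[[i]] %*% projectors[[g]])
    }
    b <- b + s * qexp[[g]]
  }
  delta <- svd(b, nu = 0, nv = 0)$d^2
  if (length(delta) < ncol(b)) delta <- c(delta, rep(0, ncol(b) - length(delta)))
  weights <- delta_weights(delta, delta_threshold, threshold_type)

  # combined mask, normalised so its maximum is exactly 1
  qbar <- Reduce(`+`, qmasks)
  qbar <- qbar / max(qbar)
  multigapped <- lapply(centered, zero_gap_cells, gaps = gaps)
  alpha <- solve_alpha(centered, multigapped, projectors, weights,
                       taper = expand_taper(qbar))

  gg <- list(means = dm$means, gaps = gaps,
             U = list(k = k0), centered = centered)
  fit <- new_mocap_fit("lwpca_fit", projectors, alpha, weights, gg,
                       taper = taper)
  fit$qbar <- qbar
  fit
}
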