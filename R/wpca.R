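#' Build per-gap eigenspaces and mappings
#'
#' Training for the gap regressors proceeds gap by gap: each gap is applied
#' alone to every (complete) training sample, the corrupted copies are
#' stacked into that gap's "gap-group", and the gap-group's principal
#' subspace is aligned to the complete-data subspace by an eigenspace
#' mapping.  The complete-data basis `U` fixes the retained dimension `k`,
#' which is imposed on every gap-group basis so each mapping is square.
#'
#' @param training list of complete `motion_sample`s, all the same shape.
#' @param gaps list of `gap_spec`s (the test sample's gaps, transplanted
#'   verbatim onto the training windows).
#' @param k,var_fraction retained-dimension rule, see [pca_subspace()].
#' @return a list with `U` (complete-data `eigen_basis`), `groups` (one
#'   element per gap: `basis`, `mapping`, `gapped` centered matrices),
#'   `means`, `centered` (list of centered matrices) and `gaps`.
#' @export
build_gap_groups <- function(training, gaps, k = NULL, var_fraction = 0.95) {
  if (inherits(training, "motion_sample")) training <- list(training)
  gaps <- as_gap_list(gaps)
  if (length(gaps) == 0L) stopf("need at least one gap")
  dm <- demean(training)
  centered <- lapply(dm$samples, `[[`, "values")
  m <- nrow(centered[[1]])
  n <- ncol(centered[[1]]) %/% 3L
  for (gap in gaps) check_gap(gap, m, n)
  stacked <- do.call(rbind, centered)
  u <- pca_subspace(stacked, k = k, var_fraction = var_fraction)
  groups <- lapply(gaps, function(gap) {
    gapped <- lapply(centered, zero_gap_cells, gaps = list(gap))
    ug <- pca_subspace(do.call(rbind, gapped), k = u$k)
    tg <- eigen_mapping(centered, u, gapped, ug)
    list(basis = ug, mapping = tg, gapped = gapped)
  })
  list(U = u, groups = groups, means = dm$means, centered = centered,
       gaps = gaps)
}

# zero the cells of centered value matrices covered by gaps (mean fill)
zero_gap_cells <- function(values, gaps) {
  for (gap in gaps) {
    cols <- if (inherits(gap, "gap_spec")) marker_cols(gap$marker) else
      seq_len(ncol(values))
    values[gap$start:gap$end, cols] <- 0
  }
  values
}

# diagonal weights from residual eigenvalues with flooring; relative
# thresholds are taken as a fraction of the largest eigenvalue.  When the
# residual vanishes entirely (perfect reconstruction) every eigenvalue is
# floored at a small absolute constant, giving a uniform weight.
delta_weights <- function(delta, threshold = 1e-3,
                          threshold_type = c("relative", "absolute")) {
  threshold_type <- match.arg(threshold_type)
  if (!is.numeric(threshold) || threshold <= 0) {
    stopf("'threshold' must be positive")
  }
  floor_val <- if (threshold_type == "relative") threshold * max(delta) else
    threshold
  if (floor_val <= 0) floor_val <- 1e-8
  structure(
    list(weights = 1 / pmax(delta, floor_val), delta = delta,
         threshold = floor_val),
    class = "weight_matrix"
  )
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat(sprintf("Residual weight matrix: %d diagonal entries in [%.3g, %.3g] (floor %.3g)\n",
              length(x$weights), min(x$weights), max(x$weights), x$threshold))
  invisible(x)
}

#' Residual-eigenvalue weight matrix
#'
#' Accumulates the reconstruction residual `B = sum_g sum_i (A_i -
#' Agap_i^g Ugap^g T^g U')` over all gap-groups and training samples, takes
#' the eigenvalues `delta` of `B'B`, and forms the diagonal weight matrix
#' with entries `1 / max(delta_i, floor)`.  Small residual directions thus
#' dominate the subsequent weighted least-squares fit, the standard remedy
#' for non-constant residual variance; the floor keeps weights finite.
#'
#' @param gap_groups result of [build_gap_groups()].
#' @param delta_threshold flooring threshold for the eigenvalues.
#' @param threshold_type `"relative"` (fraction of the largest eigenvalue,
#'   default) or `"absolute"`.
#' @param taper optional list of expanded (frames x 3n) taper masks, one per
#'   gap; each gap's residual summand is multiplied elementwise by its mask.
#' @return a `weight_matrix` object (`weights`, `delta`, `threshold`).
#' @export
residual_weight_matrix <- function(gap_groups, delta_threshold = 1e-3,
                                   threshold_type = c("relative", "absolute"),
                                   taper = NULL) {
  threshold_type <- match.arg(threshold_type)
  centered <- gap_groups$centered
  ut <- t(gap_groups$U$basis)
  b <- 0
  for (g in seq_along(gap_groups$groups)) {
    grp <- gap_groups$groups[[g]]
    proj <- grp$basis$basis %*% grp$mapping %*% ut
    s <- 0
    for (i in seq_along(centered)) {
      s <- s + (centered[[i]] - grp$gapped[[i]] %*% proj)
    }
    if (!is.null(taper)) s <- s * taper[[g]]
    b <- b + s
  }
  delta <- svd(b, nu = 0, nv = 0)$d^2
  # B'B has ncol(b) eigenvalues; svd returns min(dim) -- pad the rest (zero)
  if (length(delta) < ncol(b)) delta <- c(delta, rep(0, ncol(b) - length(delta)))
  delta_weights(delta, delta_threshold, threshold_type)
}

#' Solve the gap-combination coefficients
#'
#' Given per-gap reconstruction operators `P^g` and the training samples
#' corrupted with *all* gaps at once (the test sample's corruption pattern),
#' finds the coefficients `alpha` minimising the weighted residual
#' `sum_i tr( R_i W R_i' )`, `R_i = (A_i - Agap_i sum_g alpha_g P^g)`,
#' optionally masked elementwise by a taper before weighting.  The objective
#' is quadratic in `alpha`, so the solution comes from the G x G normal
#' equations (pseudo-inverse when singular).
#'
#' @param full list of centered complete matrices `A_i`.
#' @param gapped list of centered matrices with all gaps applied.
#' @param projectors list of `3n x 3n` per-gap operators.
#' @param weights a `weight_matrix` (or plain positive vector) of length
#'   `3n`.
#' @param taper optional frames x `3n` elementwise mask applied to the
#'   residual (locally weighted variant).
#' @return numeric vector `alpha`, one coefficient per gap.
#' @export
solve_alpha <- function(full, gapped, projectors, weights, taper = NULL) {
  w <- if (inherits(weights, "weight_matrix")) weights$weights else
    as.numeric(weights)
  if (any(w <= 0)) stopf("weights must be positive")
  ng <- length(projectors)
  if (ng < 1L) stopf("need at least one projector")
  if (length(full) != length(gapped)) stopf("sample lists differ in length")
  cmats <- vector("list", length(full))
  amats <- vector("list", length(full))
  for (i in seq_along(full)) {
    ai <- sample_values(full[[i]])
    gi <- sample_values(gapped[[i]])
    ci <- lapply(projectors, function(p) gi %*% p)
    if (!is.null(taper)) {
      ci <- lapply(ci, `*`, taper)
      ai <- ai * taper
    }
    cmats[[i]] <- ci
    amats[[i]] <- ai
  }
  if (all(vapply(cmats, function(ci)
    all(vapply(ci, function(x) all(x == 0), logical(1))), logical(1)))) {
    stopf("degenerate system: every projected sample is fully masked")
  }
  mmat <- matrix(0, ng, ng)
  bvec <- numeric(ng)
  for (i in seq_along(full)) {
    cw <- lapply(cmats[[i]], function(x) sweep(x, 2L, w, `*`))
    for (g in seq_len(ng)) {
      bvec[g] <- bvec[g] + sum(cw[[g]] * amats[[i]])
      for (h in seq_len(g)) {
        v <- sum(cw[[g]] * cmats[[i]][[h]])
        mmat[g, h] <- mmat[g, h] + v
        if (h != g) mmat[h, g] <- mmat[h, g] + v
      }
    }
  }
  alpha <- as.numeric(solve_psd(mmat, bvec))
  alpha
}

#' Fit a weighted PCA gap regressor
#'
#' The complete training pipeline for the untapered method: de-mean, build
#' the complete-data basis and one gap-group (basis + eigenspace mapping)
#' per gap, accumulate the residual weight matrix, and solve for the
#' combination coefficients on training samples corrupted with all gaps at
#' once.  The result reconstructs a test sample carrying these gaps via
#' [reconstruct()].
#'
#' @inheritParams build_gap_groups
#' @param delta_threshold,threshold_type residual-eigenvalue floor, see
#'   [residual_weight_matrix()].
#' @return an object of class `c("wpca_fit", "mocap_fit")` holding the
#'   per-gap projectors, `alpha`, the weight matrix, the training column
#'   means and the gap list.
#' @examples
#' gen <- generate_motion(synth_config(n_markers = 6, m_frames = 120,
#'                                     latent_rank = 3, noise_sd = 0.01,
#'                                     seed = 1))
#' wins <- make_training_windows(gen$sample, window = 40)
#' gaps <- list(gap_spec(2, 5, 36))
#' fit <- fit_wpca(wins[1:2], gaps, k = 3)
#' filled <- reconstruct(fit, apply_gaps(wins[[3]], gaps))
#' @export
fit_wpca <- function(training, gaps, k = NULL, var_fraction = 0.95,
                     delta_threshold = 1e-3,
                     threshold_type = c("relative", "absolute")) {
  threshold_type <- match.arg(threshold_type)
  gg <- build_gap_groups(training, gaps, k = k, var_fraction = var_fraction)
  weights <- residual_weight_matrix(gg, delta_threshold, threshold_type)
  ut <- t(gg$U$basis)
  projectors <- lapply(gg$groups, function(grp)
    grp$basis$basis %*% grp$mapping %*% ut)
  multigapped <- lapply(gg$centered, zero_gap_cells, gaps = gg$gaps)
  alpha <- solve_alpha(gg$centered, multigapped, projectors, weights)
  new_mocap_fit("wpca_fit", projectors, alpha, weights, gg, taper = NULL)
}

new_mocap_fit <- function(cls, projectors, alpha, weights, gg, taper) {
  structure(
    list(projectors = projectors, alpha = alpha, weights = weights,
         column_means = gg$means, gaps = gg$gaps, k = gg$U$k,
         shape = dim(gg$centered[[1]]), taper = taper,
         variant = sub("_fit$", "", cls)),
    class = c(cls, "mocap_fit")
  )
}

#' @export
print.mocap_fit <- function(x, ...) {
  cat(sprintf("%s gap regressor: %d gap(s), k = %d, %d x %d samples\n",
              toupper(x$variant), length(x$projectors), x$k,
              x$shape[1], x$shape[2]))
  cat("  alpha:", paste(formatC(x$alpha, format = "g", digits = 4),
                        collapse = ", "), "\n")
  invisible(x)
}

#' Reconstruct (fill) a gapped test sample
#'
#' Centers the test sample with the stored training means (missing entries
#' zero-filled, i.e. mean-imputed), applies the fitted combination of
#' per-gap operators, and restores the means.  Only originally missing
#' entries (mask 0) are replaced; observed entries pass through unchanged.
#' The returned sample has an all-ones mask.
#'
#' @param fit a fitted regressor from [fit_wpca()] or [fit_lwpca()].
#' @param test a `motion_sample` with the same shape as the training
#'   samples, carrying the gaps the regressor was fitted for.
#' @param ... unused.
#' @return the filled `motion_sample`.
#' @export
reconstruct <- function(fit, test, ...) UseMethod("reconstruct")

#' @rdname reconstruct
#' @export
reconstruct.mocap_fit <- function(fit, test, ...) {
  stopifnot(inherits(test, "motion_sample"))
  if (!identical(dim(test$values), as.integer(fit$shape))) {
    stopf("test shape (%d x %d) does not match training shape (%d x %d)",
          nrow(test$values), ncol(test$values), fit$shape[1], fit$shape[2])
  }
  centered <- center_sample(test, fit$column_means)$values
  phi <- Reduce(`+`, Map(`*`, fit$alpha, fit$projectors))
  est <- centered %*% phi
  est <- sweep(est, 2L, fit$column_means, `+`)
  out <- test
  missing <- test$mask == 0
  out$values[missing] <- est[missing]
  out$mask[] <- 1
  out
}
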