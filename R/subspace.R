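#' De-mean a set of motion samples
#'
#' Computes per-coordinate column means over the observed (mask = 1) entries
#' pooled across all samples, and subtracts them.  After de-meaning, missing
#' entries sit exactly at the pooled mean, i.e. at 0 — so the internal
#' zero-fill of gaps is mean imputation, which leaves column means unchanged
#' and is the neutral fill for subspace estimation.
#'
#' @param samples a `motion_sample` or list of them, all the same shape.
#' @return a list with `samples` (centered copies) and `means` (length-`3n`
#'   numeric vector of pooled column means).
#' @export
demean <- function(samples) {
  if (inherits(samples, "motion_sample")) samples <- list(samples)
  check_same_shape(samples)
  vals <- lapply(samples, `[[`, "values")
  masks <- lapply(samples, `[[`, "mask")
  num <- Reduce(`+`, Map(function(v, w) colSums(v * w), vals, masks))
  den <- Reduce(`+`, lapply(masks, colSums))
  if (any(den == 0)) {
    stopf("column(s) %s have no observed entries across the samples; a training mean is required",
          paste(which(den == 0), collapse = ", "))
  }
  means <- num / den
  centered <- lapply(samples, center_sample, means = means)
  list(samples = centered, means = means)
}

#' @rdname demean
#' @param sample a single `motion_sample`.
#' @param means column means to subtract (typically the training means, so
#'   that a gapped test sample is centered consistently with the training
#'   set).
#' @export
center_sample <- function(sample, means) {
  stopifnot(inherits(sample, "motion_sample"))
  if (length(means) != ncol(sample$values)) {
    stopf("means length %d does not match %d coordinate columns",
          length(means), ncol(sample$values))
  }
  sample$values <- sweep(sample$values, 2L, means) * sample$mask
  sample
}

check_same_shape <- function(samples) {
  if (length(samples) == 0L) stopf("need at least one sample")
  if (!all(vapply(samples, inherits, logical(1), "motion_sample"))) {
    stopf("all elements must be motion_sample objects")
  }
  dims <- vapply(samples, function(s) dim(s$values), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stopf("all samples must share the same frames x coordinates shape")
  }
  invisible(samples)
}

sample_values <- function(x) {
  if (inherits(x, "motion_sample")) x$values else as.matrix(x)
}

#' Principal subspace of a stacked, centered data matrix
#'
#' Computes the dominant right-singular subspace of `x` (equivalently the
#' top eigenvectors of the coordinate covariance `t(x) %*% x`) via thin SVD,
#' which is the numerically stable route to the same eigenvectors.
#' Eigenvalues are the squared singular values.  The retained dimension `k`
#' is either fixed or the smallest `k` whose cumulative eigenvalue mass
#' reaches `var_fraction`.  Basis signs follow a deterministic convention
#' (largest-magnitude entry of each column positive), so repeated calls are
#' bit-identical.
#'
#' @param x numeric matrix (rows stacked over frames and samples, columns =
#'   coordinates), already centered.
#' @param k fixed number of components; overrides `var_fraction`.  Reduced
#'   to the numerical rank with a warning if it exceeds it.
#' @param var_fraction cumulative eigenvalue fraction to retain when `k` is
#'   `NULL` (default 0.95).
#' @return an object of class `eigen_basis`: `basis` (`ncol(x)` x `k`,
#'   orthonormal columns), `eigenvalues` (retained, non-increasing), `k`,
#'   and `eigenvalues_all` (full spectrum, for variance accounting).
#' @export
pca_subspace <- function(x, k = NULL, var_fraction = 0.95) {
  x <- sample_values(x)
  if (nrow(x) < 1L || ncol(x) < 1L) stopf("empty data matrix")
  s <- svd(x, nu = 0)
  ev <- s$d^2
  rank <- if (s$d[1] > 0) {
    sum(s$d > max(dim(x)) * .Machine$double.eps * s$d[1])
  } else 0L
  rank <- max(rank, 1L)
  if (is.null(k)) {
    if (!is.numeric(var_fraction) || var_fraction <= 0 || var_fraction > 1) {
      stopf("'var_fraction' must be in (0, 1]")
    }
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
    k <- min(k, length(ev))
  }
  basis <- fix_signs(s$v[, seq_len(k), drop = FALSE])
  structure(
    list(basis = basis, eigenvalues = ev[seq_len(k)], k = as.integer(k),
         eigenvalues_all = ev),
    class = "eigen_basis"
  )
}

#' @export
print.eigen_basis <- function(x, ...) {
  frac <- if (sum(x$eigenvalues_all) > 0) {
    sum(x$eigenvalues) / sum(x$eigenvalues_all)
  } else 1
  cat(sprintf("Eigen basis: %d x %d (%.1f%% of variance)\n",
              nrow(x$basis), x$k, 100 * frac))
  invisible(x)
}

#' Eigenspace mapping between the complete and gapped subspaces
#'
#' Projections of complete samples onto the complete-data basis and of their
#' gapped counterparts onto the gapped-data basis live in two different
#' `k`-dimensional coordinate systems.  This solves for the `k` x `k` linear
#' map `T` aligning them,
#' minimising `sum_i || A_i U - Agap_i Ugap T ||_F^2` in closed form via the
#' stacked least-squares system (pseudo-inverse when singular).
#'
#' @param full_samples list of centered complete matrices (or
#'   `motion_sample`s).
#' @param full_basis `eigen_basis` of the complete stack (`U`).
#' @param gapped_samples list of centered gapped matrices, same shapes.
#' @param gapped_basis `eigen_basis` of the gapped stack, same `k`.
#' @return the `k` x `k` mapping matrix.
#' @export
eigen_mapping <- function(full_samples, full_basis, gapped_samples,
                          gapped_basis) {
  if (inherits(full_samples, "motion_sample") || is.matrix(full_samples)) {
    full_samples <- list(full_samples)
  }
  if (inherits(gapped_samples, "motion_sample") || is.matrix(gapped_samples)) {
    gapped_samples <- list(gapped_samples)
  }
  if (length(full_samples) != length(gapped_samples)) {
    stopf("sample lists differ in length (%d vs %d)",
          length(full_samples), length(gapped_samples))
  }
  if (full_basis$k != gapped_basis$k) {
    stopf("basis dimensions differ (k = %d vs %d): the mapping must be square",
          full_basis$k, gapped_basis$k)
  }
  x <- do.call(rbind, lapply(gapped_samples, function(a)
    sample_values(a) %*% gapped_basis$basis))
  y <- do.call(rbind, lapply(full_samples, function(a)
    sample_values(a) %*% full_basis$basis))
  tmap <- least_squares(x, y)
  dimnames(tmap) <- NULL
  tmap
}
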