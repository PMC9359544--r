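`%||%` <- function(a, b) if (is.null(a)) b else a

#' Least-squares solve with rank-deficiency fallback
#'
#' Solves `X %*% B = Y` in the least-squares sense via QR; falls back to the
#' Moore-Penrose pseudo-inverse (minimum-norm solution) when `X` is rank
#' deficient.
#'
#' @param x design matrix.
#' @param y response matrix (or vector).
#' @return coefficient matrix `B`.
#' @keywords internal
#' @noRd
least_squares <- function(x, y) {
  qx <- qr(x)
  if (qx$rank == ncol(x)) {
    return(qr.coef(qx, y))
  }
  MASS::ginv(x) %*% y
}

# Solve a square linear system, pseudo-inverting when singular.
solve_psd <- function(a, b) {
  out <- tryCatch(solve(a, b), error = function(e) NULL)
  if (is.null(out) || anyNA(out)) {
    out <- MASS::ginv(a) %*% b
  }
  out
}

# Deterministic sign convention for singular/eigen-vector matrices: each
# column is flipped so that its largest-magnitude entry is positive (first
# occurrence wins on ties), making decompositions reproducible bit-for-bit.
fix_signs <- function(v) {
  if (ncol(v) == 0L) return(v)
  for (j in seq_len(ncol(v))) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) v[, j] <- -v[, j]
  }
  v
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == floor(x)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
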