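#' Construct a motion sample
#'
#' A motion sample is the standard matrix representation of a marker-based
#' motion-capture take: `m` frames by `3 n` coordinates, with columns ordered
#' x, y, z per marker.  An observation mask of the same shape records which
#' entries were actually measured (1) and which are missing (0).  Missing
#' entries are stored as 0 internally; `NaN`/`NA` only appear at the file
#' boundary.
#'
#' Gap granularity is the whole marker: if any one coordinate of a marker is
#' non-finite at some frame, all three coordinates of that marker are marked
#' missing at that frame.
#'
#' @param values numeric matrix, `m` frames x `3n` coordinates.
#' @param marker_names character vector of `n` marker names; defaults to
#'   `M1..Mn`.
#' @param mask optional 0/1 matrix of the same shape; if `NULL`, derived from
#'   non-finite entries of `values`.
#' @param frame_rate optional frames-per-second scalar.
#' @return an object of class `motion_sample` with elements `values`,
#'   `marker_names`, `mask`, `frame_rate`.
#' @examples
#' s <- motion_sample(matrix(rnorm(24), 4, 6))
#' n_markers(s)
#' @export
motion_sample <- function(values, marker_names = NULL, mask = NULL,
                          frame_rate = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stopf("'values' must be a numeric matrix")
  if (nrow(values) < 1L) stopf("a motion sample needs at least one frame")
  if (ncol(values) %% 3L != 0L) {
    stopf("column count (%d) is not divisible by 3: expected x,y,z per marker",
          ncol(values))
  }
  n <- ncol(values) %/% 3L
  if (is.null(marker_names)) marker_names <- paste0("M", seq_len(n))
  if (length(marker_names) != n) {
    stopf("%d marker names supplied for %d markers", length(marker_names), n)
  }
  if (is.null(mask)) {
    mask <- matrix(1, nrow(values), ncol(values))
    bad <- !is.finite(values)
    if (any(bad)) {
      for (j in seq_len(n)) {
        cols <- marker_cols(j)
        rows <- which(rowSums(bad[, cols, drop = FALSE]) > 0)
        mask[rows, cols] <- 0
      }
    }
  } else {
    mask <- as.matrix(mask)
    if (!identical(dim(mask), dim(values))) {
      stopf("mask shape (%d x %d) does not match values (%d x %d)",
            nrow(mask), ncol(mask), nrow(values), ncol(values))
    }
    if (!all(mask %in% c(0, 1))) stopf("mask entries must be 0 or 1")
  }
  values[mask == 0] <- 0
  if (any(!is.finite(values))) {
    stopf("non-finite values at observed (mask = 1) entries")
  }
  dimnames(values) <- list(NULL, coordinate_names(marker_names))
  dimnames(mask) <- dimnames(values)
  structure(
    list(values = values, marker_names = marker_names, mask = mask,
         frame_rate = frame_rate),
    class = "motion_sample"
  )
}

coordinate_names <- function(marker_names) {
  as.vector(t(outer(marker_names, c("_x", "_y", "_z"), paste0)))
}

# columns of marker j (1-based)
marker_cols <- function(j) 3L * (j - 1L) + 1:3

#' Number of frames / markers in a motion sample
#' @param sample a `motion_sample`.
#' @return integer count.
#' @export
n_frames <- function(sample) nrow(sample$values)

#' @rdname n_frames
#' @export
n_markers <- function(sample) ncol(sample$values) %/% 3L

#' @export
print.motion_sample <- function(x, ...) {
  miss <- sum(x$mask == 0)
  cat(sprintf(
    "Motion sample: %d frames x %d markers (%d coordinate columns)\n",
    n_frames(x), n_markers(x), ncol(x$values)))
  if (!is.null(x$frame_rate)) cat(sprintf("  frame rate: %g Hz\n", x$frame_rate))
  cat(sprintf("  missing entries: %d (%.2f%%)\n", miss,
              100 * miss / length(x$mask)))
  invisible(x)
}

#' Gap specifications
#'
#' A gap is one marker missing over a contiguous frame interval; a frame gap
#' is a run of frames in which every marker is missing.  Frames are 1-based
#' and the interval `[start, end]` is closed (both endpoints missing), so a
#' gap spans `end - start + 1` frames.
#'
#' @param marker 1-based marker index.
#' @param start,end first and last missing frame (inclusive).
#' @return a `gap_spec` (or `frame_gap_spec`) object.
#' @examples
#' gap_spec(marker = 2, start = 11, end = 390)   # 380-frame gap
#' frame_gap_spec(100, 102)                      # 3 wholly missing frames
#' @export
gap_spec <- function(marker, start, end) {
  if (!is_count(marker) || marker < 1) stopf("'marker' must be a positive integer")
  check_interval(start, end)
  structure(list(marker = as.integer(marker), start = as.integer(start),
                 end = as.integer(end)), class = "gap_spec")
}

#' @rdname gap_spec
#' @export
frame_gap_spec <- function(start, end) {
  check_interval(start, end)
  structure(list(start = as.integer(start), end = as.integer(end)),
            class = "frame_gap_spec")
}

check_interval <- function(start, end) {
  if (!is_count(start) || !is_count(end) || start < 1 || end < start) {
    stopf("invalid frame interval [%s, %s]: need 1 <= start <= end",
          format(start), format(end))
  }
}

gap_length <- function(gap) gap$end - gap$start + 1L

#' @export
print.gap_spec <- function(x, ...) {
  cat(sprintf("Gap: marker %d, frames %d..%d (%d frames)\n",
              x$marker, x$start, x$end, gap_length(x)))
  invisible(x)
}

#' @export
print.frame_gap_spec <- function(x, ...) {
  cat(sprintf("Frame gap: frames %d..%d (%d whole frames missing)\n",
              x$start, x$end, gap_length(x)))
  invisible(x)
}

as_gap_list <- function(gaps) {
  if (inherits(gaps, "gap_spec") || inherits(gaps, "frame_gap_spec")) {
    gaps <- list(gaps)
  }
  if (!is.list(gaps)) stopf("'gaps' must be a gap spec or a list of them")
  gaps
}

check_gap <- function(gap, m, n) {
  if (inherits(gap, "gap_spec")) {
    if (gap$marker > n) {
      stopf("gap marker %d out of range (sample has %d markers)", gap$marker, n)
    }
  } else if (!inherits(gap, "frame_gap_spec")) {
    stopf("expected a gap_spec or frame_gap_spec")
  }
  if (gap$end > m) {
    stopf("gap frames %d..%d out of range (sample has %d frames)",
          gap$start, gap$end, m)
  }
  invisible(gap)
}

#' Apply gaps to a motion sample
#'
#' Returns a copy of `sample` with the mask zeroed (and the values zeroed)
#' over each gap's three coordinate columns and frame interval, emulating the
#' corruption pattern of a test take on a clean sample.  Idempotent; the
#' input is untouched.
#'
#' @param sample a `motion_sample`.
#' @param gaps a `gap_spec`/`frame_gap_spec` or a list of them.
#' @return the gapped `motion_sample`.
#' @examples
#' s <- motion_sample(matrix(rnorm(400 * 6), 400, 6))
#' g <- apply_gaps(s, gap_spec(1, 11, 390))
#' sum(g$mask == 0)  # 3 * 380 masked entries
#' @export
apply_gaps <- function(sample, gaps) {
  stopifnot(inherits(sample, "motion_sample"))
  gaps <- as_gap_list(gaps)
  m <- n_frames(sample)
  n <- n_markers(sample)
  for (gap in gaps) {
    check_gap(gap, m, n)
    rows <- gap$start:gap$end
    cols <- if (inherits(gap, "gap_spec")) marker_cols(gap$marker) else
      seq_len(ncol(sample$values))
    sample$values[rows, cols] <- 0
    sample$mask[rows, cols] <- 0
  }
  sample
}

#' Recover gap specifications from an observation mask
#'
#' Scans the mask of a sample and returns the maximal runs of missing frames
#' per marker as `gap_spec`s (overlapping or adjacent gaps merge into one).
#' `frame_gaps_from_mask()` returns the maximal runs of wholly missing
#' frames as `frame_gap_spec`s.
#'
#' @param sample a `motion_sample`.
#' @return a list of gap specs (possibly empty).
#' @export
gaps_from_mask <- function(sample) {
  stopifnot(inherits(sample, "motion_sample"))
  out <- list()
  for (j in seq_len(n_markers(sample))) {
    missing <- rowSums(sample$mask[, marker_cols(j), drop = FALSE]) == 0
    for (run in runs_of(missing)) {
      out[[length(out) + 1L]] <- gap_spec(j, run[1], run[2])
    }
  }
  out
}

#' @rdname gaps_from_mask
#' @export
frame_gaps_from_mask <- function(sample) {
  stopifnot(inherits(sample, "motion_sample"))
  missing <- rowSums(sample$mask) == 0
  lapply(runs_of(missing), function(run) frame_gap_spec(run[1], run[2]))
}

# maximal runs of TRUE as list of c(start, end)
runs_of <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  lapply(keep, function(i) c(starts[i], ends[i]))
}
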