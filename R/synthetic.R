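#' Synthetic motion configuration
#'
#' The generator emulates the structure the gap regressors exploit in real
#' optical mocap takes: a long multi-marker recording whose coordinate
#' trajectories are smooth and strongly correlated across markers (low
#' rank), observed with small sensor noise, on a known skeleton.  Latent
#' smooth time courses (sinusoids with seeded random frequencies and phases)
#' times a random loading matrix give an exactly rank-`latent_rank` signal;
#' optional `burst` injects a sharp localised oscillation at one marker, the
#' high-fluctuation regime that defeats global least squares and motivates
#' tapering.
#'
#' Defaults mirror a typical optical capture: 41 markers, 400-frame working
#' windows cut from longer recordings, rank well below the 123 coordinate
#' columns, and noise two orders of magnitude below the motion amplitude.
#'
#' @param n_markers number of markers (default 41).
#' @param m_frames number of frames to generate (default 400).
#' @param latent_rank rank of the noiseless signal; must not exceed
#'   `min(m_frames, 3 * n_markers)`.
#' @param noise_sd standard deviation of additive white Gaussian noise, in
#'   position units (default 0.05; the latent signal has entries of order
#'   1).
#' @param skeleton `"chain"` (markers in a line) or `"tree"` (binary tree).
#' @param burst optional localised oscillation:
#'   `list(marker =, start =, end =, amplitude =, frequency =)` with
#'   `frequency` in cycles per frame.
#' @param seed integer seed; all randomness in [generate_motion()] flows
#'   through it.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_markers = 41, m_frames = 400, latent_rank = 8,
                         noise_sd = 0.05, skeleton = c("chain", "tree"),
                         burst = NULL, seed = 1) {
  skeleton <- match.arg(skeleton)
  if (!is_count(n_markers) || n_markers < 2) stopf("'n_markers' must be >= 2")
  if (!is_count(m_frames) || m_frames < 2) stopf("'m_frames' must be >= 2")
  if (!is_count(latent_rank) || latent_rank < 1 ||
      latent_rank > min(m_frames, 3 * n_markers)) {
    stopf("'latent_rank' must be in 1..min(m_frames, 3*n_markers)")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) stopf("'noise_sd' must be >= 0")
  if (!is.null(burst)) {
    need <- c("marker", "start", "end", "amplitude", "frequency")
    if (!all(need %in% names(burst))) {
      stopf("'burst' needs fields: %s", paste(need, collapse = ", "))
    }
    if (burst$marker > n_markers || burst$end > m_frames ||
        burst$start < 1 || burst$start > burst$end) {
      stopf("burst marker/frames out of range")
    }
  }
  structure(
    list(n_markers = as.integer(n_markers), m_frames = as.integer(m_frames),
         latent_rank = as.integer(latent_rank), noise_sd = noise_sd,
         skeleton = skeleton, burst = burst, seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Generate a synthetic motion sample with known skeleton
#'
#' @param config a [synth_config()].
#' @return a list with `sample` (the noisy `motion_sample`), `noiseless`
#'   (the exact low-rank value matrix), `skeleton` (a `skeleton_model`
#'   matching the configured topology) and `config`.  Identical
#'   configurations (including seed) reproduce identical output.
#' @examples
#' gen <- generate_motion(synth_config(n_markers = 8, m_frames = 100,
#'                                     latent_rank = 3, seed = 42))
#' gen$sample
#' @export
generate_motion <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  m <- config$m_frames
  n <- config$n_markers
  r <- config$latent_rank
  out <- withr::with_seed(config$seed, {
    freqs <- runif(r, 0.5, 3)           # cycles over the whole take
    phases <- runif(r, 0, 2 * pi)
    t_norm <- (seq_len(m) - 1) / m
    theta <- vapply(seq_len(r), function(c)
      sin(2 * pi * freqs[c] * t_norm + phases[c]), numeric(m))
    loading <- matrix(rnorm(r * 3L * n), r, 3L * n)
    signal <- theta %*% loading
    if (!is.null(config$burst)) {
      b <- config$burst
      idx <- b$start:b$end
      env <- sin(pi * seq_along(idx) / (length(idx) + 1))^2   # Hann window
      wave <- b$amplitude * sin(2 * pi * b$frequency * seq_along(idx)) * env
      direction <- rnorm(3)
      direction <- direction / sqrt(sum(direction^2))
      signal[idx, marker_cols(b$marker)] <-
        signal[idx, marker_cols(b$marker)] + outer(wave, direction)
    }
    noise <- matrix(rnorm(m * 3L * n, sd = config$noise_sd), m, 3L * n)
    list(noiseless = signal, values = signal + noise)
  })
  edges <- if (config$skeleton == "chain") {
    cbind(seq_len(n - 1L), 2:n)
  } else {
    cbind(2:n, floor((2:n) / 2))
  }
  skeleton <- skeleton_model(edges, markers = paste0("M", seq_len(n)))
  list(
    sample = motion_sample(out$values),
    noiseless = out$noiseless,
    skeleton = skeleton,
    config = config
  )
}

#' Simulate gap placement
#'
#' Reproduces the usual corruption protocols: `"single"` places one gap of
#' `gap_length` frames on one random marker; `"multiple"` places `count`
#' gaps of `gap_length` frames on `count` distinct random markers;
#' `"frames"` removes one run of `count` consecutive whole frames.  Start
#' positions are uniform over the feasible range; a seed makes draws
#' reproducible.
#'
#' @param m,n frame and marker counts of the target sample.
#' @param protocol `"single"`, `"multiple"` or `"frames"`.
#' @param count number of gaps (`"multiple"`) or missing frames
#'   (`"frames"`); ignored for `"single"`.
#' @param gap_length frames per marker gap (ignored for `"frames"`).
#' @param seed optional integer seed.
#' @return a list of `gap_spec`s, or a list holding one `frame_gap_spec`.
#' @export
simulate_gaps <- function(m, n, protocol = c("single", "multiple", "frames"),
                          count = 1, gap_length = NULL, seed = NULL) {
  protocol <- match.arg(protocol)
  draw <- function() {
    switch(protocol,
      single = {
        check_feasible_gap(gap_length, m)
        marker <- sample.int(n, 1)
        start <- sample.int(m - gap_length + 1L, 1)
        list(gap_spec(marker, start, start + gap_length - 1L))
      },
      multiple = {
        check_feasible_gap(gap_length, m)
        if (!is_count(count) || count < 1 || count > n) {
          stopf("'count' must be in 1..%d (distinct markers)", n)
        }
        markers <- sample.int(n, count)
        starts <- sample.int(m - gap_length + 1L, count, replace = TRUE)
        Map(function(j, s) gap_spec(j, s, s + gap_length - 1L),
            markers, starts)
      },
      frames = {
        if (!is_count(count) || count < 1 || count >= m) {
          stopf("'count' missing frames infeasible for %d-frame sample", m)
        }
        start <- sample.int(m - count + 1L, 1)
        list(frame_gap_spec(start, start + count - 1L))
      }
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

check_feasible_gap <- function(gap_length, m) {
  if (is.null(gap_length) || !is_count(gap_length) || gap_length < 1 ||
      gap_length > m) {
    stopf("'gap_length' must be in 1..%d", m)
  }
}

#' Cut training windows from a long sequence
#'
#' @param sequence a `motion_sample`.
#' @param window frames per window.
#' @param count number of windows wanted (`NULL` = as many as fit).
#' @param stride frames between window starts (default `window`:
#'   non-overlapping).
#' @return list of `motion_sample` windows.
#' @export
make_training_windows <- function(sequence, window, count = NULL,
                                  stride = window) {
  stopifnot(inherits(sequence, "motion_sample"))
  m <- n_frames(sequence)
  if (!is_count(window) || window < 1 || window > m) {
    stopf("'window' must be in 1..%d", m)
  }
  if (!is_count(stride) || stride < 1) stopf("'stride' must be >= 1")
  starts <- seq.int(1L, m - window + 1L, by = stride)
  if (!is.null(count)) {
    if (!is_count(count) || count < 1) stopf("'count' must be >= 1")
    if (length(starts) < count) {
      stopf("sequence of %d frames yields only %d windows of %d (stride %d); %d requested",
            m, length(starts), window, stride, count)
    }
    starts <- starts[seq_len(count)]
  }
  lapply(starts, function(s) {
    idx <- s:(s + window - 1L)
    motion_sample(sequence$values[idx, , drop = FALSE],
                  marker_names = sequence$marker_names,
                  mask = sequence$mask[idx, , drop = FALSE],
                  frame_rate = sequence$frame_rate)
  })
}
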