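# shared fixtures: everything is generated in code, seeded

# long low-rank sequence cut into (n_train + 1) windows; the last window is
# the test take.  Windows of global sinusoids share their row span (the
# loading matrix), which the exact-recovery oracles rely on.
lowrank_setup <- function(n_markers = 8, window = 100, n_train = 3,
                          latent_rank = 4, noise_sd = 0, seed = 11,
                          burst = NULL) {
  gen <- generate_motion(synth_config(
    n_markers = n_markers, m_frames = (n_train + 1) * window,
    latent_rank = latent_rank, noise_sd = noise_sd, seed = seed,
    burst = burst))
  wins <- make_training_windows(gen$sample, window = window)
  list(train = wins[seq_len(n_train)], test = wins[[n_train + 1]],
       skeleton = gen$skeleton, gen = gen,
       test_var = var(as.vector(wins[[n_train + 1]]$values)))
}

rel_gap_mse <- function(filled, setup, gapped) {
  mse(filled, setup$test, gapped) / setup$test_var
}

# brute-force shortest path by exhaustive simple-path enumeration
brute_force_distance <- function(edges, weights, from, to) {
  if (from == to) return(0)
  best <- Inf
  walk <- function(node, visited, total) {
    if (total >= best) return()
    if (node == to) { best <<- min(best, total); return() }
    for (e in seq_len(nrow(edges))) {
      nxt <- if (edges[e, 1] == node) edges[e, 2] else
             if (edges[e, 2] == node) edges[e, 1] else next
      if (nxt %in% visited) next
      walk(nxt, c(visited, nxt), total + weights[e])
    }
  }
  walk(from, from, 0)
  best
}

# random spanning tree on n nodes (each node >= 2 attaches to an earlier one)
random_tree_edges <- function(n) {
  cbind(2:n, vapply(2:n, function(i) sample.int(i - 1L, 1), integer(1)))
}

# weighted quadratic objective of the coefficient solve, evaluated directly
alpha_objective <- function(alpha, full, gapped, projectors, w, taper = NULL) {
  total <- 0
  for (i in seq_along(full)) {
    phi <- Reduce(`+`, Map(`*`, alpha, projectors))
    r <- full[[i]] - gapped[[i]] %*% phi
    if (!is.null(taper)) r <- r * taper
    total <- total + sum(sweep(r, 2L, w, `*`) * r)
  }
  total
}

# zero-order hold baseline for whole-frame gaps (repeat nearest observed frame)
zoh_fill <- function(gapped, truth, fg) {
  out <- gapped
  src <- if (fg$start > 1) fg$start - 1L else fg$end + 1L
  out$values[fg$start:fg$end, ] <- rep(truth$values[src, ],
                                       each = fg$end - fg$start + 1L)
  out
}
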