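#' Skeleton connectivity model
#'
#' The spatial term of the taper mask measures how far two markers are on the
#' subject's body, not in space: the distance between markers is the
#' shortest-path length on the skeleton connectivity graph (bones as edges).
#' Edge weights default to 1, i.e. distances are counted in bone hops;
#' per-edge weights (e.g. bone lengths) may be supplied instead.
#'
#' @param edges two-column matrix or data frame of marker pairs (indices or
#'   names), one row per bone.
#' @param markers character vector naming all markers (so that isolated
#'   markers are representable); defaults to the markers appearing in
#'   `edges`, or `M1..Mn` when `edges` is numeric and `n` is inferred.
#' @param weights optional non-negative edge weights, one per row of `edges`.
#' @return an object of class `skeleton_model`.
#' @examples
#' sk <- skeleton_model(cbind(1:4, 2:5))   # 5-marker chain
#' skeleton_distance(sk, 1, 5)             # 4 hops
#' @export
skeleton_model <- function(edges, markers = NULL, weights = NULL) {
  edges <- as.matrix(edges)
  if (ncol(edges) == 3L && is.null(weights)) {
    weights <- as.numeric(edges[, 3])
    edges <- edges[, 1:2, drop = FALSE]
  }
  if (ncol(edges) != 2L) stopf("'edges' must have two columns (marker pairs)")
  if (is.numeric(edges)) {
    n <- if (is.null(markers)) max(edges) else length(markers)
    if (is.null(markers)) markers <- paste0("M", seq_len(n))
    edges <- matrix(markers[as.integer(edges)], ncol = 2L)
  } else {
    edges <- matrix(as.character(edges), ncol = 2L)
    if (is.null(markers)) markers <- sort(unique(as.vector(edges)))
  }
  if (!all(edges %in% markers)) {
    stopf("edge refers to a marker not in 'markers': %s",
          paste(setdiff(as.vector(edges), markers), collapse = ", "))
  }
  if (any(edges[, 1] == edges[, 2])) stopf("self-loop edges are not allowed")
  if (is.null(weights)) weights <- rep(1, nrow(edges))
  if (length(weights) != nrow(edges) || any(weights < 0)) {
    stopf("'weights' must be non-negative, one per edge")
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2], weight = weights),
    directed = FALSE,
    vertices = data.frame(name = markers)
  )
  g <- igraph::simplify(g, edge.attr.comb = "min")
  structure(list(graph = g, markers = markers), class = "skeleton_model")
}

#' @export
print.skeleton_model <- function(x, ...) {
  cat(sprintf("Skeleton: %d markers, %d bones\n",
              length(x$markers), igraph::ecount(x$graph)))
  invisible(x)
}

resolve_marker <- function(skeleton, j) {
  if (is.character(j)) {
    idx <- match(j, skeleton$markers)
    if (anyNA(idx)) stopf("unknown marker '%s'", j[which(is.na(idx))[1]])
    return(idx)
  }
  if (any(j < 1 | j > length(skeleton$markers))) {
    stopf("marker index out of range")
  }
  as.integer(j)
}

#' Shortest-path distance between two markers on the skeleton
#'
#' @param skeleton a `skeleton_model`.
#' @param j1,j2 marker indices or names.
#' @return non-negative shortest-path length under the edge weights.
#' @export
skeleton_distance <- function(skeleton, j1, j2) {
  stopifnot(inherits(skeleton, "skeleton_model"))
  d <- skeleton_distances(skeleton, j1)[resolve_marker(skeleton, j2)]
  unname(d)
}

# distances from one marker to every marker, in marker order
skeleton_distances <- function(skeleton, j) {
  j <- resolve_marker(skeleton, j)
  d <- igraph::distances(skeleton$graph, v = skeleton$markers[j],
                         algorithm = "dijkstra")[1, skeleton$markers]
  if (any(is.infinite(d))) {
    stopf("skeleton is disconnected: no path from marker %d to marker(s) %s",
          j, paste(which(is.infinite(d)), collapse = ", "))
  }
  unname(d)
}

#' Read a skeleton description from file
#'
#' Supports a plain-text edge list (two whitespace-separated columns of
#' marker names or indices, optional third weight column, `#` comments) and
#' YAML with an `edges:` list of pairs and optional `markers:` vector.
#'
#' @param path file path.
#' @param markers optional full marker list overriding the file's.
#' @return a `skeleton_model`.
#' @export
read_skeleton <- function(path, markers = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    doc <- yaml::read_yaml(path)
    if (is.null(doc$edges)) stopf("YAML skeleton needs an 'edges' key")
    edges <- do.call(rbind, lapply(doc$edges, function(e) e[1:2]))
    weights <- vapply(doc$edges, function(e)
      if (length(e) >= 3) as.numeric(e[[3]]) else 1, numeric(1))
    markers <- markers %||% doc$markers
    suppressWarnings({
      num <- matrix(as.numeric(edges), ncol = 2L)
    })
    if (!anyNA(num)) edges <- num
    return(skeleton_model(edges, markers = markers, weights = weights))
  }
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stopf("edge list needs at least two columns")
  weights <- if (ncol(tab) >= 3L) as.numeric(tab[[3]]) else NULL
  edges <- as.matrix(tab[, 1:2])
  suppressWarnings(num <- matrix(as.numeric(edges), ncol = 2L))
  if (!anyNA(num)) edges <- num
  skeleton_model(edges, markers = markers, weights = weights)
}
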