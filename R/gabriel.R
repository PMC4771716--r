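#' Build a Gabriel neighbour graph over site coordinates
#'
#' Two sites are Gabriel neighbours when no third site lies strictly inside
#' the open disk whose diameter is the segment joining them. The resulting
#' binary, symmetric spatial weighting matrix is the input to
#' [mem_basis()]. Coordinates must be planar (projected, e.g. km);
#' distances are Euclidean.
#'
#' A third site exactly on the circle (cocircular) does not block an edge:
#' only the strict interior of the disk counts. This keeps edges on
#' symmetric point layouts such as regular grids.
#'
#' @param sites A data frame with one row per site, or a two-column
#'   coordinate matrix.
#' @param coords Names of the two coordinate columns (ignored when `sites`
#'   is a matrix).
#' @param id Optional name of a column holding unique site labels; row
#'   numbers are used when absent.
#' @return An object of class `gabriel_graph`: a list with `n`, `ids`,
#'   `xy` (n x 2 matrix), `edges` (tibble with `from`, `to`, `from_id`,
#'   `to_id`, `length`), and the dense binary weight matrix `W`.
#' @examples
#' pts <- data.frame(x = c(0, 1, 2), y = c(0, 0, 0))
#' g <- gabriel_graph(pts)
#' tidy(g)   # the long edge 1-3 is blocked by the midpoint
#' @seealso [graph_components()], [mem_basis()]
#' @export
gabriel_graph <- function(sites, coords = c("x", "y"), id = NULL) {
  if (is.matrix(sites)) {
    xy <- sites
    ids <- rownames(sites) %||% as.character(seq_len(nrow(sites)))
  } else {
    xy <- as_num_matrix(sites, coords, "coordinate table")
    ids <- if (!is.null(id)) as.character(sites[[id]]) else
      as.character(seq_len(nrow(sites)))
  }
  if (ncol(xy) != 2) abort("coordinates must have exactly two columns")
  n <- nrow(xy)
  if (n < 3) abort("Gabriel graph construction needs at least 3 sites")
  if (anyDuplicated(ids)) abort("site ids must be unique")

  dup <- duplicated(xy) | duplicated(xy, fromLast = TRUE)
  if (any(dup)) {
    abort(sprintf("duplicate coordinates for sites: %s",
                  paste(ids[dup], collapse = ", ")))
  }

  d2 <- as.matrix(stats::dist(xy))^2
  # Min-plus self-product: mp[i, j] = min_k d2[i, k] + d2[k, j]. A pair is
  # blocked iff some third point gives a strictly smaller sum than d2[i, j]
  # (the open-disk criterion); k = i or j contributes exactly d2[i, j] and
  # therefore never blocks under the strict inequality.
  mp <- matrix(Inf, n, n)
  for (k in seq_len(n)) mp <- pmin(mp, outer(d2[, k], d2[k, ], "+"))
  keep <- (mp >= d2) & upper.tri(d2)

  idx <- which(keep, arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  edges <- tibble::tibble(
    from = idx[, 1], to = idx[, 2],
    from_id = ids[idx[, 1]], to_id = ids[idx[, 2]],
    length = sqrt(d2[idx])
  )

  W <- matrix(0, n, n)
  W[idx] <- 1
  W <- W + t(W)
  dimnames(W) <- list(ids, ids)

  structure(
    list(n = n, ids = ids, xy = xy, edges = edges, W = W),
    class = "gabriel_graph"
  )
}

#' @export
print.gabriel_graph <- function(x, ...) {
  comp <- graph_components(x)
  cat(sprintf(
    "Gabriel graph: %d sites, %d edges, %d connected component(s)\n",
    x$n, nrow(x$edges), max(comp$component)))
  invisible(x)
}

#' Connected components of a spatial graph
#'
#' The MEM construction assumes one connected graph (a connected graph on n
#' sites carries n - 1 spatial eigenvectors); this labels components so that
#' disconnection is caught early and reported by site.
#'
#' @param graph A [gabriel_graph()] object.
#' @return A tibble with `site`, `site_id` and integer `component` labels
#'   (component 1 is the largest).
#' @export
graph_components <- function(graph) {
  stopifnot(inherits(graph, "gabriel_graph"))
  ig <- igraph::graph_from_edgelist(
    as.matrix(graph$edges[, c("from", "to")]), directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0L, graph$n - igraph::vcount(ig)))
  memb <- igraph::components(ig)$membership
  sizes <- table(memb)
  relabel <- stats::setNames(rank(-as.numeric(sizes), ties.method = "first"),
                             names(sizes))
  tibble::tibble(
    site = seq_len(graph$n),
    site_id = graph$ids,
    component = as.integer(relabel[as.character(memb)])
  )
}

#' @describeIn gabriel_graph Tidy the edge list (one row per edge,
#'   lexicographically sorted site pairs).
#' @param x A `gabriel_graph` object.
#' @param ... Unused.
#' @method tidy gabriel_graph
#' @export
tidy.gabriel_graph <- function(x, ...) {
  dplyr::arrange(x$edges, .data$from_id, .data$to_id)
}

#' Write a Gabriel edge list as a two-column CSV
#'
#' @param graph A [gabriel_graph()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edges_csv <- function(graph, path) {
  ed <- tidy(graph)[, c("from_id", "to_id")]
  names(ed) <- c("site_id_a", "site_id_b")
  readr::write_csv(ed, path)
  invisible(path)
}
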