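#' Moran's Eigenvector Maps from a spatial graph
#'
#' Eigendecomposes the doubly centred spatial weighting matrix
#' \eqn{\Omega = H W H}, \eqn{H = I - \mathbf{1}\mathbf{1}'/n}, where W is
#' the binary Gabriel adjacency. The eigenvectors (MEMs) form an orthonormal
#' basis of the centred site space, ordered from the most positively
#' autocorrelated (very broad scale, large positive eigenvalue and Moran's I)
#' to the most negatively autocorrelated (very fine scale). A connected graph
#' always yields exactly n - 1 eigenvectors: the structural null eigenvalue
#' belongs to the constant vector, and any further exact-zero eigenvalues
#' (possible on symmetric layouts) correspond to genuine spatial patterns
#' with zero autocorrelation, which are recovered from the centred null
#' space and kept with eigenvalue 0.
#'
#' Eigenvalues with \eqn{|\lambda| \le 10^{-9} \max|\lambda|} are treated as
#' exactly zero. Each eigenvector's sign is fixed so its largest-magnitude
#' entry is positive, and ties in eigenvalue are ordered by the vectors' first
#' differing coordinate, making the basis deterministic across platforms.
#'
#' @param graph A connected [gabriel_graph()] object.
#' @return An object of class `mem_basis`: list with `vectors`
#'   (n x (n-1) matrix, unit-norm columns `MEM1..`), `values` (eigenvalues,
#'   descending), `morans_i` (Moran's I of each vector, equal to
#'   \eqn{n\lambda_k/\sum W}), `n`, `sum_w`, and the originating `graph`.
#' @examples
#' g <- gabriel_graph(data.frame(x = c(0, 1, 2, 3), y = c(0, 0.1, 0, 0.1)))
#' b <- mem_basis(g)
#' tidy(b)
#' @export
mem_basis <- function(graph) {
  stopifnot(inherits(graph, "gabriel_graph"))
  n <- graph$n
  if (n < 3) abort("MEM construction needs at least 3 sites")
  comp <- graph_components(graph)
  if (max(comp$component) > 1) {
    tab <- table(comp$component)
    abort(sprintf(
      "graph is disconnected (%d components of sizes %s); MEMs need one connected graph",
      length(tab), paste(tab, collapse = ", ")))
  }
  W <- graph$W
  Wc <- centre_cols(t(centre_cols(W)))   # H W H for symmetric W
  e <- eigen(Wc, symmetric = TRUE)
  keep <- abs(e$values) > 1e-9 * max(abs(e$values))
  vals <- e$values[keep]
  vecs <- e$vectors[, keep, drop = FALSE]

  # The null space of HWH always contains the constant vector; on symmetric
  # layouts (e.g. a 3-site path) it can also hold genuine spatial patterns
  # with exactly zero autocorrelation. Recover those by centring the null
  # eigenvectors and orthonormalising: a connected graph then always carries
  # the full n - 1 spatial eigenvectors, the zero-I ones sitting between the
  # positive and negative Moran's I blocks.
  if (ncol(vecs) < n - 1) {
    null_vecs <- e$vectors[, !keep, drop = FALSE]
    Nc <- centre_cols(null_vecs)
    qrn <- qr(Nc, tol = 1e-7)
    k <- qrn$rank
    if (k > 0) {
      extra <- qr.Q(qrn)[, seq_len(k), drop = FALSE]
      vecs <- cbind(vecs, extra)
      vals <- c(vals, rep(0, k))
    }
  }

  # deterministic sign: largest-magnitude entry positive
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  # deterministic order within eigenvalue ties
  ord <- order(-vals)
  r <- rle(round(vals[ord], 12))
  if (any(r$lengths > 1)) {
    stop_at <- cumsum(r$lengths)
    for (t in which(r$lengths > 1)) {
      block <- ord[seq(stop_at[t] - r$lengths[t] + 1, stop_at[t])]
      key <- apply(vecs[, block, drop = FALSE], 2, paste, collapse = ",")
      ord[seq(stop_at[t] - r$lengths[t] + 1, stop_at[t])] <- block[order(key)]
    }
  }
  vals <- vals[ord]
  vecs <- vecs[, ord, drop = FALSE]
  colnames(vecs) <- paste0("MEM", seq_len(ncol(vecs)))
  rownames(vecs) <- graph$ids

  sum_w <- sum(W)
  structure(
    list(vectors = vecs, values = vals,
         morans_i = n * vals / sum_w,
         n = n, sum_w = sum_w, graph = graph),
    class = "mem_basis"
  )
}

#' @export
print.mem_basis <- function(x, ...) {
  cat(sprintf(
    "MEM basis: %d eigenvectors over %d sites (%d positive, %d negative Moran's I)\n",
    ncol(x$vectors), x$n, sum(x$morans_i > 0), sum(x$morans_i < 0)))
  invisible(x)
}

#' @describeIn mem_basis One row per eigenvector: `mem`, `eigenvalue`,
#'   `morans_i`, and the broad/fine `scale` label from the sign of Moran's I.
#' @param x A `mem_basis` object.
#' @param ... Unused.
#' @method tidy mem_basis
#' @export
tidy.mem_basis <- function(x, ...) {
  tibble::tibble(
    mem = colnames(x$vectors),
    eigenvalue = x$values,
    morans_i = x$morans_i,
    scale = ifelse(x$morans_i > 0, "broad_medium", "fine")
  )
}

#' Moran's I spatial autocorrelation coefficient
#'
#' \deqn{I = \frac{n}{\sum_{ij} w_{ij}} \cdot
#'   \frac{\sum_{ij} w_{ij} (x_i - \bar x)(x_j - \bar x)}
#'        {\sum_i (x_i - \bar x)^2}}
#'
#' Positive values indicate smooth broad-scale structure, negative values
#' fine-grained alternation between neighbours.
#'
#' @param x A numeric vector of site-indexed values (non-constant).
#' @param graph A [gabriel_graph()] object over the same sites.
#' @return A single number.
#' @export
morans_i <- function(x, graph) {
  stopifnot(inherits(graph, "gabriel_graph"))
  if (length(x) != graph$n) abort("`x` must have one value per site")
  xc <- x - mean(x)
  ssq <- sum(xc^2)
  if (ssq == 0) abort("`x` is constant: Moran's I is undefined (zero variance)")
  (graph$n / sum(graph$W)) * drop(crossprod(xc, graph$W %*% xc)) / ssq
}

#' Split a MEM basis by the sign of Moran's I
#'
#' Partitions the eigenvectors into broad-to-medium scale patterns (positive
#' Moran's I) and fine scale patterns (negative Moran's I). Vectors with
#' |Moran's I| below `tol` are assigned to the fine subset with a warning.
#'
#' @param basis A [mem_basis()] object.
#' @param tol Tolerance below which Moran's I counts as zero.
#' @return A list with matrices `broad_medium` and `fine` (either may have
#'   zero columns); column names are kept so subsets can be traced back.
#' @export
mem_split <- function(basis, tol = 1e-12) {
  stopifnot(inherits(basis, "mem_basis"))
  zero <- abs(basis$morans_i) < tol
  if (any(zero)) {
    warn(sprintf("%d MEM(s) with |Moran's I| < %g assigned to the fine-scale subset",
                 sum(zero), tol))
  }
  broad <- basis$morans_i >= tol
  list(
    broad_medium = basis$vectors[, broad, drop = FALSE],
    fine = basis$vectors[, !broad, drop = FALSE]
  )
}

#' Export a MEM basis as CSV plus a JSON sidecar
#'
#' Writes the sites-by-vectors matrix to `path` and the eigenvalues with
#' Moran's I to `paste0(path, ".json")`.
#'
#' @param basis A [mem_basis()] object.
#' @param path CSV output path.
#' @return Paths of the written files, invisibly.
#' @export
write_mem_csv <- function(basis, path) {
  df <- tibble::as_tibble(basis$vectors)
  df <- dplyr::bind_cols(tibble::tibble(site_id = rownames(basis$vectors)), df)
  readr::write_csv(df, path)
  side <- paste0(path, ".json")
  jsonlite::write_json(
    list(n = basis$n, sum_w = basis$sum_w,
         eigenvalues = basis$values, morans_i = basis$morans_i),
    side, auto_unbox = TRUE, digits = NA)
  invisible(c(path, side))
}
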