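# Independent brute-force oracles and small fixture builders.

# Literal O(n^3) Gabriel test: edge (i, j) present iff no third point lies
# strictly inside the open disk with diameter ij.
brute_gabriel_edges <- function(xy) {
  n <- nrow(xy)
  out <- NULL
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      dij <- sum((xy[i, ] - xy[j, ])^2)
      blocked <- FALSE
      for (k in seq_len(n)) {
        if (k == i || k == j) next
        if (sum((xy[i, ] - xy[k, ])^2) + sum((xy[j, ] - xy[k, ])^2) < dij) {
          blocked <- TRUE
          break
        }
      }
      if (!blocked) out <- rbind(out, c(i, j))
    }
  }
  out
}

# Breadth-first component labelling from an edge matrix.
bfs_components <- function(edges, n) {
  adj <- vector("list", n)
  if (!is.null(edges)) {
    for (r in seq_len(nrow(edges))) {
      i <- edges[r, 1]; j <- edges[r, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  lab <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(lab[s])) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      for (w in adj[[v]]) {
        if (is.na(lab[w])) {
          lab[w] <- cur
          queue <- c(queue, w)
        }
      }
    }
  }
  lab
}

# Random point set with a connected Gabriel graph.
random_sites <- function(n, seed, extent = c(100, 100)) {
  withr::with_seed(seed, {
    data.frame(x = runif(n, 0, extent[1]), y = runif(n, 0, extent[2]))
  })
}

random_mem <- function(n, seed) {
  mem_basis(gabriel_graph(random_sites(n, seed)))
}

# Small random count community (positive row and column totals).
random_counts <- function(n, s, seed) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n * s, 5) + rbinom(n * s, 1, 0.5), n, s)
    m[cbind(seq_len(n), sample(s, n, replace = TRUE))] <-
      m[cbind(seq_len(n), sample(s, n, replace = TRUE))] + 1L
    colnames(m) <- paste0("sp", seq_len(s))
    as.data.frame(m)
  })
}

# Explicit hat-matrix RDA oracle: fitted values and R2 from the normal
# equations, no QR sharing with the implementation.
hat_rda_oracle <- function(Y, X, standardise = TRUE) {
  Yc <- scale(as.matrix(Y), scale = FALSE)
  Xm <- as.matrix(X)
  Xc <- if (standardise) scale(Xm) else scale(Xm, scale = FALSE)
  H <- Xc %*% solve(crossprod(Xc)) %*% t(Xc)
  fitted <- H %*% Yc
  list(fitted = fitted, r2 = sum(fitted^2) / sum(Yc^2))
}

# Greedy forward path by exhaustive R2 evaluation (no permutation stops).
greedy_forward_oracle <- function(Y, X) {
  Yc <- scale(as.matrix(Y), scale = FALSE)
  Xs <- scale(as.matrix(X))
  ssy <- sum(Yc^2)
  sel <- integer(0)
  repeat {
    rest <- setdiff(seq_len(ncol(Xs)), sel)
    if (length(rest) == 0) break
    r2s <- vapply(rest, function(j) {
      hat_rda_oracle(Yc, Xs[, c(sel, j), drop = FALSE], standardise = FALSE)$r2
    }, numeric(1))
    sel <- c(sel, rest[which.max(r2s)])
  }
  colnames(X)[sel]
}
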