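#' Project axis scores onto the MEM basis (raw scalogram)
#'
#' For centred site scores s and orthonormal MEMs \eqn{v_k}, the fraction of
#' the score variance carried by each spatial eigenvector is
#' \eqn{R^2_k = (v_k's)^2 / (s's)}. Because the MEMs form an orthonormal
#' basis of the centred space, the fractions sum to one: the scalogram is the
#' exact decomposition of an ordination axis across spatial scales, from very
#' broad (first MEMs, positive Moran's I) to very fine (last MEMs).
#'
#' @param scores Numeric vector of site scores, centred (|mean| below 1e-8
#'   relative to the score spread) and non-constant; typically a column of
#'   [ord_scores()].
#' @param basis A [mem_basis()] object over the same sites.
#' @return A tibble with `mem`, `eigenvalue`, `morans_i`, `r2`.
#' @export
mem_scalogram <- function(scores, basis) {
  stopifnot(inherits(basis, "mem_basis"))
  s <- as.numeric(scores)
  if (length(s) != basis$n) abort("`scores` must have one value per site")
  if (sd(s) == 0) abort("`scores` is constant; scalogram undefined")
  if (abs(mean(s)) > 1e-8 * max(1, sd(s))) {
    abort("`scores` must be centred (use ordination site scores)")
  }
  proj <- as.numeric(crossprod(basis$vectors, s))
  tibble::tibble(
    mem = colnames(basis$vectors),
    eigenvalue = basis$values,
    morans_i = basis$morans_i,
    r2 = proj^2 / sum(s^2)
  )
}

# Block index for smoothing: `k` values into `g` consecutive blocks of
# near-equal size, earlier (broader-scale) blocks taking the extras.
smooth_groups <- function(k, g) {
  sizes <- rep(k %/% g, g)
  extra <- k %% g
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  rep(seq_len(g), times = sizes)
}

#' Smooth a raw scalogram into consecutive spatial components
#'
#' Sums the per-MEM fractions over `n_groups` consecutive blocks of
#' (near-)equal size, in eigenvalue order, giving a coarse gradient from very
#' broad (component 1) to very fine (component `n_groups`) scales. With 328
#' MEMs and 8 groups each block holds exactly 41 successive MEMs. Block sums
#' preserve the total, so the smoothed values still sum to one for centred
#' scores.
#'
#' @param r2 Numeric vector of per-MEM fractions (the `r2` column of
#'   [mem_scalogram()]), in eigenvalue order.
#' @param n_groups Number of spatial components (default 8).
#' @return A tibble with `component`, `n_mems`, `r2`.
#' @export
smooth_scalogram <- function(r2, n_groups = 8) {
  r2 <- as.numeric(r2)
  if (n_groups < 1 || n_groups > length(r2)) {
    abort(sprintf("`n_groups` must be between 1 and %d", length(r2)))
  }
  grp <- smooth_groups(length(r2), n_groups)
  tibble::tibble(
    component = seq_len(n_groups),
    n_mems = tabulate(grp, n_groups),
    r2 = as.numeric(rowsum(r2, grp))
  )
}

#' Permutation test of the maximal smoothed scalogram component
#'
#' Tests whether the largest smoothed component (R2max - the spatial scale at
#' which an axis is mainly structured) exceeds what spatially unstructured
#' scores produce. The null is built by randomly permuting the score values
#' across sites, which destroys any spatial arrangement while keeping the
#' value distribution; each permutation yields a full smoothed scalogram and
#' its maximum. Under this null the per-MEM fractions are exchangeable, so
#' the smoothed components are near-uniform.
#'
#' @inheritParams mem_scalogram
#' @param n_groups Number of smoothed components (default 8).
#' @param nperm Number of permutations (default 999).
#' @param seed Seed for the permutation stream.
#' @return An object of class `scalogram`: per-MEM table, smoothed table with
#'   the per-component 95% upper null quantile (`null_q95`), the observed
#'   `r2max` with its `component`, the permutation `p_value`
#'   `(1 + #(max_perm >= max_obs)) / (nperm + 1)`, `nperm`, `n_groups`,
#'   `seed`.
#' @export
r2max_test <- function(scores, basis, n_groups = 8, nperm = 999, seed = NULL) {
  if (nperm < 1) abort("`nperm` must be at least 1")
  per_mem <- mem_scalogram(scores, basis)
  smoothed <- smooth_scalogram(per_mem$r2, n_groups)
  obs_max <- max(smoothed$r2)
  obs_comp <- smoothed$component[which.max(smoothed$r2)]

  s <- as.numeric(scores)
  ssq <- sum(s^2)
  Vt <- t(basis$vectors)
  grp <- smooth_groups(nrow(per_mem), n_groups)
  null_mat <- with_seed(seed, {
    vapply(seq_len(nperm), function(i) {
      proj <- Vt %*% s[sample.int(length(s))]
      as.numeric(rowsum(proj^2 / ssq, grp))
    }, numeric(n_groups))
  })
  null_max <- apply(null_mat, 2, max)
  smoothed$null_q95 <- apply(null_mat, 1, quantile, probs = 0.95, names = FALSE)

  structure(
    list(per_mem = per_mem, smoothed = smoothed,
         r2max = obs_max, component = obs_comp,
         p_value = (1 + sum(null_max >= obs_max)) / (nperm + 1),
         nperm = nperm, n_groups = n_groups, seed = seed),
    class = "scalogram"
  )
}

#' @export
print.scalogram <- function(x, ...) {
  cat(sprintf(
    "Scalogram: R2max = %.3f at component %d of %d (p = %.4g, %d permutations)\n",
    x$r2max, x$component, x$n_groups, x$p_value, x$nperm))
  invisible(x)
}

#' @describeIn r2max_test Smoothed component table (`component`, `n_mems`,
#'   `r2`, `null_q95`).
#' @param x A `scalogram` object.
#' @param ... Unused.
#' @method tidy scalogram
#' @export
tidy.scalogram <- function(x, ...) x$smoothed

#' @describeIn r2max_test One-row summary (`r2max`, `component`, `p_value`,
#'   `n_groups`, `nperm`).
#' @method glance scalogram
#' @export
glance.scalogram <- function(x, ...) {
  tibble::tibble(
    r2max = x$r2max, component = x$component, p_value = x$p_value,
    n_groups = x$n_groups, nperm = x$nperm
  )
}

#' Write a scalogram as CSV plus JSON summary
#'
#' The CSV holds the smoothed components (component, r2, null 95% limit);
#' the JSON sidecar records R2max, its component, the p-value, seed and
#' permutation count.
#'
#' @param x A `scalogram` object.
#' @param path CSV output path.
#' @return Paths written, invisibly.
#' @export
write_scalogram_csv <- function(x, path) {
  stopifnot(inherits(x, "scalogram"))
  readr::write_csv(x$smoothed, path)
  side <- paste0(path, ".json")
  jsonlite::write_json(
    list(r2max = x$r2max, component = x$component, p_value = x$p_value,
         n_groups = x$n_groups, nperm = x$nperm, seed = x$seed),
    side, auto_unbox = TRUE, digits = NA)
  invisible(c(path, side))
}
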