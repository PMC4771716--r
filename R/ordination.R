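#' Principal component analysis of a (transformed) community table
#'
#' Column-centred singular value decomposition. Eigenvalues are squared
#' singular values divided by n - 1; site scores are reported in scaling 1
#' (distance-preserving, `U %*% diag(d)`), and each axis sign is fixed so the
#' species loading of largest magnitude is positive.
#'
#' @param y A data frame or matrix of transformed abundances (sites x
#'   species), e.g. from [hellinger_transform()].
#' @param species Optional column subset.
#' @return An object of class `ordination` (kind `"pca"`) with eigenvalues,
#'   per-axis variance proportions, site scores, species loadings and total
#'   inertia. Use [tidy()] / [glance()] / [ord_scores()] to extract pieces.
#' @examples
#' y <- hellinger_transform(data.frame(a = rpois(20, 8), b = rpois(20, 2)))
#' fit <- fit_pca(y)
#' glance(fit)
#' @export
fit_pca <- function(y, species = NULL) {
  Y <- as_num_matrix(y, species, "community table")
  if (nrow(Y) <= 1) abort("PCA needs more than one site")
  Yc <- centre_cols(Y)
  new_ordination(Yc, kind = "pca",
                 total_inertia = ss_total(Yc) / (nrow(Yc) - 1),
                 transform = attr(y, "transform"))
}

# Shared SVD core: decompose `M` (already centred), attach accounting
# relative to `total_inertia` (variance units, divisor n - 1). `zero_scale`
# anchors the rank cut-off: axes with singular values below 1e-9 of it are
# noise (needed when M itself may be numerically zero, e.g. PRA residuals
# of a saturated model).
new_ordination <- function(M, kind, total_inertia, X = NULL, r2 = NULL,
                           adj_r2 = NULL, wa_space = NULL, transform = NULL,
                           zero_scale = NULL) {
  n <- nrow(M)
  sv <- svd(M)
  ref <- max(sv$d[1], zero_scale %||% 0, .Machine$double.eps)
  keep <- sv$d > ref * 1e-9
  if (sv$d[1] == 0) keep <- rep(FALSE, length(sv$d))
  d <- sv$d[keep]
  U <- sv$u[, keep, drop = FALSE]
  V <- sv$v[, keep, drop = FALSE]
  # axis sign: largest-magnitude species loading positive
  for (j in seq_along(d)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) {
      V[, j] <- -V[, j]
      U[, j] <- -U[, j]
    }
  }
  eig <- d^2 / max(1, n - 1)
  scores <- U %*% diag(d, length(d))
  axes <- paste0(toupper(kind), seq_along(d))
  wa <- if (is.null(wa_space)) NULL else wa_space %*% V
  if (length(d) > 0) {
    colnames(scores) <- axes
    if (!is.null(colnames(M))) rownames(V) <- colnames(M)
    colnames(V) <- axes
    if (!is.null(wa)) colnames(wa) <- axes
  }
  structure(
    list(kind = kind, eigenvalues = eig,
         prop_total = if (total_inertia > 0) eig / total_inertia else eig * 0,
         prop_axes = if (sum(eig) > 0) eig / sum(eig) else eig * 0,
         scores = scores, wa_scores = wa, loadings = V,
         total_inertia = total_inertia, n = n,
         r2 = r2, adj_r2 = adj_r2, transform = transform),
    class = "ordination"
  )
}

#' Redundancy analysis (RDA)
#'
#' PCA of the fitted values of a multivariate linear regression of the
#' (centred) community table on the explanatory variables: constrained
#' ordination. Explanatory columns are standardised to zero mean and unit
#' variance by default (mixed units; R-squared is unaffected). Site scores
#' are the fitted "LC" scores (the constrained pattern itself); weighted-
#' average "WA" scores (observed table projected on the canonical axes) are
#' also stored.
#'
#' @param y Transformed community table (sites x species).
#' @param x Explanatory data frame or matrix (sites x variables), full
#'   column rank, with n > m + 1.
#' @param species,vars Optional column subsets for `y` and `x`.
#' @param standardise Standardise explanatory columns first (default TRUE).
#' @return An `ordination` of kind `"rda"`, carrying `r2`
#'   (SS(fitted)/SS(total)) and the Ezekiel-adjusted `adj_r2`.
#' @export
fit_rda <- function(y, x, species = NULL, vars = NULL, standardise = TRUE) {
  Y <- as_num_matrix(y, species, "community table")
  X <- as_num_matrix(x, vars, "explanatory table")
  if (nrow(X) != nrow(Y)) abort("y and x must have the same number of rows")
  n <- nrow(Y)
  m <- ncol(X)
  if (n <= m + 1) {
    abort(sprintf("RDA needs n > m + 1 (n = %d sites, m = %d variables)", n, m))
  }
  Xc <- if (standardise) standardise_cols(X) else centre_cols(X)
  Q <- ortho_basis(Xc, "explanatory table")
  Yc <- centre_cols(Y)
  fitted <- Q %*% crossprod(Q, Yc)
  ssy <- ss_total(Yc)
  r2 <- if (ssy > 0) min(1, ss_total(fitted) / ssy) else 0
  new_ordination(fitted, kind = "rda",
                 total_inertia = ssy / (n - 1),
                 r2 = r2, adj_r2 = adjusted_r2(r2, n, m),
                 wa_space = Yc, transform = attr(y, "transform"))
}

#' Residuals of the community table after removing explanatory effects
#'
#' Multivariate least-squares residuals \eqn{R = Y_c - \hat Y}; every column
#' of R is orthogonal to every centred explanatory column, and
#' SS(Y) = SS(fitted) + SS(R).
#'
#' @inheritParams fit_rda
#' @return A tibble of residuals (same species columns as `y`).
#' @export
partial_residuals <- function(y, x, species = NULL, vars = NULL,
                              standardise = TRUE) {
  Y <- as_num_matrix(y, species, "community table")
  X <- as_num_matrix(x, vars, "explanatory table")
  if (nrow(X) != nrow(Y)) abort("y and x must have the same number of rows")
  if (nrow(Y) <= ncol(X) + 1) abort("needs n > m + 1")
  Xc <- if (standardise) standardise_cols(X) else centre_cols(X)
  Q <- ortho_basis(Xc, "explanatory table")
  Yc <- centre_cols(Y)
  R <- Yc - Q %*% crossprod(Q, Yc)
  res <- tibble::as_tibble(as.data.frame(R))
  attr(res, "transform") <- attr(y, "transform")
  res
}

#' Partial residual analysis (PRA)
#'
#' PCA of the residual table left after regressing the community table on
#' the explanatory variables: the ordination of the variance the
#' environmental model does not explain. Its total inertia equals
#' (1 - R-squared) times the unconstrained PCA inertia.
#'
#' @inheritParams fit_rda
#' @return An `ordination` of kind `"pra"`.
#' @export
fit_pra <- function(y, x, species = NULL, vars = NULL, standardise = TRUE) {
  R <- partial_residuals(y, x, species, vars, standardise)
  Rm <- as.matrix(R)
  Yc <- centre_cols(as_num_matrix(y, species, "community table"))
  new_ordination(Rm, kind = "pra",
                 total_inertia = ss_total(Rm) / (nrow(Rm) - 1),
                 transform = attr(y, "transform"),
                 zero_scale = sqrt(ss_total(Yc)))
}

#' Ezekiel's adjusted R-squared
#'
#' \deqn{R^2_a = 1 - (1 - R^2) \frac{n - 1}{n - m - 1}}
#'
#' Corrects the explained fraction for the number of fitted explanatory
#' variables; may be negative for weak models.
#'
#' @param r2 Unadjusted R-squared in `[0, 1]`.
#' @param n Number of sites.
#' @param m Number of explanatory variables.
#' @return A single number.
#' @examples
#' adjusted_r2(0.46, 329, 10)  # 0.443
#' @export
adjusted_r2 <- function(r2, n, m) {
  check_scalar(r2, "r2")
  if (r2 < 0 || r2 > 1) abort("`r2` must lie in [0, 1]")
  if (n <= m + 1) abort(sprintf("adjusted R2 needs n > m + 1 (n = %d, m = %d)", n, m))
  1 - (1 - r2) * (n - 1) / (n - m - 1)
}

#' Permutation test of the RDA R-squared
#'
#' Rows of the community table are permuted `nperm` times and the canonical
#' R-squared recomputed; the p-value is
#' `(1 + #(R2_perm >= R2_obs)) / (nperm + 1)`.
#'
#' @inheritParams fit_rda
#' @param nperm Number of permutations (999 by default).
#' @param seed Seed for the permutation stream (reproducible when set).
#' @return A one-row tibble: `r2`, `adj_r2`, `p_value`, `nperm`.
#' @export
rda_perm_test <- function(y, x, species = NULL, vars = NULL, nperm = 999,
                          seed = NULL, standardise = TRUE) {
  if (nperm < 1) abort("`nperm` must be at least 1")
  Y <- as_num_matrix(y, species, "community table")
  X <- as_num_matrix(x, vars, "explanatory table")
  if (nrow(X) != nrow(Y)) abort("y and x must have the same number of rows")
  n <- nrow(Y)
  if (n <= ncol(X) + 1) abort("needs n > m + 1")
  Xc <- if (standardise) standardise_cols(X) else centre_cols(X)
  Q <- ortho_basis(Xc, "explanatory table")
  Yc <- centre_cols(Y)
  ssy <- ss_total(Yc)
  r2_of <- function(M) min(1, ss_total(crossprod(Q, M)) / ssy)
  r2_obs <- r2_of(Yc)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(nperm), function(i) {
      r2_of(Yc[sample.int(n), , drop = FALSE])
    }, numeric(1)) >= r2_obs)
  })
  tibble::tibble(
    r2 = r2_obs,
    adj_r2 = adjusted_r2(r2_obs, n, ncol(X)),
    p_value = (1 + exceed) / (nperm + 1),
    nperm = nperm
  )
}

#' Extract ordination site scores
#'
#' @param ord An [fit_pca()]/[fit_rda()]/[fit_pra()] result.
#' @param axes Which axes (default first two).
#' @param type For RDA, `"lc"` (fitted/constrained, default) or `"wa"`
#'   (weighted-average) site scores.
#' @return A tibble with `site` and one column per requested axis.
#' @export
ord_scores <- function(ord, axes = 1:2, type = c("lc", "wa")) {
  stopifnot(inherits(ord, "ordination"))
  type <- match.arg(type)
  sc <- if (type == "wa" && !is.null(ord$wa_scores)) ord$wa_scores else ord$scores
  axes <- axes[axes <= ncol(sc)]
  out <- tibble::as_tibble(as.data.frame(sc[, axes, drop = FALSE]))
  dplyr::bind_cols(tibble::tibble(site = seq_len(nrow(sc))), out)
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("%s ordination: %d sites, %d axes, total inertia %.4g\n",
              toupper(x$kind), x$n, length(x$eigenvalues), x$total_inertia))
  if (!is.null(x$r2)) {
    cat(sprintf("  constrained R2 = %.4f (adjusted %.4f)\n", x$r2, x$adj_r2))
  }
  k <- min(2, length(x$eigenvalues))
  if (k > 0) {
    cat(sprintf("  axis %d: %.1f%% of %s\n", seq_len(k),
                100 * x$prop_axes[seq_len(k)],
                if (x$kind == "rda") "constrained variance" else "total variance"),
        sep = "")
  }
  invisible(x)
}

#' @describeIn fit_pca One row per axis: eigenvalue, share of total inertia,
#'   share of the decomposed (constrained, for RDA) variance, cumulative share.
#' @param x An `ordination` object.
#' @param ... Unused.
#' @method tidy ordination
#' @export
tidy.ordination <- function(x, ...) {
  tibble::tibble(
    axis = colnames(x$scores),
    eigenvalue = x$eigenvalues,
    prop_total = x$prop_total,
    prop_axes = x$prop_axes,
    cum_prop_axes = cumsum(x$prop_axes)
  )
}

#' @describeIn fit_pca One-row model summary (kind, n, axes, inertia, R2).
#' @method glance ordination
#' @export
glance.ordination <- function(x, ...) {
  tibble::tibble(
    kind = x$kind,
    n = x$n,
    n_axes = length(x$eigenvalues),
    total_inertia = x$total_inertia,
    r2 = x$r2 %||% NA_real_,
    adj_r2 = x$adj_r2 %||% NA_real_
  )
}
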