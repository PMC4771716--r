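# Forward selection and variation partitioning for constrained ordination.

# R-squared of the RDA of centred Yc on an orthonormal basis Q.
r2_proj <- function(Q, Yc, ssy) {
  if (is.null(Q) || ncol(Q) == 0) return(0)
  ss_total(crossprod(Q, Yc)) / ssy
}

#' Forward selection of explanatory variables with a double stopping rule
#'
#' Iteratively adds the candidate variable that most increases the canonical
#' R-squared of the community table. A candidate is admitted only if (a) its
#' marginal permutation p-value is at or below `alpha` and (b) the cumulative
#' adjusted R-squared of the selected set does not exceed the adjusted
#' R-squared of the global model containing every candidate. Selection stops
#' at the first candidate failing either criterion (or when candidates are
#' exhausted). The double rule protects against the inflated type I error
#' and overfitting of classical forward selection in canonical ordination.
#'
#' The marginal test statistic is the pseudo-F of the candidate given the
#' already-selected variables; its null distribution is obtained by permuting
#' the rows of the residuals of the reduced (already-selected) model.
#'
#' Selection is preceded by a permutation test of the global model (all
#' candidates at once): if the global test is not significant at `alpha`,
#' no variable is selected (`reason = "global_ns"`). Without this gate,
#' testing the best of many null candidates inflates the type I error far
#' above `alpha`. The gate is skipped when `global_adj_r2` is supplied,
#' since the saturated models that require that argument have a degenerate
#' global test.
#'
#' @inheritParams fit_rda
#' @param alpha Significance level for the marginal test (default 0.05).
#' @param nperm Permutations per marginal test (default 999, minimum 99).
#' @param seed Master seed; per-step permutation streams are derived from it.
#' @param global_adj_r2 Adjusted R-squared of the global model. `NULL`
#'   (default) computes it from the full candidate table, which then must
#'   satisfy n > m + 1. Supply a value to reuse a precomputed threshold, or
#'   `Inf` to disable the second stopping rule - needed when the candidates
#'   span the whole centred site space (e.g. a complete MEM basis, m = n - 1),
#'   where the saturated global model has R-squared 1 by construction and no
#'   meaningful adjusted value.
#' @return An object of class `forward_selection` with a per-step table
#'   (`variable`, `order` = column index in `x`, `r2`, `r2_cum`,
#'   `adj_r2_cum`, `statistic` (pseudo-F), `p_value`), the stopping reason
#'   (`"alpha"`, `"global_adjr2"`, `"global_ns"` or `"exhausted"`), and the
#'   global model's R-squared values and permutation p-value (`global_p`).
#' @export
forward_select <- function(y, x, species = NULL, vars = NULL, alpha = 0.05,
                           nperm = 999, seed = NULL, standardise = TRUE,
                           global_adj_r2 = NULL) {
  if (nperm < 99) abort("`nperm` must be at least 99 for selection")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie strictly between 0 and 1")
  }
  Y <- as_num_matrix(y, species, "community table")
  X <- as_num_matrix(x, vars, "explanatory table")
  if (ncol(X) == 0) abort("explanatory table has no candidate columns")
  if (nrow(X) != nrow(Y)) abort("y and x must have the same number of rows")
  n <- nrow(Y)
  m_all <- ncol(X)
  if (is.null(global_adj_r2) && n <= m_all + 1) {
    abort("needs n > m + 1 for the global model (or supply `global_adj_r2`)")
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(m_all))

  Xs <- if (standardise) standardise_cols(X) else centre_cols(X)
  Yc <- centre_cols(Y)
  ssy <- ss_total(Yc)
  if (ssy == 0) abort("community table has zero variance")

  if (is.null(global_adj_r2)) {
    Q_all <- ortho_basis(Xs, "explanatory table")
    global_r2 <- r2_proj(Q_all, Yc, ssy)
    global_adj <- adjusted_r2(global_r2, n, m_all)
  } else {
    check_scalar_or_inf(global_adj_r2, "global_adj_r2")
    global_r2 <- NA_real_
    global_adj <- global_adj_r2
  }

  step_seeds <- if (is.null(seed)) rep(list(NULL), m_all + 1L) else
    as.list(derive_seeds(seed, m_all + 1L))

  selected <- integer(0)
  steps <- list()
  reason <- "exhausted"
  Q_sel <- NULL
  r2_cum <- 0

  global_p <- NA_real_
  if (is.null(global_adj_r2)) {
    # gate: permutation test of the global model before any selection
    exceed_g <- with_seed(step_seeds[[m_all + 1L]], {
      sum(vapply(seq_len(nperm), function(i) {
        r2_proj(Q_all, Yc[sample.int(n), , drop = FALSE], ssy)
      }, numeric(1)) >= global_r2)
    })
    global_p <- (1 + exceed_g) / (nperm + 1)
    if (global_p > alpha) reason <- "global_ns"
  }

  while (reason != "global_ns" && length(selected) < m_all) {
    remaining <- setdiff(seq_len(m_all), selected)
    # residualise candidates against the selected set; marginal R2 gain is
    # the squared projection of Yc on the unit residual direction
    Xr <- Xs[, remaining, drop = FALSE]
    if (!is.null(Q_sel)) Xr <- Xr - Q_sel %*% crossprod(Q_sel, Xr)
    norms <- sqrt(colSums(Xr^2))
    ok <- norms > 1e-8 * sqrt(n)
    if (!any(ok)) break
    gains <- rep(-Inf, length(remaining))
    gains[ok] <- colSums(crossprod(Yc, sweep(Xr[, ok, drop = FALSE], 2,
                                             norms[ok], "/"))^2) / ssy
    best <- which.max(gains)           # ties: lower column index wins
    j <- remaining[best]
    xr_unit <- Xr[, best] / norms[best]
    delta <- gains[best]
    q <- length(selected) + 1L
    r2_new <- r2_cum + delta
    f_obs <- delta / ((1 - r2_new) / (n - q - 1))

    # permutation of reduced-model residuals
    Yhat <- if (is.null(Q_sel)) matrix(0, n, ncol(Yc)) else
      Q_sel %*% crossprod(Q_sel, Yc)
    Rres <- Yc - Yhat
    exceed <- with_seed(step_seeds[[q]], {
      sum(vapply(seq_len(nperm), function(i) {
        Yp <- Yhat + Rres[sample.int(n), , drop = FALSE]
        ssp <- ss_total(Yp)
        r2s <- r2_proj(Q_sel, Yp, ssp)
        dlt <- sum(crossprod(Yp, xr_unit)^2) / ssp
        dlt / ((1 - r2s - dlt) / (n - q - 1))
      }, numeric(1)) >= f_obs)
    })
    p_val <- (1 + exceed) / (nperm + 1)
    if (p_val > alpha) {
      reason <- "alpha"
      break
    }
    adj_new <- adjusted_r2(r2_new, n, q)
    if (adj_new > global_adj + 1e-8) {
      reason <- "global_adjr2"
      break
    }
    selected <- c(selected, j)
    r2_cum <- r2_new
    steps[[q]] <- tibble::tibble(
      variable = colnames(X)[j], order = j, r2 = delta,
      r2_cum = r2_cum, adj_r2_cum = adj_new,
      statistic = f_obs, p_value = p_val
    )
    Q_sel <- ortho_basis(Xs[, selected, drop = FALSE])
  }

  structure(
    list(steps = if (length(steps)) dplyr::bind_rows(steps) else
           tibble::tibble(variable = character(), order = integer(),
                          r2 = numeric(), r2_cum = numeric(),
                          adj_r2_cum = numeric(), statistic = numeric(),
                          p_value = numeric()),
         selected = colnames(X)[selected],
         reason = reason, alpha = alpha, nperm = nperm, seed = seed,
         global_r2 = global_r2, global_adj_r2 = global_adj,
         global_p = global_p, n = n,
         m_candidates = m_all),
    class = "forward_selection"
  )
}

#' @export
print.forward_selection <- function(x, ...) {
  cat(sprintf(
    "Forward selection: %d of %d variables retained (stop: %s)\n",
    length(x$selected), x$m_candidates, x$reason))
  cat(sprintf("  global model R2 = %.4f (adjusted %.4f)\n",
              x$global_r2, x$global_adj_r2))
  if (nrow(x$steps)) print(x$steps)
  invisible(x)
}

#' @describeIn forward_select Per-step selection table (mirrors the layout
#'   variable / order / R2 / R2Cum / AdjR2Cum / F / pval).
#' @param x A `forward_selection` object.
#' @param ... Unused.
#' @method tidy forward_selection
#' @export
tidy.forward_selection <- function(x, ...) x$steps

#' @describeIn forward_select One-row summary with the stopping reason and
#'   global-model R-squared.
#' @method glance forward_selection
#' @export
glance.forward_selection <- function(x, ...) {
  tibble::tibble(
    n_selected = length(x$selected), m_candidates = x$m_candidates,
    reason = x$reason,
    r2_cum = if (nrow(x$steps)) max(x$steps$r2_cum) else 0,
    adj_r2_cum = if (nrow(x$steps)) max(x$steps$adj_r2_cum) else 0,
    global_r2 = x$global_r2, global_adj_r2 = x$global_adj_r2,
    global_p = x$global_p, alpha = x$alpha, nperm = x$nperm
  )
}

#' Write a selection table as CSV
#'
#' Column layout: variable, order, R2, R2Cum, AdjR2Cum, F, pval.
#'
#' @param x A `forward_selection` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection_csv <- function(x, path) {
  stopifnot(inherits(x, "forward_selection"))
  out <- x$steps
  names(out) <- c("variable", "order", "R2", "R2Cum", "AdjR2Cum", "F", "pval")
  readr::write_csv(out, path)
  invisible(path)
}

#' Semipartial R-squared of one predictor set given another
#'
#' The variance fraction explained by `x` over and above the conditioning
#' set `z`: `R2(x union z) - R2(z)`, with the adjusted version computed as
#' the difference of the Ezekiel-adjusted values of the two nested models.
#'
#' @inheritParams fit_rda
#' @param z Conditioning explanatory table (may be `NULL` for none).
#' @param vars_z Optional column subset of `z`.
#' @return One-row tibble: `r2`, `adj_r2`, `m_x`, `m_z`.
#' @export
partial_rda_r2 <- function(y, x, z = NULL, species = NULL, vars = NULL,
                           vars_z = NULL, standardise = TRUE) {
  Y <- as_num_matrix(y, species, "community table")
  X <- as_num_matrix(x, vars, "explanatory table")
  n <- nrow(Y)
  Z <- if (is.null(z)) NULL else as_num_matrix(z, vars_z, "conditioning table")
  m_x <- ncol(X)
  m_z <- if (is.null(Z)) 0L else ncol(Z)
  if (n <= m_x + m_z + 1) abort("needs n > m_x + m_z + 1")
  prep <- function(M) if (standardise) standardise_cols(M) else centre_cols(M)
  Yc <- centre_cols(Y)
  ssy <- ss_total(Yc)
  # rank-tolerant: if X lies (partly) inside span(Z) the union is charged
  # its rank, so a fully redundant X contributes exactly zero
  Q_xz <- rank_basis(prep(cbind(X, Z)))
  Q_z <- if (m_z == 0) NULL else rank_basis(prep(Z))
  r2_xz <- r2_proj(Q_xz, Yc, ssy)
  r2_z <- if (m_z == 0) 0 else r2_proj(Q_z, Yc, ssy)
  adj <- adjusted_r2(r2_xz, n, ncol(Q_xz)) -
    if (m_z == 0) 0 else adjusted_r2(r2_z, n, ncol(Q_z))
  tibble::tibble(r2 = r2_xz - r2_z, adj_r2 = adj, m_x = m_x, m_z = m_z)
}

# Orthonormal basis of the column space, tolerating collinearity across
# blocks (e.g. a variable appearing in two subsets): rank, not column
# count, is what the union's adjusted R2 must be charged for.
rank_basis <- function(M) {
  qrm <- qr(M)
  qr.Q(qrm)[, seq_len(qrm$rank), drop = FALSE]
}

# Adjusted R2 of the RDA on a union of standardised predictor blocks.
r2a_union <- function(blocks, idx, Yc, ssy, n) {
  M <- do.call(cbind, blocks[idx])
  Q <- rank_basis(M)
  list(r2 = r2_proj(Q, Yc, ssy), m = ncol(Q))
}

# Permutation p-value for the unique fraction of block `i` given the others.
test_unique_fraction <- function(blocks, i, Yc, ssy, n, nperm, seed) {
  rest <- do.call(cbind, blocks[-i])
  full <- do.call(cbind, blocks)
  Q_rest <- rank_basis(rest)
  Q_full <- rank_basis(full)
  m_full <- ncol(Q_full)
  m_i <- max(1L, m_full - ncol(Q_rest))
  r2_full <- r2_proj(Q_full, Yc, ssy)
  r2_rest <- r2_proj(Q_rest, Yc, ssy)
  f_obs <- ((r2_full - r2_rest) / m_i) / ((1 - r2_full) / (n - m_full - 1))
  Yhat <- Q_rest %*% crossprod(Q_rest, Yc)
  Rres <- Yc - Yhat
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(nperm), function(k) {
      Yp <- Yhat + Rres[sample.int(n), , drop = FALSE]
      ssp <- ss_total(Yp)
      r2f <- r2_proj(Q_full, Yp, ssp)
      r2r <- r2_proj(Q_rest, Yp, ssp)
      ((r2f - r2r) / m_i) / ((1 - r2f) / (n - m_full - 1))
    }, numeric(1)) >= f_obs)
  })
  (1 + exceed) / (nperm + 1)
}

#' Variation partitioning of a community table over 2 or 3 predictor sets
#'
#' Decomposes the adjusted R-squared of the community table into the unique
#' and shared fractions of two or three sets of explanatory variables by
#' inclusion-exclusion over the adjusted R-squared of every subset union,
#' plus the residual fraction. Fractions are reported as computed - shared
#' fractions of adjusted R-squared can be negative - so that all fractions
#' plus the residual sum to one exactly. Unique (testable) fractions get a
#' permutation p-value from the pseudo-F of the semipartial model, permuting
#' the rows of the reduced-model residuals; shared fractions are not
#' individually testable.
#'
#' @inheritParams fit_rda
#' @param subsets Named list of 2 or 3 explanatory tables (data frames or
#'   matrices over the same sites).
#' @param nperm Permutations per testable fraction (default 999).
#' @param seed Master seed; per-fraction streams are derived from it.
#' @return An object of class `variation_partition` whose `fractions` tibble
#'   has `fraction` (label), `sets`, `adj_r2`, `testable`, `p_value`.
#' @export
variation_partition <- function(y, subsets, nperm = 999, seed = NULL,
                                species = NULL, standardise = TRUE) {
  if (!is.list(subsets) || length(subsets) < 2 || length(subsets) > 3) {
    abort("`subsets` must be a named list of 2 or 3 explanatory tables")
  }
  k <- length(subsets)
  nm <- names(subsets) %||% paste0("X", seq_len(k))
  nm[nm == ""] <- paste0("X", which(nm == ""))
  Y <- as_num_matrix(y, species, "community table")
  n <- nrow(Y)
  Yc <- centre_cols(Y)
  ssy <- ss_total(Yc)
  blocks <- lapply(seq_len(k), function(i) {
    M <- as_num_matrix(subsets[[i]], NULL, paste0("subset '", nm[i], "'"))
    if (ncol(M) == 0) abort(sprintf("subset '%s' is empty", nm[i]))
    if (nrow(M) != n) abort(sprintf("subset '%s' row count differs from y", nm[i]))
    if (standardise) standardise_cols(M, nm[i]) else centre_cols(M)
  })
  m_total <- sum(vapply(blocks, ncol, integer(1)))
  if (n <= m_total + 1) abort("needs n > total number of predictors + 1")

  # adjusted R2 of every union
  unions <- unlist(lapply(seq_len(k), function(sz) {
    utils::combn(k, sz, simplify = FALSE)
  }), recursive = FALSE)
  r2a <- vapply(unions, function(idx) {
    u <- r2a_union(blocks, idx, Yc, ssy, n)
    adjusted_r2(u$r2, n, u$m)
  }, numeric(1))
  names(r2a) <- vapply(unions, paste, character(1), collapse = "")
  g <- function(key) unname(r2a[[key]])

  if (k == 2) {
    full <- g("12")
    fr <- tibble::tibble(
      fraction = c(paste0("unique:", nm[1]), paste0("unique:", nm[2]),
                   paste0("shared:", nm[1], "&", nm[2]), "residual"),
      sets = c(nm[1], nm[2], paste(nm, collapse = "&"), "none"),
      adj_r2 = c(full - g("2"), full - g("1"),
                 g("1") + g("2") - full, 1 - full),
      testable = c(TRUE, TRUE, FALSE, FALSE)
    )
    unique_rows <- 1:2
  } else {
    full <- g("123")
    a <- full - g("23"); b <- full - g("13"); cc <- full - g("12")
    gg <- g("1") + g("2") + g("3") - g("12") - g("13") - g("23") + full
    d12 <- g("1") + g("2") - g("12") - gg
    d23 <- g("2") + g("3") - g("23") - gg
    d13 <- g("1") + g("3") - g("13") - gg
    fr <- tibble::tibble(
      fraction = c(paste0("unique:", nm),
                   paste0("shared:", nm[1], "&", nm[2]),
                   paste0("shared:", nm[2], "&", nm[3]),
                   paste0("shared:", nm[1], "&", nm[3]),
                   paste0("shared:", paste(nm, collapse = "&")),
                   "residual"),
      sets = c(nm, paste(nm[c(1, 2)], collapse = "&"),
               paste(nm[c(2, 3)], collapse = "&"),
               paste(nm[c(1, 3)], collapse = "&"),
               paste(nm, collapse = "&"), "none"),
      adj_r2 = c(a, b, cc, d12, d23, d13, gg, 1 - full),
      testable = c(TRUE, TRUE, TRUE, rep(FALSE, 5))
    )
    unique_rows <- 1:3
  }

  seeds <- if (is.null(seed)) rep(list(NULL), k) else as.list(derive_seeds(seed, k))
  fr$p_value <- NA_real_
  for (i in seq_along(unique_rows)) {
    fr$p_value[unique_rows[i]] <-
      test_unique_fraction(blocks, i, Yc, ssy, n, nperm, seeds[[i]])
  }

  structure(
    list(fractions = fr, r2a_unions = r2a, set_names = nm, n = n,
         nperm = nperm, seed = seed),
    class = "variation_partition"
  )
}

#' @method tidy variation_partition
#' @export
print.variation_partition <- function(x, ...) {
  cat(sprintf("Variation partitioning over %d sets (%s), n = %d sites\n",
              length(x$set_names), paste(x$set_names, collapse = ", "), x$n))
  print(x$fractions)
  invisible(x)
}

#' @describeIn variation_partition Fraction table (adjusted R2 per unique /
#'   shared / residual fraction, with permutation p for testable fractions).
#' @param x A `variation_partition` object.
#' @param ... Unused.
#' @method glance variation_partition
#' @export
tidy.variation_partition <- function(x, ...) x$fractions

#' @describeIn variation_partition One-row summary (total explained adjusted
#'   R2 and residual fraction).
#' @export
glance.variation_partition <- function(x, ...) {
  resid <- x$fractions$adj_r2[x$fractions$fraction == "residual"]
  tibble::tibble(
    n_sets = length(x$set_names), n = x$n,
    adj_r2_total = 1 - resid, residual = resid, nperm = x$nperm
  )
}
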