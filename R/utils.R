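# Internal helpers shared across modules.

# Extract a numeric matrix from a data frame given column names (or a matrix
# as-is), with row alignment preserved.
as_num_matrix <- function(x, cols = NULL, what = "input") {
  if (is.matrix(x)) {
    m <- x
    if (!is.null(cols)) m <- m[, cols, drop = FALSE]
  } else if (is.data.frame(x)) {
    if (is.null(cols)) cols <- names(x)[vapply(x, is.numeric, logical(1))]
    missing <- setdiff(cols, names(x))
    if (length(missing) > 0) {
      abort(sprintf("%s is missing columns: %s", what,
                    paste(missing, collapse = ", ")))
    }
    m <- as.matrix(x[, cols, drop = FALSE])
  } else {
    abort(sprintf("%s must be a data frame or matrix", what))
  }
  if (!is.numeric(m)) abort(sprintf("%s contains non-numeric columns", what))
  if (anyNA(m)) abort(sprintf("%s contains missing values", what))
  m
}

# Column-centre a matrix.
centre_cols <- function(m) sweep(m, 2, colMeans(m), "-")

# Standardise columns to zero mean, unit variance; constant columns rejected.
standardise_cols <- function(m, what = "X") {
  s <- apply(m, 2, sd)
  if (any(s == 0)) {
    abort(sprintf("%s has constant column(s): %s", what,
                  paste(colnames(m)[s == 0], collapse = ", ")))
  }
  scale(m, center = TRUE, scale = s)[, , drop = FALSE]
}

# Total sum of squares of a (centred) matrix.
ss_total <- function(m) sum(m^2)

# Derive a stream of reproducible child seeds from one master seed, so that
# independent pipeline stages draw from independent streams.
derive_seeds <- function(seed, n) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# Run an expression under a temporary RNG seed, restoring the caller's
# RNG state afterwards. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Orthonormal basis of the column space of a centred matrix (QR with
# rank check). Used for projections in RDA and permutation tests.
ortho_basis <- function(Xc, what = "X") {
  qrx <- qr(Xc)
  if (qrx$rank < ncol(Xc)) {
    bad <- colnames(Xc)[qrx$pivot[seq(qrx$rank + 1, ncol(Xc))]]
    abort(sprintf("%s is rank deficient; collinear column(s): %s", what,
                  paste(bad, collapse = ", ")))
  }
  qr.Q(qrx)[, seq_len(qrx$rank), drop = FALSE]
}

check_scalar_or_inf <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
    abort(sprintf("`%s` must be a single number (Inf allowed)", name))
  }
  invisible(x)
}

check_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  invisible(x)
}
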