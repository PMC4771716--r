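#' Community-matrix transformations
#'
#' Pre-transformations that make species abundance tables suitable for
#' Euclidean-based ordination (PCA/RDA). The Hellinger transformation,
#' \eqn{y'_{ij} = \sqrt{y_{ij} / y_{i+}}}, emphasises abundant species and
#' gives every site unit sum of squares. The chi-square transformation,
#' \eqn{y'_{ij} = \sqrt{y_{++}}\, y_{ij} / (y_{i+} \sqrt{y_{+j}})},
#' up-weights rare species by scaling each column by the square root of its
#' total.
#'
#' @param counts A data frame or matrix of non-negative species counts,
#'   sites in rows. Non-numeric columns of a data frame are dropped with
#'   `species = NULL`; otherwise `species` names the count columns.
#' @param species Optional character vector of species column names.
#' @return A tibble of transformed values with the species columns, plus
#'   attributes `transform` (`"hellinger"` or `"chisq"`).
#' @examples
#' y <- data.frame(a = c(4, 1), b = c(0, 1), c = c(0, 2))
#' hellinger_transform(y)
#' chisq_transform(y)
#' @name community_transforms
NULL

check_counts <- function(counts, species, need_cols = FALSE) {
  m <- as_num_matrix(counts, species, "count table")
  if (any(m < 0)) abort("count table has negative entries")
  rs <- rowSums(m)
  if (any(rs == 0)) {
    abort(sprintf("zero row total at site row(s): %s",
                  paste(which(rs == 0), collapse = ", ")))
  }
  if (need_cols) {
    cs <- colSums(m)
    if (any(cs == 0)) {
      abort(sprintf("zero column total for species: %s",
                    paste(colnames(m)[cs == 0], collapse = ", ")))
    }
  }
  m
}

#' @rdname community_transforms
#' @export
hellinger_transform <- function(counts, species = NULL) {
  m <- check_counts(counts, species)
  out <- sqrt(m / rowSums(m))
  res <- tibble::as_tibble(out)
  attr(res, "transform") <- "hellinger"
  res
}

#' @rdname community_transforms
#' @export
chisq_transform <- function(counts, species = NULL) {
  m <- check_counts(counts, species, need_cols = TRUE)
  rs <- rowSums(m)
  cs <- colSums(m)
  out <- sqrt(sum(m)) * (m / rs) / rep(sqrt(cs), each = nrow(m))
  res <- tibble::as_tibble(out)
  attr(res, "transform") <- "chisq"
  res
}
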