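# ggplot2 displays for the main result types.

#' @describeIn gabriel_graph Plot the sites and Gabriel edges.
#' @param object A `gabriel_graph` object (autoplot method).
#' @method autoplot gabriel_graph
#' @export
autoplot.gabriel_graph <- function(object, ...) {
  ed <- object$edges
  seg <- tibble::tibble(
    x = object$xy[ed$from, 1], y = object$xy[ed$from, 2],
    xend = object$xy[ed$to, 1], yend = object$xy[ed$to, 2]
  )
  pts <- tibble::tibble(x = object$xy[, 1], y = object$xy[, 2])
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      colour = "grey60", linewidth = 0.3) +
    ggplot2::geom_point(data = pts, ggplot2::aes(.data$x, .data$y), size = 1) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km)",
                  title = sprintf("Gabriel graph (%d sites, %d edges)",
                                  object$n, nrow(ed))) +
    ggplot2::theme_minimal()
}

#' @describeIn r2max_test Plot the smoothed scalogram with the null 95%
#'   limit; the maximal component is filled darker and annotated with the
#'   permutation p-value.
#' @param object A `scalogram` object (autoplot method).
#' @method autoplot scalogram
#' @export
autoplot.scalogram <- function(object, ...) {
  sm <- object$smoothed
  sm$is_max <- sm$component == object$component
  ggplot2::ggplot(sm, ggplot2::aes(factor(.data$component), .data$r2)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$is_max), show.legend = FALSE) +
    ggplot2::geom_point(ggplot2::aes(y = .data$null_q95), shape = 3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$null_q95, group = 1),
                       linetype = "dotted") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "#2c5c8f")) +
    ggplot2::labs(
      x = "spatial component (broad → fine)", y = expression(R^2),
      title = sprintf("Scalogram: R²max = %.2f (p = %.3g)",
                      object$r2max, object$p_value),
      subtitle = "+ dotted: 95% limit of the permutation null") +
    ggplot2::theme_minimal()
}

#' @describeIn fit_pca Ordination biplot: site scores (points) and species
#'   loadings (arrows), first two axes.
#' @param object An `ordination` object (autoplot method).
#' @method autoplot ordination
#' @export
autoplot.ordination <- function(object, ...) {
  if (length(object$eigenvalues) < 2) {
    abort("biplot needs at least two ordination axes")
  }
  sc <- ord_scores(object, 1:2)
  names(sc)[2:3] <- c("a1", "a2")
  lo <- tibble::as_tibble(as.data.frame(object$loadings[, 1:2]))
  names(lo) <- c("a1", "a2")
  lo$species <- rownames(object$loadings) %||%
    paste0("sp", seq_len(nrow(object$loadings)))
  mult <- 0.8 * max(abs(unlist(sc[, 2:3]))) / max(abs(unlist(lo[, 1:2])))
  labs <- tidy(object)
  ggplot2::ggplot(sc, ggplot2::aes(.data$a1, .data$a2)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_segment(
      data = lo,
      ggplot2::aes(x = 0, y = 0, xend = .data$a1 * mult,
                   yend = .data$a2 * mult),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "#b03a2e") +
    ggplot2::geom_text(
      data = lo,
      ggplot2::aes(x = .data$a1 * mult * 1.08, y = .data$a2 * mult * 1.08,
                   label = .data$species),
      colour = "#b03a2e", size = 3) +
    ggplot2::labs(
      x = sprintf("%s (%.0f%%)", labs$axis[1], 100 * labs$prop_axes[1]),
      y = sprintf("%s (%.0f%%)", labs$axis[2], 100 * labs$prop_axes[2]),
      title = sprintf("%s ordination (scaling 1)", toupper(object$kind))) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' @describeIn variation_partition Bar chart of the partition fractions
#'   with permutation p-values on the testable bars.
#' @param object A `variation_partition` object (autoplot method).
#' @method autoplot variation_partition
#' @export
autoplot.variation_partition <- function(object, ...) {
  fr <- object$fractions
  fr$fraction <- factor(fr$fraction, levels = rev(fr$fraction))
  fr$lab <- ifelse(fr$testable, sprintf("p = %.3g", fr$p_value), "")
  ggplot2::ggplot(fr, ggplot2::aes(.data$adj_r2, .data$fraction)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$testable),
                      show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(label = .data$lab), hjust = -0.1, size = 3) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "#2c5c8f")) +
    ggplot2::labs(x = expression("adjusted" ~ R^2), y = NULL,
                  title = "Variation partitioning") +
    ggplot2::theme_minimal()
}
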