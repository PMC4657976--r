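#' Plot a rarefaction curve
#'
#' Expected richness with its percentile-bootstrap confidence band.
#'
#' @param object A [rarefaction_curve()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rarefaction_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$m, y = .data$expected)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                         fill = "grey80") +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Individuals subsampled", y = "Expected species richness") +
    ggplot2::theme_minimal()
}

#' Plot paired site scores of a co-inertia analysis
#'
#' Each site appears twice, once per table, joined by a segment; short
#' segments mean the two community representations agree on that site.
#'
#' @param object A [coinertia_fit()] object.
#' @param meta Optional metadata used to colour sites by region.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.coinertia <- function(object, meta = NULL, ...) {
  sa <- object$site_scores_a
  sb <- object$site_scores_b
  if (ncol(sa) < 2) abort("need at least 2 co-inertia axes to plot")
  df <- tibble::tibble(
    site_id = rownames(sa),
    xa = sa[, 1], ya = sa[, 2], xb = sb[, 1], yb = sb[, 2]
  )
  if (!is.null(meta)) {
    meta <- validate_metadata(meta)
    df$region <- meta$region[match(df$site_id, meta$site_id)]
  }
  p <- ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$xa, y = .data$ya,
                                       xend = .data$xb, yend = .data$yb),
                          colour = "grey60") +
    ggplot2::labs(x = "Co-inertia axis 1", y = "Co-inertia axis 2") +
    ggplot2::theme_minimal()
  if (!is.null(meta)) {
    p + ggplot2::geom_point(ggplot2::aes(x = .data$xa, y = .data$ya,
                                         colour = .data$region), size = 2)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(x = .data$xa, y = .data$ya), size = 2)
  }
}

#' Plot a bipartite association network
#'
#' Fungi on one side, beetles on the other; solid segments are positive
#' correlations, dashed segments negative, width scaled by |rho|.
#'
#' @param object An `assoc_network`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.assoc_network <- function(object, ...) {
  if (nrow(object) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", 0, 0, label = "no edges at this threshold") +
             ggplot2::theme_void())
  }
  fungi <- sort(unique(object$fungus_id))
  beetles <- sort(unique(object$beetle_id))
  pos <- dplyr::bind_rows(
    tibble::tibble(name = fungi, x = 0,
                   y = seq(0, 1, length.out = max(length(fungi), 2))[seq_along(fungi)],
                   taxon_class = "fungus"),
    tibble::tibble(name = beetles, x = 1,
                   y = seq(0, 1, length.out = max(length(beetles), 2))[seq_along(beetles)],
                   taxon_class = "beetle")
  )
  seg <- tibble::as_tibble(object) |>
    dplyr::mutate(
      x = 0, xend = 1,
      y = pos$y[match(.data$fungus_id, pos$name)],
      yend = pos$y[match(.data$beetle_id, pos$name)]
    )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend,
                   linetype = .data$sign, linewidth = abs(.data$rho))
    ) +
    ggplot2::geom_point(data = pos,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$taxon_class), size = 3) +
    ggplot2::geom_text(data = pos,
                       ggplot2::aes(x = .data$x + ifelse(.data$x == 0, -0.05, 0.05),
                                    y = .data$y, label = .data$name),
                       hjust = ifelse(pos$x == 0, 1, 0), size = 3) +
    ggplot2::scale_linetype_manual(values = c(positive = "solid", negative = "dashed")) +
    ggplot2::scale_linewidth(range = c(0.3, 1.4), guide = "none") +
    ggplot2::xlim(-0.5, 1.5) +
    ggplot2::theme_void()
}
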