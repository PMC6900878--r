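#' Stacked-bar plot of substitution-pattern spectra
#'
#' @param spectrum A [pattern_spectrum()] tibble.
#' @return A ggplot object: per-group stacked proportions of the 12
#'   substitution patterns.
#' @export
plot_pattern_spectrum <- function(spectrum) {
  ggplot2::ggplot(spectrum,
                  ggplot2::aes(x = .data$group, y = .data$prop,
                               fill = .data$pattern)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "proportion of synonymous mutations",
                  fill = "pattern") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Radar-style plot of amino-acid distributions
#'
#' @param aa_spec An [aa_spectrum()] tibble (grouped or not).
#' @return A ggplot object: polar line plot of per-amino-acid proportions.
#' @export
plot_aa_radar <- function(aa_spec) {
  if (!"group" %in% names(aa_spec)) aa_spec$group <- "all"
  ggplot2::ggplot(aa_spec,
                  ggplot2::aes(x = .data$aa, y = .data$prop,
                               group = .data$group,
                               colour = .data$group)) +
    ggplot2::geom_polygon(fill = NA) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_polar() +
    ggplot2::labs(x = NULL, y = "proportion", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a hotspot call set
#'
#' Reported hotspots by cancer type, coloured by the dominant
#' sequence-context subtype (the subtype with the largest observed count
#' at the position).
#'
#' @param object A `syn_hotspots` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.syn_hotspots <- function(object, ...) {
  x <- dplyr::filter(tibble::as_tibble(object), .data$reported)
  if (nrow(x) == 0) stop("no reported hotspots to plot", call. = FALSE)
  obs_cols <- grep("^obs_", names(x), value = TRUE)
  dom <- apply(as.matrix(x[, obs_cols]), 1, function(r) {
    r[is.na(r)] <- 0
    sub("^obs_", "", obs_cols[which.max(r)])
  })
  x$dominant_subtype <- dom
  ggplot2::ggplot(x, ggplot2::aes(x = .data$cancer_type,
                                  fill = .data$dominant_subtype)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = NULL, y = "reported hotspots",
                  fill = "dominant subtype") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
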