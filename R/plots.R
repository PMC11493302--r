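#' Scree plot of a shape model
#'
#' Eigenvalue against component index for the displayed components; the knee
#' of this curve is one of the three component-selection criteria.
#'
#' @param object A `shape_model`.
#' @param all Plot undisplayed components too.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.shape_model <- function(object, all = FALSE, ...) {
  tab <- tidy(object, all = all)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$pc, y = .data$ev)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Principal component", y = "Eigenvalue (EV)") +
    ggplot2::theme_minimal()
}

#' DBV slope plot
#'
#' DBV of the `+/- 3 SD` shape pair per component, optionally for several
#' shape models (e.g. a subset sweep) overlaid.
#'
#' @param models A `shape_model` or named list of them.
#' @param upto Components per model (default: each model's displayed PCs).
#' @return A ggplot object.
#' @export
plot_dbv_slope <- function(models, upto = NULL) {
  if (inherits(models, "shape_model")) models <- list(model = models)
  tab <- purrr::imap_dfr(models, function(m, nm) {
    d <- dbv_per_pc(m, upto = upto %||% min(m$n_displayed, 10L))
    d$set <- as.character(nm)
    d
  })
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$pc, y = .data$dbv,
                                    colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Principal component", y = "DBV of ±3 SD shapes (mm)",
                  colour = "model set") +
    ggplot2::theme_minimal()
}

#' Assignment-frequency bar chart
#'
#' Share of classified meshes assigned to each criterion image.
#'
#' @param classification A `cohort_classification`.
#' @param region Region to plot.
#' @return A ggplot object.
#' @export
plot_assignment_frequencies <- function(classification,
                                        region = "upper_auricle") {
  tab <- assignment_frequencies(classification, region)
  tab$label <- factor(tab$label, levels = tab$label)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$label, y = .data$fraction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Criterion image", y = "Fraction of classified meshes",
                  title = region) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
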