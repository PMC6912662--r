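srp_palette <- function(m) {
  labs <- vapply(0:(factorial(m) - 1L), symbol_label, character(1), m = m)
  cols <- if (m == 3L) {
    # increasing = black, decreasing = red, echoing the usual SRP colouring
    c("black", "#377EB8", "#4DAF4A", "#984EA3", "#FF7F00", "red")
  } else {
    grDevices::hcl.colors(factorial(m), "Dark 3")
  }
  stats::setNames(cols, labs)
}

#' Plot a symbolic recurrence plot
#'
#' Renders the non-empty cells of a recurrence matrix as coloured points,
#' one colour per ordinal pattern (for `m = 3` the increasing pattern is
#' black and the decreasing one red). Diagonal structure signals repeated
#' symbol sequences; vertical/horizontal structure signals persistence of
#' one pattern.
#'
#' @param M an `srqa_matrix`, or a `symbol_seq` (converted on the fly).
#' @return a ggplot object.
#' @export
plot_srp <- function(M) {
  if (inherits(M, "symbol_seq")) M <- recurrence_matrix(M)
  pts <- srp_points(M)
  m <- attr(M, "m")
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$t, y = .data$s,
                                    colour = .data$pattern)) +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::scale_colour_manual(values = srp_palette(m), name = "symbol") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "t", y = "s", title = "Symbolic recurrence plot") +
    ggplot2::theme_minimal()
}

#' @rdname plot_srp
#' @param object an `srqa_matrix`.
#' @param ... unused.
#' @export
autoplot.srqa_matrix <- function(object, ...) plot_srp(object)

#' Plot a ROC threshold grid
#'
#' ROC curve over the 1001-point threshold grid with the chosen
#' threshold (nearest the (0, 1) corner) marked.
#'
#' @param object an `af_roc` from [roc_threshold()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.af_roc <- function(object, ...) {
  at <- object$grid[object$grid$tau == object$tau, ]
  ggplot2::ggplot(object$grid, ggplot2::aes(x = .data$fpr, y = .data$se)) +
    ggplot2::geom_path() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_point(data = at, colour = "red", size = 2) +
    ggplot2::annotate("text", x = at$fpr + 0.03, y = at$se - 0.03, hjust = 0,
                      label = sprintf("tau = %.3f", object$tau)) +
    ggplot2::labs(x = "false positive rate", y = "sensitivity",
                  title = "ROC threshold selection") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
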