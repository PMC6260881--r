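#' Tidy a Prony fit into its component table
#'
#' @param x A [prony_fit] object.
#' @param ... Unused.
#' @return Tibble with one row per component: `amp`, `damping`, `freq`,
#'   `phase`, `pole`, `weight`, `zero_pole`.
#' @exportS3Method generics::tidy
tidy.prony_fit <- function(x, ...) {
  as_tibble(x$components)
}

#' One-row summary of a Prony fit
#'
#' @param x A [prony_fit] object.
#' @param ... Unused.
#' @return One-row tibble: `method`, `order`, `n`, `ts`, `n_components`,
#'   `n_zero_poles`, `g`.
#' @exportS3Method generics::glance
glance.prony_fit <- function(x, ...) {
  tibble(
    method = x$method,
    order = x$order,
    n = x$n,
    ts = x$ts,
    n_components = nrow(x$components),
    n_zero_poles = sum(x$components$zero_pole),
    g = x$g
  )
}

#' @exportS3Method generics::tidy
tidy.mfvep_report <- function(x, ...) as_tibble(x$records)

#' @exportS3Method generics::glance
glance.mfvep_report <- function(x, ...) x$summary

#' @exportS3Method generics::glance
glance.prony_benchmark <- function(x, ...) summarize_benchmark(x)

#' Plot a Prony fit against its input signal
#'
#' Observed samples and the resynthesized approximation on a shared time
#' axis, annotated with the goodness factor G.
#'
#' @param object A [prony_fit] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.prony_fit <- function(object, ...) {
  df <- tibble(
    time = (seq_len(object$n) - 1) * object$ts,
    observed = Re(object$x),
    fitted = Re(object$fitted)
  )
  df <- tidyr::pivot_longer(df, c("observed", "fitted"),
                            names_to = "series", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "time (s)", y = "signal", colour = NULL,
      title = sprintf("Prony fit (%s, p = %d)", object$method, object$order),
      subtitle = sprintf("G = %s", fmt_or_na(object$g, 4))
    ) +
    ggplot2::theme_minimal()
}

#' Pole plot of a Prony decomposition
#'
#' Estimated poles in the complex plane with the unit circle for reference;
#' poles inside the circle decay, poles on it are undamped.
#'
#' @param object A [prony_fit] object or component tibble.
#' @return A ggplot object.
#' @export
plot_poles <- function(object) {
  comps <- as_components(object)
  circ <- tibble(theta = seq(0, 2 * pi, length.out = 256))
  ggplot2::ggplot(comps, ggplot2::aes(Re(.data$pole), Im(.data$pole))) +
    ggplot2::geom_path(data = circ,
                       ggplot2::aes(cos(.data$theta), sin(.data$theta)),
                       linetype = "dashed", colour = "grey60",
                       inherit.aes = FALSE) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$zero_pole)) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 4),
                                guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Re(z)", y = "Im(z)", title = "Estimated poles") +
    ggplot2::theme_minimal()
}

#' Plot benchmark counts per configuration
#'
#' @param object A `"prony_benchmark"` tibble from [run_benchmark()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.prony_benchmark <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$p, .data$correct / .data$replicates,
                                   colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~n, scales = "free_x",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "order p", y = "fraction correctly approximated",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
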