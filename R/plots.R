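# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   scale_y_log10 labs theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot a SAXS profile (log intensity vs q)
#'
#' @param object a [saxs_profile].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.saxs_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$q, y = .data$intensity)) +
    geom_point(size = 0.8, alpha = 0.7) +
    scale_y_log10() +
    labs(x = "q [1/Å]", y = "I(q)") +
    theme_minimal()
}

#' Kratky plot (q^2 I(q) vs q)
#'
#' @param profile a [saxs_profile].
#' @return A ggplot.
#' @export
plot_kratky <- function(profile) {
  k <- kratky(profile)
  ggplot(k, aes(x = .data$q, y = .data$q2I)) +
    geom_line() +
    labs(x = "q [1/Å]", y = expression(q^2 * I(q))) +
    theme_minimal()
}

#' Cluster-size bar chart
#'
#' @param object a `cluster_set`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.cluster_set <- function(object, ...) {
  d <- tibble(cluster = factor(seq_along(object$clusters)),
              size = lengths(object$clusters))
  ggplot(d, aes(x = .data$cluster, y = .data$size)) +
    geom_col() +
    labs(x = "cluster", y = "structures",
         title = sprintf("QT clusters (DRMS cutoff %.3g Å)", object$cutoff)) +
    theme_minimal()
}

#' Membrane contact-probability profile along the bead sequence
#'
#' @param object a `contact_profile` from [contact_probability()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.contact_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$bead, y = .data$probability,
                     colour = factor(.data$z0))) +
    geom_line() +
    labs(x = "bead", y = "membrane contact probability",
         colour = expression(z[0] ~ "[Å]")) +
    theme_minimal()
}
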