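# ggplot2 visualisations and tidiers for the metric results.

map_to_tibble <- function(m, name) {
  tibble::tibble(
    y = rep(seq_len(nrow(m)), times = ncol(m)),
    x = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m),
    map = name
  )
}

#' @export
tidy.quality_result <- function(x, ...) {
  tibble::tibble(
    map = c("DS", "MS", "GS"),
    mean = c(mean(x$ds_map), mean(x$ms_map), mean(x$gs_map)),
    pooled_deviation = c(x$dss, x$mss, x$gss)
  )
}

#' @export
glance.quality_result <- function(x, ...) {
  tibble::tibble(dss = x$dss, mss = x$mss, gss = x$gss,
                 m_ds = x$m_ds, m_gs = x$m_gs, n_pixels = x$n_pixels)
}

#' Plot the similarity maps of a quality result
#'
#' Raster panels of the DS, MS and GS maps (darker = less similar).
#'
#' @param object A [score_pair()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.quality_result <- function(object, ...) {
  df <- dplyr::bind_rows(
    map_to_tibble(object$ds_map, "DS"),
    map_to_tibble(object$ms_map, "MS"),
    map_to_tibble(object$gs_map, "GS")
  )
  df$map <- factor(df$map, levels = c("DS", "MS", "GS"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~map) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(NA, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "similarity",
                  title = sprintf("DSS = %.4f, MSS = %.4f, GSS = %.4f",
                                  object$dss, object$mss, object$gss))
}

#' Plot a gradient-amplitude histogram
#'
#' Log-domain probability per bin, the view in which natural-image gradients
#' show a sharp zero peak with smooth heavy tails and screen content shows a
#' spiky, oscillating tail.
#'
#' @param object A [gradient_histogram()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gradient_histogram <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df[!is.na(df$log_probability), ],
                  ggplot2::aes(x = .data$bin_mid, y = .data$log_probability)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = if (identical(object$domain, "log"))
                        "log(1 + gradient amplitude)" else "gradient amplitude",
                  y = "log probability")
}

#' Plot mediation path estimates
#'
#' Dot-and-interval display of the standardized path coefficients
#' (+/- 1.96 SE) from a three-step mediation fit.
#'
#' @param object A [baron_kenny()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mediation_fit <- function(object, ...) {
  df <- tidy(object)
  df$path <- factor(df$path, levels = c("c", "a", "b", "c_prime"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$path, y = .data$beta)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$beta - 1.96 * .data$se,
                                          ymax = .data$beta + 1.96 * .data$se)) +
    ggplot2::labs(x = "path", y = "standardized coefficient",
                  title = sprintf("%s mediation", object$verdict))
}
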