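# ggplot2 views of the package's result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

mask_df <- function(m, what) {
  idx <- which(m != 0, arr.ind = TRUE)
  tibble::tibble(x = idx[, 2] - 0.5, y = idx[, 1] - 0.5, what = what)
}

#' Plot a fixture scene
#'
#' Shows the instance label map; occluded instances are annotated with
#' their occlusion edges.
#'
#' @param object A `fixture_scene`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fixture_scene <- function(object, ...) {
  lm <- object$label_map
  idx <- which(lm != 0, arr.ind = TRUE)
  df <- tibble::tibble(
    x = idx[, 2] - 0.5, y = idx[, 1] - 0.5,
    instance = factor(lm[idx])
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$instance)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("Fixture scene (%d instances, %d occlusion edges)",
                      length(object$amodal), nrow(object$edges)),
      x = NULL, y = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot a synthesis sample
#'
#' Shows the intact, occluder and visible-occluded masks of one synthesized
#' training triple side by side.
#'
#' @param object A `synthesis_sample`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.synthesis_sample <- function(object, ...) {
  df <- dplyr::bind_rows(
    mask_df(object$m_intact_s, "intact"),
    mask_df(object$m_occder_s, "occluder"),
    mask_df(object$m_occ_s, "occluded (visible)")
  )
  df$what <- factor(df$what, c("intact", "occluder", "occluded (visible)"))
  m <- object$meta
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(fill = "darkgreen") +
    ggplot2::facet_wrap(~what) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("%s cover sample (case %s, beta %s, epsilon %.2f%s)",
                      m$strategy, ifelse(is.na(m$case_alpha), "-", m$case_alpha),
                      ifelse(is.na(m$beta), "-", sprintf("%.2f", m$beta)),
                      m$epsilon, if (m$gamma) ", reverse" else ""),
      x = NULL, y = NULL
    ) +
    ggplot2::theme_minimal()
}

plot_training_log <- function(log, title) {
  ggplot2::ggplot(log, ggplot2::aes(x = .data$iteration)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$loss), alpha = 0.35) +
    ggplot2::geom_line(ggplot2::aes(y = .data$running_loss), linewidth = 0.8) +
    ggplot2::labs(title = title, x = "iteration", y = "loss") +
    ggplot2::theme_minimal()
}

#' Plot the training curve of an amodal completion model
#'
#' @param object A trained `amodal_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.amodal_model <- function(object, ...) {
  plot_training_log(tidy(object), "Amodal completion training loss")
}

#' Plot the training curve of the dual-decoder heads
#'
#' @param object A `heads_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.heads_model <- function(object, ...) {
  plot_training_log(tidy(object),
                    sprintf("Dual-decoder heads training loss (%s, PALM %s)",
                            object$cfg$supervision,
                            if (object$cfg$use_palm) "on" else "off"))
}
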