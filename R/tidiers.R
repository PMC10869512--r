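#' Tidy a demix model into a long factor table
#'
#' @param x A `demix_model`.
#' @param ... Unused.
#' @return Tibble: `mode` (spatial/temporal/prevalence), `index` (channel,
#'   coefficient or unit), `component`, `value`.
#' @export
tidy.demix_model <- function(x, ...) {
  one <- function(mode) {
    M <- x[[mode]]
    tibble(mode = mode,
           index = rep(seq_len(nrow(M)), ncol(M)),
           component = rep(seq_len(ncol(M)), each = nrow(M)),
           value = as.numeric(M))
  }
  dplyr::bind_rows(lapply(c("spatial", "temporal", "prevalence"), one))
}

#' One-row model summary of a demix model
#'
#' @param x A `demix_model`.
#' @param ... Unused.
#' @return Tibble: rank, relative reconstruction error, iterations,
#'   convergence flag.
#' @export
glance.demix_model <- function(x, ...) {
  tibble(R = x$R, reconstruction_error = x$reconstruction_error,
         iterations = x$iterations, converged = x$converged)
}

#' Tidy an ME hierarchy into the family assignment table
#'
#' @param x An `me_hierarchy`.
#' @param ... Unused.
#' @return Tibble: `family`, `me_class`.
#' @export
tidy.me_hierarchy <- function(x, ...) {
  tibble(family = names(x$me_assignment),
         me_class = as.integer(x$me_assignment))
}

#' Tidy a classifier report into its importance table
#'
#' @param x A `classifier_report`.
#' @param ... Unused.
#' @return Tibble: `feature`, `gini_importance`.
#' @export
tidy.classifier_report <- function(x, ...) {
  tibble(feature = names(x$gini_importances),
         gini_importance = as.numeric(x$gini_importances))
}

#' One-row summary of a classifier report
#'
#' @param x A `classifier_report`.
#' @param ... Unused.
#' @return Tibble with holdout/OOB/CV accuracies and selected parameters.
#' @export
glance.classifier_report <- function(x, ...) {
  tibble(holdout_accuracy = x$holdout_accuracy, oob_score = x$oob_score,
         cv_accuracy = x$cv_accuracy,
         max_depth = x$best_params$max_depth,
         num_trees = x$best_params$num_trees)
}

#' Plot the spatial sources of a demix model
#'
#' Contribution of each EAP source across the 31 probe channels, centered
#' on the perisomatic channel.
#'
#' @param model A `demix_model`.
#' @param pitch Channel pitch, um.
#' @param normalize Scale each source to unit maximum (display convention).
#' @return A ggplot object.
#' @export
plot_spatial_sources <- function(model, pitch = 10, normalize = TRUE) {
  S <- nrow(model$spatial)
  center <- (S + 1) / 2
  df <- tidy(model) |>
    dplyr::filter(.data$mode == "spatial") |>
    dplyr::mutate(y = (.data$index - center) * pitch,
                  component = factor(.data$component))
  if (normalize) {
    df <- df |>
      dplyr::group_by(.data$component) |>
      dplyr::mutate(value = .data$value / max(.data$value)) |>
      dplyr::ungroup()
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$y, y = .data$value,
                                   color = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = "distance from center channel (um)",
                  y = "spatial contribution", color = "source") +
    ggplot2::theme_minimal()
}

#' Plot reconstructed temporal-source dynamics
#'
#' Inverse Haar reconstruction of each multiresolution temporal source,
#' displayed as contribution magnitude against time relative to the spike.
#'
#' @param model A `demix_model`.
#' @param dt Sample interval, ms.
#' @param spike_index 1-based spike sample within the snippet.
#' @return A ggplot object.
#' @export
plot_temporal_sources <- function(model, dt = 5.6 / 128, spike_index = 33L) {
  W <- nrow(model$temporal)
  t_ms <- (seq_len(W) - spike_index) * dt
  df <- dplyr::bind_rows(lapply(seq_len(model$R), function(r) {
    tibble(t = t_ms, component = factor(r),
           value = abs(reconstruct_temporal_source(model$temporal[, r])))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        color = "grey50") +
    ggplot2::labs(x = "time from spike (ms)",
                  y = "reconstructed contribution magnitude") +
    ggplot2::theme_minimal()
}

#' Autoplot a demix model
#'
#' Spatial and multiresolution temporal factors side by side.
#'
#' @param object A `demix_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.demix_model <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::filter(.data$mode %in% c("spatial", "temporal")) |>
    dplyr::mutate(component = factor(.data$component))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$value,
                                   color = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~mode, scales = "free") +
    ggplot2::labs(x = "index", y = "contribution", color = "source") +
    ggplot2::theme_minimal()
}

#' Plot an amplitude profile along the probe
#'
#' @param unit A `unit_recording` (64 channels).
#' @param pitch Channel pitch, um.
#' @return A ggplot object.
#' @export
plot_amplitude_profile <- function(unit, pitch = 10) {
  prof <- amplitude_profile(unit)
  df <- tibble(channel = seq_along(prof),
               y = (seq_along(prof) - (length(prof) + 1) / 2) * pitch,
               amplitude = prof)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$amplitude, y = .data$y)) +
    ggplot2::geom_path() +
    ggplot2::labs(x = "peak-to-trough amplitude (uV)",
                  y = "channel position (um)") +
    ggplot2::theme_minimal()
}

#' Autoplot an ME hierarchy as a dendrogram
#'
#' @param object An `me_hierarchy`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.me_hierarchy <- function(object, ...) {
  hc <- object$linkage
  # extract segment coordinates from the hclust merge structure
  n <- length(hc$order)
  xpos <- numeric(n)
  xpos[hc$order] <- seq_len(n)
  node_x <- numeric(nrow(hc$merge))
  node_h <- hc$height
  segs <- list()
  get_x <- function(k) if (k < 0) xpos[-k] else node_x[k]
  get_h <- function(k) if (k < 0) 0 else node_h[k]
  for (i in seq_len(nrow(hc$merge))) {
    a <- hc$merge[i, 1]; b <- hc$merge[i, 2]
    xa <- get_x(a); xb <- get_x(b)
    node_x[i] <- (xa + xb) / 2
    segs[[length(segs) + 1L]] <- tibble(
      x = c(xa, xa, xb), xend = c(xa, xb, xb),
      y = c(get_h(a), node_h[i], node_h[i]),
      yend = c(node_h[i], node_h[i], get_h(b)))
  }
  df <- dplyr::bind_rows(segs)
  labs <- tibble(x = seq_len(n), label = hc$labels[hc$order])
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed",
                        color = "red") +
    ggplot2::scale_x_continuous(breaks = labs$x, labels = labs$label) +
    ggplot2::labs(x = NULL, y = "normalized distance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
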