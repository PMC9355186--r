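## broom-style accessors and plots for evaluation results.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a screening evaluation
#'
#' @param x A `screening_eval` from [evaluate_screening()].
#' @param ... Unused.
#' @return A tibble with one row per metric: `metric`, `mean`, `ci_low`,
#'   `ci_high`, `n_experiments`.
#' @export
tidy.screening_eval <- function(x, ...) {
  dplyr::mutate(x$summary, n_experiments = x$n_experiments)
}

#' One-row summary of a screening evaluation
#'
#' @inheritParams tidy.screening_eval
#' @return A one-row tibble with the three metric means and CI bounds plus
#'   the evaluation settings.
#' @export
glance.screening_eval <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$summary, names_from = "metric",
                             values_from = c("mean", "ci_low", "ci_high"),
                             names_glue = "{metric}_{.value}")
  dplyr::bind_cols(wide,
                   tibble::tibble(n_experiments = x$n_experiments,
                                  base_seed = x$base_seed, k = x$k, C = x$C,
                                  kernel = x$kernel))
}

#' Plot the per-experiment metric distributions
#'
#' Violin of the per-experiment accuracy, sensitivity and specificity with
#' the mean and 95% confidence interval overlaid.
#'
#' @param object A `screening_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.screening_eval <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$experiments[c("accuracy", "sensitivity", "specificity")],
    cols = dplyr::everything(), names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_violin(fill = "grey85", colour = NA) +
    ggplot2::geom_pointrange(
      data = object$summary,
      ggplot2::aes(x = .data$metric, y = .data$mean,
                   ymin = .data$ci_low, ymax = .data$ci_high),
      colour = "firebrick"
    ) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "proportion",
                  title = sprintf("Repeated-split screening performance (%d experiments)",
                                  object$n_experiments)) +
    ggplot2::theme_minimal()
}

#' Plot per-subject position features
#'
#' Scatter of the similarity ratio S against the CLR ratio (measured
#' values only), coloured by label — the two geometric features the
#' classifier fuses with the embedding components.
#'
#' @param features A feature tibble from [process_cohort()] or
#'   [truth_features()].
#' @return A ggplot object.
#' @export
plot_position_features <- function(features) {
  ggplot2::ggplot(features,
                  ggplot2::aes(x = .data$S, y = .data$clr_measured,
                               colour = .data$label)) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = unlist(clr_reference_range()[1:2]),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "position-similarity ratio S",
                  y = "measured CLR ratio", colour = NULL,
                  title = "Geometric screening features") +
    ggplot2::theme_minimal()
}

#' Display a synthetic scene with its ground truth
#'
#' Renders the image as a raster with canthus landmarks, pupil centres and
#' reflex centres overlaid.
#'
#' @param image RGB array (0-255).
#' @param truth Optional `eye_truth` to overlay.
#' @return A ggplot object.
#' @export
plot_eye_scene <- function(image, truth = NULL) {
  gray <- as_gray(image)
  df <- tidyr::expand_grid(y = seq_len(nrow(gray)) - 1,
                           x = seq_len(ncol(gray)) - 1)
  df$value <- as.vector(t(gray))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255), guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (!is.null(truth)) {
    pts <- list()
    for (side in c("right", "left")) {
      for (f in c("canthus_medial", "canthus_lateral", "pupil_center",
                  "reflex_center")) {
        p0 <- truth[[paste0(f, "_", side)]]
        if (!is.null(p0)) {
          pts[[paste(f, side)]] <- tibble::tibble(x = p0[1], y = p0[2],
                                                  what = f)
        }
      }
    }
    pts <- dplyr::bind_rows(pts)
    p <- p + ggplot2::geom_point(
      data = pts, ggplot2::aes(x = .data$x, y = .data$y, colour = .data$what),
      inherit.aes = FALSE, size = 2
    ) + ggplot2::labs(colour = NULL)
  }
  p
}
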