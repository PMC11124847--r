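#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a signal dataset
#'
#' Overlays every decay in the dataset, coloured by its label — the usual
#' first look at a measurement campaign.
#'
#' @param object An `otter_dataset`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot otter_dataset
#' @export
autoplot.otter_dataset <- function(object, ...) {
  df <- tidy(object)
  colour_var <- names(object$labels)[1]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s * 1e3,
                                   y = .data$signal,
                                   group = .data$row,
                                   colour = .data[[colour_var]])) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "time [ms]", y = "signal [detector units]",
                  colour = colour_var,
                  title = sprintf("%s dataset (%d signals)", object$kind,
                                  nrow(object$signals))) +
    ggplot2::theme_minimal()
}

#' Plot a depth profile
#'
#' Absorption coefficient (and hydration, when present) against probing
#' depth in microns.
#'
#' @param object An `otter_depth_profile` from [sls_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot otter_depth_profile
#' @export
autoplot.otter_depth_profile <- function(object, ...) {
  df <- as.data.frame(object)
  if ("hydration" %in% names(df)) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$z_um,
                                     y = 100 * .data$hydration)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "depth [µm]", y = "hydration [%]",
                    title = "SLS hydration depth profile") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$z_um, y = .data$beta)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "depth [µm]",
                    y = "emission absorption coefficient [1/m]",
                    title = "SLS depth profile") +
      ggplot2::theme_minimal()
  }
}

#' Plot a two-component embedding
#'
#' @param object An `otter_embedding` from [embed_signals()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot otter_embedding
#' @export
autoplot.otter_embedding <- function(object, ...) {
  df <- as.data.frame(object)
  label_col <- setdiff(names(df), c("row", grep("^comp", names(df),
                                                value = TRUE)))[1]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$comp1, y = .data$comp2))
  if (!is.na(label_col)) {
    p <- p + ggplot2::geom_point(
      ggplot2::aes(colour = factor(.data[[label_col]])), size = 3) +
      ggplot2::labs(colour = label_col)
  } else {
    p <- p + ggplot2::geom_point(size = 3)
  }
  p + ggplot2::labs(x = "component 1", y = "component 2",
                    title = toupper(attr(object, "method"))) +
    ggplot2::theme_minimal()
}

#' Plot predicted versus true values per model
#'
#' @param object An `otter_regression_report`.
#' @param ... Unused.
#' @return A ggplot object faceted by model.
#' @method autoplot otter_regression_report
#' @export
autoplot.otter_regression_report <- function(object, ...) {
  ok <- object[is.na(object$error), , drop = FALSE]
  df <- dplyr::bind_rows(
    lapply(seq_len(nrow(ok)), function(i) {
      cbind(model = ok$model[i], target = ok$target[i],
            as.data.frame(ok$predictions[[i]]))
    }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$truth, y = .data$predicted,
                                   colour = .data$partition)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~ model) +
    ggplot2::labs(title = "predicted vs true") +
    ggplot2::theme_minimal()
}

#' Plot the top-ranked features of an importance report
#'
#' @param object An `otter_importance_report`.
#' @param top_n Number of leading features to show (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot otter_importance_report
#' @export
autoplot.otter_importance_report <- function(object, top_n = 20, ...) {
  df <- as.data.frame(object)
  df <- df[order(df$rank), , drop = FALSE][seq_len(min(top_n, nrow(df))), ]
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = sprintf("importance (%s)", df$method[1]),
                  y = "feature",
                  title = "feature importance") +
    ggplot2::theme_minimal()
}
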