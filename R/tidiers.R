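#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted decay model
#'
#' @param x An `otter_fit` from [fit_homogeneous()] or [fit_gradient()].
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`).
#' @method tidy otter_fit
#' @export
tidy.otter_fit <- function(x, ...) {
  params <- x$params[!vapply(x$params, is.null, logical(1))]
  tibble::tibble(term = names(params),
                 estimate = unlist(params, use.names = FALSE))
}

#' One-row summary of a fitted decay model
#'
#' @inheritParams tidy.otter_fit
#' @return A tibble with `model`, `beta`, `residual_rms`, `converged`,
#'   `n_iter`.
#' @method glance otter_fit
#' @export
glance.otter_fit <- function(x, ...) {
  tibble::tibble(model = x$model, beta = x$beta,
                 residual_rms = x$residual_rms, converged = x$converged,
                 n_iter = x$n_iter)
}

#' Tidy a linearized depth profile
#'
#' @param x A `linear_beta_profile` from [linearize_profile()].
#' @param ... Unused.
#' @return A tibble with `term` (`beta0`, `w_beta`) and `estimate`.
#' @method tidy linear_beta_profile
#' @export
tidy.linear_beta_profile <- function(x, ...) {
  tibble::tibble(term = c("beta0", "w_beta"),
                 estimate = c(x$beta0, x$w_beta))
}

#' Long-format view of a signal dataset
#'
#' @param x An `otter_dataset`.
#' @param ... Unused.
#' @return A tibble with one row per (signal, time sample): `row`,
#'   `time_s`, `signal`, and the dataset's label columns.
#' @method tidy otter_dataset
#' @export
tidy.otter_dataset <- function(x, ...) {
  n <- nrow(x$signals)
  p <- ncol(x$signals)
  out <- tibble::tibble(
    row = rep(seq_len(n), each = p),
    time_s = rep(x$grid, times = n),
    signal = as.vector(t(x$signals)))
  for (nm in names(x$labels)) {
    out[[nm]] <- rep(x$labels[[nm]], each = p)
  }
  out
}

#' One-row summary of a signal dataset
#'
#' @inheritParams tidy.otter_dataset
#' @return A tibble with `kind`, `n_signals`, `n_points`, `t_max_s`,
#'   `noise_sd`, `seed`.
#' @method glance otter_dataset
#' @export
glance.otter_dataset <- function(x, ...) {
  tibble::tibble(kind = x$kind, n_signals = nrow(x$signals),
                 n_points = ncol(x$signals), t_max_s = max(x$grid),
                 noise_sd = x$acq$noise_sd, seed = x$seed)
}
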