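#' Signal window
#'
#' A half-open pair of sample indices delimiting the usable part of a raw
#' record: from the laser-pulse peak to where the decay reaches the noise
#' floor.
#'
#' @param start,end Sample indices, `1 <= start < end <=` record length.
#' @param n Optional record length for bound checking.
#' @return An object of class `signal_window`.
#' @export
signal_window <- function(start, end, n = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1 || end <= start) {
    stop("need 1 <= start < end", call. = FALSE)
  }
  if (!is.null(n) && end > n) {
    stop("`end` exceeds the record length", call. = FALSE)
  }
  structure(list(start = start, end = end), class = "signal_window")
}

as_signal_tbl <- function(sig) {
  if (inherits(sig, "otter_dataset")) {
    stop("pass a single signal (e.g. dataset_signal(data, i)), not a dataset",
         call. = FALSE)
  }
  sig <- as.data.frame(sig)
  if (!all(c("time_s", "signal") %in% names(sig))) {
    if (ncol(sig) < 2) stop("signal needs `time_s` and `signal` columns",
                            call. = FALSE)
    names(sig)[1:2] <- c("time_s", "signal")
  }
  sig
}

#' Locate the transient within a raw record
#'
#' The window starts at the global-maximum sample (the laser-pulse peak;
#' earliest index on ties) and ends at the first later sample where the
#' moving-average-smoothed signal falls below `floor_frac` of the peak above
#' baseline. If the decay never reaches that floor, the window runs to the
#' last sample. The baseline is the median of the pre-peak samples (the
#' record minimum when the record starts at the peak).
#'
#' @param sig A data frame with columns `time_s` and `signal`, at least 32
#'   rows.
#' @param floor_frac Fraction of the peak-above-baseline at which the decay
#'   is considered over (default 0.02).
#' @param smooth_n Width (samples) of the moving average used before
#'   thresholding (default 5).
#' @return A [signal_window()].
#' @export
detect_window <- function(sig, floor_frac = 0.02, smooth_n = 5) {
  sig <- as_signal_tbl(sig)
  s <- sig$signal
  n <- length(s)
  if (n < 32) stop("record too short: need >= 32 samples", call. = FALSE)
  if (max(s) == min(s)) {
    stop("flat record: no transient detected", call. = FALSE)
  }
  start <- which.max(s)
  # baseline from the pre-pulse samples; a record that opens at the peak
  # is taken as already baseline-corrected
  baseline <- if (start >= 8) stats::median(s[1:(start - 1)]) else 0
  peak <- s[start]
  sm <- as.numeric(stats::filter(s, rep(1 / smooth_n, smooth_n),
                                 sides = 2))
  sm[is.na(sm)] <- s[is.na(sm)]
  floor_level <- baseline + floor_frac * (peak - baseline)
  below <- which(sm[(start + 1):n] < floor_level)
  end <- if (length(below)) start + below[1] else n
  signal_window(start, end, n)
}

window_or_default <- function(sig, window) {
  if (is.null(window)) signal_window(1, nrow(sig), nrow(sig)) else window
}

new_otter_fit <- function(model, params, beta, residual_rms, converged,
                          n_iter, window, D) {
  structure(
    list(model = model, params = params, beta = beta,
         residual_rms = residual_rms, converged = converged,
         n_iter = n_iter, window = window, D = D),
    class = "otter_fit"
  )
}

#' @export
print.otter_fit <- function(x, ...) {
  cat(sprintf("<otter_fit: %s model>\n", x$model))
  p <- x$params
  cat(sprintf("  A = %.6g  tau = %.6g s%s\n", p$A, p$tau,
              if (!is.null(p$W)) sprintf("  W = %.6g 1/s", p$W) else ""))
  cat(sprintf("  beta = %.6g 1/m  residual rms = %.3g  %s (%d iter)\n",
              x$beta, x$residual_rms,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

lm_fit_control <- function() {
  minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10, maxiter = 200)
}

init_homogeneous <- function(tt, s) {
  A0 <- max(s[1], .Machine$double.eps)
  # lifetime guess: time at which the decay crosses exp_erfc(1) * A0
  target <- exp_erfc(1) * A0
  idx <- which(s <= target)
  tau0 <- if (length(idx) && tt[idx[1]] > 0) tt[idx[1]] else
    max(stats::median(tt), .Machine$double.eps)
  c(A = A0, tau = tau0)
}

#' Fit the homogeneous decay model to a windowed signal
#'
#' Least-squares estimation of amplitude `A` and decay lifetime `tau` of
#' the homogeneous transient emission model, by Levenberg-Marquardt
#' trust-region iteration with positivity bounds. Time is taken relative to
#' the window start. The absorption coefficient `beta = 1/sqrt(tau D)` is
#' derived from the fitted lifetime.
#'
#' @param sig A data frame with columns `time_s` and `signal`.
#' @param window A [signal_window()], or `NULL` to use the whole record.
#' @param D Thermal diffusivity, m^2/s, used to convert `tau` to `beta`.
#' @param init Optional named vector `c(A=, tau=)` of starting values;
#'   defaults to the first windowed sample and a grid lookup of the
#'   `exp_erfc(1)` crossing.
#' @return An `otter_fit` with elements `params` (`A`, `tau`), `beta`,
#'   `residual_rms`, `converged`, `n_iter`. Non-convergence is reported
#'   honestly through `converged = FALSE`, never raised.
#' @seealso [fit_gradient()], [sls_profile()], [tidy.otter_fit()]
#' @export
fit_homogeneous <- function(sig, window = NULL, D = skin_defaults()$D,
                            init = NULL) {
  sig <- as_signal_tbl(sig)
  window <- window_or_default(sig, window)
  idx <- window$start:window$end
  if (length(idx) < 8) {
    stop("window too short: need >= 8 samples to fit", call. = FALSE)
  }
  tt <- sig$time_s[idx] - sig$time_s[window$start]
  s <- sig$signal[idx]
  start <- if (is.null(init)) init_homogeneous(tt, s) else init
  res <- minpack.lm::nls.lm(
    par = list(A = unname(start["A"]), tau = unname(start["tau"])),
    lower = c(1e-12, 1e-12), upper = c(Inf, Inf),
    fn = function(p) p$A * exp_erfc(tt / p$tau) - s,
    control = lm_fit_control()
  )
  p <- as.list(stats::coef(res))
  new_otter_fit(
    model = "homogeneous",
    params = list(A = p$A, tau = p$tau),
    beta = beta_from_tau(p$tau, D),
    residual_rms = sqrt(mean(res$fvec^2)),
    converged = res$info %in% 1:3,
    n_iter = res$niter,
    window = window, D = D
  )
}

#' Fit the linear-gradient decay model to a windowed signal
#'
#' Least-squares estimation of `(A, tau, W)` in the graded-absorption
#' transient model. Initialised from the homogeneous fit with `W = 0`; `W`
#' is bounded below so that `2 W t + 1` stays positive over the window
#' (the model's validity region). `beta` is the surface absorption
#' coefficient derived from the fitted surface lifetime.
#'
#' @inheritParams fit_homogeneous
#' @return An `otter_fit` with `params` (`A`, `tau`, `W`).
#' @export
fit_gradient <- function(sig, window = NULL, D = skin_defaults()$D,
                         init = NULL) {
  sig <- as_signal_tbl(sig)
  window <- window_or_default(sig, window)
  idx <- window$start:window$end
  if (length(idx) < 8) {
    stop("window too short: need >= 8 samples to fit", call. = FALSE)
  }
  tt <- sig$time_s[idx] - sig$time_s[window$start]
  s <- sig$signal[idx]
  if (is.null(init)) {
    h <- fit_homogeneous(sig, window, D)
    start <- list(A = h$params$A, tau = h$params$tau, W = 0)
  } else {
    start <- as.list(init)
    if (is.null(start$W)) start$W <- 0
  }
  t_max <- max(tt)
  W_lower <- -(1 - 1e-9) / (2 * t_max)
  res <- minpack.lm::nls.lm(
    par = start,
    lower = c(1e-12, 1e-12, W_lower), upper = c(Inf, Inf, Inf),
    fn = function(p) {
      den <- 2 * p$W * tt + 1
      p$A * (2 * p$W * sqrt(tt * p$tau / pi) / den +
               exp_erfc((tt / p$tau) / den) / den^1.5) - s
    },
    control = lm_fit_control()
  )
  p <- as.list(stats::coef(res))
  new_otter_fit(
    model = "gradient",
    params = list(A = p$A, tau = p$tau, W = p$W),
    beta = beta_from_tau(p$tau, D),
    residual_rms = sqrt(mean(res$fvec^2)),
    converged = res$info %in% 1:3,
    n_iter = res$niter,
    window = window, D = D
  )
}

#' Segmented least-squares depth profiling
#'
#' Recovers an absorption-coefficient (and hydration) depth profile from a
#' single decay by segmented least squares: the window is divided into
#' `n_slices` equal-duration slices; for each `k`, the homogeneous model is
#' fitted to the cumulative data from slice 1 through slice `k`, giving
#' `beta_k`; the probing depth assigned to slice `k` is the thermal
#' diffusion length \eqn{z_k = \sqrt{D t_k}} (times an optional prefactor)
#' at the slice's end time, measured from the window start. Early slices
#' see only shallow material, so the `beta_k` sequence resolves depth
#' structure within roughly the top 20 microns of skin.
#'
#' The whole-window fit seeds the first slice fit; each cumulative fit then
#' warm-starts the next. A cumulative fit that fails to converge is flagged
#' in the `converged` column, never fabricated.
#'
#' @inheritParams fit_homogeneous
#' @param n_slices Number of slices (default 10); the window must hold at
#'   least `4 * n_slices` samples.
#' @param beta_w,beta_d Optional reference absorption coefficients; when
#'   given, a `hydration` column is added through the hydration relation.
#' @param depth_prefactor Multiplier on the `sqrt(D t)` probing depth
#'   (default 1).
#' @return A tibble of class `otter_depth_profile` with columns `slice`,
#'   `t_end_s`, `z_m`, `z_um`, `beta`, `converged` (and `hydration` when an
#'   optical pair is supplied), plus attributes `D` and `slice_bounds`.
#' @seealso [linearize_profile()]
#' @export
sls_profile <- function(sig, window = NULL, D = skin_defaults()$D,
                        n_slices = 10, beta_w = NULL, beta_d = NULL,
                        depth_prefactor = 1) {
  sig <- as_signal_tbl(sig)
  window <- window_or_default(sig, window)
  idx <- window$start:window$end
  if (n_slices < 1 || n_slices != round(n_slices)) {
    stop("`n_slices` must be a whole number >= 1", call. = FALSE)
  }
  if (length(idx) < 4 * n_slices) {
    stop(sprintf("window too short: need >= %d samples for %d slices",
                 4 * n_slices, n_slices), call. = FALSE)
  }
  tt <- sig$time_s[idx] - sig$time_s[window$start]
  T_total <- max(tt)
  whole <- fit_homogeneous(sig, window, D)
  init <- c(A = whole$params$A, tau = whole$params$tau)

  slice <- integer(n_slices)
  t_end <- numeric(n_slices)
  beta_k <- numeric(n_slices)
  conv <- logical(n_slices)
  bounds <- integer(n_slices)
  for (k in seq_len(n_slices)) {
    edge <- T_total * k / n_slices
    last <- max(which(tt <= edge + 1e-12 * T_total))
    last <- min(max(last, 8L), length(idx))  # a fit needs >= 8 samples
    sub <- signal_window(window$start, window$start + last - 1, nrow(sig))
    fit <- fit_homogeneous(sig, sub, D, init = init)
    slice[k] <- k
    t_end[k] <- edge
    beta_k[k] <- fit$beta
    conv[k] <- fit$converged
    bounds[k] <- sub$end
    if (fit$converged) init <- c(A = fit$params$A, tau = fit$params$tau)
  }
  z <- depth_prefactor * sqrt(D * t_end)
  out <- tibble::tibble(slice = slice, t_end_s = t_end, z_m = z,
                        z_um = z * 1e6, beta = beta_k, converged = conv)
  if (!is.null(beta_w) && !is.null(beta_d)) {
    out$hydration <- suppressWarnings(
      hydration_from_beta(out$beta, beta_w, beta_d))
  }
  attr(out, "D") <- D
  attr(out, "slice_bounds") <- bounds
  class(out) <- c("otter_depth_profile", class(out))
  out
}

#' Linearize a depth profile
#'
#' Ordinary least-squares straight line `beta(z) = beta0 + w_beta z`
#' through the points of a depth profile, summarising the profile by its
#' surface value and gradient.
#'
#' @param profile An [sls_profile()] result, or any data frame with columns
#'   `z_m` and `beta`; at least 2 valid points.
#' @return A list of class `linear_beta_profile` with `beta0` (1/m),
#'   `w_beta` (1/m^2), `r_squared`, and `n_points`.
#' @export
linearize_profile <- function(profile) {
  df <- as.data.frame(profile)
  if (!all(c("z_m", "beta") %in% names(df))) {
    stop("profile needs `z_m` and `beta` columns", call. = FALSE)
  }
  if ("converged" %in% names(df)) df <- df[df$converged, , drop = FALSE]
  df <- df[is.finite(df$z_m) & is.finite(df$beta), , drop = FALSE]
  if (nrow(df) < 2) {
    stop("need at least 2 valid profile points to fit a line",
         call. = FALSE)
  }
  fit <- stats::lm(beta ~ z_m, data = df)
  ss_tot <- sum((df$beta - mean(df$beta))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(
    list(beta0 = unname(stats::coef(fit)[1]),
         w_beta = unname(stats::coef(fit)[2]),
         r_squared = r2, n_points = nrow(df)),
    class = "linear_beta_profile"
  )
}

#' @export
print.linear_beta_profile <- function(x, ...) {
  cat(sprintf("<linear_beta_profile> beta0 = %.6g 1/m, w_beta = %.6g 1/m^2 (R^2 = %.4f, %d points)\n",
              x$beta0, x$w_beta, x$r_squared, x$n_points))
  invisible(x)
}
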