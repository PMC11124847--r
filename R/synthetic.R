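#' Acquisition settings for synthetic signal generation
#'
#' Describes how a transient decay is digitised: number of samples, record
#' length relative to the decay lifetime, additive detector noise, and
#' baseline offset. The defaults emulate a millisecond-scale photothermal
#' decay recorded well into its tail.
#'
#' @param n_points Samples per record (default 512, minimum 16).
#' @param t_max_over_tau Record length as a multiple of the reference decay
#'   lifetime (default 20).
#' @param noise_sd Standard deviation of additive Gaussian noise, relative to
#'   each signal's amplitude `A` (default 0.01).
#' @param baseline Additive offset in detector units (default 0).
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(n_points = 512, t_max_over_tau = 20,
                               noise_sd = 0.01, baseline = 0) {
  if (!is.numeric(n_points) || length(n_points) != 1 || n_points < 16 ||
      n_points != round(n_points)) {
    stop("`n_points` must be a whole number >= 16", call. = FALSE)
  }
  check_positive(t_max_over_tau, "t_max_over_tau")
  if (!is.numeric(noise_sd) || length(noise_sd) != 1 || !is.finite(noise_sd) ||
      noise_sd < 0) {
    stop("`noise_sd` must be a single finite value >= 0", call. = FALSE)
  }
  if (!is.numeric(baseline) || length(baseline) != 1 || !is.finite(baseline)) {
    stop("`baseline` must be a single finite value", call. = FALSE)
  }
  structure(
    list(n_points = as.integer(n_points), t_max_over_tau = t_max_over_tau,
         noise_sd = noise_sd, baseline = baseline),
    class = "acquisition_config"
  )
}

#' Specification of a synthetic hydration-regression campaign
#'
#' Defines the population from which labelled decays are drawn. In
#' `"homogeneous"` mode each signal carries a single hydration fraction; in
#' `"gradient"` mode it carries a (surface hydration, hydration depth
#' gradient) pair realised through the linear absorption-gradient signal
#' model.
#'
#' @param n_signals Number of signals (default 97, the size of the
#'   volunteer regression campaign this generator emulates; minimum 4).
#' @param hydration_range Interval within `[0, 1]` from which hydration
#'   fractions are drawn uniformly (default `c(0.3, 0.9)`).
#' @param mode `"homogeneous"` or `"gradient"`.
#' @param gradient_range Interval for the hydration depth gradient label,
#'   fraction per metre of depth (default `c(-2e3, 2e3)`, i.e. up to
#'   +/-0.2 % hydration per micron — the validity region of the
#'   linear-gradient model over a 20-lifetime record).
#' @param amplitude_mean,amplitude_sd Mean and standard deviation of the
#'   per-signal amplitude `A` (detector units); amplitudes vary between
#'   measurements through skin emissivity and optical coupling.
#' @param D Thermal diffusivity, m^2/s.
#' @param beta_w,beta_d Reference emission absorption coefficients, 1/m.
#' @return An object of class `regression_spec`.
#' @export
regression_spec <- function(n_signals = 97, hydration_range = c(0.3, 0.9),
                            mode = c("homogeneous", "gradient"),
                            gradient_range = c(-2e3, 2e3),
                            amplitude_mean = 1, amplitude_sd = 0.05,
                            D = skin_defaults()$D,
                            beta_w = skin_defaults()$beta_w,
                            beta_d = skin_defaults()$beta_d) {
  mode <- match.arg(mode)
  if (!is.numeric(n_signals) || length(n_signals) != 1 || n_signals < 4 ||
      n_signals != round(n_signals)) {
    stop("`n_signals` must be a whole number >= 4", call. = FALSE)
  }
  if (!is.numeric(hydration_range) || length(hydration_range) != 2 ||
      hydration_range[1] > hydration_range[2] ||
      hydration_range[1] < 0 || hydration_range[2] > 1) {
    stop("`hydration_range` must be an ordered interval within [0, 1]",
         call. = FALSE)
  }
  if (!is.numeric(gradient_range) || length(gradient_range) != 2 ||
      gradient_range[1] > gradient_range[2]) {
    stop("`gradient_range` must be an ordered interval", call. = FALSE)
  }
  check_positive(amplitude_mean, "amplitude_mean")
  structure(
    list(n_signals = as.integer(n_signals),
         hydration_range = hydration_range, mode = mode,
         gradient_range = gradient_range, amplitude_mean = amplitude_mean,
         amplitude_sd = amplitude_sd, D = D, beta_w = beta_w,
         beta_d = beta_d),
    class = "regression_spec"
  )
}

#' Specification of a synthetic subject-classification campaign
#'
#' Emulates a small classification study: a few subjects, each measured a
#' handful of times. Subjects differ in mean hydration (hence decay
#' lifetime) and in mean amplitude (skin emissivity / optical coupling);
#' within-subject spread is small relative to the between-subject
#' separation, mirroring visually separable repeated measurements.
#'
#' @param n_classes Number of subjects (default 4, minimum 2).
#' @param per_class Signals per subject (default 5, minimum 2).
#' @param class_hydration Per-subject mean hydration fractions
#'   (length `n_classes`).
#' @param class_amplitude Per-subject mean amplitudes, detector units.
#' @param hydration_sd Within-subject hydration standard deviation.
#' @param amplitude_sd Within-subject amplitude standard deviation.
#' @inheritParams regression_spec
#' @return An object of class `classification_spec`.
#' @export
classification_spec <- function(n_classes = 4, per_class = 5,
                                class_hydration = c(0.35, 0.5, 0.65, 0.8),
                                class_amplitude = c(0.9, 1.0, 1.1, 1.2),
                                hydration_sd = 0.02, amplitude_sd = 0.02,
                                D = skin_defaults()$D,
                                beta_w = skin_defaults()$beta_w,
                                beta_d = skin_defaults()$beta_d) {
  if (!is.numeric(n_classes) || length(n_classes) != 1 || n_classes < 2 ||
      n_classes != round(n_classes)) {
    stop("`n_classes` must be a whole number >= 2", call. = FALSE)
  }
  if (!is.numeric(per_class) || length(per_class) != 1 || per_class < 2 ||
      per_class != round(per_class)) {
    stop("`per_class` must be a whole number >= 2", call. = FALSE)
  }
  if (length(class_hydration) != n_classes ||
      length(class_amplitude) != n_classes) {
    stop("`class_hydration` and `class_amplitude` must have one entry per ",
         "class", call. = FALSE)
  }
  structure(
    list(n_classes = as.integer(n_classes), per_class = as.integer(per_class),
         class_hydration = class_hydration,
         class_amplitude = class_amplitude, hydration_sd = hydration_sd,
         amplitude_sd = amplitude_sd, D = D, beta_w = beta_w,
         beta_d = beta_d),
    class = "classification_spec"
  )
}

#' Add seeded Gaussian detector noise to a signal
#'
#' @param signal Numeric vector of signal values.
#' @param sd Noise standard deviation in detector units, `>= 0`; `sd = 0`
#'   returns the input unchanged.
#' @param seed Optional integer seed for a reproducible draw.
#' @return The noisy signal, same length as the input.
#' @export
add_noise <- function(signal, sd, seed = NULL) {
  if (!is.numeric(sd) || length(sd) != 1 || !is.finite(sd) || sd < 0) {
    stop("`sd` must be a single finite value >= 0", call. = FALSE)
  }
  if (sd == 0) return(signal)
  if (!is.null(seed)) set.seed(seed)
  signal + stats::rnorm(length(signal), mean = 0, sd = sd)
}

new_otter_dataset <- function(signals, grid, labels, truth, kind, spec, acq,
                              seed) {
  stopifnot(nrow(signals) == nrow(labels), nrow(signals) == nrow(truth),
            ncol(signals) == length(grid))
  rownames(signals) <- sprintf("s%03d", seq_len(nrow(signals)))
  structure(
    list(signals = signals, grid = grid, labels = labels, truth = truth,
         kind = kind, spec = spec, acq = acq, seed = seed),
    class = "otter_dataset"
  )
}

#' @export
print.otter_dataset <- function(x, ...) {
  cat(sprintf("<otter_dataset: %s>\n", x$kind))
  cat(sprintf("  %d signals x %d time samples (t in [0, %.3g] s)\n",
              nrow(x$signals), ncol(x$signals), max(x$grid)))
  cat(sprintf("  labels: %s | seed: %s\n",
              paste(names(x$labels), collapse = ", "),
              format(x$seed)))
  invisible(x)
}

draw_positive <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  bad <- x <= 0
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- x <= 0
  }
  x
}

#' Generate a labelled synthetic hydration-regression dataset
#'
#' Draws hydration labels, maps them to forward-model parameters through the
#' hydration relation and `tau = 1/(beta^2 D)`, synthesises each decay on a
#' common time grid, and adds seeded Gaussian noise. The grid spans
#' `[0, t_max_over_tau * tau_ref]` where `tau_ref` is the median generated
#' lifetime, so that all rows share one feature grid. Generation is a pure
#' function of `(spec, acq, seed)`.
#'
#' In `"gradient"` mode the label is the pair (surface hydration, hydration
#' depth gradient in fraction/m); the gradient maps to the effective
#' gradient `W = w_beta * D` of the linear-gradient signal model, and draws
#' whose `W` would make the model singular on the grid raise an error.
#'
#' @param spec A [regression_spec()].
#' @param acq An [acquisition_config()].
#' @param seed Integer seed.
#' @return An `otter_dataset` with fields `signals` (matrix, rows =
#'   signals), `grid` (seconds), `labels` and `truth` (tibbles), and
#'   generation provenance.
#' @examples
#' ds <- generate_regression_dataset(regression_spec(n_signals = 8),
#'                                   acquisition_config(n_points = 64),
#'                                   seed = 1)
#' ds
#' @export
generate_regression_dataset <- function(spec = regression_spec(),
                                        acq = acquisition_config(),
                                        seed = 1) {
  stopifnot(inherits(spec, "regression_spec"),
            inherits(acq, "acquisition_config"))
  set.seed(seed)
  n <- spec$n_signals
  A <- draw_positive(n, spec$amplitude_mean, spec$amplitude_sd)

  if (spec$mode == "homogeneous") {
    H <- stats::runif(n, spec$hydration_range[1], spec$hydration_range[2])
    beta <- beta_from_hydration(H, spec$beta_w, spec$beta_d)
    if (any(beta <= 0)) {
      stop("hydration range maps to non-positive beta for this optical pair",
           call. = FALSE)
    }
    tau <- tau_from_beta(beta, spec$D)
    grid <- seq(0, acq$t_max_over_tau * stats::median(tau),
                length.out = acq$n_points)
    clean <- t(vapply(seq_len(n),
                      function(i) signal_homogeneous(grid, A[i], tau[i]),
                      numeric(acq$n_points)))
    labels <- tibble::tibble(hydration = H)
    truth <- tibble::tibble(A = A, tau = tau, beta = beta, hydration = H)
  } else {
    H0 <- stats::runif(n, spec$hydration_range[1], spec$hydration_range[2])
    g <- stats::runif(n, spec$gradient_range[1], spec$gradient_range[2])
    beta0 <- beta_from_hydration(H0, spec$beta_w, spec$beta_d)
    if (any(beta0 <= 0)) {
      stop("hydration range maps to non-positive beta for this optical pair",
           call. = FALSE)
    }
    # as-printed hydration relation: beta = beta_w - H (beta_w - beta_d),
    # so dbeta/dz = -(beta_w - beta_d) * dH/dz
    w_beta <- -(spec$beta_w - spec$beta_d) * g
    W <- w_beta * spec$D
    tau <- tau_from_beta(beta0, spec$D)
    grid <- seq(0, acq$t_max_over_tau * stats::median(tau),
                length.out = acq$n_points)
    if (any(2 * W * max(grid) + 1 <= 0.05)) {
      stop("`gradient_range` drives the linear-gradient model to its ",
           "singularity within the record; narrow the range or shorten ",
           "the record", call. = FALSE)
    }
    clean <- t(vapply(seq_len(n),
                      function(i) signal_gradient(grid, A[i], tau[i], W[i]),
                      numeric(acq$n_points)))
    labels <- tibble::tibble(h_surface = H0, h_gradient = g)
    truth <- tibble::tibble(A = A, tau = tau, beta0 = beta0,
                            w_beta = w_beta, W = W, h_surface = H0,
                            h_gradient = g)
  }

  noise <- matrix(stats::rnorm(n * acq$n_points), nrow = n) *
    (acq$noise_sd * A)
  signals <- clean + if (acq$noise_sd > 0) noise else 0
  signals <- signals + acq$baseline

  new_otter_dataset(signals, grid, labels, truth, kind = "regression",
                    spec = spec, acq = acq, seed = seed)
}

#' Generate a labelled synthetic subject-classification dataset
#'
#' Draws `per_class` (amplitude, hydration) pairs around each subject's
#' means, maps hydration to the decay lifetime, synthesises homogeneous
#' decays on a common grid, and adds seeded noise. Labels are subject
#' identities (`factor` `"1"`, `"2"`, ...). Deterministic given the seed.
#'
#' @param spec A [classification_spec()].
#' @inheritParams generate_regression_dataset
#' @return An `otter_dataset` of kind `"classification"`.
#' @examples
#' ds <- generate_classification_dataset(
#'   classification_spec(), acquisition_config(n_points = 64), seed = 1)
#' table(ds$labels$subject)
#' @export
generate_classification_dataset <- function(spec = classification_spec(),
                                            acq = acquisition_config(),
                                            seed = 1) {
  stopifnot(inherits(spec, "classification_spec"),
            inherits(acq, "acquisition_config"))
  set.seed(seed)
  n <- spec$n_classes * spec$per_class
  cls <- rep(seq_len(spec$n_classes), each = spec$per_class)
  A <- draw_positive(n, spec$class_amplitude[cls], spec$amplitude_sd)
  H <- stats::rnorm(n, spec$class_hydration[cls], spec$hydration_sd)
  H <- pmin(pmax(H, 1e-3), 1 - 1e-3)
  beta <- beta_from_hydration(H, spec$beta_w, spec$beta_d)
  tau <- tau_from_beta(beta, spec$D)
  grid <- seq(0, acq$t_max_over_tau * stats::median(tau),
              length.out = acq$n_points)
  clean <- t(vapply(seq_len(n),
                    function(i) signal_homogeneous(grid, A[i], tau[i]),
                    numeric(acq$n_points)))
  noise <- matrix(stats::rnorm(n * acq$n_points), nrow = n) *
    (acq$noise_sd * A)
  signals <- clean + if (acq$noise_sd > 0) noise else 0
  signals <- signals + acq$baseline

  labels <- tibble::tibble(subject = factor(cls))
  truth <- tibble::tibble(A = A, tau = tau, beta = beta, hydration = H,
                          subject = factor(cls))
  new_otter_dataset(signals, grid, labels, truth, kind = "classification",
                    spec = spec, acq = acq, seed = seed)
}

#' Extract a single record from a dataset as a signal table
#'
#' @param data An `otter_dataset`.
#' @param i Row index.
#' @return A tibble with columns `time_s` and `signal`.
#' @export
dataset_signal <- function(data, i) {
  stopifnot(inherits(data, "otter_dataset"),
            i >= 1, i <= nrow(data$signals))
  tibble::tibble(time_s = data$grid, signal = data$signals[i, ])
}

#' Reorder the rows of a dataset
#'
#' Permutes signals, labels, and truth together, preserving alignment.
#'
#' @param data An `otter_dataset`.
#' @param idx Integer permutation of the row indices.
#' @return The permuted `otter_dataset`.
#' @export
permute_dataset <- function(data, idx) {
  stopifnot(inherits(data, "otter_dataset"),
            setequal(idx, seq_len(nrow(data$signals))))
  data$signals <- data$signals[idx, , drop = FALSE]
  data$labels <- data$labels[idx, , drop = FALSE]
  data$truth <- data$truth[idx, , drop = FALSE]
  data
}
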