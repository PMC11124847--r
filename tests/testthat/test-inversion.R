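sig_clean <- function(A = 1, tau = 1e-3, n = 256, span = 20) {
  t <- seq(0, span * tau, length.out = n)
  tibble::tibble(time_s = t, signal = signal_homogeneous(t, A, tau))
}

test_that("detect_window finds the pulse peak and the decay floor", {
  # clean decay prepended with a zero baseline: start at the peak sample;
  # the algebraic 1/sqrt(pi t/tau) tail only reaches 2% near t ~ 800 tau
  tau <- 1e-3
  base <- sig_clean(tau = tau, n = 480, span = 2000)
  pre <- tibble::tibble(time_s = seq(-1e-3, -1e-5, length.out = 32),
                        signal = rep(0, 32))
  pre$time_s <- pre$time_s - min(pre$time_s) # shift to >= 0
  rec <- tibble::tibble(
    time_s = c(pre$time_s, base$time_s + max(pre$time_s) + 1e-5),
    signal = c(pre$signal, base$signal))
  w <- detect_window(rec)
  expect_equal(w$start, 33)
  # floor-crossing time agrees with a scalar root-finder on the kernel
  t_end <- rec$time_s[w$end] - rec$time_s[w$start]
  t_star <- stats::uniroot(function(t) exp_erfc(t / tau) - 0.02,
                           c(tau, 1e4 * tau), tol = 1e-12)$root
  dt <- diff(rec$time_s)[40]
  expect_lt(abs(t_end - t_star), 3 * dt)
})

test_that("detect_window falls back to the last sample and rejects flat records", {
  s <- sig_clean(n = 64, span = 3)   # never decays to 2% within the record
  w <- detect_window(s)
  expect_equal(w$end, 64)
  flat <- tibble::tibble(time_s = seq(0, 1, length.out = 64),
                         signal = rep(1, 64))
  expect_error(detect_window(flat), "flat record")
  expect_error(detect_window(sig_clean(n = 16)), "32 samples")
})

test_that("homogeneous fit recovers noiseless parameters to 1e-6 relative", {
  s <- sig_clean(A = 1, tau = 1e-3)
  fit <- fit_homogeneous(s, D = 1e-7)
  expect_true(fit$converged)
  expect_lt(abs(fit$params$A - 1), 1e-6)
  expect_lt(abs(fit$params$tau - 1e-3), 1e-9)
  expect_equal(fit$beta, beta_from_tau(fit$params$tau, 1e-7))
  expect_lt(fit$residual_rms, 1e-8)
  td <- tidy(fit)
  expect_equal(td$term, c("A", "tau"))
})

test_that("fits refuse windows shorter than 8 samples", {
  s <- sig_clean()
  expect_error(fit_homogeneous(s, signal_window(1, 6)), ">= 8 samples")
  expect_error(fit_gradient(s, signal_window(1, 6)), ">= 8 samples")
})

test_that("gradient fit recovers W = 0 and nonzero gradients from clean signals", {
  s0 <- sig_clean(A = 1.2, tau = 8e-4)
  f0 <- fit_gradient(s0, D = 1e-7)
  expect_true(f0$converged)
  expect_lt(abs(f0$params$W) * 2 * max(s0$time_s), 1e-4)
  expect_lt(abs(f0$params$A / 1.2 - 1), 1e-4)
  expect_lt(abs(f0$params$tau / 8e-4 - 1), 1e-4)
  tau <- 8e-4
  t <- seq(0, 20 * tau, length.out = 256)
  for (W in c(60, -25)) {
    sg <- tibble::tibble(time_s = t,
                         signal = signal_gradient(t, 1, tau, W))
    fit <- fit_gradient(sg, D = 1e-7)
    expect_true(fit$converged)
    expect_equal(sign(fit$params$W), sign(W))
    expect_lt(abs(fit$params$W / W - 1), 0.1)
  }
})

test_that("the gradient model residual never exceeds the nested homogeneous one", {
  tau <- 1e-3
  t <- seq(0, 20 * tau, length.out = 256)
  set.seed(9)
  for (W in c(0, 40, -20)) {
    y <- signal_gradient(t, 1, tau, W) + rnorm(256, sd = 0.01)
    sig <- tibble::tibble(time_s = t, signal = y)
    rh <- fit_homogeneous(sig, D = 1e-7)$residual_rms
    rg <- fit_gradient(sig, D = 1e-7)$residual_rms
    expect_lte(rg, rh * (1 + 1e-6))
  }
})

test_that("noisy lifetime recovery is unbiased within Monte-Carlo tolerance", {
  # 40 seeds at 1% noise: |median relative error| under 0.5%, IQR modest
  spec <- regression_spec(n_signals = 40)
  ds <- generate_regression_dataset(spec, acq_fast(n_points = 256),
                                    seed = 21)
  rel <- vapply(seq_len(40), function(i) {
    fit_homogeneous(dataset_signal(ds, i), D = spec$D)$params$tau /
      ds$truth$tau[i] - 1
  }, numeric(1))
  expect_lt(abs(stats::median(rel)), 0.005)
  expect_lt(diff(stats::quantile(rel, c(0.25, 0.75))), 0.04)
})

test_that("SLS on a homogeneous signal is flat and degenerates cleanly to one slice", {
  s <- sig_clean(A = 1, tau = 1e-3, n = 400, span = 20)
  prof <- sls_profile(s, D = 1e-7, n_slices = 10)
  beta_true <- beta_from_tau(1e-3, 1e-7)
  expect_true(all(prof$converged))
  expect_lt(max(abs(prof$beta / beta_true - 1)), 1e-4)
  expect_lt(stats::sd(prof$beta) / mean(prof$beta), 0.01)
  expect_true(all(diff(prof$z_m) > 0))
  one <- sls_profile(s, D = 1e-7, n_slices = 1)
  whole <- fit_homogeneous(s, D = 1e-7)
  expect_equal(one$beta, whole$beta, tolerance = 1e-10)
  expect_error(sls_profile(s, n_slices = 200), "window too short")
})

test_that("SLS probing depth scales as the square root of the diffusivity", {
  s <- sig_clean(n = 400)
  p1 <- sls_profile(s, D = 1e-7, n_slices = 5)
  p2 <- sls_profile(s, D = 2e-7, n_slices = 5)
  expect_equal(p2$z_m, sqrt(2) * p1$z_m, tolerance = 1e-12)
  p3 <- sls_profile(s, D = 1e-7, n_slices = 5, depth_prefactor = 2)
  expect_equal(p3$z_m, 2 * p1$z_m, tolerance = 1e-12)
})

test_that("SLS ordering follows the generating gradient on layered-oracle signals", {
  D <- 1e-7
  beta0 <- 1.5e5
  tau <- 1 / (beta0^2 * D)
  t <- seq(0, 20 * tau, length.out = 200)
  for (w in c(-2e8, 2e9)) {  # beta decreasing / increasing with depth
    y <- quad_oracle_signal(t, 1, function(z) beta0 + w * z, D, n_z = 8001)
    prof <- sls_profile(tibble::tibble(time_s = t, signal = y), D = D,
                        n_slices = 8)
    expect_equal(sign(prof$beta[8] - prof$beta[1]), sign(w))
    lin <- linearize_profile(prof)
    expect_equal(sign(lin$w_beta), sign(w))
  }
})

test_that("profile linearization is exact on linear input and handles degeneracies", {
  z <- seq(0, 2e-5, length.out = 8)
  prof <- tibble::tibble(z_m = z, beta = 1e5 - 2e9 * z)
  lin <- linearize_profile(prof)
  expect_equal(lin$beta0, 1e5, tolerance = 1e-9)
  expect_equal(lin$w_beta, -2e9, tolerance = 1e-9)
  expect_equal(lin$r_squared, 1)
  const <- tibble::tibble(z_m = z, beta = rep(7e4, 8))
  linc <- linearize_profile(const)
  expect_equal(linc$w_beta, 0, tolerance = 1e-6)
  expect_equal(linc$beta0, 7e4)
  expect_error(linearize_profile(tibble::tibble(z_m = 0, beta = 1e5)),
               "at least 2")
  # symmetric +/-1% perturbation leaves the slope within 5%
  pert <- tibble::tibble(z_m = z,
                         beta = (1e5 - 2e9 * z) *
                           (1 + 0.01 * rep(c(1, -1), 4)))
  expect_lt(abs(linearize_profile(pert)$w_beta / -2e9 - 1), 0.05)
})
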