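test_that("generation is a pure function of (spec, acq, seed)", {
  spec <- regression_spec(n_signals = 12)
  a <- generate_regression_dataset(spec, acq_fast(), seed = 42)
  b <- generate_regression_dataset(spec, acq_fast(), seed = 42)
  expect_identical(a$signals, b$signals)
  expect_identical(a$labels, b$labels)
  expect_identical(a$truth, b$truth)
  c <- generate_regression_dataset(spec, acq_fast(), seed = 43)
  expect_false(identical(a$signals, c$signals))
})

test_that("noise-free rows equal the forward model of their truth exactly", {
  ds <- generate_regression_dataset(regression_spec(n_signals = 6),
                                    acq_fast(noise_sd = 0), seed = 5)
  for (i in seq_len(6)) {
    expect_equal(ds$signals[i, ],
                 signal_homogeneous(ds$grid, ds$truth$A[i], ds$truth$tau[i]),
                 ignore_attr = TRUE)
  }
  dg <- generate_regression_dataset(
    regression_spec(n_signals = 6, mode = "gradient"),
    acq_fast(noise_sd = 0), seed = 5)
  for (i in seq_len(6)) {
    expect_equal(dg$signals[i, ],
                 signal_gradient(dg$grid, dg$truth$A[i], dg$truth$tau[i],
                                 dg$truth$W[i]),
                 ignore_attr = TRUE)
  }
})

test_that("default regression campaign has 97 rows with hydration labels in [0, 1]", {
  ds <- generate_regression_dataset(regression_spec(), acq_fast(), seed = 1)
  expect_equal(nrow(ds$signals), 97)
  expect_true(all(ds$labels$hydration >= 0 & ds$labels$hydration <= 1))
  expect_equal(nrow(ds$labels), 97)
  expect_equal(nrow(ds$truth), 97)
})

test_that("default classification campaign is 20 signals, 4 subjects, 5 each", {
  ds <- generate_classification_dataset(classification_spec(), acq_fast(),
                                        seed = 1)
  expect_equal(nrow(ds$signals), 20)
  expect_equal(as.vector(table(ds$labels$subject)), rep(5, 4))
})

test_that("zero spread and zero noise collapse each subject to identical rows", {
  spec <- classification_spec(hydration_sd = 0, amplitude_sd = 0)
  ds <- generate_classification_dataset(spec, acq_fast(noise_sd = 0),
                                        seed = 2)
  for (cl in levels(ds$labels$subject)) {
    rows <- ds$signals[ds$labels$subject == cl, , drop = FALSE]
    expect_equal(max(apply(rows, 2, function(col) diff(range(col)))), 0)
  }
})

test_that("well-separated subjects are perfectly recovered by a brute-force 1-NN", {
  ds <- generate_classification_dataset(classification_spec(), acq_fast(),
                                        seed = 3)
  # default class lifetimes are spread by ratios >= 1.4 at 1% noise
  expect_equal(loo_1nn_accuracy(ds$signals, ds$labels$subject), 1)
})

test_that("add_noise is an identity at sd = 0, reproducible, and unbiased", {
  x <- sin(seq(0, 5, length.out = 200))
  expect_identical(add_noise(x, 0), x)
  expect_equal(add_noise(x, 0.1, seed = 7), add_noise(x, 0.1, seed = 7))
  expect_error(add_noise(x, -0.1), ">= 0")
  n <- 1e5
  resid <- add_noise(rep(0, n), sd = 0.5, seed = 11)
  expect_lt(abs(mean(resid)), 4 * 0.5 / sqrt(n))
})

test_that("permuting rows keeps signals, labels, and truth aligned", {
  ds <- generate_regression_dataset(regression_spec(n_signals = 10),
                                    acq_fast(), seed = 4)
  set.seed(1)
  idx <- sample(10)
  pm <- permute_dataset(ds, idx)
  expect_equal(pm$signals, ds$signals[idx, ], ignore_attr = TRUE)
  expect_equal(pm$labels$hydration, ds$labels$hydration[idx])
  expect_equal(pm$truth$tau, ds$truth$tau[idx])
  # round trip restores the original
  back <- permute_dataset(pm, order(idx))
  expect_equal(back$signals, ds$signals)
})

test_that("noise-free datasets are invertible back to their generating parameters", {
  ds <- generate_regression_dataset(regression_spec(n_signals = 5),
                                    acq_fast(noise_sd = 0, n_points = 256),
                                    seed = 6)
  for (i in seq_len(5)) {
    fit <- fit_homogeneous(dataset_signal(ds, i), D = skin_defaults()$D)
    expect_lt(abs(fit$params$tau / ds$truth$tau[i] - 1), 1e-4)
    expect_lt(abs(fit$params$A / ds$truth$A[i] - 1), 1e-4)
  }
})

test_that("degenerate generator settings are rejected", {
  expect_error(regression_spec(n_signals = 2), ">= 4")
  expect_error(regression_spec(hydration_range = c(0.9, 0.3)), "interval")
  expect_error(classification_spec(n_classes = 1), ">= 2")
  expect_error(classification_spec(per_class = 1), ">= 2")
  expect_error(acquisition_config(n_points = 4), ">= 16")
  expect_error(acquisition_config(noise_sd = -1), ">= 0")
  # gradients past the model singularity
  expect_error(
    generate_regression_dataset(
      regression_spec(mode = "gradient", gradient_range = c(3e4, 4e4)),
      acq_fast(), seed = 1),
    "singular")
})
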