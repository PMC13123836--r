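# Network construction, training contracts and checkpoints.

test_that("full-scale architecture lands in the published weight window", {
  arch <- arch_config()
  expect_gte(arch$n_weights, 4.0e6)
  expect_lte(arch$n_weights, 5.0e6)
  expect_equal(length(arch$kernels), 7)
  # mirror skips connect equal-width layers
  expect_identical(arch$skips, c(-1L, -1L, -1L, 2L, 1L, 0L, -1L))

  m <- build_model(arch, seed = 1)
  n_stored <- sum(vapply(m$weights,
                         function(w) length(w$W) + length(w$b), numeric(1)))
  expect_identical(n_stored, as.numeric(arch$n_weights))
})

test_that("a small receptive field triggers the X-arm warning", {
  sch <- reduced_scheme()
  expect_warning(build_model(arch_config(widths = c(4, 4), kernels = 3),
                             seed = 1, scheme = sch),
                 "receptive field")
  expect_silent(m <- build_model(reduced_arch_config(), seed = 1,
                                 scheme = sch))
})

test_that("forward passes are finite, deterministic without dropout, and
           shape-preserving", {
  arch <- arch_config(widths = c(4, 6, 4), kernels = 3)
  m <- build_model(arch, seed = 3)
  x <- array(0, c(24, 10, 2))
  y <- predict_map(m, x)
  expect_identical(dim(y$data), c(24L, 10L))
  expect_true(all(is.finite(y$data)))

  set.seed(9)
  x2 <- array(rnorm(24 * 10 * 2), c(24, 10, 2))
  y1 <- predict_map(m, x2)
  y2 <- predict_map(m, x2)
  expect_identical(y1$data, y2$data)
})

test_that("training reduces the loss and is reproducible given a seed", {
  arch <- arch_config(widths = c(4, 6, 4), kernels = 3, l2 = 1e-6)
  m <- build_model(arch, seed = 3)
  cfg <- micro_generator_config(n_peaks_max = 2)
  exs <- generate_examples(cfg, 24, seed = 301)
  arr <- examples_to_arrays(exs)
  tc <- train_config(curriculum = list(list(n_peaks_max = 2,
                                            n_examples = 24)),
                     epochs = 8, batch_size = 4, lr = 3e-3, seed = 7)
  t1 <- train_model(m, cfg = tc, data = arr)
  expect_lt(mean(tail(t1$history[[1]]$loss, 3)),
            mean(head(t1$history[[1]]$loss, 3)))

  t2 <- train_model(m, cfg = tc, data = arr)
  expect_identical(t1$history[[1]]$loss, t2$history[[1]]$loss)
  expect_identical(t1$weights[[1]]$W, t2$weights[[1]]$W)

  # non-decreasing curricula are enforced
  expect_error(train_config(curriculum = list(
    list(n_peaks_max = 5, n_examples = 1),
    list(n_peaks_max = 2, n_examples = 1))), "non-decreasing")
})

test_that("evaluate_mse matches its closed forms", {
  arch <- arch_config(widths = c(3, 3), kernels = 3)
  m <- build_model(arch, seed = 5)
  # zero all weights: the model outputs 0, so MSE = mean of squared targets
  m$weights <- lapply(m$weights, function(w) {
    list(W = w$W * 0, b = w$b * 0)
  })
  set.seed(11)
  x <- array(rnorm(16 * 8 * 2 * 3), c(16, 8, 2, 3))
  y <- array(rnorm(16 * 8 * 3), c(16, 8, 3))
  ev <- evaluate_mse(m, x, y)
  expect_equal(ev$mse, mean(y^2), tolerance = 1e-12)
  expect_equal(ev$per_example,
               apply(y, 3, function(t) mean(t^2)), tolerance = 1e-12)
})

test_that("checkpoints round-trip losslessly", {
  arch <- arch_config(widths = c(4, 6, 4), kernels = 3)
  m <- build_model(arch, seed = 13)
  cfg <- micro_generator_config(n_peaks_max = 1)
  arr <- examples_to_arrays(generate_examples(cfg, 4, seed = 77))
  m <- train_model(m, cfg = train_config(curriculum = list(
    list(n_peaks_max = 1, n_examples = 4)), epochs = 1, batch_size = 2,
    seed = 3), data = arr)
  stem <- withr::local_tempfile()
  save_model(m, stem)
  back <- load_model(stem)
  for (l in seq_along(m$weights)) {
    expect_identical(back$weights[[l]]$W, m$weights[[l]]$W)
    expect_identical(back$weights[[l]]$b, m$weights[[l]]$b)
  }
  e1 <- evaluate_mse(m, arr$inputs, arr$targets)$mse
  e2 <- evaluate_mse(back, arr$inputs, arr$targets)$mse
  expect_equal(e1, e2, tolerance = 1e-12)

  con <- file(paste0(stem, ".bin"), "r+b")
  writeBin(4.2, con, size = 8)
  close(con)
  expect_error(load_model(stem), "md5|corrupt")
})

test_that("reconstruction is translation-equivariant and intensity-monotone
           on single-peak inputs", {
  model <- benchmark_model()
  sch <- reduced_scheme()
  px_h <- 2.5 / 128  # ppm per 1H pixel
  base <- spin_system(wH = 0.45, wC = 13, r2_h = 30, r2_mq = 15,
                      r2_aph = 35)
  argmax_px <- function(m) which(m == max(m), arr.ind = TRUE)[1, ]
  ds0 <- simulate_offres_dataset(base, sch, normalize = TRUE)
  p0 <- argmax_px(predict_map(model, ds0$data)$data)
  for (k in c(-8, 6)) {
    sp <- base; sp$wH <- base$wH + k * px_h
    dsk <- simulate_offres_dataset(sp, sch, normalize = TRUE)
    pk <- argmax_px(predict_map(model, dsk$data)$data)
    expect_lte(abs((pk[1] - p0[1]) - k), 1)
    expect_lte(abs(pk[2] - p0[2]), 1)
  }

  # scaling a noiseless single-peak input scales the reconstructed height
  # monotonically
  h <- vapply(c(0.5, 1), function(alpha) {
    max(predict_map(model, ds0$data * alpha)$data)
  }, numeric(1))
  expect_gt(h[2], h[1])
  expect_gt(h[1], 0)
})
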