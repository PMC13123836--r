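# Training-example generation: determinism, normalization, target
# construction and shard IO.

test_that("sample_example is deterministic and normalized", {
  cfg <- micro_generator_config()
  e1 <- sample_example(cfg, 42)
  e2 <- sample_example(cfg, 42)
  expect_identical(e1$input$data, e2$input$data)
  expect_identical(e1$target$data, e2$target$data)
  expect_identical(max(e1$input$data), 1)
  expect_true(all(e1$target$data >= 0))
  expect_identical(dim(e1$input$data)[1:2], dim(e1$target$data))

  # different seeds give different draws
  e3 <- sample_example(cfg, 43)
  expect_false(identical(e1$input$data, e3$input$data))

  # n_peaks_max = 1 -> exactly one spin in the truth
  cfg1 <- micro_generator_config(n_peaks_max = 1)
  for (s in 1:5) expect_length(sample_example(cfg1, s)$truth$spins, 1)
})

test_that("noise-free single-peak example concentrates intensity at the
           resonance and equals the simulator output", {
  cfg <- micro_generator_config(n_peaks_max = 1, noise_max_range = c(0, 0),
                                fid_phase_range = c(0, 0))
  ex <- sample_example(cfg, 7)
  sp <- ex$truth$spins[[1]]
  w <- which(ex$input$data == max(ex$input$data), arr.ind = TRUE)[1, ]
  px_c <- abs(diff(ex$input$axis_ppm_c[1:2]))
  px_h <- abs(diff(ex$input$axis_ppm_h[1:2]))
  expect_lt(abs(ex$input$axis_ppm_c[w[2]] - sp$wC), px_c)
  expect_lt(abs(ex$input$axis_ppm_h[w[1]] - sp$wH), 1.5 * px_h)

  # noise-free limit: identical to the simulator's normalized stack
  ds <- simulate_offres_dataset(ex$truth$spins, ex$truth$scheme,
                                normalize = TRUE, phase = ex$truth$phase)
  expect_equal(ex$input$data, ds$data, tolerance = 1e-14)
})

test_that("peak count is uniform on 1..n_peaks_max", {
  cfg <- micro_generator_config(n_peaks_max = 5)
  n <- vapply(seq_len(1000),
              function(s) length(sample_example(cfg, 20000 + s)$truth$spins),
              numeric(1))
  tab <- tabulate(n, nbins = 5)
  p <- stats::chisq.test(tab, p = rep(0.2, 5))$p.value
  expect_gt(p, 0.01)
})

test_that("target maps follow the linewidth, amplitude and volume rules", {
  # fine 1H grid so the rendered 20 Hz line is well resolved (~12 px/FWHM)
  sch <- acquisition_scheme(n_zf = 2048,
                            offsets_c = seq(5, 21, length.out = 64))
  # R2H/pi below the floor -> rendered 1H FWHM equals the 20 Hz minimum
  spin <- spin_system(wH = 0.45, wC = 13, r2_h = 25, r2_mq = 10,
                      r2_aph = 20)
  tm <- build_target_map(spin, sch, min_fwhm_h_hz = 20, fwhm_c_hz = 30)
  prof <- tm$data[, which.max(apply(tm$data, 2, max))]
  ax_hz <- (h_axis(sch)$ppm - sch$carrier_h) * sch$f_h
  above <- range(which(prof > max(prof) / 2))
  interp_cross <- function(i, rising) {
    j <- if (rising) i - 1 else i + 1
    ax_hz[i] + (max(prof) / 2 - prof[i]) / (prof[j] - prof[i]) *
      (ax_hz[j] - ax_hz[i])
  }
  fwhm <- interp_cross(above[2], FALSE) - interp_cross(above[1], TRUE)
  expect_equal(fwhm, 20, tolerance = 0.01)

  # additivity of co-located peaks
  tm2 <- build_target_map(list(spin, spin), sch)
  expect_equal(max(tm2$data), 2 * max(tm$data), tolerance = 1e-12)

  # integrated volume of a unit-amplitude Gaussian pair of FWHMs (fx, fy):
  # fx fy pi / (4 ln 2) in axis units
  px_h <- abs(diff(tm$axis_ppm_h[1:2]))
  px_c <- abs(diff(tm$axis_ppm_c[1:2]))
  vol <- sum(tm$data) * px_h * px_c
  fx <- 20 / sch$f_h
  fy <- 30 / (sch$f_h * sch$gamma_ratio)
  expect_equal(vol, fx * fy * pi / (4 * log(2)), tolerance = 0.01)

  # above the floor the 1H width tracks R2H/pi
  spin_b <- spin_system(wH = 0.45, wC = 13, r2_h = 80 * pi)
  tmb <- build_target_map(spin_b, sch)
  profb <- tmb$data[, which.max(apply(tmb$data, 2, max))]
  expect_gt(sum(profb > max(profb) / 2), 3 * sum(prof > max(prof) / 2))

  expect_error(build_target_map(spin_system(wH = 5, wC = 13), sch),
               "outside")
})

test_that("shards round-trip bit-identically and split as expected", {
  cfg <- micro_generator_config(n_peaks_max = 2)
  exs <- generate_examples(cfg, 9, seed = 5)
  dir <- withr::local_tempdir()
  write_shards(exs, dir, shard_size = 4)
  files <- list.files(dir, pattern = "bin$")
  expect_length(files, 3)  # 4 + 4 + 1
  back <- read_shards(dir)
  arr <- examples_to_arrays(exs)
  expect_identical(back$inputs, arr$inputs)
  expect_identical(back$targets, arr$targets)
  expect_length(back$truth, 9)

  expect_error(write_shards(list(), dir), "empty")

  # corruption is detected
  con <- file(file.path(dir, files[1]), "r+b")
  writeBin(rep(0.123, 4), con, size = 8)
  close(con)
  expect_error(read_shards(dir), "md5|corrupt")
})
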