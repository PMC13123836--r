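# Peak picking, ensemble intensity fitting, RMSD matching and slopes.

# render a map with 2D Gaussians at given (wH, wC, amp, fwhm_h, fwhm_c)
render_map <- function(peaks, nh = 96, nc = 40, ax_h = seq(0, 1, length.out = nh),
                       ax_c = seq(10, 16, length.out = nc)) {
  m <- matrix(0, length(ax_h), length(ax_c))
  for (k in seq_len(nrow(peaks))) {
    gh <- exp(-4 * log(2) * ((ax_h - peaks$wH[k]) / peaks$fh[k])^2)
    gc <- exp(-4 * log(2) * ((ax_c - peaks$wC[k]) / peaks$fc[k])^2)
    m <- m + peaks$amp[k] * outer(gh, gc)
  }
  correlation_map(m, ax_h, ax_c)
}

test_that("parabolic interpolation reproduces its closed form", {
  # symmetric triple: no shift, height equals the centre
  m <- matrix(0, 5, 5)
  m[2:4, 3] <- c(1, 2, 1)
  mp <- correlation_map(m, 1:5, 1:5)
  pk <- pick_peaks(mp, threshold = 0.5)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$wH_ppm, 3)
  # the 13C triple here is (0, 2, 0), also symmetric
  expect_equal(pk$wC_ppm, 3)

  # asymmetric triple (1, 2, 1.5): delta = +1/6 px, height 2.0208
  m2 <- matrix(0, 5, 5)
  m2[2:4, 3] <- c(1, 2, 1.5)
  pk2 <- pick_peaks(correlation_map(m2, 1:5, 1:5), threshold = 0.5)
  expect_equal(pk2$wH_ppm - 3, 1 / 6, tolerance = 1e-10)
  # height carries both dimensions' corrections; isolate the 1H one
  h_corr_c <- -(0 - 0) / 4  # 13C triple symmetric: no correction
  expect_equal(pk2$height, 2 + 0.5 * (1 / 6) / 4 + h_corr_c,
               tolerance = 1e-10)
  expect_equal(pk2$height, 2.0208, tolerance = 1e-4)

  expect_error(pick_peaks(correlation_map(matrix(1, 2, 2), 1:2, 1:2), 0.5),
               "3x3")
  expect_error(pick_peaks(mp, threshold = 2), "threshold")
})

test_that("a rendered Gaussian at a subpixel centre is recovered to
           0.05 pixel", {
  ax_h <- seq(0, 1, length.out = 96)
  ax_c <- seq(10, 16, length.out = 40)
  px_h <- diff(ax_h)[1]; px_c <- diff(ax_c)[1]
  truth <- data.frame(wH = 0.503 + 0.37 * px_h, wC = 13.1 + 0.44 * px_c,
                      amp = 1, fh = 3.2 * px_h, fc = 2.7 * px_c)
  mp <- render_map(truth)
  pk <- pick_peaks(mp, threshold = 0.3)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$wH_ppm - truth$wH) / px_h, 0.05)
  expect_lt(abs(pk$wC_ppm - truth$wC) / px_c, 0.05)

  # picker height and ensemble-fit amplitude agree within 3% for isolated
  # Gaussians
  fit <- fit_intensities(list(mp, mp), pk)
  expect_lt(abs(fit$height - pk$height) / fit$height, 0.03)
})

test_that("ensemble Gaussian fitting recovers amplitudes and propagates
           MC errors", {
  ax_h <- seq(0, 1, length.out = 96)
  ax_c <- seq(10, 16, length.out = 40)
  px_h <- diff(ax_h)[1]; px_c <- diff(ax_c)[1]
  one <- data.frame(wH = 0.5, wC = 13, amp = 0.8, fh = 3 * px_h,
                    fc = 3 * px_c)
  mp <- render_map(one)
  pos <- peak_list(data.frame(wH_ppm = one$wH, wC_ppm = one$wC, height = NA))

  # identical duplicated maps: exact amplitude, zero sigma
  fit <- fit_intensities(list(mp, mp), pos)
  expect_equal(fit$height, 0.8, tolerance = 1e-6)
  expect_equal(fit$sigma_height, 0, tolerance = 1e-9)
  expect_true(all(fit$converged))

  # ensemble amplitudes {1.0, 1.1}: sigma = 1.4 sd = 0.0990
  mp10 <- mp; mp10$data <- mp$data / 0.8
  mp11 <- mp; mp11$data <- 1.1 * mp$data / 0.8
  fit2 <- fit_intensities(list(mp10, mp11), pos)
  expect_equal(fit2$height, 1.05, tolerance = 1e-4)
  expect_equal(fit2$sigma_height, 1.4 * stats::sd(c(1, 1.1)),
               tolerance = 1e-4)
  expect_equal(fit2$sigma_height, 0.0990, tolerance = 1e-3)

  # two overlapping Gaussians one FWHM apart, amplitudes 1 and 0.5:
  # joint fit recovers both within 2%
  fh <- 4 * px_h
  two <- data.frame(wH = c(0.45, 0.45 + fh), wC = c(13, 13),
                    amp = c(1, 0.5), fh = fh, fc = 3 * px_c)
  mp2 <- render_map(two)
  pos2 <- peak_list(data.frame(wH_ppm = two$wH, wC_ppm = two$wC,
                               height = NA))
  fit3 <- fit_intensities(list(mp2, mp2), pos2)
  expect_equal(fit3$height, c(1, 0.5), tolerance = 0.02)
})

test_that("shift RMSD matches greedily within tolerances", {
  a <- peak_list(data.frame(wH_ppm = c(0.2, 0.5, 0.8),
                            wC_ppm = c(11, 13, 15), height = 1))
  expect_equal(shift_rmsd(a, a)$rmsd_H, 0)
  expect_equal(shift_rmsd(a, a)$n_matched, 3L)

  b <- a; b$wH_ppm <- b$wH_ppm + 0.001
  r <- shift_rmsd(a, b)
  expect_equal(r$rmsd_H, 0.001, tolerance = 1e-12)
  expect_equal(r$rmsd_C, 0, tolerance = 1e-12)

  # out-of-tolerance peaks stay unmatched, reported not thrown
  far <- peak_list(data.frame(wH_ppm = 0.2 + 5, wC_ppm = 11, height = 1))
  r2 <- shift_rmsd(a, far)
  expect_identical(r2$n_matched, 0L)
  expect_true(is.na(r2$rmsd_H))
})

test_that("intensity slopes are exact on constructed lists and unbiased
           under noise", {
  a <- peak_list(data.frame(label = sprintf("P%d", 1:6),
                            wH_ppm = seq(0.1, 0.6, 0.1), wC_ppm = 11:16,
                            height = c(1, 2, 3, 4, 5, 6) / 6,
                            sigma_height = 0.01))
  b3 <- a; b3$height <- 3 * a$height
  expect_equal(intensity_slope(a, b3)$slope, 3, tolerance = 1e-12)
  expect_equal(intensity_slope(a, a)$slope, 1, tolerance = 1e-12)
  expect_error(intensity_slope(a[1, ], a[1, ]), "fewer than 2")

  # 100 noisy repeats at 5% noise: mean slope within 1 SE of the truth
  set.seed(1234)
  slopes <- replicate(100, {
    an <- a; bn <- b3
    an$height <- a$height * (1 + stats::rnorm(6, 0, 0.05))
    bn$height <- b3$height * (1 + stats::rnorm(6, 0, 0.05))
    an$sigma_height <- 0.05 * a$height
    bn$sigma_height <- 0.05 * b3$height
    intensity_slope(an, bn)$slope
  })
  se <- stats::sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 3), 2 * se + 0.02)
})

test_that("viscosity-scaled effective size is multiplicative", {
  expect_equal(effective_size(360, 2.2), 792)
  expect_equal(effective_size(360, 2.95), 1062)
  expect_equal(effective_size(123.4, 1), 123.4)
  expect_error(effective_size(-1, 2), "mass")
})

test_that("peak lists round-trip through TSV", {
  a <- peak_list(data.frame(label = c("A", "B"), wH_ppm = c(0.1, 0.2),
                            wC_ppm = c(11, 12), height = c(1, 2),
                            sigma_height = c(0.1, 0.2)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_peaks(a, path)
  back <- read_peaks(path)
  expect_equal(back$height, a$height)
  expect_equal(back$label, a$label)
})
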