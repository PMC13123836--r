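# Spectral processing and off-resonance dataset assembly.

test_that("synthesize_spectrum handles degenerate FIDs and calibrates axes", {
  sch <- acquisition_scheme(n_zf = 512)

  zero <- synthesize_spectrum(complex(sch$n_t), sch)
  expect_true(all(zero$intensity == 0))
  expect_length(zero$axis_ppm, sch$n_zf)

  # unapodized delta FID -> flat magnitude spectrum
  delta <- complex(sch$n_t); delta[1] <- 1
  fl <- synthesize_spectrum(delta, sch, apodize = FALSE)
  expect_equal(diff(range(Mod(fl$intensity))), 0, tolerance = 1e-12)

  # a spin at +150 Hz appears at +150 Hz on the axis
  spin <- spin_system(wH = sch$carrier_h + 150 / sch$f_h, wC = 13,
                      j_hc = 1e-300, r2_h = 20, r2_mq = 0, r2_aph = 0)
  fid <- propagate_fid(build_liouvillian(spin, 0, 13, sch), time_grid(sch))
  sp <- synthesize_spectrum(fid, sch)
  expect_equal(sp$axis_hz[which.max(Re(sp$intensity))], 150,
               tolerance = sch$sw_hz / sch$n_zf)

  expect_error(synthesize_spectrum(complex(10), sch), "does not match")
  expect_error(acquisition_scheme(n_zf = 16), "smaller than")
})

test_that("far-off 1H linewidth is R2H/pi within 1% at 16x zero-fill", {
  # long acquisition so the exponential has fully decayed (no truncation
  # broadening), zero-filled ~16x
  sch <- acquisition_scheme(t_max = 0.4, n_zf = 32768)
  spin <- spin_system(wH = sch$carrier_h, wC = 13, j_hc = 1e-300, r2_h = 25,
                      r2_mq = 0, r2_aph = 0)
  fid <- propagate_fid(build_liouvillian(spin, 0, 13, sch), time_grid(sch))
  sp <- synthesize_spectrum(fid, sch, apodize = FALSE)
  y <- Re(sp$intensity)
  half <- max(y) / 2
  above <- which(y > half)
  # linear interpolation at the half-height crossings
  lo <- min(above); hi <- max(above)
  f_lo <- sp$axis_hz[lo - 1] + (half - y[lo - 1]) / (y[lo] - y[lo - 1]) *
    (sp$axis_hz[lo] - sp$axis_hz[lo - 1])
  f_hi <- sp$axis_hz[hi] + (y[hi] - half) / (y[hi] - y[hi + 1]) *
    (sp$axis_hz[hi + 1] - sp$axis_hz[hi])
  expect_equal(f_hi - f_lo, 25 / pi, tolerance = 0.01)
})

test_that("off-resonance datasets obey superposition and reference rules", {
  sch <- acquisition_scheme(n_zf = 128, sw_h = 2.5,
                            offsets_c = seq(10, 16, length.out = 12))
  a <- spin_system(wH = 0.3, wC = 12, j_hc = 125, r2_h = 25, r2_mq = 20,
                   r2_aph = 30)
  b <- spin_system(wH = 0.7, wC = 14.5, j_hc = 123, r2_h = 40, r2_mq = 25,
                   r2_aph = 45, i0 = 0.6)
  dsa <- simulate_offres_dataset(a, sch)
  dsb <- simulate_offres_dataset(b, sch)
  dsab <- simulate_offres_dataset(list(a, b), sch)
  expect_equal(dsab$data, dsa$data + dsb$data, tolerance = 1e-12)

  expect_error(simulate_offres_dataset(list(), sch), "empty")

  # reference independence: the B1 = 0 reference removes exactly the same
  # spectrum at every offset, so raw minus difference is offset-constant
  raw <- simulate_offres_dataset(a, sch, subtract_reference = FALSE)
  refplane <- raw$data - dsa$data
  for (ch in 1:2) {
    spread <- apply(refplane[, , ch], 1, function(r) diff(range(r)))
    expect_lt(max(spread), 1e-10 * max(abs(refplane)))
  }
})

test_that("single-spin X pattern collapses on resonance and subtraction
           removes far-off streaks", {
  # one spin, decoupler grid through resonance (Fig. 1E-style geometry)
  f_h <- 700; gr <- 0.25144953
  sch <- acquisition_scheme(f_h = f_h, sw_h = 2.5, n_zf = 256,
                            offsets_c = 13 + seq(-500, 500, by = 50) /
                              (f_h * gr),
                            b1_list = 110)
  spin <- spin_system(wH = sch$carrier_h, wC = 13, j_hc = 125, r2_h = 25,
                      r2_mq = 25, r2_aph = 25)
  ds <- simulate_offres_dataset(spin, sch)
  m <- ds$data[, , 1]
  onres <- which.min(abs(sch$offsets_c - 13))
  # on-resonance column: single collapsed maximum at wH
  y <- m[, onres]
  pk <- which(diff(sign(diff(y))) == -2) + 1
  pk <- pk[y[pk] > 0.5 * max(y)]
  expect_length(pk, 1)
  expect_equal(ds$axis_ppm_h[pk], sch$carrier_h, tolerance = 0.02)
  # X-arms: splitting grows away from resonance, symmetric about the centre
  split_at <- function(col) {
    y <- m[, col]
    p <- which(diff(sign(diff(y))) == -2) + 1
    p <- p[y[p] > 0.3 * max(y)]
    if (length(p) < 2) 0 else diff(range(ds$axis_hz_h[p]))
  }
  expect_gt(split_at(onres + 8), split_at(onres + 3))
  expect_equal(split_at(onres - 6), split_at(onres + 6), tolerance = 0.15)

  # far-offset residual: with |nuC - nuRF| > 20 B1 the difference column is
  # <2% of the stack's global maximum
  sch2 <- acquisition_scheme(f_h = f_h, sw_h = 2.5, n_zf = 256,
                             offsets_c = seq(13, 13 + 3000 / (f_h * gr),
                                             length.out = 25),
                             b1_list = 110)
  ds2 <- simulate_offres_dataset(spin, sch2)
  far <- ds2$data[, 25, 1]
  expect_gt(abs(sch2$offsets_c[25] - 13) * f_h * gr, 20 * 110)
  expect_lt(max(abs(far)), 0.02 * max(ds2$data))
})

test_that("normalization flag and scale bookkeeping are consistent", {
  sch <- acquisition_scheme(n_zf = 128, sw_h = 2.5,
                            offsets_c = seq(11, 15, length.out = 8))
  spin <- spin_system(wH = 0.5, wC = 13)
  dsn <- simulate_offres_dataset(spin, sch, normalize = TRUE)
  expect_identical(max(dsn$data), 1)
  expect_true(dsn$normalized)
  dsr <- simulate_offres_dataset(spin, sch)
  expect_equal(dsr$data, dsn$data * dsn$scale, tolerance = 1e-12)
  expect_error(
    offres_dataset(dsr$data * 2, dsr$axis_ppm_h, dsr$axis_hz_h,
                   dsr$axis_ppm_c, dsr$b1_list, normalized = TRUE),
    "maximum")
})
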