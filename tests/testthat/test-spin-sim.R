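# Liouvillian construction, FID propagation and the closed-form oracles.

test_that("liouvillian has the stated block structure and decay spectrum", {
  sch <- acquisition_scheme()
  spin <- spin_system(wH = 0.8, wC = 12.5, j_hc = 125, r2_h = 25,
                      r2_mq = 25, r2_aph = 25)

  # with B1 = 0 the detectable {Hx,Hy,2HxCz,2HyCz} block decouples from the
  # four double-transverse terms
  L0 <- build_liouvillian(spin, 0, 12.5, sch)$matrix
  sq <- c(1, 2, 7, 8); mq <- c(3, 4, 5, 6)
  expect_true(all(L0[sq, mq] == 0))
  expect_true(all(L0[mq, sq] == 0))

  # eigenvalues never have negative real part (signal cannot grow)
  for (b1 in c(0, 110, 220)) {
    for (nu in c(12.5, 10, -50)) {
      ev <- eigen(build_liouvillian(spin, b1, nu, sch)$matrix,
                  only.values = TRUE)$values
      expect_true(all(Re(ev) >= -1e-9))
    }
  }

  # equal rates on resonance: every detectable mode decays at exactly that
  # rate, so the slowest-decaying eigenmode sits at 25 s^-1
  Lr <- build_liouvillian(spin, 110, 12.5, sch)$matrix
  ev <- eigen(Lr, only.values = TRUE)$values
  expect_equal(min(Re(ev)), 25, tolerance = 1e-10)
  expect_equal(max(Re(ev)), 25, tolerance = 1e-10)

  expect_error(build_liouvillian(spin, NaN, 12.5, sch), "b1")
  expect_error(spin_system(wH = 1, wC = 12, j_hc = Inf), "j_hc")
  expect_error(spin_system(wH = 1, wC = 12, r2_h = -1), "rates")
})

test_that("FID propagation matches free-precession and decay closed forms", {
  sch <- acquisition_scheme()
  tg <- time_grid(sch)

  # pure undamped oscillation at +100 Hz offset (j_hc tiny: uncoupled limit)
  spin <- spin_system(wH = sch$carrier_h + 100 / sch$f_h, wC = 13,
                      j_hc = 1e-300, r2_h = 0, r2_mq = 0, r2_aph = 0)
  l8 <- build_liouvillian(spin, 0, 13, sch)
  s <- propagate_fid(l8, tg)
  expect_equal(Mod(s), rep(1, length(s)), tolerance = 1e-9)
  phase_rate <- Arg(s[2] / s[1]) / (2 * pi) * sch$sw_hz
  expect_equal(phase_rate, 100, tolerance = 1e-6)

  # pure exponential decay: s(t) = I0 exp(-R2H t)
  spin2 <- spin_system(wH = sch$carrier_h, wC = 13, j_hc = 1e-300,
                       r2_h = 25, r2_mq = 0, r2_aph = 0)
  s2 <- propagate_fid(build_liouvillian(spin2, 0, 13, sch), tg)
  expect_equal(Re(s2), exp(-25 * tg), tolerance = 1e-9)
  expect_equal(Re(s2[length(tg)]), exp(-25 * 0.064), tolerance = 1e-9)

  # linearity in I0
  spin3 <- spin2; spin3$i0 <- 2
  s3 <- propagate_fid(build_liouvillian(spin3, 0, 13, sch), tg)
  expect_equal(s3, 2 * s2, tolerance = 1e-12)

  # literal real detection equals Hx - Hy
  sl <- propagate_fid(build_liouvillian(spin2, 0, 13, sch), tg,
                      detection = "literal_D")
  expect_true(all(Im(sl) == 0))

  expect_error(propagate_fid(l8, c(0, 0.001, 0.003)), "uniform")
  expect_error(propagate_fid(l8, tg + 1), "start at 0")
})

test_that("coupled reference spectrum is a 1J_HC doublet", {
  sch <- acquisition_scheme(n_zf = 8192)
  spin <- spin_system(wH = sch$carrier_h, wC = 13, j_hc = 125, r2_h = 25,
                      r2_mq = 25, r2_aph = 25)
  fid <- propagate_fid(build_liouvillian(spin, 0, 13, sch), time_grid(sch))
  spec <- synthesize_spectrum(fid, sch)
  y <- Re(spec$intensity)
  pk <- which(diff(sign(diff(y))) == -2) + 1
  pk <- pk[order(y[pk], decreasing = TRUE)][1:2]
  expect_equal(abs(diff(spec$axis_hz[pk])), 125,
               tolerance = 2 * sch$sw_hz / sch$n_zf / 125)
})

test_that("effective splitting formula evaluates its closed form", {
  expect_identical(effective_splitting(125, 110, 0), 0)
  expect_equal(effective_splitting(125, 110, 8800), 125, tolerance = 1e-4)
  expect_equal(effective_splitting(125, 110, 110), 125 / sqrt(2),
               tolerance = 1e-12)
})

test_that("simulated splittings track the oracle over the (B1, delta) grid", {
  # approximate oracle: within one digital resolution element at a
  # resolution commensurate with the approximation's accuracy
  res_el <- 5 * 700 / 2048
  for (b1 in c(110, 220)) {
    for (delta in c(-800, -400, -200, 200, 400, 800)) {
      pred <- effective_splitting(125, b1, delta)
      if (pred < 2 * res_el) next
      meas <- measured_splitting(125, b1, delta, n_zf = 2048)
      expect_lt(abs(meas - pred), res_el)
    }
  }
  # the exact two-level splitting agrees far more tightly (0.2 Hz at 32x
  # finer digital resolution)
  exact <- function(j, b1, d) sqrt((d + j / 2)^2 + b1^2) -
    sqrt((d - j / 2)^2 + b1^2)
  for (b1 in c(110, 220)) {
    for (delta in c(200, 800)) {
      meas <- measured_splitting(125, b1, delta, n_zf = 65536)
      expect_equal(meas, exact(125, b1, delta), tolerance = 0.2 / 100)
    }
  }
})

test_that("limiting rate oracles match their printed forms and simulation", {
  spin <- spin_system(wH = 0.5, wC = 13, j_hc = 125, r2_h = 25, r2_mq = 25,
                      r2_aph = 25)
  lim <- limiting_rate_oracle(spin, 110)
  expect_equal(lim$far_linewidth, 25 / pi, tolerance = 1e-12)
  expect_equal(lim$onres_rate, 25, tolerance = 1e-12)

  spin2 <- spin_system(wH = 0.5, wC = 13, j_hc = 125, r2_h = 40, r2_mq = 20,
                       r2_aph = 40)
  lim2 <- limiting_rate_oracle(spin2, 220)
  expect_equal(lim2$onres_rate, 40 - 20 / (1 + (440 / 125)^2),
               tolerance = 1e-12)
  expect_equal(lim2$onres_rate, 38.51, tolerance = 1e-3)

  # on-resonance effective decay of the simulated FID envelope matches the
  # approximation within 10% in the B1 >> J regime (B1 = 2J)
  sch <- acquisition_scheme()
  spin3 <- spin_system(wH = sch$carrier_h, wC = 13, j_hc = 125, r2_h = 40,
                       r2_mq = 20, r2_aph = 40)
  s <- propagate_fid(build_liouvillian(spin3, 250, 13, sch), time_grid(sch))
  tg <- time_grid(sch)
  sel <- tg > 0.005 & tg < 0.05
  rate_fit <- -stats::coef(stats::lm(log(Mod(s[sel])) ~ tg[sel]))[2]
  pred <- limiting_rate_oracle(spin3, 250)$onres_rate
  expect_lt(abs(rate_fit - pred) / pred, 0.10)
})

test_that("decay bound: |s(t)| never exceeds |s(0)| for equal rates", {
  sch <- acquisition_scheme()
  for (b1 in c(0, 110, 220)) {
    for (nu in c(13, 11)) {
      spin <- spin_system(wH = 0.7, wC = 13, j_hc = 125, r2_h = 8,
                          r2_mq = 8, r2_aph = 8)
      s <- propagate_fid(build_liouvillian(spin, b1, nu, sch),
                         time_grid(sch))
      expect_true(all(Mod(s) <= Mod(s[1]) + 1e-12))
    }
  }
})
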