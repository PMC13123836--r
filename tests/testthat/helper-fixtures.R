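# Shared fixtures: micro-scale generator configs for fast distributional
# tests, a measured-splitting helper, and the memoized reduced-scale
# benchmark model used by the end-to-end tests.

# tiny grid: cheap enough for hundreds of draws in a test
micro_generator_config <- function(n_peaks_max = 5, ...) {
  generator_config(n_zf = 32, n_offsets = 6, sw_h_range = c(2.5, 2.5),
                   offsets_span_range = c(4, 4), offsets_center = 13,
                   t_max = 0.008, wH_window = c(0.1, 0.8),
                   wC_window = c(11.5, 14.5), n_peaks_max = n_peaks_max,
                   ...)
}

# doublet separation (Hz) measured from a finely zero-filled simulated
# spectrum of a single on-carrier spin with the decoupler delta Hz away
# from the 13C resonance
measured_splitting <- function(j_hc, b1, delta_hz, rates = 25, n_zf = 2048,
                               sw_h = 5, f_h = 700, apodize = TRUE) {
  sch <- acquisition_scheme(f_h = f_h, sw_h = sw_h, n_zf = n_zf,
                            carrier_h = 0.45)
  spin <- spin_system(wH = sch$carrier_h, wC = 13, j_hc = j_hc,
                      r2_h = rates, r2_mq = rates, r2_aph = rates)
  nu_rf <- spin$wC - delta_hz / (f_h * sch$gamma_ratio)
  l8 <- build_liouvillian(spin, b1, nu_rf, sch)
  fid <- propagate_fid(l8, time_grid(sch))
  spec <- synthesize_spectrum(fid, sch, apodize = apodize)
  y <- Re(spec$intensity)
  pk <- which(diff(sign(diff(y))) == -2) + 1
  pk <- pk[y[pk] > 0.5 * max(y)]
  if (length(pk) < 2) return(0)
  pk <- pk[order(y[pk], decreasing = TRUE)][1:2]
  # sub-bin refinement: three-point parabola around each maximum
  refine <- function(i) {
    d <- (y[i - 1] - y[i + 1]) / (2 * (y[i - 1] - 2 * y[i] + y[i + 1]))
    i + d
  }
  df <- spec$axis_hz[2] - spec$axis_hz[1]
  abs(refine(pk[1]) - refine(pk[2])) * df
}

# memoized reduced-scale benchmark: trains once per session, reuses after
.benchmark_env <- new.env(parent = emptyenv())

benchmark_model <- function() {
  if (!is.null(.benchmark_env$model)) return(.benchmark_env$model)
  cfg <- reduced_generator_config()
  sch <- reduced_scheme()
  model <- build_model(reduced_arch_config(), seed = 11, scheme = sch)
  tc <- train_config(curriculum = list(list(n_peaks_max = 3,
                                            n_examples = 300, epochs = 2),
                                       list(n_peaks_max = 8,
                                            n_examples = 400, epochs = 3),
                                       list(n_peaks_max = 16,
                                            n_examples = 800, epochs = 4)),
                     batch_size = 4, lr = 1e-3, lr_decay = 0.6, seed = 101)
  .benchmark_env$untrained <- model
  .benchmark_env$model <- train_model(model, gen_cfg = cfg, cfg = tc)
  .benchmark_env$model
}

benchmark_untrained <- function() {
  benchmark_model()
  .benchmark_env$untrained
}
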