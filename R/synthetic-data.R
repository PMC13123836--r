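#' Configuration for the synthetic training-data generator
#'
#' Parameter ranges from which each training example draws its global
#' (spectrometer-level) and per-peak parameters.  Defaults emulate methyl
#' 13CHD2 probes at 16.4 T with the published acquisition design: ~5 ppm 1H
#' sweep, 200 decoupler offsets over ~30 ppm, B1 of 220/110 Hz with a few
#' percent jitter, scalar couplings around 125 Hz, and relaxation rates
#' spanning small proteins to ~MDa-equivalent tumbling.  All ranges are
#' `c(lo, hi)` and sampled uniformly.
#'
#' @param n_zf 1H grid size (zero-fill), default 512.
#' @param n_offsets Number of 13C decoupler offsets, default 200.
#' @param f_h_nominal 1H base frequency (MHz).
#' @param b0_jitter Fractional jitter on `f_h_nominal`.
#' @param b1_nominal B1 fields (Hz), high to low.
#' @param b1_jitter Fractional jitter on each B1.
#' @param sw_h_range 1H sweep width range (ppm).
#' @param offsets_span_range 13C offset-span range (ppm).
#' @param offsets_center 13C offset-grid centre (ppm).
#' @param carrier_h 1H carrier (ppm).
#' @param t_max Acquisition time (s).
#' @param wH_window,wC_window Chemical-shift windows for drawn peaks (ppm).
#' @param j_range Scalar-coupling range (Hz).
#' @param r2h_range,r2mq_range,r2aph_range Relaxation-rate ranges (s^-1).
#' @param i0_range Peak starting-magnetization range.
#' @param fid_phase_range Zero-order FID phase range (degrees).
#' @param noise_max_range Range of the Gaussian noise standard deviation, as
#'   a fraction of the unit-normalized stack maximum.
#' @param n_peaks_max Maximum number of peaks per example.
#' @param min_fwhm_h_hz,fwhm_c_hz Target-map linewidth rules (Hz); see
#'   [build_target_map()].
#' @param max_retries Resampling budget for out-of-window draws.
#'
#' @return Object of class `generator_config`.
#' @seealso [reduced_generator_config()] for the small-grid benchmark
#'   configuration used by the test suite.
#' @export
generator_config <- function(n_zf = 512, n_offsets = 200, f_h_nominal = 700,
                             b0_jitter = 0.01, b1_nominal = c(220, 110),
                             b1_jitter = 0.03, sw_h_range = c(4.8, 5.2),
                             offsets_span_range = c(29, 31),
                             offsets_center = 13, carrier_h = 0.45,
                             t_max = 0.064, wH_window = c(-0.7, 1.6),
                             wC_window = c(-1, 27), j_range = c(120, 130),
                             r2h_range = c(5, 120), r2mq_range = c(2, 120),
                             r2aph_range = c(5, 150), i0_range = c(0.05, 1),
                             fid_phase_range = c(-30, 30),
                             noise_max_range = c(0, 0.05), n_peaks_max = 10,
                             min_fwhm_h_hz = 20, fwhm_c_hz = 30,
                             max_retries = 100) {
  rng2 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 2L || x[1] > x[2]) {
      stop("generator_config: '", nm, "' must be an ordered range c(lo, hi)",
           call. = FALSE)
    }
    as.numeric(x)
  }
  stopifnot(n_peaks_max >= 1, n_zf >= 8, n_offsets >= 2)
  cfg <- list(n_zf = as.integer(n_zf), n_offsets = as.integer(n_offsets),
              f_h_nominal = f_h_nominal, b0_jitter = b0_jitter,
              b1_nominal = b1_nominal, b1_jitter = b1_jitter,
              sw_h_range = rng2(sw_h_range, "sw_h_range"),
              offsets_span_range = rng2(offsets_span_range,
                                        "offsets_span_range"),
              offsets_center = offsets_center, carrier_h = carrier_h,
              t_max = t_max, wH_window = rng2(wH_window, "wH_window"),
              wC_window = rng2(wC_window, "wC_window"),
              j_range = rng2(j_range, "j_range"),
              r2h_range = rng2(r2h_range, "r2h_range"),
              r2mq_range = rng2(r2mq_range, "r2mq_range"),
              r2aph_range = rng2(r2aph_range, "r2aph_range"),
              i0_range = rng2(i0_range, "i0_range"),
              fid_phase_range = rng2(fid_phase_range, "fid_phase_range"),
              noise_max_range = rng2(noise_max_range, "noise_max_range"),
              n_peaks_max = as.integer(n_peaks_max),
              min_fwhm_h_hz = min_fwhm_h_hz, fwhm_c_hz = fwhm_c_hz,
              max_retries = as.integer(max_retries))
  class(cfg) <- "generator_config"
  cfg
}

#' Reduced-scale generator configuration
#'
#' A small-grid (128 x 48) analogue of the full acquisition design, used for
#' the package's end-to-end benchmark: the 1H sweep, offset span and target
#' linewidths are scaled together so that peak widths in pixels match the
#' full-scale setup, keeping the learning problem equivalent while the grids
#' (and hence training cost) shrink by ~17x.
#'
#' @param n_peaks_max Maximum peaks per example (default 8).
#' @param ... Overrides passed to [generator_config()].
#' @return A `generator_config`.
#' @export
reduced_generator_config <- function(n_peaks_max = 8, ...) {
  generator_config(n_zf = 128, n_offsets = 48, sw_h_range = c(2.45, 2.55),
                   offsets_span_range = c(11.8, 12.2), offsets_center = 13,
                   wH_window = c(-0.15, 1.05), wC_window = c(8.5, 17.5),
                   r2h_range = c(5, 80), r2mq_range = c(2, 80),
                   r2aph_range = c(5, 100), min_fwhm_h_hz = 40,
                   fwhm_c_hz = 90, n_peaks_max = n_peaks_max, ...)
}

# draw a scalar uniformly from a range
runif1 <- function(r) stats::runif(1, r[1], r[2])

#' Draw one synthetic training example
#'
#' Draws global parameters (field, B1 pair, sweep widths, FID phase, noise
#' level), a peak count uniform on `1..n_peaks_max`, and per-peak parameters;
#' simulates the two-B1 difference off-resonance stack through the exact
#' Liouvillian propagator; applies the drawn FID phase, cosine-square
#' apodization, zero-fill and Fourier transform; normalizes the stack to a
#' global maximum of 1, adds Gaussian noise with the drawn amplitude and
#' rescales to a maximum of 1.  The paired target map is built noise-free
#' from the same truth list.
#'
#' @param cfg A [generator_config()].
#' @param seed Integer seed; the example is a deterministic function of
#'   `(cfg, seed)`.
#' @return Object of class `training_example`: list with `input` (normalized
#'   `offres_dataset`), `target` (`correlation_map`), `truth` (spin list and
#'   drawn globals) and `seed`.
#' @export
sample_example <- function(cfg, seed) {
  stopifnot(inherits(cfg, "generator_config"))
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  f_h <- cfg$f_h_nominal * (1 + stats::runif(1, -cfg$b0_jitter, cfg$b0_jitter))
  b1 <- cfg$b1_nominal *
    (1 + stats::runif(length(cfg$b1_nominal), -cfg$b1_jitter, cfg$b1_jitter))
  sw_h <- runif1(cfg$sw_h_range)
  span <- runif1(cfg$offsets_span_range)
  offsets <- seq(cfg$offsets_center - span / 2, cfg$offsets_center + span / 2,
                 length.out = cfg$n_offsets)
  phase <- runif1(cfg$fid_phase_range)
  noise_amp <- runif1(cfg$noise_max_range)
  scheme <- acquisition_scheme(f_h = f_h, carrier_h = cfg$carrier_h,
                               sw_h = sw_h, t_max = cfg$t_max,
                               n_zf = cfg$n_zf, b1_list = b1,
                               offsets_c = offsets, reference_mode = "none")
  ax_h <- h_axis(scheme)$ppm
  # windows must sit inside the drawn axes; resample out-of-window draws
  draw_peak <- function() {
    for (i in seq_len(cfg$max_retries)) {
      wH <- runif1(cfg$wH_window)
      wC <- runif1(cfg$wC_window)
      if (wH >= min(ax_h) && wH <= max(ax_h) &&
          wC >= min(offsets) && wC <= max(offsets)) {
        return(spin_system(wH = wH, wC = wC, j_hc = runif1(cfg$j_range),
                           r2_h = runif1(cfg$r2h_range),
                           r2_mq = runif1(cfg$r2mq_range),
                           r2_aph = runif1(cfg$r2aph_range),
                           i0 = runif1(cfg$i0_range)))
      }
    }
    stop("sample_example: could not draw a peak inside the axes (check ",
         "wH_window/wC_window against the sweep settings)", call. = FALSE)
  }
  n_peaks <- sample.int(cfg$n_peaks_max, 1)
  spins <- lapply(seq_len(n_peaks), function(i) draw_peak())

  ds <- simulate_offres_dataset(spins, scheme, normalize = FALSE,
                                apodize = TRUE, phase = phase)
  x <- ds$data
  scale0 <- max(x)
  if (scale0 > 0) x <- x / scale0
  if (noise_amp > 0) {
    x <- x + array(stats::rnorm(length(x), 0, noise_amp), dim(x))
    x <- x / max(x)
  }
  input <- offres_dataset(x, ds$axis_ppm_h, ds$axis_hz_h, ds$axis_ppm_c,
                          ds$b1_list, normalized = TRUE, scale = scale0,
                          meta = list(source = "synthetic", seed = seed,
                                      noise_amp = noise_amp, phase = phase))
  target <- build_target_map(spins, scheme,
                             min_fwhm_h_hz = cfg$min_fwhm_h_hz,
                             fwhm_c_hz = cfg$fwhm_c_hz)
  structure(list(input = input, target = target,
                 truth = list(spins = spins, f_h = f_h, b1 = b1, sw_h = sw_h,
                              offsets = offsets, phase = phase,
                              noise_amp = noise_amp, scheme = scheme),
                 seed = seed),
            class = "training_example")
}

#' Generate a batch of training examples
#'
#' @param cfg A [generator_config()].
#' @param n Number of examples.
#' @param seed Base seed; example i uses `seed + i - 1`.
#' @return List of `training_example`s.
#' @export
generate_examples <- function(cfg, n, seed = 1) {
  lapply(seq_len(n), function(i) sample_example(cfg, seed + i - 1))
}

#' Stack training examples into dense arrays
#'
#' @param examples List of `training_example`s on a common grid.
#' @return List with `inputs` `(n_h, n_offsets, n_b1, n)` and `targets`
#'   `(n_h, n_offsets, n)`.
#' @export
examples_to_arrays <- function(examples) {
  stopifnot(length(examples) >= 1)
  d <- dim(examples[[1]]$input$data)
  inputs <- array(0, c(d, length(examples)))
  targets <- array(0, c(d[1], d[2], length(examples)))
  for (i in seq_along(examples)) {
    stopifnot(all(dim(examples[[i]]$input$data) == d))
    inputs[, , , i] <- examples[[i]]$input$data
    targets[, , i] <- examples[[i]]$target$data
  }
  list(inputs = inputs, targets = targets)
}

#' Write training examples to shards on disk
#'
#' Each shard is a pair of files: a raw little-endian double array
#' (`shard-NNNN.bin`) holding the input stacks and targets back to back, and
#' a JSON sidecar (`shard-NNNN.json`) with dimensions, per-example truth
#' metadata, seeds and an md5 of the binary payload for integrity checking.
#'
#' @param examples Non-empty list of `training_example`s.
#' @param path Output directory (created if needed).
#' @param shard_size Examples per shard (default 32).
#' @return Invisibly, the sidecar file paths.
#' @export
write_shards <- function(examples, path, shard_size = 32) {
  if (!length(examples)) stop("write_shards: empty example list",
                              call. = FALSE)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  idx <- split(seq_along(examples),
               ceiling(seq_along(examples) / shard_size))
  sidecars <- character(0)
  for (s in seq_along(idx)) {
    exs <- examples[idx[[s]]]
    arr <- examples_to_arrays(exs)
    bin <- file.path(path, sprintf("shard-%04d.bin", s))
    con <- file(bin, "wb")
    writeBin(as.vector(arr$inputs), con, size = 8, endian = "little")
    writeBin(as.vector(arr$targets), con, size = 8, endian = "little")
    close(con)
    truth <- lapply(exs, function(e) {
      list(seed = e$seed,
           spins = apply(spins_matrix(e$truth$spins), 1, as.list),
           f_h = e$truth$f_h, b1 = e$truth$b1, sw_h = e$truth$sw_h,
           phase = e$truth$phase, noise_amp = e$truth$noise_amp)
    })
    side <- list(n = length(exs), dim_input = dim(arr$inputs)[1:3],
                 md5 = unname(tools::md5sum(bin)),
                 axis_ppm_h = exs[[1]]$input$axis_ppm_h,
                 axis_ppm_c = exs[[1]]$input$axis_ppm_c,
                 b1_list = exs[[1]]$input$b1_list, truth = truth)
    sc <- file.path(path, sprintf("shard-%04d.json", s))
    jsonlite::write_json(side, sc, auto_unbox = TRUE, digits = NA)
    sidecars <- c(sidecars, sc)
  }
  invisible(sidecars)
}

#' Read shards written by [write_shards()]
#'
#' @param path Shard directory.
#' @return List with `inputs`, `targets` (dense arrays over all shards) and
#'   `truth` (per-example metadata).
#' @export
read_shards <- function(path) {
  sidecars <- sort(list.files(path, pattern = "^shard-\\d+\\.json$",
                              full.names = TRUE))
  if (!length(sidecars)) stop("read_shards: no shards in ", path,
                              call. = FALSE)
  ins <- list(); tgs <- list(); truth <- list()
  for (sc in sidecars) {
    side <- jsonlite::read_json(sc, simplifyVector = TRUE,
                                simplifyDataFrame = FALSE,
                                simplifyMatrix = FALSE)
    bin <- sub("\\.json$", ".bin", sc)
    if (!identical(unname(tools::md5sum(bin)), side$md5)) {
      stop("read_shards: md5 mismatch for ", basename(bin),
           " (corrupt shard)", call. = FALSE)
    }
    d <- as.integer(side$dim_input)
    n <- as.integer(side$n)
    con <- file(bin, "rb")
    vals <- readBin(con, "double", n * (prod(d) + d[1] * d[2]), size = 8,
                    endian = "little")
    close(con)
    n_in <- prod(d) * n
    ins[[length(ins) + 1]] <- array(vals[seq_len(n_in)], c(d, n))
    tgs[[length(tgs) + 1]] <- array(vals[-seq_len(n_in)], c(d[1], d[2], n))
    truth <- c(truth, side$truth)
  }
  d <- dim(ins[[1]])[1:3]
  ntot <- sum(vapply(ins, function(x) dim(x)[4], numeric(1)))
  inputs <- array(0, c(d, ntot)); targets <- array(0, c(d[1], d[2], ntot))
  at <- 0
  for (i in seq_along(ins)) {
    k <- dim(ins[[i]])[4]
    inputs[, , , at + seq_len(k)] <- ins[[i]]
    targets[, , at + seq_len(k)] <- tgs[[i]]
    at <- at + k
  }
  list(inputs = inputs, targets = targets, truth = truth)
}
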