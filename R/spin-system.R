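#' Define a 1H-13C spin system
#'
#' Represents one isolated 1H-13C pair (a 13CHD2 methyl probe): the two
#' chemical shifts, the one-bond scalar coupling and the three transverse
#' relaxation rates that enter the 8x8 Liouvillian.  The single-quantum 13C
#' rate does not enter the dynamics of the detected signal and is therefore
#' not a field.
#'
#' @param wH 1H chemical shift (ppm).
#' @param wC 13C chemical shift (ppm).
#' @param j_hc One-bond scalar coupling 1J_HC (Hz), must be positive
#'   (~125 Hz for methyl groups).
#' @param r2_h 1H single-quantum transverse relaxation rate R2,H (s^-1).
#' @param r2_mq Multiple-quantum relaxation rate R2,MQ (s^-1), shared by the
#'   four double-transverse terms 2HjCk (j,k in x,y).
#' @param r2_aph Antiphase relaxation rate R2,APH (s^-1) for 2HxCz and 2HyCz.
#' @param i0 Starting magnetization I0 (arbitrary positive units).
#'
#' @return An object of class `spin_system`.
#' @examples
#' sp <- spin_system(wH = 0.8, wC = 12.5, j_hc = 125,
#'                   r2_h = 25, r2_mq = 25, r2_aph = 25)
#' @export
spin_system <- function(wH, wC, j_hc = 125, r2_h = 25, r2_mq = 25,
                        r2_aph = 25, i0 = 1) {
  for (nm in c("wH", "wC", "j_hc", "r2_h", "r2_mq", "r2_aph", "i0")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("spin_system: field '", nm, "' must be a finite numeric scalar",
           call. = FALSE)
    }
  }
  if (j_hc <= 0) stop("spin_system: 'j_hc' must be > 0", call. = FALSE)
  if (r2_h < 0 || r2_mq < 0 || r2_aph < 0) {
    stop("spin_system: relaxation rates must be >= 0", call. = FALSE)
  }
  if (i0 <= 0) stop("spin_system: 'i0' must be > 0", call. = FALSE)
  structure(list(wH = wH, wC = wC, j_hc = j_hc, r2_h = r2_h, r2_mq = r2_mq,
                 r2_aph = r2_aph, i0 = i0),
            class = "spin_system")
}

#' @export
print.spin_system <- function(x, ...) {
  cat(sprintf(
    "<spin_system> wH = %.3f ppm, wC = %.3f ppm, 1J_HC = %.1f Hz\n",
    x$wH, x$wC, x$j_hc))
  cat(sprintf("  R2,H = %.2f  R2,MQ = %.2f  R2,APH = %.2f s^-1;  I0 = %.3g\n",
              x$r2_h, x$r2_mq, x$r2_aph, x$i0))
  invisible(x)
}

#' Convert a list of spin systems to a parameter matrix
#'
#' Internal plumbing used by the batch simulator: one row per spin, columns
#' (wH, wC, j_hc, r2_h, r2_mq, r2_aph, i0).
#' @param spins A `spin_system` or list of them.
#' @return Numeric matrix with 7 columns.
#' @keywords internal
spins_matrix <- function(spins) {
  if (inherits(spins, "spin_system")) spins <- list(spins)
  if (!length(spins)) stop("empty spin list", call. = FALSE)
  m <- t(vapply(spins, function(s) {
    stopifnot(inherits(s, "spin_system"))
    c(s$wH, s$wC, s$j_hc, s$r2_h, s$r2_mq, s$r2_aph, s$i0)
  }, numeric(7)))
  colnames(m) <- c("wH", "wC", "j_hc", "r2_h", "r2_mq", "r2_aph", "i0")
  m
}

#' Define an acquisition scheme for the single-pulse experiment
#'
#' Collects the spectrometer and sampling parameters: static field (as the 1H
#' base frequency), CW 13C decoupling field strengths, decoupler offset grid,
#' 1H sweep width and acquisition timing.  The default grid matches the
#' published experimental design at 16.4 T: a ~5 ppm 1H sweep, 64 ms of
#' acquisition, 200 decoupler offsets spanning ~30 ppm of the methyl 13C
#' region, and B1 fields of 220 and 110 Hz (channel order fixed high -> low).
#'
#' @param f_h 1H base frequency (MHz); 700 corresponds to 16.4 T.
#' @param gamma_ratio gammaC/gammaH, used for ppm <-> Hz on the 13C axis.
#' @param carrier_h 1H carrier position (ppm).
#' @param sw_h 1H sweep width (ppm).
#' @param t_max Acquisition time (s).
#' @param n_zf Zero-fill size (points); must be at least the number of
#'   acquired points.
#' @param b1_list CW decoupling field strengths (Hz), ordered high to low.
#' @param offsets_c Ordered decoupler positions nuRF (ppm); strictly
#'   monotone.  Default: 200 values spanning 30 ppm centred on the methyl
#'   region.
#' @param reference_mode Either `"none"` (reference simulated with B1 = 0) or
#'   a single number: the far-offset decoupler position in ppm (e.g. -50, as
#'   used experimentally).
#'
#' @return An object of class `acquisition_scheme`.  The derived quantities
#'   `n_t` (acquired complex points) and `dt` (dwell time, s) are included.
#' @examples
#' sch <- acquisition_scheme()
#' sch$n_t   # 225 points at 5 ppm / 700 MHz / 64 ms
#' @export
acquisition_scheme <- function(f_h = 700, gamma_ratio = 0.25144953,
                               carrier_h = 0.45, sw_h = 5, t_max = 0.064,
                               n_zf = 512, b1_list = c(220, 110),
                               offsets_c = seq(-2, 28, length.out = 200),
                               reference_mode = "none") {
  stopifnot(is.numeric(f_h), f_h > 0, is.numeric(sw_h), sw_h > 0,
            is.numeric(t_max), t_max > 0, is.numeric(n_zf), n_zf >= 1)
  if (any(!is.finite(b1_list)) || any(b1_list <= 0)) {
    stop("acquisition_scheme: all B1 values must be positive", call. = FALSE)
  }
  d <- diff(offsets_c)
  if (length(offsets_c) > 1 && !(all(d > 0) || all(d < 0))) {
    stop("acquisition_scheme: 'offsets_c' must be strictly monotone",
         call. = FALSE)
  }
  sw_hz <- sw_h * f_h
  n_t <- floor(t_max * sw_hz) + 1L
  if (n_zf < n_t) {
    stop("acquisition_scheme: 'n_zf' (", n_zf,
         ") is smaller than the number of acquired points (", n_t, ")",
         call. = FALSE)
  }
  ref <- if (identical(reference_mode, "none")) {
    list(mode = "none")
  } else if (is.numeric(reference_mode) && length(reference_mode) == 1L &&
             is.finite(reference_mode)) {
    list(mode = "far_offset", ppm = as.numeric(reference_mode))
  } else {
    stop("acquisition_scheme: 'reference_mode' must be \"none\" or a ",
         "far-offset position in ppm", call. = FALSE)
  }
  structure(list(f_h = f_h, gamma_ratio = gamma_ratio, carrier_h = carrier_h,
                 sw_h = sw_h, t_max = t_max, n_zf = as.integer(n_zf),
                 b1_list = as.numeric(b1_list),
                 offsets_c = as.numeric(offsets_c), reference = ref,
                 sw_hz = sw_hz, n_t = n_t, dt = 1 / sw_hz),
            class = "acquisition_scheme")
}

#' @export
print.acquisition_scheme <- function(x, ...) {
  cat(sprintf("<acquisition_scheme> %.0f MHz 1H, sw %.2f ppm, %d pts -> zf %d\n",
              x$f_h, x$sw_h, x$n_t, x$n_zf))
  cat(sprintf("  B1 = {%s} Hz; %d 13C offsets %.2f..%.2f ppm; reference: %s\n",
              paste(x$b1_list, collapse = ", "), length(x$offsets_c),
              min(x$offsets_c), max(x$offsets_c),
              if (x$reference$mode == "none") "B1 = 0" else
                sprintf("far offset %.1f ppm", x$reference$ppm)))
  invisible(x)
}

#' 1H frequency axis of a processed spectrum
#'
#' Ascending axis after the centred Fourier transform; `hz` is offset from the
#' carrier, `ppm` is absolute.
#' @param scheme An `acquisition_scheme`.
#' @return List with `hz` and `ppm` vectors of length `n_zf`.
#' @export
h_axis <- function(scheme) {
  n <- scheme$n_zf
  hz <- (seq_len(n) - 1 - n / 2) * scheme$sw_hz / n
  list(hz = hz, ppm = scheme$carrier_h + hz / scheme$f_h)
}

#' Time grid of the acquired FID
#' @param scheme An `acquisition_scheme`.
#' @return Numeric vector `0, dt, ..., (n_t-1) dt`.
#' @export
time_grid <- function(scheme) (seq_len(scheme$n_t) - 1) * scheme$dt
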