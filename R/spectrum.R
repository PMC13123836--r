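#' Process a FID into a 1D 1H spectrum
#'
#' Applies (optionally) a zero-order phase, cosine-square apodization over the
#' acquired length, zero-filling to `n_zf` points and a centred complex
#' Fourier transform.  The first time-domain point is halved (the usual
#' discrete-FT convention that removes the baseline offset of one-sided
#' sampling).
#'
#' @param fid Complex FID of length `scheme$n_t`.
#' @param scheme An [acquisition_scheme()].
#' @param apodize Apply the cosine-square window (default TRUE).
#' @param phase Zero-order phase correction (degrees).
#'
#' @return Object of class `spectrum1d`: list with complex `intensity`
#'   (length `n_zf`), `axis_hz`, `axis_ppm` (ascending) and the scheme.
#' @examples
#' sch <- acquisition_scheme()
#' sp <- spin_system(wH = 1.0, wC = 12)
#' fid <- propagate_fid(build_liouvillian(sp, 0, 12, sch), time_grid(sch))
#' spec <- synthesize_spectrum(fid, sch)
#' spec$axis_ppm[which.max(Re(spec$intensity))]  # ~1.0 ppm
#' @export
synthesize_spectrum <- function(fid, scheme, apodize = TRUE, phase = 0) {
  stopifnot(inherits(scheme, "acquisition_scheme"))
  n_t <- length(fid)
  if (n_t != scheme$n_t) {
    stop("synthesize_spectrum: FID length (", n_t,
         ") does not match the scheme's acquired points (", scheme$n_t, ")",
         call. = FALSE)
  }
  n_zf <- scheme$n_zf
  if (n_zf < n_t) {
    stop("synthesize_spectrum: zero-fill size smaller than FID length",
         call. = FALSE)
  }
  x <- fid * exp(1i * phase * pi / 180)
  if (apodize) {
    w <- cos(0.5 * pi * (seq_len(n_t) - 1) / (n_t - 1))^2
    x <- x * w
  }
  x[1] <- 0.5 * x[1]
  buf <- complex(n_zf)
  buf[seq_len(n_t)] <- x
  sp <- stats::fft(buf)
  half <- n_zf %/% 2
  sp <- sp[c((half + 1):n_zf, 1:half)]  # fftshift: ascending frequency
  ax <- h_axis(scheme)
  structure(list(intensity = sp, axis_hz = ax$hz, axis_ppm = ax$ppm,
                 scheme = scheme),
            class = "spectrum1d")
}

#' Simulate a (difference) off-resonance dataset
#'
#' For every (decoupler offset, B1) pair, computes the summed difference FID
#' of all spins (decoupled minus reference, the reference being simulated with
#' B1 = 0 or with far-offset decoupling per the scheme's `reference_mode`),
#' processes it like [synthesize_spectrum()], and stacks the real parts into
#' an array of shape `(n_zf, n_offsets, n_b1)`.  Superposition over spins
#' holds exactly before normalization.
#'
#' @param spins A `spin_system` or list of them.
#' @param scheme An [acquisition_scheme()].
#' @param normalize Scale the stack so its global maximum is 1 (default
#'   FALSE; the training generator normalizes after adding noise).
#' @param apodize,phase Passed to the spectral processing.
#' @param subtract_reference Set FALSE to keep the raw (coupled-background)
#'   stack.
#'
#' @return Object of class `offres_dataset`: list with `data` (the stack),
#'   `axis_ppm_h`, `axis_hz_h`, `axis_ppm_c` (the offset grid), `b1_list`,
#'   `normalized` flag, `scale` (the pre-normalization global maximum; 1 when
#'   not normalized) and `meta` provenance.
#' @examples
#' sch <- acquisition_scheme(offsets_c = seq(10, 15, length.out = 21),
#'                           n_zf = 256)
#' ds <- simulate_offres_dataset(spin_system(wH = 0.45, wC = 12.5), sch)
#' dim(ds$data)
#' @export
simulate_offres_dataset <- function(spins, scheme, normalize = FALSE,
                                    apodize = TRUE, phase = 0,
                                    subtract_reference = TRUE) {
  stopifnot(inherits(scheme, "acquisition_scheme"))
  sm <- spins_matrix(spins)
  ref_mode <- if (!subtract_reference) -1L
              else if (scheme$reference$mode == "none") 0L else 1L
  ref_ppm <- if (scheme$reference$mode == "far_offset") scheme$reference$ppm
             else 0
  fids <- sim_diff_fids_cpp(sm, scheme$f_h, scheme$gamma_ratio,
                            scheme$carrier_h, scheme$offsets_c,
                            scheme$b1_list, time_grid(scheme),
                            if (ref_mode < 0L) 2L else ref_mode,
                            if (ref_mode < 0L) NA_real_ else ref_ppm)
  stack <- process_fid_cube_cpp(fids, scheme$n_zf, apodize, phase)
  ax <- h_axis(scheme)
  scale <- 1
  if (normalize) {
    scale <- max(stack)
    if (scale > 0) stack <- stack / scale
  }
  offres_dataset(stack, ax$ppm, ax$hz, scheme$offsets_c, scheme$b1_list,
                 normalized = normalize, scale = scale,
                 meta = list(source = "simulated", n_spins = nrow(sm),
                             scheme = scheme))
}

#' Construct an off-resonance dataset container
#'
#' Low-level constructor used by the simulator, the training generator and
#' the experimental-data ingest path.
#'
#' @param data Real array `(n_h, n_offsets, n_b1)`.
#' @param axis_ppm_h,axis_hz_h 1H axes (ascending).
#' @param axis_ppm_c 13C decoupler-offset axis (ppm).
#' @param b1_list B1 values (Hz), high to low.
#' @param normalized Logical: global maximum scaled to 1.
#' @param scale Pre-normalization global maximum (for downstream quantitative
#'   comparisons).
#' @param meta Provenance list.
#' @return Object of class `offres_dataset`.
#' @export
offres_dataset <- function(data, axis_ppm_h, axis_hz_h, axis_ppm_c, b1_list,
                           normalized = FALSE, scale = 1, meta = list()) {
  stopifnot(length(dim(data)) == 3L,
            dim(data)[1] == length(axis_ppm_h),
            dim(data)[2] == length(axis_ppm_c),
            dim(data)[3] == length(b1_list))
  if (normalized && max(data) > 0 && abs(max(data) - 1) > 1e-8) {
    stop("offres_dataset: normalized flag set but global maximum != 1",
         call. = FALSE)
  }
  structure(list(data = data, axis_ppm_h = axis_ppm_h, axis_hz_h = axis_hz_h,
                 axis_ppm_c = axis_ppm_c, b1_list = b1_list,
                 normalized = normalized, scale = scale, meta = meta),
            class = "offres_dataset")
}

#' @export
print.offres_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<offres_dataset> %d x %d x %d (1H x 13C offsets x B1)\n",
              d[1], d[2], d[3]))
  cat(sprintf("  B1 = {%s} Hz; normalized: %s; pre-norm scale: %.4g\n",
              paste(x$b1_list, collapse = ", "), x$normalized, x$scale))
  invisible(x)
}
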