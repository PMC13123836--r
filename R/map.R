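#' Construct a 1H-13C correlation map
#'
#' The network target/output container: a real `(n_h, n_offsets)` matrix with
#' calibrated ppm axes and an optional point-wise uncertainty matrix of the
#' same shape.
#'
#' @param data Real matrix (1H along rows, 13C along columns).
#' @param axis_ppm_h,axis_ppm_c Calibrated axes (ascending ppm).
#' @param sigma Optional uncertainty matrix, same shape.
#' @param meta Provenance list.
#' @return Object of class `correlation_map`.
#' @export
correlation_map <- function(data, axis_ppm_h, axis_ppm_c, sigma = NULL,
                            meta = list()) {
  stopifnot(is.matrix(data), nrow(data) == length(axis_ppm_h),
            ncol(data) == length(axis_ppm_c))
  if (!is.null(sigma)) {
    stopifnot(is.matrix(sigma), all(dim(sigma) == dim(data)))
  }
  structure(list(data = data, axis_ppm_h = axis_ppm_h,
                 axis_ppm_c = axis_ppm_c, sigma = sigma, meta = meta),
            class = "correlation_map")
}

#' @export
print.correlation_map <- function(x, ...) {
  cat(sprintf("<correlation_map> %d x %d (1H x 13C)%s\n", nrow(x$data),
              ncol(x$data), if (is.null(x$sigma)) "" else " + sigma"))
  cat(sprintf("  1H %.3f..%.3f ppm; 13C %.2f..%.2f ppm; max %.4g\n",
              min(x$axis_ppm_h), max(x$axis_ppm_h), min(x$axis_ppm_c),
              max(x$axis_ppm_c), max(x$data)))
  invisible(x)
}

#' Render the Gaussian-peak target correlation map for a set of spins
#'
#' Builds the noise-free training target: one 2D Gaussian per spin at
#' (wH, wC), amplitude I0.  The 1H full width at half maximum is
#' `max(R2,H / pi, min_fwhm_h_hz)` Hz; the 13C width is fixed at
#' `fwhm_c_hz` because the off-resonance data carry no direct 13C linewidth
#' information.  Overlapping peaks add.  Gaussians are evaluated at pixel
#' centres (no subpixel integration), consistently between training and
#' evaluation.
#'
#' @param spins A `spin_system` or list of them.
#' @param scheme An [acquisition_scheme()] defining the grid and axes.
#' @param min_fwhm_h_hz Minimum 1H FWHM (Hz), default 20.
#' @param fwhm_c_hz Fixed 13C FWHM (Hz), default 30.
#' @return A [correlation_map()].
#' @examples
#' sch <- acquisition_scheme(n_zf = 256,
#'                           offsets_c = seq(5, 20, length.out = 50))
#' tm <- build_target_map(spin_system(wH = 0.8, wC = 12.5, r2_h = 25), sch)
#' max(tm$data)  # 1 at the peak centre pixel (up to pixel offset)
#' @export
build_target_map <- function(spins, scheme, min_fwhm_h_hz = 20,
                             fwhm_c_hz = 30) {
  stopifnot(inherits(scheme, "acquisition_scheme"))
  sm <- spins_matrix(spins)
  ax_h <- h_axis(scheme)$ppm
  ax_c <- scheme$offsets_c
  if (any(sm[, "wH"] < min(ax_h) | sm[, "wH"] > max(ax_h)) ||
      any(sm[, "wC"] < min(ax_c) | sm[, "wC"] > max(ax_c))) {
    stop("build_target_map: spin outside the map axes", call. = FALSE)
  }
  m <- matrix(0, length(ax_h), length(ax_c))
  f_c <- scheme$f_h * scheme$gamma_ratio  # MHz on 13C
  for (i in seq_len(nrow(sm))) {
    fwhm_h <- max(sm[i, "r2_h"] / pi, min_fwhm_h_hz) / scheme$f_h   # ppm
    fwhm_c <- fwhm_c_hz / f_c                                       # ppm
    gh <- exp(-4 * log(2) * ((ax_h - sm[i, "wH"]) / fwhm_h)^2)
    gc <- exp(-4 * log(2) * ((ax_c - sm[i, "wC"]) / fwhm_c)^2)
    m <- m + sm[i, "i0"] * outer(gh, gc)
  }
  correlation_map(m, ax_h, ax_c,
                  meta = list(source = "target", n_spins = nrow(sm),
                              min_fwhm_h_hz = min_fwhm_h_hz,
                              fwhm_c_hz = fwhm_c_hz))
}
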