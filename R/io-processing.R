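#' A raw off-resonance series for one B1 field
#'
#' Ordered per-offset 1D records (time-domain FIDs or frequency-domain
#' spectra) plus the reference record and the acquisition metadata needed to
#' process and calibrate them.
#'
#' @param records Complex (time-domain) or numeric (frequency-domain) matrix,
#'   one column per decoupler offset.
#' @param reference Reference record (same length/domain as the columns of
#'   `records`): recorded with no or far-off-resonance decoupling.
#' @param domain `"time"` or `"freq"`.
#' @param f_h 1H base frequency (MHz).
#' @param sw_h 1H sweep width (ppm).
#' @param carrier_h 1H carrier (ppm).
#' @param t_max Acquisition time (s) (time-domain series).
#' @param offsets Decoupler offsets (ppm), one per column.
#' @param b1 CW field strength (Hz).
#' @param reference_mode `"none"` or the far-offset position (ppm).
#' @return Object of class `raw_series`.
#' @export
raw_series <- function(records, reference, domain = c("time", "freq"), f_h,
                       sw_h, carrier_h, t_max, offsets, b1,
                       reference_mode = "none") {
  domain <- match.arg(domain)
  records <- as.matrix(records)
  if (ncol(records) != length(offsets)) {
    stop("raw_series: ", ncol(records), " records but ", length(offsets),
         " offsets declared", call. = FALSE)
  }
  if (length(reference) != nrow(records)) {
    stop("raw_series: reference record length differs from the series",
         call. = FALSE)
  }
  if (!is.numeric(b1) || length(b1) != 1L || b1 <= 0) {
    stop("raw_series: 'b1' must be a positive scalar (Hz)", call. = FALSE)
  }
  structure(list(records = records, reference = reference, domain = domain,
                 f_h = f_h, sw_h = sw_h, carrier_h = carrier_h,
                 t_max = t_max, offsets = as.numeric(offsets), b1 = b1,
                 reference_mode = reference_mode),
            class = "raw_series")
}

#' Spectral processing parameters
#'
#' @param phase0 Zero-order phase (degrees).
#' @param phase1 First-order phase (degrees across the sweep; default 0, as
#'   appropriate for single-pulse FIDs).
#' @param apodize Cosine-square apodization (default TRUE).
#' @param n_zf Zero-fill target (points, default 512); must be at least the
#'   record length.
#' @return Object of class `processing_params`.
#' @export
processing_params <- function(phase0 = 0, phase1 = 0, apodize = TRUE,
                              n_zf = 512) {
  structure(list(phase0 = phase0, phase1 = phase1, apodize = apodize,
                 n_zf = as.integer(n_zf)),
            class = "processing_params")
}

process_record <- function(x, domain, params, n_zf) {
  if (domain == "freq") return(Re(x))
  n_t <- length(x)
  if (n_zf < n_t) stop("processing: zero-fill smaller than record length",
                       call. = FALSE)
  x <- x * exp(1i * params$phase0 * pi / 180)
  if (params$phase1 != 0) {
    x <- x * exp(1i * params$phase1 * (seq_len(n_t) - 1) / n_t * pi / 180)
  }
  if (params$apodize) {
    x <- x * cos(0.5 * pi * (seq_len(n_t) - 1) / (n_t - 1))^2
  }
  x[1] <- 0.5 * x[1]
  buf <- complex(n_zf)
  buf[seq_len(n_t)] <- x
  sp <- stats::fft(buf)
  half <- n_zf %/% 2
  Re(sp[c((half + 1):n_zf, 1:half)])
}

#' Assemble a network-ready input stack from two raw series
#'
#' Processes every record (phase, apodize, zero-fill, Fourier transform when
#' time-domain), subtracts the processed reference spectrum from every offset
#' spectrum, stacks the two B1 channels (order: high B1 first) and scales the
#' joint stack to a global maximum of 1 (recording the pre-normalization
#' scale).  Subtracting reference FIDs before the transform and reference
#' spectra after it are equivalent by linearity; this routine subtracts after
#' transforming.
#'
#' @param series_hi,series_lo [raw_series()] for the higher and lower B1.
#' @param params A [processing_params()].
#' @return An `offres_dataset` (normalized unless the stack is identically
#'   zero, in which case normalization is skipped and flagged in `meta`).
#' @export
build_input_stack <- function(series_hi, series_lo,
                              params = processing_params()) {
  stopifnot(inherits(series_hi, "raw_series"),
            inherits(series_lo, "raw_series"))
  if (series_hi$b1 == series_lo$b1) {
    stop("build_input_stack: equal B1 values; channel order is ambiguous",
         call. = FALSE)
  }
  if (series_hi$b1 < series_lo$b1) {
    stop("build_input_stack: 'series_hi' must be the higher-B1 series",
         call. = FALSE)
  }
  if (length(series_hi$offsets) != length(series_lo$offsets) ||
      max(abs(series_hi$offsets - series_lo$offsets)) > 1e-9) {
    stop("build_input_stack: offset grids differ between the B1 series",
         call. = FALSE)
  }
  n_zf <- params$n_zf
  one <- function(s) {
    ref <- process_record(s$reference, s$domain, params, n_zf)
    apply(s$records, 2,
          function(col) process_record(col, s$domain, params, n_zf) - ref)
  }
  hi <- one(series_hi); lo <- one(series_lo)
  stack <- array(c(hi, lo), c(n_zf, length(series_hi$offsets), 2))
  scale <- max(stack)
  zero <- !is.finite(scale) || scale <= 0
  if (!zero) stack <- stack / scale
  sch <- acquisition_scheme(f_h = series_hi$f_h, carrier_h =
                              series_hi$carrier_h, sw_h = series_hi$sw_h,
                            t_max = series_hi$t_max, n_zf = n_zf,
                            b1_list = c(series_hi$b1, series_lo$b1),
                            offsets_c = series_hi$offsets)
  ax <- h_axis(sch)
  offres_dataset(stack, ax$ppm, ax$hz, series_hi$offsets,
                 c(series_hi$b1, series_lo$b1),
                 normalized = !zero, scale = if (zero) 1 else scale,
                 meta = list(source = "processed", all_zero = zero))
}

#' Co-add two difference off-resonance datasets
#'
#' Forms `a + ratio * b` on the common pre-normalization scale (mimicking a
#' mixture of two samples), then renormalizes and records the combined scale
#' so downstream intensity comparisons remain quantitative.
#'
#' @param a,b `offres_dataset`s with identical axes and shapes.
#' @param ratio Scalar mixing ratio applied to `b`.
#' @return A normalized `offres_dataset`.
#' @export
coadd <- function(a, b, ratio) {
  stopifnot(inherits(a, "offres_dataset"), inherits(b, "offres_dataset"))
  if (!all(dim(a$data) == dim(b$data)) ||
      max(abs(a$axis_ppm_h - b$axis_ppm_h)) > 1e-9 ||
      max(abs(a$axis_ppm_c - b$axis_ppm_c)) > 1e-9) {
    stop("coadd: axis/shape mismatch", call. = FALSE)
  }
  pre <- a$data * a$scale + ratio * (b$data * b$scale)
  scale <- max(pre)
  out <- if (scale > 0) pre / scale else pre
  offres_dataset(out, a$axis_ppm_h, a$axis_hz_h, a$axis_ppm_c, a$b1_list,
                 normalized = scale > 0, scale = if (scale > 0) scale else 1,
                 meta = list(source = "coadd", ratio = ratio,
                             scale_a = a$scale, scale_b = b$scale))
}

#' Write a raw series to disk
#'
#' `array_container`: complex records are stored as interleaved real and
#' imaginary doubles with all metadata in the JSON sidecar.  `nmrpipe`: one
#' pseudo-2D plane (records as rows) plus the reference as a second file
#' `<path>-ref`, with the offset list and B1 in a JSON sidecar `<path>.json`
#' (the plane header cannot carry them).
#'
#' @param series A [raw_series()].
#' @param stem Output file stem.
#' @param format `"array_container"` or `"nmrpipe"`.
#' @return Invisibly, `stem`.
#' @export
write_series <- function(series, stem,
                         format = c("array_container", "nmrpipe")) {
  format <- match.arg(format)
  stopifnot(inherits(series, "raw_series"))
  meta <- list(kind = "raw_series", domain = series$domain, f_h = series$f_h,
               sw_h = series$sw_h, carrier_h = series$carrier_h,
               t_max = series$t_max, offsets = series$offsets,
               b1 = series$b1, reference_mode = series$reference_mode,
               n_t = nrow(series$records), complex = is.complex(series$records))
  if (format == "array_container") {
    interleave <- function(x) as.vector(rbind(as.vector(Re(x)),
                                              as.vector(Im(x))))
    vals <- c(interleave(series$records), interleave(series$reference))
    write_array_container(vals, stem, meta = meta)
  } else {
    rec <- series$records
    m <- t(Re(rec))
    con <- file(paste0(stem, ".fid"), "wb")
    writeBin(pipe_header(nrow(rec), ncol(rec), series$sw_h * series$f_h,
                         0, series$f_h, ft_x = 0, ft_y = 0),
             con, size = 4, endian = "little")
    writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
    if (is.complex(rec)) {
      writeBin(as.numeric(t(t(Im(rec)))), con, size = 4, endian = "little")
    }
    close(con)
    con <- file(paste0(stem, "-ref.fid"), "wb")
    writeBin(pipe_header(nrow(rec), 1, series$sw_h * series$f_h, 0,
                         series$f_h, ft_x = 0, ft_y = 0),
             con, size = 4, endian = "little")
    writeBin(Re(series$reference), con, size = 4, endian = "little")
    if (is.complex(rec)) {
      writeBin(Im(series$reference), con, size = 4, endian = "little")
    }
    close(con)
    jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(stem)
}

#' Read a raw series written by [write_series()]
#'
#' @param stem File stem used at write time.
#' @param format Format the series was written in.
#' @return A [raw_series()].  Missing metadata (offset list, B1) is rejected
#'   with the missing key named.
#' @export
read_series <- function(stem, format = c("array_container", "nmrpipe")) {
  format <- match.arg(format)
  if (format == "array_container") {
    ac <- read_array_container(stem)
    meta <- ac$meta
    for (key in c("offsets", "b1", "f_h", "sw_h", "n_t")) {
      if (is.null(meta[[key]])) {
        stop("read_series: metadata key '", key, "' is missing",
             call. = FALSE)
      }
    }
    n_t <- as.integer(meta$n_t)
    n_off <- length(meta$offsets)
    vals <- ac$data
    nrec <- 2L * n_t * n_off
    recs <- matrix(vals[seq_len(nrec)], nrow = 2L * n_t)
    ref <- vals[nrec + seq_len(2L * n_t)]
    odd <- seq(1L, 2L * n_t, by = 2L)
    records <- recs[odd, , drop = FALSE] + 1i * recs[odd + 1L, , drop = FALSE]
    reference <- ref[odd] + 1i * ref[odd + 1L]
    if (!isTRUE(meta$complex)) {
      records <- Re(records); reference <- Re(reference)
    }
    raw_series(records, reference, domain = meta$domain, f_h = meta$f_h,
               sw_h = meta$sw_h, carrier_h = meta$carrier_h,
               t_max = meta$t_max, offsets = as.numeric(meta$offsets),
               b1 = meta$b1,
               reference_mode = if (is.numeric(meta$reference_mode))
                 meta$reference_mode else "none")
  } else {
    meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
    for (key in c("offsets", "b1")) {
      if (is.null(meta[[key]])) {
        stop("read_series: metadata key '", key, "' is missing",
             call. = FALSE)
      }
    }
    rd <- function(p) {
      con <- file(p, "rb")
      on.exit(close(con))
      h <- readBin(con, "numeric", 512, size = 4, endian = "little")
      nx <- as.integer(h[.pipe_idx$FDSIZE + 1])
      ny <- as.integer(h[.pipe_idx$FDSPECNUM + 1])
      re <- matrix(readBin(con, "numeric", nx * ny, size = 4,
                           endian = "little"), ny, nx, byrow = TRUE)
      if (isTRUE(meta$complex)) {
        im <- matrix(readBin(con, "numeric", nx * ny, size = 4,
                             endian = "little"), ny, nx, byrow = TRUE)
        t(re) + 1i * t(im)
      } else t(re)
    }
    n_off <- length(meta$offsets)
    records <- rd(paste0(stem, ".fid"))
    if (ncol(records) != n_off) {
      stop("read_series: ", ncol(records), " records but ", n_off,
           " offsets declared", call. = FALSE)
    }
    reference <- rd(paste0(stem, "-ref.fid"))[, 1]
    raw_series(records, reference, domain = meta$domain, f_h = meta$f_h,
               sw_h = meta$sw_h, carrier_h = meta$carrier_h,
               t_max = meta$t_max, offsets = as.numeric(meta$offsets),
               b1 = meta$b1,
               reference_mode = if (is.numeric(meta$reference_mode))
                 meta$reference_mode else "none")
  }
}
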