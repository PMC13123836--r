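# 2D map and series export/import: the package's array container (raw
# little-endian doubles + JSON sidecar), UCSF (Sparky) and NMRPipe single
# plane.  The binary layouts follow the public format descriptions; only the
# header fields this package itself needs are populated.

#' Write a correlation map to disk
#'
#' @param map A [correlation_map()] with calibrated ppm axes.
#' @param path Output path.  For `array_container` this is a file stem
#'   (writes `<path>.bin` + `<path>.json`); otherwise a file name.
#' @param format `"array_container"` (lossless doubles), `"ucsf"` (Sparky,
#'   float32) or `"nmrpipe_ft2"` (float32 single plane).
#' @param f_h,gamma_ratio Spectrometer frequencies (MHz and gammaC/gammaH)
#'   used to fill the UCSF/NMRPipe frequency fields.
#' @return Invisibly, `path`.  The sigma plane, when present, is written as a
#'   sibling file with suffix `-sigma`.
#' @export
write_map <- function(map, path,
                      format = c("array_container", "ucsf", "nmrpipe_ft2"),
                      f_h = 700, gamma_ratio = 0.25144953) {
  format <- match.arg(format)
  stopifnot(inherits(map, "correlation_map"))
  if (is.null(map$axis_ppm_h) || is.null(map$axis_ppm_c)) {
    stop("write_map: map has no calibrated axes", call. = FALSE)
  }
  sib <- function(p, tag) {
    if (grepl("\\.[A-Za-z0-9]+$", p)) sub("(\\.[A-Za-z0-9]+)$",
                                          paste0("-", tag, "\\1"), p)
    else paste0(p, "-", tag)
  }
  if (format == "array_container") {
    write_array_container(map$data, path,
                          meta = list(kind = "correlation_map",
                                      axis_ppm_h = map$axis_ppm_h,
                                      axis_ppm_c = map$axis_ppm_c))
    if (!is.null(map$sigma)) {
      write_array_container(map$sigma, sib(path, "sigma"),
                            meta = list(kind = "sigma_map",
                                        axis_ppm_h = map$axis_ppm_h,
                                        axis_ppm_c = map$axis_ppm_c))
    }
  } else if (format == "ucsf") {
    write_ucsf2(map$data, map$axis_ppm_h, map$axis_ppm_c, path, f_h,
                f_h * gamma_ratio)
    if (!is.null(map$sigma)) {
      write_ucsf2(map$sigma, map$axis_ppm_h, map$axis_ppm_c,
                  sib(path, "sigma"), f_h, f_h * gamma_ratio)
    }
  } else {
    write_pipe2(map$data, map$axis_ppm_h, map$axis_ppm_c, path, f_h,
                f_h * gamma_ratio)
    if (!is.null(map$sigma)) {
      write_pipe2(map$sigma, map$axis_ppm_h, map$axis_ppm_c,
                  sib(path, "sigma"), f_h, f_h * gamma_ratio)
    }
  }
  invisible(path)
}

#' Read a correlation map written by [write_map()]
#'
#' @param path Path (file stem for `array_container`).
#' @param format Format the file was written in.
#' @return A [correlation_map()] (without sigma; read the sibling file for
#'   it).
#' @export
read_map <- function(path,
                     format = c("array_container", "ucsf", "nmrpipe_ft2")) {
  format <- match.arg(format)
  if (format == "array_container") {
    ac <- read_array_container(path)
    correlation_map(ac$data, as.numeric(ac$meta$axis_ppm_h),
                    as.numeric(ac$meta$axis_ppm_c))
  } else if (format == "ucsf") {
    u <- read_ucsf2(path)
    correlation_map(u$data, u$axis_ppm_h, u$axis_ppm_c)
  } else {
    p <- read_pipe2(path)
    correlation_map(p$data, p$axis_ppm_h, p$axis_ppm_c)
  }
}

# ---- array container ------------------------------------------------------

#' Write a numeric array as raw doubles + JSON sidecar
#' @param x Numeric array/matrix/vector.
#' @param stem Output file stem (`<stem>.bin`, `<stem>.json`).
#' @param meta Extra metadata stored in the sidecar.
#' @return Invisibly, `stem`.
#' @export
write_array_container <- function(x, stem, meta = list()) {
  bin <- paste0(stem, ".bin")
  con <- file(bin, "wb")
  writeBin(as.vector(as.numeric(x)), con, size = 8, endian = "little")
  close(con)
  side <- c(list(dim = if (is.null(dim(x))) length(x) else dim(x),
                 storage = "float64-little",
                 md5 = unname(tools::md5sum(bin))), meta)
  jsonlite::write_json(side, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' Read an array container written by [write_array_container()]
#' @param stem File stem used at write time.
#' @return List with `data` (dimensioned array) and `meta` (sidecar fields).
#' @export
read_array_container <- function(stem) {
  side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  bin <- paste0(stem, ".bin")
  if (!identical(unname(tools::md5sum(bin)), side$md5)) {
    stop("read_array_container: md5 mismatch (corrupt file)", call. = FALSE)
  }
  d <- as.integer(side$dim)
  con <- file(bin, "rb")
  vals <- readBin(con, "double", prod(d), size = 8, endian = "little")
  close(con)
  data <- if (length(d) > 1L) array(vals, d) else vals
  list(data = data, meta = side)
}

# ---- UCSF (Sparky) --------------------------------------------------------

# 2D UCSF file: 180-byte global header, one 128-byte axis header per
# dimension (w1 = 13C, w2 = 1H), float32 big-endian data in one tile.
write_ucsf2 <- function(data, axis_ppm_h, axis_ppm_c, path, obs_h, obs_c) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- raw(180)
  magic <- charToRaw("UCSF NMR")
  hdr[seq_along(magic)] <- magic
  hdr[11] <- as.raw(2)  # dimensions
  hdr[12] <- as.raw(1)  # real components
  hdr[14] <- as.raw(2)  # format version
  writeBin(hdr, con)
  axis_hdr <- function(nuc, n, obs_mhz, sw_hz, center_ppm) {
    h <- raw(128)
    nr <- charToRaw(nuc)
    h[seq_along(nr)] <- nr
    writeBin(h[1:8], con)
    writeBin(as.integer(n), con, size = 4, endian = "big")
    writeBin(raw(4), con)                                   # unused
    writeBin(as.integer(n), con, size = 4, endian = "big")  # tile size
    writeBin(as.numeric(obs_mhz), con, size = 4, endian = "big")
    writeBin(as.numeric(sw_hz), con, size = 4, endian = "big")
    writeBin(as.numeric(center_ppm), con, size = 4, endian = "big")
    writeBin(raw(128 - 8 - 4 * 6), con)
  }
  nh <- length(axis_ppm_h); nc <- length(axis_ppm_c)
  sw_h_hz <- axis_sw_hz(axis_ppm_h, obs_h)
  sw_c_hz <- axis_sw_hz(axis_ppm_c, obs_c)
  axis_hdr("13C", nc, obs_c, sw_c_hz, mean(range(axis_ppm_c)))
  axis_hdr("1H", nh, obs_h, sw_h_hz, mean(range(axis_ppm_h)))
  # w1 slowest: data[w1, w2] row-major, both axes descending ppm (NMR
  # convention); our internal axes ascend, so reverse both
  m <- t(data)[rev(seq_len(nc)), rev(seq_len(nh)), drop = FALSE]
  writeBin(as.numeric(t(m)), con, size = 4, endian = "big")
  invisible(path)
}

read_ucsf2 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 180)
  if (rawToChar(hdr[1:8]) != "UCSF NMR") {
    stop("read_ucsf2: not a UCSF file", call. = FALSE)
  }
  ndim <- as.integer(hdr[11])
  if (ndim != 2L) stop("read_ucsf2: expected a 2D file", call. = FALSE)
  rd_axis <- function() {
    nuc <- readBin(con, "raw", 8)
    n <- readBin(con, "integer", 1, size = 4, endian = "big")
    invisible(readBin(con, "raw", 4))
    tile <- readBin(con, "integer", 1, size = 4, endian = "big")
    obs <- readBin(con, "numeric", 1, size = 4, endian = "big")
    sw <- readBin(con, "numeric", 1, size = 4, endian = "big")
    center <- readBin(con, "numeric", 1, size = 4, endian = "big")
    invisible(readBin(con, "raw", 128 - 8 - 4 * 6))
    list(n = n, tile = tile, obs = obs, sw = sw, center = center)
  }
  a1 <- rd_axis(); a2 <- rd_axis()
  vals <- readBin(con, "numeric", a1$n * a2$n, size = 4, endian = "big")
  m <- matrix(vals, a1$n, a2$n, byrow = TRUE)  # (w1 = 13C, w2 = 1H)
  ax <- function(a) {
    sw_ppm <- a$sw / a$obs * (a$n - 1) / a$n
    seq(a$center + sw_ppm / 2, a$center - sw_ppm / 2, length.out = a$n)
  }
  ppm_c <- ax(a1); ppm_h <- ax(a2)
  # back to internal ascending axes, (1H x 13C)
  data <- t(m)[rev(seq_len(a2$n)), rev(seq_len(a1$n)), drop = FALSE]
  list(data = data, axis_ppm_h = rev(ppm_h), axis_ppm_c = rev(ppm_c))
}

# ---- NMRPipe --------------------------------------------------------------

# minimal NMRPipe header: 512 float32 words; indices (0-based) used here
# follow the public fdatap.h definitions
.pipe_idx <- list(FDMAGIC = 0, FDFLTFORMAT = 1, FDFLTORDER = 2,
                  FDDIMCOUNT = 9, FDF2SW = 100, FDF2ORIG = 101,
                  FDQUADFLAG = 106, FDF2OBS = 119, FDSIZE = 99,
                  FDSPECNUM = 219, FDF2FTFLAG = 220, FDTRANSPOSED = 221,
                  FDF1OBS = 218, FDF1SW = 229, FDF1ORIG = 249,
                  FDF1FTFLAG = 222, FDF2QUADFLAG = 56, FDF1QUADFLAG = 55)

pipe_header <- function(n_x, n_y, sw_x, orig_x, obs_x, sw_y = 0, orig_y = 0,
                        obs_y = 1, ft_x = 1, ft_y = 1) {
  h <- numeric(512)
  i <- .pipe_idx
  h[i$FDFLTFORMAT + 1] <- 4008636160  # float32 marker
  h[i$FDFLTORDER + 1] <- 2.345
  h[i$FDDIMCOUNT + 1] <- 2
  h[i$FDSIZE + 1] <- n_x
  h[i$FDSPECNUM + 1] <- n_y
  h[i$FDQUADFLAG + 1] <- 1
  h[i$FDF2QUADFLAG + 1] <- 1
  h[i$FDF1QUADFLAG + 1] <- 1
  h[i$FDF2SW + 1] <- sw_x
  h[i$FDF2ORIG + 1] <- orig_x
  h[i$FDF2OBS + 1] <- obs_x
  h[i$FDF2FTFLAG + 1] <- ft_x
  h[i$FDF1SW + 1] <- sw_y
  h[i$FDF1ORIG + 1] <- orig_y
  h[i$FDF1OBS + 1] <- obs_y
  h[i$FDF1FTFLAG + 1] <- ft_y
  h
}

# frequency of point i (0-based, descending axis): orig + sw*(n-1-i)/n
pipe_axis_ppm <- function(n, sw, orig, obs) {
  (orig + sw * (n - 1 - (0:(n - 1))) / n) / obs
}

axis_sw_hz <- function(axis_ppm, obs) {
  n <- length(axis_ppm)
  if (n < 2) return(0)
  abs(diff(range(axis_ppm))) * obs * n / (n - 1)
}

write_pipe2 <- function(data, axis_ppm_h, axis_ppm_c, path, obs_h, obs_c) {
  nh <- length(axis_ppm_h); nc <- length(axis_ppm_c)
  sw_h <- axis_sw_hz(axis_ppm_h, obs_h)
  sw_c <- axis_sw_hz(axis_ppm_c, obs_c)
  orig_h <- min(axis_ppm_h) * obs_h
  orig_c <- min(axis_ppm_c) * obs_c
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(pipe_header(nh, nc, sw_h, orig_h, obs_h, sw_c, orig_c, obs_c),
           con, size = 4, endian = "little")
  # x = 1H (descending ppm within each row), one row per 13C point
  # (descending ppm)
  m <- t(data)[rev(seq_len(nc)), rev(seq_len(nh)), drop = FALSE]
  writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
  invisible(path)
}

read_pipe2 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  h <- readBin(con, "numeric", 512, size = 4, endian = "little")
  i <- .pipe_idx
  if (abs(h[i$FDFLTORDER + 1] - 2.345) > 1e-4) {
    stop("read_pipe2: not a (little-endian) NMRPipe file", call. = FALSE)
  }
  nh <- as.integer(h[i$FDSIZE + 1]); nc <- as.integer(h[i$FDSPECNUM + 1])
  vals <- readBin(con, "numeric", nh * nc, size = 4, endian = "little")
  m <- matrix(vals, nc, nh, byrow = TRUE)
  ppm_h <- pipe_axis_ppm(nh, h[i$FDF2SW + 1], h[i$FDF2ORIG + 1],
                         h[i$FDF2OBS + 1])
  ppm_c <- pipe_axis_ppm(nc, h[i$FDF1SW + 1], h[i$FDF1ORIG + 1],
                         h[i$FDF1OBS + 1])
  data <- t(m)[rev(seq_len(nh)), rev(seq_len(nc)), drop = FALSE]
  list(data = data, axis_ppm_h = rev(ppm_h), axis_ppm_c = rev(ppm_c))
}
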