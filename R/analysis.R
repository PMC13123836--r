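#' Pick peaks from a correlation map by parabolic interpolation
#'
#' Finds interior local maxima above `threshold * max(map)` and refines each
#' position and height per dimension with the three-point parabola used by
#' Sparky's quadratic interpolation: offset
#' \eqn{\delta = (y_{-1} - y_{+1}) / (2 (y_{-1} - 2 y_0 + y_{+1}))} pixels,
#' height correction \eqn{-(y_{-1} - y_{+1}) \delta / 4} per dimension.
#'
#' @param map A [correlation_map()].
#' @param threshold Fraction of the global maximum, in (0, 1).
#' @return A `peak_list`: data frame with columns `wH_ppm`, `wC_ppm`,
#'   `height`, `sigma_height` (from the map's sigma plane at the peak pixel
#'   when available, else NA) and `label`.
#' @export
pick_peaks <- function(map, threshold = 0.1) {
  stopifnot(inherits(map, "correlation_map"))
  m <- map$data
  if (nrow(m) < 3 || ncol(m) < 3) {
    stop("pick_peaks: map smaller than 3x3", call. = FALSE)
  }
  if (!(threshold > 0 && threshold < 1)) {
    stop("pick_peaks: threshold must be in (0, 1)", call. = FALSE)
  }
  cut <- threshold * max(m)
  nh <- nrow(m); nc <- ncol(m)
  res <- list()
  for (j in 2:(nc - 1)) {
    for (i in 2:(nh - 1)) {
      y0 <- m[i, j]
      if (y0 < cut) next
      nbr <- m[(i - 1):(i + 1), (j - 1):(j + 1)]
      if (y0 < max(nbr[-5])) next
      if (any(nbr[-5] == y0)) {
        # plateau tie-break: keep only the lexicographically first pixel
        eq <- which(nbr == y0, arr.ind = TRUE)
        off <- cbind(eq[, 1] - 2L, eq[, 2] - 2L)
        off <- off[!(off[, 1] == 0L & off[, 2] == 0L), , drop = FALSE]
        if (any(off[, 2] < 0L | (off[, 2] == 0L & off[, 1] < 0L))) next
      }
      interp <- function(ym, yc, yp) {
        den <- ym - 2 * yc + yp
        if (den >= 0) return(c(0, 0))  # not curved downward; no refinement
        d <- (ym - yp) / (2 * den)
        c(d, -(ym - yp) * d / 4)
      }
      ih <- interp(m[i - 1, j], y0, m[i + 1, j])
      ic <- interp(m[i, j - 1], y0, m[i, j + 1])
      px_h <- i + ih[1]; px_c <- j + ic[1]
      res[[length(res) + 1]] <- c(
        wH = approx_axis(map$axis_ppm_h, px_h),
        wC = approx_axis(map$axis_ppm_c, px_c),
        height = y0 + ih[2] + ic[2],
        sigma = if (!is.null(map$sigma)) map$sigma[i, j] else NA_real_)
    }
  }
  if (!length(res)) {
    return(peak_list(data.frame(wH_ppm = numeric(0), wC_ppm = numeric(0),
                                height = numeric(0),
                                sigma_height = numeric(0),
                                label = character(0))))
  }
  df <- as.data.frame(do.call(rbind, res))
  names(df) <- c("wH_ppm", "wC_ppm", "height", "sigma_height")
  df <- df[order(-df$height), , drop = FALSE]
  df$label <- sprintf("P%03d", seq_len(nrow(df)))
  rownames(df) <- NULL
  peak_list(df)
}

# linear interpolation of a (uniform) axis at fractional pixel index
approx_axis <- function(axis, px) {
  n <- length(axis)
  px <- min(max(px, 1), n)
  i0 <- floor(px)
  if (i0 >= n) return(axis[n])
  axis[i0] + (px - i0) * (axis[i0 + 1] - axis[i0])
}

#' Construct a peak list
#' @param df Data frame with columns `wH_ppm`, `wC_ppm`, `height`,
#'   `sigma_height`, `label`.
#' @param source Optional provenance string.
#' @return The data frame with class `peak_list`.
#' @export
peak_list <- function(df, source = NULL) {
  stopifnot(all(c("wH_ppm", "wC_ppm", "height") %in% names(df)))
  if (is.null(df$sigma_height)) df$sigma_height <- NA_real_
  if (is.null(df$label)) df$label <- sprintf("P%03d", seq_len(nrow(df)))
  attr(df, "source") <- source
  class(df) <- c("peak_list", "data.frame")
  df
}

#' Fit peak intensities across an MC ensemble of maps
#'
#' Fits 2D Gaussians at fixed (shared) positions with free amplitudes and
#' widths to each ensemble map; overlapping peaks (closer than
#' `cluster_radius` in pixels) are fitted jointly.  The reported height of a
#' peak is the mean of its fitted amplitudes over the ensemble, and
#' `sigma_height = sigma_factor x SD` of those amplitudes.
#'
#' @param mc_maps List of at least 2 [correlation_map()]s on a common grid
#'   (e.g. the per-pass maps of [mc_reconstruct()]), or a single map given
#'   twice for a noiseless sanity fit.
#' @param positions A `peak_list` with the positions to fit.
#' @param sigma_factor Error calibration factor (default 1.4).
#' @param init_fwhm_h,init_fwhm_c Initial Gaussian FWHMs (ppm); defaults are
#'   3 pixels per axis.
#' @param cluster_radius Joint-fit grouping radius (pixels, default 6).
#' @return A `peak_list` with fitted `height`, `sigma_height` and a
#'   `converged` flag (non-convergent peaks are flagged, never dropped).
#' @export
fit_intensities <- function(mc_maps, positions, sigma_factor = 1.4,
                            init_fwhm_h = NULL, init_fwhm_c = NULL,
                            cluster_radius = 6) {
  if (inherits(mc_maps, "correlation_map")) mc_maps <- list(mc_maps)
  stopifnot(length(mc_maps) >= 2, inherits(positions, "data.frame"),
            nrow(positions) >= 1)
  ax_h <- mc_maps[[1]]$axis_ppm_h; ax_c <- mc_maps[[1]]$axis_ppm_c
  px_h <- abs(mean(diff(ax_h))); px_c <- abs(mean(diff(ax_c)))
  if (is.null(init_fwhm_h)) init_fwhm_h <- 3 * px_h
  if (is.null(init_fwhm_c)) init_fwhm_c <- 3 * px_c
  n_pk <- nrow(positions)
  # cluster peaks whose pixel distance is below cluster_radius (single link)
  ih <- (positions$wH_ppm - ax_h[1]) / px_h + 1
  ic <- (positions$wC_ppm - ax_c[1]) / px_c + 1
  cl <- seq_len(n_pk)
  repeat {
    changed <- FALSE
    for (a in seq_len(n_pk)) for (b in seq_len(n_pk)) {
      if (cl[a] != cl[b] &&
          sqrt((ih[a] - ih[b])^2 + (ic[a] - ic[b])^2) < cluster_radius) {
        cl[cl == cl[b]] <- cl[a]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  amps <- matrix(NA_real_, n_pk, length(mc_maps))
  conv <- rep(TRUE, n_pk)
  ln4 <- 4 * log(2)
  for (g in unique(cl)) {
    pk <- which(cl == g)
    # fit window: union of +-3 init FWHM around the group's peaks
    ri <- range(ih[pk]); rj <- range(ic[pk])
    wi <- max(2, ceiling(3 * init_fwhm_h / px_h))
    wj <- max(2, ceiling(3 * init_fwhm_c / px_c))
    ii <- max(1, floor(ri[1]) - wi):min(length(ax_h), ceiling(ri[2]) + wi)
    jj <- max(1, floor(rj[1]) - wj):min(length(ax_c), ceiling(rj[2]) + wj)
    H <- matrix(ax_h[ii], length(ii), length(jj))
    C <- matrix(ax_c[jj], length(ii), length(jj), byrow = TRUE)
    model <- function(p) {
      y <- 0
      for (q in seq_along(pk)) {
        a <- p[3 * q - 2]; fh <- abs(p[3 * q - 1]); fc <- abs(p[3 * q])
        y <- y + a * exp(-ln4 * (((H - positions$wH_ppm[pk[q]]) / fh)^2 +
                                   ((C - positions$wC_ppm[pk[q]]) / fc)^2))
      }
      y
    }
    for (e in seq_along(mc_maps)) {
      z <- mc_maps[[e]]$data[ii, jj]
      p0 <- as.vector(rbind(
        vapply(pk, function(q) {
          i0 <- round(min(max(ih[q], 1), length(ax_h)))
          j0 <- round(min(max(ic[q], 1), length(ax_c)))
          mc_maps[[e]]$data[i0, j0]
        }, numeric(1)), init_fwhm_h, init_fwhm_c))
      fit <- tryCatch(
        minpack.lm::nls.lm(par = p0, fn = function(p) as.vector(z - model(p)),
                           control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (is.null(fit) || fit$info %in% c(0, 5, 9)) {
        conv[pk] <- FALSE
        amps[pk, e] <- NA_real_
      } else {
        amps[pk, e] <- fit$par[3 * seq_along(pk) - 2]
      }
    }
  }
  out <- positions
  out$height <- rowMeans(amps)
  out$sigma_height <- sigma_factor * apply(amps, 1, stats::sd)
  out$converged <- conv
  peak_list(out, source = "ensemble_fit")
}

#' Chemical-shift RMSD between two peak lists
#'
#' Greedy nearest-neighbour matching (each peak used at most once) within
#' per-dimension tolerances, then per-dimension RMSD over the matches.
#'
#' @param a,b `peak_list`s (non-empty).
#' @param match_tol `c(H, C)` matching tolerances in ppm (default 0.05 and
#'   0.3).
#' @return List with `rmsd_H`, `rmsd_C` (ppm), `n_matched` and the match
#'   index matrix `pairs`.  Zero matches are reported (`n_matched = 0`,
#'   RMSDs NA), not an error.
#' @export
shift_rmsd <- function(a, b, match_tol = c(0.05, 0.3)) {
  stopifnot(nrow(a) >= 1, nrow(b) >= 1, length(match_tol) == 2)
  dh <- outer(a$wH_ppm, b$wH_ppm, "-")
  dc <- outer(a$wC_ppm, b$wC_ppm, "-")
  d <- sqrt((dh / match_tol[1])^2 + (dc / match_tol[2])^2)
  d[abs(dh) > match_tol[1] | abs(dc) > match_tol[2]] <- Inf
  pairs <- NULL
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  ord <- order(d)
  for (k in ord) {
    if (!is.finite(d[k])) break
    i <- (k - 1) %% nrow(a) + 1
    j <- (k - 1) %/% nrow(a) + 1
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE; used_b[j] <- TRUE
    pairs <- rbind(pairs, c(i, j))
  }
  if (is.null(pairs)) {
    return(list(rmsd_H = NA_real_, rmsd_C = NA_real_, n_matched = 0L,
                pairs = matrix(integer(0), 0, 2)))
  }
  list(rmsd_H = sqrt(mean((a$wH_ppm[pairs[, 1]] - b$wH_ppm[pairs[, 2]])^2)),
       rmsd_C = sqrt(mean((a$wC_ppm[pairs[, 1]] - b$wC_ppm[pairs[, 2]])^2)),
       n_matched = nrow(pairs), pairs = pairs)
}

#' Error-weighted intensity slope between two peak lists
#'
#' Least-squares slope of `height_b` versus `height_a` through the origin
#' over the peaks common to both lists (matched by label), weighted by
#' 1/sigma^2 when intensity errors are available.  Used for mixture-ratio
#' analysis, where peaks scaled by the mixing change should show the ratio of
#' mixing ratios as the slope.
#'
#' @param a,b `peak_list`s with `label` and `height` (and ideally
#'   `sigma_height`).
#' @param labels Labels of the peaks to use; default all common labels.
#' @return List with `slope`, `se` (standard error) and `n`.
#' @export
intensity_slope <- function(a, b, labels = NULL) {
  common <- intersect(a$label, b$label)
  if (!is.null(labels)) common <- intersect(common, labels)
  if (length(common) < 2) {
    stop("intensity_slope: fewer than 2 common peaks", call. = FALSE)
  }
  ha <- a$height[match(common, a$label)]
  hb <- b$height[match(common, b$label)]
  sa <- a$sigma_height[match(common, a$label)]
  sb <- b$sigma_height[match(common, b$label)]
  s2 <- ifelse(is.na(sb) | sb <= 0, 0, sb^2) +
    ifelse(is.na(sa) | sa <= 0, 0, sa^2)
  w <- if (all(s2 > 0)) 1 / s2 else rep(1, length(common))
  slope <- sum(w * ha * hb) / sum(w * ha^2)
  resid <- hb - slope * ha
  se <- if (all(s2 > 0)) {
    sqrt(1 / sum(ha^2 / s2))
  } else {
    sqrt(sum(resid^2) / (length(common) - 1) / sum(ha^2))
  }
  list(slope = slope, se = se, n = length(common))
}

#' Relaxation-equivalent molecular size after a viscosity change
#'
#' Rotational correlation times scale with solvent viscosity, so a particle
#' of mass M tumbling in a solvent `viscosity_ratio` times more viscous
#' relaxes like a particle of mass `M * viscosity_ratio` at the reference
#' condition.
#'
#' @param mass_kda Particle mass (kDa).
#' @param viscosity_ratio Viscosity ratio (dimensionless), e.g. ~2.2 for
#'   D2O at 10 vs 37 degrees C.
#' @return Effective mass (kDa).
#' @examples
#' effective_size(360, 2.2)   # ~790 kDa
#' @export
effective_size <- function(mass_kda, viscosity_ratio) {
  stopifnot(mass_kda > 0, viscosity_ratio > 0)
  mass_kda * viscosity_ratio
}

#' Write a peak list as TSV
#' @param peaks A `peak_list`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_peaks <- function(peaks, path) {
  cols <- intersect(c("label", "wH_ppm", "wC_ppm", "height", "sigma_height",
                      "converged"), names(peaks))
  utils::write.table(as.data.frame(peaks)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a peak-list TSV written by [write_peaks()]
#' @param path TSV path.
#' @return A `peak_list`.
#' @export
read_peaks <- function(path) {
  peak_list(utils::read.table(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE))
}
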