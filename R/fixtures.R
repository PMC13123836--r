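# Deterministic synthetic protein-like spin lists used as benchmarks and
# test fixtures.  These are synthetic stand-ins constructed to resemble the
# methyl content of a small (14-methyl) and a medium (60-methyl) ILV-labeled
# protein; they are not experimental shift lists.

#' Synthetic 14-methyl spin list (small-protein benchmark)
#'
#' Fourteen ILV-like 13CHD2 methyl spin systems with shifts spread over the
#' methyl region, mixed relaxation rates and intensities.  Deterministic.
#'
#' @param scale `"full"` places the peaks in the full methyl window
#'   (~5 ppm 1H sweep / 30 ppm 13C span); `"reduced"` compresses them into
#'   the reduced 128 x 48 benchmark windows.
#' @return List of 14 [spin_system()]s.
#' @export
ff_like_spins <- function(scale = c("reduced", "full")) {
  scale <- match.arg(scale)
  # (wH, wC) pairs on a deliberately irregular grid; all pairs separated by
  # >= ~8 px on the reduced 128 x 48 grid so every cross-peak is resolvable
  # in the fixed-linewidth target (X-arms still overlap heavily in the
  # input stacks, which is the hard part of the transform)
  pos <- cbind(
    wH = c(0.08, 0.95, 0.22, 0.78, 0.47, 0.66, 0.12, 0.88, 0.35, 0.58,
           0.72, 0.28, 0.52, 0.90),
    wC = c(9.3, 9.8, 12.6, 11.9, 9.0, 14.1, 15.6, 16.6, 16.2, 11.3,
           9.6, 10.6, 13.2, 13.9))
  if (scale == "full") {
    pos[, "wH"] <- -0.5 + 2.0 * pos[, "wH"]
    pos[, "wC"] <- 2 * (pos[, "wC"] - 13) + 14
  }
  r2h <- c(18, 30, 24, 45, 20, 36, 28, 22, 40, 26, 33, 21, 29, 25)
  r2mq <- c(10, 22, 15, 30, 12, 25, 18, 14, 28, 16, 23, 13, 19, 17)
  i0 <- c(1.0, 0.85, 0.9, 0.6, 0.95, 0.7, 0.8, 0.9, 0.65, 0.75,
          0.7, 0.85, 0.8, 0.9)
  j <- c(125, 124, 126, 125, 123, 127, 125, 124, 126, 125, 125, 124, 126,
         125)
  lapply(seq_len(14), function(k) {
    spin_system(wH = pos[k, "wH"], wC = pos[k, "wC"], j_hc = j[k],
                r2_h = r2h[k], r2_mq = r2mq[k], r2_aph = r2h[k] + 5,
                i0 = i0[k])
  })
}

#' Synthetic 60-methyl spin list (medium-protein benchmark)
#'
#' Sixty ILV-like methyl spin systems generated deterministically from a
#' fixed seed, with several crowded regions.  Synthetic stand-in, not an
#' experimental shift list.
#'
#' @param scale As in [ff_like_spins()].
#' @return List of 60 [spin_system()]s.
#' @export
t4l_like_spins <- function(scale = c("reduced", "full")) {
  scale <- match.arg(scale)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(60604)
  if (scale == "reduced") {
    wH <- stats::runif(60, -0.1, 1.0)
    wC <- stats::runif(60, 9, 17)
  } else {
    wH <- stats::runif(60, -0.6, 1.5)
    wC <- stats::runif(60, 0, 26)
  }
  lapply(seq_len(60), function(k) {
    spin_system(wH = wH[k], wC = wC[k],
                j_hc = stats::runif(1, 123, 127),
                r2_h = stats::runif(1, 15, 50),
                r2_mq = stats::runif(1, 8, 40),
                r2_aph = stats::runif(1, 20, 60),
                i0 = stats::runif(1, 0.5, 1))
  })
}

#' Reduced-scale acquisition scheme for the benchmark fixtures
#'
#' The 128 x 48 analogue of the full design: 2.5 ppm 1H sweep, 12 ppm
#' 13C offset span, B1 = 220/110 Hz, 64 ms acquisition.
#'
#' @param ... Overrides passed to [acquisition_scheme()].
#' @return An [acquisition_scheme()].
#' @export
reduced_scheme <- function(...) {
  acquisition_scheme(sw_h = 2.5, n_zf = 128,
                     offsets_c = seq(7, 19, length.out = 48), ...)
}
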