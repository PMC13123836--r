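#' Monte-Carlo dropout configuration
#'
#' @param n_passes Number of stochastic forward passes (default 20).
#' @param sigma_factor Calibration factor relating the ensemble SD to the
#'   reconstruction uncertainty, sigma_recon = sigma_factor x SD (default
#'   1.4).
#' @param dropout_rate Dropout probability during the passes (default: the
#'   model's training rate).
#' @param seed Seed for the dropout masks.
#' @return Object of class `mc_config`.
#' @export
mc_config <- function(n_passes = 20, sigma_factor = 1.4, dropout_rate = NULL,
                      seed = 1) {
  stopifnot(n_passes >= 2, sigma_factor > 0)
  structure(list(n_passes = as.integer(n_passes),
                 sigma_factor = sigma_factor, dropout_rate = dropout_rate,
                 seed = as.integer(seed)),
            class = "mc_config")
}

#' Reconstruct a correlation map with MC-dropout uncertainties
#'
#' Runs `n_passes` stochastic forward passes with dropout active in all but
#' the last hidden layer; the reconstruction is the point-wise mean of the
#' passes and the uncertainty map is `sigma_factor` times the point-wise SD.
#' The raw per-pass maps are retained (in `meta$passes`) for downstream
#' intensity-error propagation.  Inputs must already be normalized to a
#' global maximum of 1; silent rescaling is forbidden because the
#' normalization scale carries quantitative meaning.
#'
#' @param model A trained `offres_model`.
#' @param input A normalized `offres_dataset`.
#' @param cfg An [mc_config()].
#' @return A [correlation_map()] with `sigma`; per-pass maps in
#'   `meta$passes` (array `(n_h, n_offsets, n_passes)`).
#' @export
mc_reconstruct <- function(model, input, cfg = mc_config()) {
  stopifnot(inherits(model, "offres_model"), inherits(cfg, "mc_config"))
  x <- if (inherits(input, "offres_dataset")) {
    if (!isTRUE(input$normalized)) {
      stop("mc_reconstruct: input stack is not normalized (max != 1); ",
           "normalize explicitly before reconstruction", call. = FALSE)
    }
    input$data
  } else input
  stopifnot(length(dim(x)) == 3L)
  rate <- cfg$dropout_rate %||% model$arch$dropout_rate
  passes <- cnn_predict_cpp(x, model$weights, model$arch$kernels,
                            model$arch$skips, rate, cfg$n_passes,
                            rate > 0, cfg$seed)
  m <- apply(passes, c(1, 2), mean)
  s <- if (cfg$n_passes > 1 && rate > 0) {
    cfg$sigma_factor * apply(passes, c(1, 2), stats::sd)
  } else {
    matrix(0, dim(x)[1], dim(x)[2])
  }
  ax <- axes_of(input, dim(x))
  correlation_map(m, ax$h, ax$c, sigma = s,
                  meta = list(source = "mc_dropout", passes = passes,
                              n_passes = cfg$n_passes,
                              sigma_factor = cfg$sigma_factor,
                              dropout_rate = rate, seed = cfg$seed))
}
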