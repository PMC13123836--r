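#' Architecture of the map-to-map convolutional network
#'
#' Seven hidden convolutional layers plus the 1-channel output convolution,
#' with additive skip connections between mirror layers of equal width, ReLU
#' activations on hidden layers and a linear output.  Inputs are two-channel
#' difference off-resonance stacks `(n_h, n_offsets, 2)`, outputs are
#' correlation maps of the same spatial shape.  The default full-scale
#' topology (9 x 9 kernels, widths 2-64-96-128-128-96-64-1) lands at ~4.3
#' million trainable weights; the exact layer sizes are configurable and the
#' weight count is reported at build time.
#'
#' @param widths Hidden-layer channel widths (the output layer always has 1
#'   channel).
#' @param kernels Square kernel size per layer (length `length(widths) + 1`),
#'   or a single value recycled.
#' @param dropout_rate Dropout probability applied after every hidden layer
#'   except the last hidden layer (default 0.30).
#' @param l2 L2 regularization coefficient (default 1e-6).
#' @return Object of class `arch_config` including the derived `skips`
#'   (0-based source layer of each additive skip, -1 for none), the total
#'   `n_weights` and the `receptive_field` (pixels per axis).
#' @export
arch_config <- function(widths = c(64, 96, 128, 128, 96, 64),
                        kernels = 9, dropout_rate = 0.30, l2 = 1e-6) {
  n_layer <- length(widths) + 1L
  if (length(kernels) == 1L) kernels <- rep(kernels, n_layer)
  stopifnot(length(kernels) == n_layer, all(kernels %% 2 == 1),
            dropout_rate >= 0, dropout_rate < 1)
  ch <- c(2L, as.integer(widths), 1L)  # channels entering/leaving each layer
  # additive skips: mirror pairs among hidden layers with equal width
  skips <- rep(-1L, n_layer)
  nh <- length(widths)
  for (l in seq_len(nh)) {
    m <- nh + 1L - l
    if (m > l && widths[m] == widths[l]) skips[m] <- l - 1L
  }
  n_w <- sum(kernels^2 * ch[-length(ch)] * ch[-1]) + sum(ch[-1])
  structure(list(widths = as.integer(widths), kernels = as.integer(kernels),
                 dropout_rate = dropout_rate, l2 = l2, skips = skips,
                 n_weights = n_w,
                 receptive_field = 1L + sum(kernels - 1L)),
            class = "arch_config")
}

#' Reduced-scale architecture
#'
#' The small architecture used by the package's end-to-end benchmark on the
#' 128 x 48 grid: 5 x 5 kernels, widths 12-16-20-20-16-12 (~37k weights).
#' @param ... Overrides passed to [arch_config()].
#' @return An `arch_config`.
#' @export
reduced_arch_config <- function(...) {
  arch_config(widths = c(12, 16, 20, 20, 16, 12), kernels = 5, ...)
}

#' @export
print.arch_config <- function(x, ...) {
  cat(sprintf("<arch_config> %d conv layers, widths 2-%s-1, kernels %s\n",
              length(x$kernels), paste(x$widths, collapse = "-"),
              paste(unique(x$kernels), collapse = "/")))
  cat(sprintf("  %s trainable weights; receptive field %d px; dropout %.2f; l2 %g\n",
              format(x$n_weights, big.mark = ","), x$receptive_field,
              x$dropout_rate, x$l2))
  invisible(x)
}

#' Build (initialize) a network model
#'
#' He-normal weight initialization, zero biases.  If a `scheme` is supplied,
#' the receptive field along the 13C axis is checked against the widest
#' expected X-arm (~4 B1max of decoupler offset) and a warning is emitted if
#' the network cannot span it.
#'
#' @param arch An [arch_config()].
#' @param seed Integer seed for the weight draw.
#' @param scheme Optional [acquisition_scheme()] for the receptive-field
#'   check.
#' @return Object of class `offres_model`.
#' @export
build_model <- function(arch, seed = 1, scheme = NULL) {
  stopifnot(inherits(arch, "arch_config"))
  ch <- c(2L, arch$widths, 1L)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  weights <- lapply(seq_along(arch$kernels), function(l) {
    fan_in <- arch$kernels[l]^2 * ch[l]
    list(W = matrix(stats::rnorm(ch[l + 1] * fan_in, 0, sqrt(2 / fan_in)),
                    ch[l + 1], fan_in),
         b = rep(0, ch[l + 1]))
  })
  if (!is.null(scheme)) {
    hz_per_px <- abs(diff(range(scheme$offsets_c))) * scheme$f_h *
      scheme$gamma_ratio / (length(scheme$offsets_c) - 1)
    arm_px <- 4 * max(scheme$b1_list) / hz_per_px
    if (arch$receptive_field < arm_px) {
      warning(sprintf(
        "receptive field (%d px) is smaller than the widest expected X-arm (~%.0f px along the 13C axis)",
        arch$receptive_field, arm_px), call. = FALSE)
    }
  }
  structure(list(arch = arch, weights = weights, history = list(),
                 trained = FALSE, seed = seed, data_config_hash = NULL),
            class = "offres_model")
}

#' @export
print.offres_model <- function(x, ...) {
  cat(sprintf("<offres_model> %s weights; %s\n",
              format(x$arch$n_weights, big.mark = ","),
              if (x$trained) "trained" else "untrained"))
  if (length(x$history)) {
    h <- x$history[[length(x$history)]]
    cat(sprintf("  %d training round(s); last-round final batch MSE %.4g\n",
                length(x$history), h$loss[length(h$loss)]))
  }
  invisible(x)
}

#' Training configuration
#'
#' The curriculum is a list of rounds; each round draws fresh synthetic
#' examples with its own `n_peaks_max` (non-decreasing across rounds, easy
#' to hard) and trains for `epochs` passes.  The learning rate decays by
#' `lr_decay` per round.
#'
#' @param curriculum Data frame or list of rounds with elements
#'   `n_peaks_max` and `n_examples`, and optionally a per-round `epochs`
#'   override (crowded late rounds usually warrant more passes).
#' @param epochs Passes over each round's examples (default 2).
#' @param batch_size Mini-batch size (default 8).
#' @param lr Initial Adam learning rate (default 1e-3).
#' @param lr_decay Multiplicative per-round decay (default 0.3).
#' @param seed Seed for example generation, shuffling and dropout.
#' @return Object of class `train_config`.
#' @export
train_config <- function(curriculum = list(list(n_peaks_max = 3,
                                                n_examples = 300,
                                                epochs = 2),
                                           list(n_peaks_max = 8,
                                                n_examples = 400,
                                                epochs = 3),
                                           list(n_peaks_max = 16,
                                                n_examples = 800,
                                                epochs = 4)),
                         epochs = 2, batch_size = 4, lr = 1e-3,
                         lr_decay = 0.6, seed = 1) {
  np <- vapply(curriculum, function(r) r$n_peaks_max, numeric(1))
  if (is.unsorted(np)) {
    stop("train_config: curriculum n_peaks_max must be non-decreasing",
         call. = FALSE)
  }
  structure(list(curriculum = curriculum, epochs = epochs,
                 batch_size = batch_size, lr = lr, lr_decay = lr_decay,
                 seed = seed),
            class = "train_config")
}

#' Train the network on synthetic data
#'
#' Runs the curriculum: for each round, draws `n_examples` fresh synthetic
#' examples from `gen_cfg` with the round's `n_peaks_max` (unless `data` is
#' supplied, in which case those arrays are used for every round), and
#' minimizes the MSE against the noise-free targets with Adam, dropout and
#' L2 regularization.  Loss history is recorded per round.
#'
#' @param model An `offres_model`.
#' @param gen_cfg A [generator_config()] on the model's grid.
#' @param cfg A [train_config()].
#' @param data Optional list with `inputs` `(H, W, 2, N)` and `targets`
#'   `(H, W, N)` (e.g. from [read_shards()] or [examples_to_arrays()]).
#' @param verbose Print per-round progress.
#' @return The trained `offres_model` (weights, history, Adam state).
#' @export
train_model <- function(model, gen_cfg = NULL, cfg = train_config(),
                        data = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "offres_model"), inherits(cfg, "train_config"))
  arch <- model$arch
  adam <- model$adam %||% list()
  lr <- cfg$lr
  gen_seed <- cfg$seed
  for (r in seq_along(cfg$curriculum)) {
    round <- cfg$curriculum[[r]]
    if (is.null(data)) {
      stopifnot(inherits(gen_cfg, "generator_config"))
      gcfg <- gen_cfg
      gcfg$n_peaks_max <- as.integer(round$n_peaks_max)
      exs <- generate_examples(gcfg, round$n_examples, seed = gen_seed)
      gen_seed <- gen_seed + round$n_examples
      arr <- examples_to_arrays(exs)
    } else {
      arr <- data
    }
    epochs <- round$epochs %||% cfg$epochs
    fit <- cnn_train_cpp(arr$inputs, arr$targets, model$weights,
                         arch$kernels, arch$skips, arch$dropout_rate,
                         arch$l2, lr, as.integer(epochs),
                         as.integer(cfg$batch_size),
                         as.integer(cfg$seed + r), adam)
    model$weights <- lapply(fit$weights,
                            function(w) list(W = w$W, b = drop(w$b)))
    adam <- fit$adam
    model$history[[r]] <- list(n_peaks_max = round$n_peaks_max,
                               n_examples = if (is.null(data))
                                 round$n_examples else dim(arr$targets)[3],
                               lr = lr, loss = fit$loss)
    if (verbose) {
      message(sprintf(
        "round %d (n_peaks_max %d): batch MSE %.4g -> %.4g", r,
        round$n_peaks_max, fit$loss[1], fit$loss[length(fit$loss)]))
    }
    lr <- lr * cfg$lr_decay
  }
  model$adam <- adam
  model$trained <- TRUE
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deterministic forward pass
#'
#' @param model An `offres_model`.
#' @param input An `offres_dataset` (or bare `(H, W, 2)` array).
#' @return A [correlation_map()] (dropout disabled, deterministic).
#' @export
predict_map <- function(model, input) {
  x <- if (inherits(input, "offres_dataset")) input$data else input
  stopifnot(length(dim(x)) == 3L)
  y <- cnn_predict_cpp(x, model$weights, model$arch$kernels,
                       model$arch$skips, 0, 1L, FALSE, 0L)[, , 1]
  ax <- axes_of(input, dim(x))
  correlation_map(y, ax$h, ax$c, meta = list(source = "dnn"))
}

axes_of <- function(input, d) {
  if (inherits(input, "offres_dataset")) {
    list(h = input$axis_ppm_h, c = input$axis_ppm_c)
  } else {
    list(h = seq_len(d[1]), c = seq_len(d[2]))
  }
}

#' Mean squared reconstruction error over a validation set
#'
#' @param model An `offres_model`.
#' @param inputs `(H, W, 2, N)` array.
#' @param targets `(H, W, N)` array.
#' @return List with `mse` (mean over the set) and `per_example` vector.
#' @export
evaluate_mse <- function(model, inputs, targets) {
  stopifnot(length(dim(inputs)) == 4L, length(dim(targets)) == 3L,
            dim(inputs)[4] == dim(targets)[3])
  per <- cnn_mse_cpp(inputs, targets, model$weights, model$arch$kernels,
                     model$arch$skips)
  list(mse = mean(per), per_example = as.numeric(per))
}

#' Save a model checkpoint
#'
#' Self-describing text+binary container: a JSON header (architecture,
#' training history, seeds) and a raw little-endian double file with all
#' weights concatenated; round-trips losslessly.
#'
#' @param model An `offres_model`.
#' @param path File stem; writes `<path>.json` and `<path>.bin`.
#' @return Invisibly, `path`.
#' @export
save_model <- function(model, path) {
  vals <- unlist(lapply(model$weights, function(w) c(as.vector(w$W), w$b)))
  bin <- paste0(path, ".bin")
  con <- file(bin, "wb")
  writeBin(vals, con, size = 8, endian = "little")
  close(con)
  hdr <- list(widths = model$arch$widths, kernels = model$arch$kernels,
              dropout_rate = model$arch$dropout_rate, l2 = model$arch$l2,
              skips = model$arch$skips, trained = model$trained,
              seed = model$seed,
              history = lapply(model$history, function(h) {
                list(n_peaks_max = h$n_peaks_max, n_examples = h$n_examples,
                     lr = h$lr, loss = h$loss)
              }),
              md5 = unname(tools::md5sum(bin)))
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load a model checkpoint written by [save_model()]
#'
#' @param path File stem used at save time.
#' @return An `offres_model`.
#' @export
load_model <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  bin <- paste0(path, ".bin")
  if (!identical(unname(tools::md5sum(bin)), hdr$md5)) {
    stop("load_model: md5 mismatch (corrupt checkpoint)", call. = FALSE)
  }
  arch <- arch_config(widths = hdr$widths, kernels = hdr$kernels,
                      dropout_rate = hdr$dropout_rate, l2 = hdr$l2)
  ch <- c(2L, arch$widths, 1L)
  con <- file(bin, "rb")
  vals <- readBin(con, "double", arch$n_weights, size = 8, endian = "little")
  close(con)
  at <- 0
  weights <- lapply(seq_along(arch$kernels), function(l) {
    fan_in <- arch$kernels[l]^2 * ch[l]
    nw <- ch[l + 1] * fan_in
    W <- matrix(vals[at + seq_len(nw)], ch[l + 1], fan_in)
    b <- vals[at + nw + seq_len(ch[l + 1])]
    at <<- at + nw + ch[l + 1]
    list(W = W, b = b)
  })
  hist <- if (is.data.frame(hdr$history)) {
    lapply(seq_len(nrow(hdr$history)), function(i) as.list(hdr$history[i, ]))
  } else hdr$history
  structure(list(arch = arch, weights = weights, history = hist,
                 trained = isTRUE(hdr$trained), seed = hdr$seed,
                 data_config_hash = NULL),
            class = "offres_model")
}
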