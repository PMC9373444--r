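#' Network configuration
#'
#' Defaults are the tuned architecture: 256 width-12 first-layer kernels
#' (valid padding, stride 1), 128 width-30 second-layer kernels (same
#' padding, stride 2), max-pooling of size 5 / stride 5, dropout 0.7 after
#' each convolution and after pooling, batch normalization after the
#' branch concatenation, RMSProp with batch size 1024, at most 100 epochs
#' and early-stopping patience 20.
#'
#' @param conv1_kernels,conv1_size First convolution: number and width of
#'   kernels (valid padding, stride 1).
#' @param conv2_kernels,conv2_size,conv2_stride Second convolution: number,
#'   width and stride of kernels (same padding).
#' @param pool_size,pool_stride Temporal max-pooling window and stride.
#' @param dropout1,dropout2 Drop probabilities in `[0, 1)`; `dropout2` is
#'   also used for the post-pooling dropout and for the dropout layer that
#'   replaces batch normalization in the `bn_to_dropout` ablation.
#' @param batchnorm Keep the batch-normalization layer after concatenation?
#' @param bn_as_dropout Replace batch normalization by a dropout layer
#'   (the `BN -> Dropout` ablation variant); requires `batchnorm = FALSE`.
#' @param learning_rate RMSProp learning rate.
#' @param batch_size Minibatch size.
#' @param max_epochs Hard epoch cap.
#' @param early_stopping_patience Epochs without validation-loss
#'   improvement tolerated before stopping (best weights are restored).
#' @param validation_fraction Fraction of the training set carved off as
#'   the internal validation split when none is supplied.
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout.
#' @return A `backsplicer_config` object (a validated list).
#' @export
model_config <- function(conv1_kernels = 256L, conv1_size = 12L,
                         conv2_kernels = 128L, conv2_size = 30L,
                         conv2_stride = 2L,
                         pool_size = 5L, pool_stride = 5L,
                         dropout1 = 0.7, dropout2 = 0.7,
                         batchnorm = TRUE, bn_as_dropout = FALSE,
                         learning_rate = 1e-3, batch_size = 1024L,
                         max_epochs = 100L, early_stopping_patience = 20L,
                         validation_fraction = 0.1, seed = 1L) {
  cfg <- list(
    conv1_kernels = as.integer(conv1_kernels), conv1_size = as.integer(conv1_size),
    conv1_padding = "valid", conv1_stride = 1L,
    conv2_kernels = as.integer(conv2_kernels), conv2_size = as.integer(conv2_size),
    conv2_padding = "same", conv2_stride = as.integer(conv2_stride),
    pool_size = as.integer(pool_size), pool_stride = as.integer(pool_stride),
    dropout1 = dropout1, dropout2 = dropout2,
    batchnorm = isTRUE(batchnorm), bn_as_dropout = isTRUE(bn_as_dropout),
    optimizer = "rmsprop", learning_rate = learning_rate,
    batch_size = as.integer(batch_size), max_epochs = as.integer(max_epochs),
    early_stopping_patience = as.integer(early_stopping_patience),
    validation_fraction = validation_fraction, seed = as.integer(seed)
  )
  with(cfg, {
    stopifnot(
      conv1_kernels >= 1L, conv1_size >= 1L, conv2_kernels >= 1L,
      conv2_size >= 1L, conv2_stride >= 1L, pool_size >= 1L, pool_stride >= 1L,
      dropout1 >= 0, dropout1 < 1, dropout2 >= 0, dropout2 < 1,
      learning_rate > 0, batch_size >= 1L, max_epochs >= 1L,
      early_stopping_patience >= 0L,
      validation_fraction > 0, validation_fraction < 1
    )
  })
  if (cfg$batchnorm && cfg$bn_as_dropout) {
    bs_abort("bn_as_dropout requires batchnorm = FALSE.", "architecture_infeasible")
  }
  structure(cfg, class = "backsplicer_config")
}

## 'same' padding for a strided convolution, TensorFlow convention:
## out = ceil(L / s), pad_left = floor(total_pad / 2)
same_pad <- function(L, w, s) {
  out <- ceiling(L / s)
  total <- max((out - 1L) * s + w - L, 0L)
  list(out = as.integer(out), left = as.integer(total %/% 2L),
       right = as.integer(total - total %/% 2L))
}

#' Layer-by-layer output shapes of the network
#'
#' Computes, symbolically, the output shape of every layer for a given
#' configuration: per branch, input `(100, 4)`; valid conv1
#' `(100 - conv1_size + 1, conv1_kernels)`; same-padded strided conv2
#' `(ceil(prev / stride), conv2_kernels)`; max-pooling
#' `(floor((prev - pool_size) / pool_stride) + 1, conv2_kernels)`;
#' flatten; then the concatenation of the two branches and the output
#' layer.  With the default configuration this reproduces the published
#' layer table (89, 45, 9, 1152, 2304).
#'
#' @param cfg A [model_config()].
#' @return A tibble with columns `layer`, `d1`, `d2` (`d2` is `NA` for
#'   flat layers); per-branch rows describe one branch (both are
#'   identical).
#' @export
shape_contract <- function(cfg = model_config()) {
  stopifnot(inherits(cfg, "backsplicer_config"))
  p1 <- WINDOW_LEN - cfg$conv1_size + 1L
  if (p1 < 1L) bs_abort("conv1 output length would be < 1.", "architecture_infeasible")
  p2 <- same_pad(p1, cfg$conv2_size, cfg$conv2_stride)$out
  p3 <- (p2 - cfg$pool_size) %/% cfg$pool_stride + 1L
  if (p3 < 1L) bs_abort("pooled output length would be < 1.", "architecture_infeasible")
  flat <- p3 * cfg$conv2_kernels
  rows <- list(
    c("input", WINDOW_LEN, 4L),
    c("conv1", p1, cfg$conv1_kernels),
    c("dropout1", p1, cfg$conv1_kernels),
    c("conv2", p2, cfg$conv2_kernels),
    c("dropout2", p2, cfg$conv2_kernels),
    c("maxpool", p3, cfg$conv2_kernels),
    c("dropout3", p3, cfg$conv2_kernels),
    c("flatten", flat, NA),
    c("concatenate", 2L * flat, NA)
  )
  if (cfg$batchnorm) rows <- c(rows, list(c("batchnorm", 2L * flat, NA)))
  if (cfg$bn_as_dropout) rows <- c(rows, list(c("dropout_bn", 2L * flat, NA)))
  rows <- c(rows, list(c("dense", 1L, NA)))
  tibble(
    layer = vapply(rows, `[`, "", 1L),
    d1 = as.integer(vapply(rows, `[`, "", 2L)),
    d2 = suppressWarnings(as.integer(vapply(rows, `[`, "", 3L)))
  )
}
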