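#' Build an untrained dual-branch network
#'
#' Two convolutional branches with unshared weights read the SA and SD
#' windows respectively (per branch: conv1 -> dropout -> conv2 -> dropout
#' -> max-pool -> dropout -> flatten); their flattened features are
#' concatenated, batch-normalized (unless ablated) and fed to a single
#' sigmoid output unit.  Initialization is Glorot-uniform and fully
#' determined by `cfg$seed`.
#'
#' @param cfg A [model_config()].
#' @return An object of class `backsplicer_model`.
#' @export
build_model <- function(cfg = model_config()) {
  stopifnot(inherits(cfg, "backsplicer_config"))
  shape_contract(cfg)  # errors if the architecture is infeasible
  geom <- branch_geometry(cfg)
  k1 <- cfg$conv1_kernels; k2 <- cfg$conv2_kernels
  in1 <- cfg$conv1_size * 4L
  in2 <- cfg$conv2_size * k1
  nf <- 2L * geom$flat
  par <- withr::with_seed(cfg$seed, {
    p <- list()
    for (br in c("sa", "sd")) {
      p[[paste0("W1_", br)]] <- glorot(in1, k1, in1, cfg$conv1_size * k1)
      p[[paste0("b1_", br)]] <- numeric(k1)
      p[[paste0("W2_", br)]] <- glorot(in2, k2, in2, cfg$conv2_size * k2)
      p[[paste0("b2_", br)]] <- numeric(k2)
    }
    p$Wd <- glorot(nf, 1L, nf, 1L)
    p$bd <- 0
    if (cfg$batchnorm) {
      p$gamma <- rep(1, nf)
      p$beta <- numeric(nf)
    }
    p
  })
  structure(
    list(config = cfg, par = par,
         bn = if (cfg$batchnorm) list(rmean = numeric(nf), rvar = rep(1, nf)),
         geom = geom, trained = FALSE, history = NULL,
         best_epoch = NA_integer_, stopped_epoch = NA_integer_,
         best_hash = NA_character_),
    class = "backsplicer_model"
  )
}

branch_par <- function(par, br) {
  list(W1 = par[[paste0("W1_", br)]], b1 = par[[paste0("b1_", br)]],
       W2 = par[[paste0("W2_", br)]], b2 = par[[paste0("b2_", br)]])
}

model_forward <- function(model, Asa, Asd, train = FALSE, keep = FALSE) {
  cfg <- model$config; geom <- model$geom
  fsa <- branch_forward(branch_par(model$par, "sa"), Asa, cfg, geom, train, keep)
  fsd <- branch_forward(branch_par(model$par, "sd"), Asd, cfg, geom, train, keep)
  H <- cbind(fsa$H, fsd$H)
  bn_cache <- NULL; Mbn <- NULL
  if (cfg$batchnorm) {
    if (train) {
      bn_cache <- bn_fwd_train(H, model$par$gamma, model$par$beta)
      Hb <- bn_cache$out
    } else {
      Hb <- bn_fwd_infer(H, model$par$gamma, model$par$beta,
                         model$bn$rmean, model$bn$rvar)
    }
  } else if (cfg$bn_as_dropout && train) {
    Mbn <- dropout_mask(length(H), cfg$dropout2)
    Hb <- apply_mask(H, Mbn)
  } else {
    Hb <- H
  }
  z <- Hb %*% model$par$Wd + model$par$bd
  prob <- as.vector(stats::plogis(z))
  out <- list(prob = prob)
  if (keep) {
    out$cache <- list(sa = fsa$cache, sd = fsd$cache, H = H, Hb = Hb,
                      bn = bn_cache, Mbn = Mbn)
  }
  out
}

model_backward <- function(model, fw, y) {
  cfg <- model$config; geom <- model$geom
  cache <- fw$cache
  B <- length(y)
  dz <- matrix((fw$prob - y) / B, ncol = 1L)
  grads <- list(
    Wd = crossprod(cache$Hb, dz),
    bd = sum(dz)
  )
  dHb <- tcrossprod(dz, model$par$Wd)
  if (cfg$batchnorm) {
    bb <- bn_bwd(dHb, cache$bn, model$par$gamma)
    grads$gamma <- bb$dgamma
    grads$beta <- bb$dbeta
    dH <- bb$dH
  } else {
    dH <- apply_mask(dHb, cache$Mbn)
  }
  half <- geom$flat
  for (br in c("sa", "sd")) {
    cols <- if (br == "sa") seq_len(half) else half + seq_len(half)
    g <- branch_backward(branch_par(model$par, br), dH[, cols, drop = FALSE],
                         cfg, geom, cache[[br]])
    grads[[paste0("W1_", br)]] <- g$W1
    grads[[paste0("b1_", br)]] <- g$b1
    grads[[paste0("W2_", br)]] <- g$W2
    grads[[paste0("b2_", br)]] <- g$b2
  }
  grads
}

bce_loss <- function(y, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

encode_pair_batch <- function(pairs) {
  list(sa = encode_batch(pairs$sa_seq), sd = encode_batch(pairs$sd_seq))
}

check_windows <- function(pairs) {
  pairs <- as_tibble(pairs)
  pairs$sa_seq <- canonicalize(pairs$sa_seq)
  pairs$sd_seq <- canonicalize(pairs$sd_seq)
  bad <- nchar(pairs$sa_seq) != WINDOW_LEN | nchar(pairs$sd_seq) != WINDOW_LEN
  if (any(bad)) {
    bs_abort(sprintf("Record %d: windows must be exactly %d nt.",
                     which(bad)[1L], WINDOW_LEN), "length_mismatch")
  }
  pairs
}

infer_chunk_size <- function(model) {
  cfg <- model$config; geom <- model$geom
  max(1L, min(1024L,
              floor(2.5e7 / (geom$P2 * cfg$conv2_size * cfg$conv1_kernels))))
}

predict_encoded <- function(model, Asa, Asd) {
  n <- dim(Asa)[3L]
  chunk <- infer_chunk_size(model)
  out <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    out[s:e] <- model_forward(model,
                              Asa[, , s:e, drop = FALSE],
                              Asd[, , s:e, drop = FALSE])$prob
  }
  out
}

#' Predict back-splicing probabilities
#'
#' Runs the network in inference mode (dropout off, batch normalization on
#' its running statistics), so predictions are deterministic and invariant
#' to how the input is batched.
#'
#' @param object A trained `backsplicer_model`.
#' @param pairs Tibble with `sa_seq` and `sd_seq` (100-nt windows).
#' @param ... Unused.
#' @return Numeric vector of probabilities in `[0, 1]`, named by `id` when
#'   present.
#' @export
predict.backsplicer_model <- function(object, pairs, ...) {
  pairs <- check_windows(pairs)
  enc <- encode_pair_batch(pairs)
  p <- predict_encoded(object, enc$sa, enc$sd)
  if ("id" %in% names(pairs)) names(p) <- pairs$id
  p
}

#' Train the network
#'
#' Minimizes binary cross-entropy with RMSProp.  Training stops when the
#' validation loss has not improved for `early_stopping_patience`
#' consecutive epochs (with `patience = 0`, after the first non-improving
#' epoch) or at `max_epochs`, whichever comes first, and the weights of
#' the best validation epoch are restored.  If no validation set is given,
#' a stratified `validation_fraction` split is carved from the training
#' data.  All randomness (shuffling, dropout, the internal split) is
#' driven by the configuration seed, so a rerun reproduces the fit
#' exactly.
#'
#' @param model A `backsplicer_model` from [build_model()], or a
#'   [model_config()] (a fresh model is built first).
#' @param train_pairs Tibble with `id`, `sa_seq`, `sd_seq`, `label`; both
#'   classes must be present.
#' @param val_pairs Optional validation tibble of the same shape.
#' @param verbose Print per-epoch progress?
#' @return The trained model, carrying `history` (per-epoch losses and
#'   accuracies), `best_epoch`, `stopped_epoch` and `best_hash` (hash of
#'   the restored parameter state).
#' @export
train_model <- function(model, train_pairs, val_pairs = NULL, verbose = FALSE) {
  if (inherits(model, "backsplicer_config")) model <- build_model(model)
  stopifnot(inherits(model, "backsplicer_model"))
  cfg <- model$config
  train_pairs <- check_windows(train_pairs)
  if (length(unique(train_pairs$label)) < 2L) {
    bs_abort("Training data contains a single class.", "degenerate_labels")
  }
  withr::with_seed(cfg$seed, {
    if (is.null(val_pairs)) {
      n <- nrow(train_pairs)
      val_idx <- unlist(lapply(split(seq_len(n), train_pairs$label), function(ix) {
        nv <- max(1L, round(length(ix) * cfg$validation_fraction))
        nv <- min(nv, length(ix) - 1L)
        sample(ix, nv)
      }), use.names = FALSE)
      val_pairs <- train_pairs[val_idx, , drop = FALSE]
      train_pairs <- train_pairs[-val_idx, , drop = FALSE]
    } else {
      val_pairs <- check_windows(val_pairs)
    }
    tr <- encode_pair_batch(train_pairs)
    va <- encode_pair_batch(val_pairs)
    y <- as.numeric(train_pairs$label)
    yv <- as.numeric(val_pairs$label)
    n <- length(y)

    opt_state <- lapply(model$par, function(p) p * 0)
    best <- list(loss = Inf, par = NULL, bn = NULL, epoch = NA_integer_)
    wait <- 0L
    hist <- list()
    stop_at <- cfg$max_epochs

    for (epoch in seq_len(cfg$max_epochs)) {
      idx <- sample.int(n)
      ep_loss <- 0; ep_correct <- 0
      for (s in seq(1L, n, by = cfg$batch_size)) {
        take <- idx[s:min(s + cfg$batch_size - 1L, n)]
        Asa <- tr$sa[, , take, drop = FALSE]
        Asd <- tr$sd[, , take, drop = FALSE]
        yb <- y[take]
        fw <- model_forward(model, Asa, Asd, train = TRUE, keep = TRUE)
        ep_loss <- ep_loss + bce_loss(yb, fw$prob) * length(take)
        ep_correct <- ep_correct + sum((fw$prob >= 0.5) == (yb == 1))
        grads <- model_backward(model, fw, yb)
        upd <- rmsprop_step(model$par, grads, opt_state,
                            lr = cfg$learning_rate)
        model$par <- upd$par
        opt_state <- upd$state
        if (cfg$batchnorm) {
          model$bn$rmean <- BN_MOMENTUM * model$bn$rmean +
            (1 - BN_MOMENTUM) * fw$cache$bn$mu
          model$bn$rvar <- BN_MOMENTUM * model$bn$rvar +
            (1 - BN_MOMENTUM) * fw$cache$bn$var
        }
      }
      pv <- predict_encoded(model, va$sa, va$sd)
      val_loss <- bce_loss(yv, pv)
      hist[[epoch]] <- tibble(
        epoch = epoch, train_loss = ep_loss / n, train_acc = ep_correct / n,
        val_loss = val_loss, val_acc = mean((pv >= 0.5) == (yv == 1))
      )
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  acc %.3f  val_loss %.4f  val_acc %.3f",
                        epoch, ep_loss / n, ep_correct / n, val_loss,
                        mean((pv >= 0.5) == (yv == 1))))
      }
      if (val_loss < best$loss) {
        best <- list(loss = val_loss, par = model$par, bn = model$bn,
                     epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= max(cfg$early_stopping_patience, 1L)) {
          stop_at <- epoch
          break
        }
      }
    }
  })
  model$par <- best$par
  model$bn <- best$bn
  model$history <- dplyr::bind_rows(hist)
  model$best_epoch <- best$epoch
  model$stopped_epoch <- min(stop_at, nrow(model$history))
  model$best_hash <- rlang::hash(list(best$par, best$bn))
  model$trained <- TRUE
  model
}

#' First-convolution-layer activation scores
#'
#' Runs one branch's first convolution (post-ReLU) over a set of windows,
#' yielding for each sequence a `(100 - conv1_size + 1) x conv1_kernels`
#' matrix of candidate-motif scores — the raw material of the motif
#' interpretation pipeline.
#'
#' @param model A trained `backsplicer_model`.
#' @param pairs Tibble with `id`, `sa_seq`, `sd_seq` (and `label` if
#'   present, which is carried along).
#' @param branch `"SA"` or `"SD"`.
#' @return A `backsplicer_cmem` object: list with `scores` (array
#'   `positions x filters x sequences`), `ids`, `labels`, `seqs`, `branch`
#'   and `width` (the kernel width).
#' @export
first_layer_activations <- function(model, pairs, branch = c("SA", "SD")) {
  branch <- match.arg(branch)
  pairs <- check_windows(pairs)
  cfg <- model$config
  seqs <- if (branch == "SA") pairs$sa_seq else pairs$sd_seq
  par <- branch_par(model$par, tolower(branch))
  n <- length(seqs)
  P1 <- model$geom$P1
  scores <- array(0, dim = c(P1, cfg$conv1_kernels, n))
  chunk <- max(1L, floor(5e6 / (P1 * cfg$conv1_kernels)))
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    A <- encode_batch(seqs[s:e])
    X1 <- im2col(A, cfg$conv1_size)
    A1 <- relu(sweep(X1 %*% par$W1, 2L, par$b1, "+"))
    scores[, , s:e] <- array(A1, dim = c(P1, e - s + 1L, cfg$conv1_kernels)) |>
      aperm(c(1L, 3L, 2L))
  }
  structure(
    list(scores = scores, ids = pairs$id,
         labels = if ("label" %in% names(pairs)) as.integer(pairs$label),
         seqs = seqs, branch = branch, width = cfg$conv1_size),
    class = "backsplicer_cmem"
  )
}

#' Observed layer shapes from an actual forward pass
#'
#' Feeds a batch through the network and reports the dimensionality of
#' every layer's real output tensor, in the same format as
#' [shape_contract()] — the two must agree for any valid configuration.
#'
#' @param model A `backsplicer_model`.
#' @param pairs Tibble of windows to feed (a couple of rows suffice).
#' @return A tibble `layer, d1, d2`.
#' @export
observed_shapes <- function(model, pairs) {
  pairs <- check_windows(pairs)
  enc <- encode_pair_batch(pairs)
  B <- dim(enc$sa)[3L]
  fw <- model_forward(model, enc$sa, enc$sd, train = FALSE, keep = TRUE)
  ca <- fw$cache$sa
  cfg <- model$config
  p1 <- nrow(ca$A1) %/% B
  p2 <- nrow(ca$A2) %/% B
  p3 <- nrow(ca$argmax_row) %/% B
  flat <- ncol(fw$cache$H) %/% 2L
  rows <- list(
    c("input", dim(enc$sa)[1L], dim(enc$sa)[2L]),
    c("conv1", p1, ncol(ca$A1)),
    c("dropout1", p1, ncol(ca$A1)),
    c("conv2", p2, ncol(ca$A2)),
    c("dropout2", p2, ncol(ca$A2)),
    c("maxpool", p3, ncol(ca$argmax_row)),
    c("dropout3", p3, ncol(ca$argmax_row)),
    c("flatten", flat, NA),
    c("concatenate", ncol(fw$cache$H), NA)
  )
  if (cfg$batchnorm) rows <- c(rows, list(c("batchnorm", ncol(fw$cache$Hb), NA)))
  if (cfg$bn_as_dropout) rows <- c(rows, list(c("dropout_bn", ncol(fw$cache$Hb), NA)))
  rows <- c(rows, list(c("dense", 1L, NA)))
  tibble(
    layer = vapply(rows, `[`, "", 1L),
    d1 = as.integer(vapply(rows, `[`, "", 2L)),
    d2 = suppressWarnings(as.integer(vapply(rows, `[`, "", 3L)))
  )
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single file holding the configuration, every
#' parameter array, the batch-normalization running statistics and the
#' training history, stamped with a format version.  Loading restores a
#' model whose predictions are bit-identical to the saved one.
#'
#' @param model A `backsplicer_model`.
#' @param path Checkpoint file path.
#' @return `save_model()` returns `path` invisibly; `load_model()` the
#'   restored model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "backsplicer_model"))
  saveRDS(list(format = "backsplicer_checkpoint", format_version = 1L,
               package_version = as.character(utils::packageVersion("backsplicer")),
               model = model),
          path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "backsplicer_checkpoint")) {
    bs_abort("Not a backsplicer checkpoint.", "parse_error")
  }
  x$model
}

#' @export
print.backsplicer_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<backsplicer_model> %s, conv1 %dx%d, conv2 %dx%d, %s\n",
              if (x$trained) "trained" else "untrained",
              cfg$conv1_kernels, cfg$conv1_size,
              cfg$conv2_kernels, cfg$conv2_size,
              if (cfg$batchnorm) "batchnorm" else
                if (cfg$bn_as_dropout) "bn-as-dropout" else "no batchnorm"))
  if (x$trained) {
    cat(sprintf("  epochs run %d, best epoch %d (val loss %.4f)\n",
                x$stopped_epoch, x$best_epoch,
                x$history$val_loss[x$best_epoch]))
  }
  invisible(x)
}

#' @export
tidy.backsplicer_model <- function(x, ...) {
  if (is.null(x$history)) return(tibble())
  x$history
}

#' @export
glance.backsplicer_model <- function(x, ...) {
  n_par <- sum(vapply(x$par, length, 1L))
  tibble(
    trained = x$trained, n_parameters = n_par,
    epochs_run = x$stopped_epoch %||% NA_integer_,
    best_epoch = x$best_epoch,
    best_val_loss = if (!is.null(x$history)) min(x$history$val_loss) else NA_real_
  )
}
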