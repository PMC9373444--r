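#' Stratified k-fold cross-validation of the network
#'
#' For each fold, a fresh model is trained on the other `k - 1` folds
#' (carving its internal validation split from them) and evaluated on the
#' held-out fold, so every sample is tested exactly once.  Fold
#' assignment, initialization and training are all driven by `seed`, and
#' samples are canonicalized by id before splitting, so the result does
#' not depend on input row order.
#'
#' @param pairs Tibble with `id`, `sa_seq`, `sd_seq`, `label`.
#' @param cfg A [model_config()].
#' @param k Number of folds (default 7).
#' @param seed Integer seed.
#' @param threshold Hard-call threshold passed to [compute_metrics()].
#' @param keep_best_model Keep the trained model of the fold with the
#'   highest test AUC (used downstream for motif extraction)?
#' @param folds Optional precomputed [kfold_split()] assignment, e.g. to
#'   share folds across ablation variants.
#' @param verbose Print per-fold progress?
#' @return A `backsplicer_cv` object: list with `folds` (per-fold metric
#'   tibble), `mean` and `best` (fold with highest AUC) summaries,
#'   `predictions` (`id, label, fold, prob`), `assignments`, and
#'   `best_model` if requested.
#' @export
cross_validate <- function(pairs, cfg, k = 7L, seed = 1L, threshold = 0.5,
                           keep_best_model = FALSE, folds = NULL,
                           verbose = FALSE) {
  pairs <- check_windows(pairs)
  if (is.null(folds)) folds <- kfold_split(pairs, k = k, seed = seed)
  k <- max(folds$fold)
  pairs <- dplyr::inner_join(pairs, folds[, c("id", "fold")], by = "id")
  pairs <- dplyr::arrange(pairs, .data$id)
  per_fold <- list()
  preds <- list()
  best_auc <- -Inf
  best_model <- NULL
  for (f in seq_len(k)) {
    train_set <- pairs[pairs$fold != f, , drop = FALSE]
    test_set <- pairs[pairs$fold == f, , drop = FALSE]
    fold_cfg <- cfg
    fold_cfg$seed <- cfg$seed + f
    fit <- train_model(build_model(fold_cfg), train_set, verbose = verbose)
    p <- predict(fit, test_set)
    m <- compute_metrics(test_set$label, p, threshold = threshold)
    per_fold[[f]] <- dplyr::bind_cols(tibble(fold = f), m)
    preds[[f]] <- tibble(id = test_set$id, label = test_set$label,
                         fold = f, prob = unname(p))
    if (verbose) message(sprintf("fold %d: AUC %.4f ACC %.4f", f, m$auc, m$acc))
    if (keep_best_model && isTRUE(m$auc > best_auc)) {
      best_auc <- m$auc
      best_model <- fit
    }
  }
  fold_tbl <- dplyr::bind_rows(per_fold)
  metric_cols <- c("acc", "auc", "mcc", "sensitivity", "specificity")
  structure(
    list(
      folds = fold_tbl,
      mean = dplyr::summarise(fold_tbl,
                              dplyr::across(dplyr::all_of(metric_cols), mean)),
      best = fold_tbl[which.max(fold_tbl$auc), , drop = FALSE],
      predictions = dplyr::bind_rows(preds),
      assignments = folds,
      best_model = best_model,
      k = k, seed = seed
    ),
    class = "backsplicer_cv"
  )
}

#' @export
print.backsplicer_cv <- function(x, ...) {
  cat(sprintf("<backsplicer_cv> %d folds\n", x$k))
  cat("mean: ", paste(sprintf("%s %.4f", names(x$mean), unlist(x$mean)),
                      collapse = "  "), "\n")
  invisible(x)
}

#' @export
tidy.backsplicer_cv <- function(x, ...) x$folds

#' @export
glance.backsplicer_cv <- function(x, ...) {
  dplyr::bind_cols(
    tibble(k = x$k),
    setNames(x$mean, paste0("mean_", names(x$mean))),
    setNames(x$best[, names(x$mean)], paste0("best_", names(x$mean)))
  )
}

#' Batch-normalization ablation harness
#'
#' Cross-validates the three architecture variants — the default (batch
#' normalization after concatenation), `no_bn` (the layer removed), and
#' `bn_to_dropout` (the layer replaced by dropout) — under identical fold
#' assignments, enabling a paired comparison of the five metrics.
#'
#' @inheritParams cross_validate
#' @param variants Subset of `c("default", "no_bn", "bn_to_dropout")`.
#' @return A `backsplicer_ablation` object: list with `summary` (one row
#'   per variant with the five mean metrics), `results` (named list of
#'   `backsplicer_cv`), and the shared `assignments`.
#' @export
ablation_suite <- function(pairs, cfg, variants = c("default", "no_bn",
                                                    "bn_to_dropout"),
                           k = 7L, seed = 1L, verbose = FALSE) {
  variants <- match.arg(variants, several.ok = TRUE)
  pairs <- check_windows(pairs)
  folds <- kfold_split(pairs, k = k, seed = seed)
  results <- list()
  for (v in variants) {
    vcfg <- cfg
    if (v == "no_bn") {
      vcfg$batchnorm <- FALSE
    } else if (v == "bn_to_dropout") {
      vcfg$batchnorm <- FALSE
      vcfg$bn_as_dropout <- TRUE
    }
    results[[v]] <- cross_validate(pairs, vcfg, seed = seed, folds = folds,
                                   verbose = verbose)
  }
  summary <- purrr::map_dfr(names(results), function(v)
    dplyr::bind_cols(tibble(variant = v), results[[v]]$mean))
  structure(list(summary = summary, results = results, assignments = folds),
            class = "backsplicer_ablation")
}

#' @export
print.backsplicer_ablation <- function(x, ...) {
  cat("<backsplicer_ablation>\n")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.backsplicer_ablation <- function(x, ...) x$summary
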