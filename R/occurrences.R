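#' Scan motif occurrences of one filter across a dataset
#'
#' Every window position whose first-layer activation reaches
#' `threshold_fraction` times the filter's maximum activation over the
#' scanned set becomes an occurrence.  Occurrences are recorded for
#' positive and negative samples alike so their positional distributions
#' can be contrasted.  The intron/exon side of an occurrence is decided
#' by the centre of its receptive field (`start + floor(width / 2)`)
#' relative to the splice boundary at position 50.
#'
#' @param model A trained `backsplicer_model`.
#' @param pairs Tibble with `id`, `sa_seq`, `sd_seq`, `label`.
#' @param branch `"SA"` or `"SD"`.
#' @param filter 1-based filter index.
#' @param threshold_fraction Fraction of the set-wide maximum activation
#'   required (default 0.5; 1.0 keeps only global-maximum positions).
#' @return A tibble `filter, branch, seq_id, label, start, side, score`
#'   (0-based `start`), with the kernel width in attribute `width` and
#'   per-class sequence counts in attributes `n_pos` / `n_neg`.
#' @export
scan_occurrences <- function(model, pairs, branch = c("SA", "SD"), filter,
                             threshold_fraction = 0.5) {
  branch <- match.arg(branch)
  pairs <- check_windows(pairs)
  cfg <- model$config
  if (filter < 1L || filter > cfg$conv1_kernels) {
    bs_abort(sprintf("Filter index %d out of range 1..%d.",
                     filter, cfg$conv1_kernels), "parse_error")
  }
  stopifnot(threshold_fraction > 0, threshold_fraction <= 1)
  seqs <- if (branch == "SA") pairs$sa_seq else pairs$sd_seq
  par <- branch_par(model$par, tolower(branch))
  w <- cfg$conv1_size
  P1 <- model$geom$P1
  n <- length(seqs)
  ## single-filter convolution over all sequences
  scores <- matrix(0, nrow = P1, ncol = n)
  chunk <- max(1L, floor(2e6 / P1))
  kvec <- par$W1[, filter]
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    X1 <- im2col(encode_batch(seqs[s:e]), w)
    scores[, s:e] <- matrix(relu(X1 %*% kvec + par$b1[filter]), nrow = P1)
  }
  cutoff <- threshold_fraction * max(scores)
  hit <- which(scores >= cutoff & scores > 0, arr.ind = TRUE)
  start <- as.integer(hit[, 1L] - 1L)
  seq_i <- hit[, 2L]
  side <- window_side(start + w %/% 2L, branch)
  out <- tibble(
    filter = filter, branch = branch,
    seq_id = pairs$id[seq_i], label = as.integer(pairs$label[seq_i]),
    start = start, side = side,
    score = scores[hit]
  )
  out <- dplyr::arrange(out, .data$seq_id, .data$start)
  attr(out, "width") <- w
  attr(out, "n_pos") <- sum(pairs$label == 1)
  attr(out, "n_neg") <- sum(pairs$label == 0)
  class(out) <- c("backsplicer_occurrences", class(out))
  out
}

moving_average <- function(x, window = 5L) {
  k <- rep(1, window)
  as.vector(stats::filter(x, k / window, sides = 2L)) |>
    (\(v) ifelse(is.na(v), x, v))()
}

#' Per-position occurrence density profiles
#'
#' For each window start position, the number of occurrences at that
#' position divided by the number of scanned sequences of the class —
#' one profile for positives, one for negatives.  Each profile sums to
#' the mean number of occurrences per sequence of its class.
#'
#' @param occurrences A [scan_occurrences()] result (one branch, one
#'   filter).
#' @param n_pos,n_neg Class sizes; taken from the occurrence attributes
#'   when omitted.
#' @param smooth Apply a centred moving average (window 5) for plotting?
#' @return A `backsplicer_density` tibble: `position, class, density`
#'   with `class` in `{"positive", "negative"}` and one row per position
#'   0..(100 - width).
#' @export
occurrence_density <- function(occurrences, n_pos = NULL, n_neg = NULL,
                               smooth = FALSE) {
  n_pos <- n_pos %||% attr(occurrences, "n_pos")
  n_neg <- n_neg %||% attr(occurrences, "n_neg")
  if (is.null(n_pos) || is.null(n_neg) || (n_pos + n_neg) == 0) {
    bs_abort("Class sizes are required (zero scanned sequences?).",
             "no_occurrences")
  }
  w <- attr(occurrences, "width") %||%
    (if (nrow(occurrences)) max(occurrences$start) else 0L)
  positions <- 0L:(WINDOW_LEN - w)
  prof <- function(lbl, denom) {
    counts <- tabulate(occurrences$start[occurrences$label == lbl] + 1L,
                       nbins = length(positions))
    d <- if (denom > 0) counts / denom else counts * NA_real_
    if (smooth) d <- moving_average(d, 5L)
    d
  }
  out <- tibble(
    position = rep(positions, 2L),
    class = rep(c("positive", "negative"), each = length(positions)),
    density = c(prof(1L, n_pos), prof(0L, n_neg))
  )
  attr(out, "width") <- w
  attr(out, "branch") <- if (nrow(occurrences)) occurrences$branch[1L]
  class(out) <- c("backsplicer_density", class(out))
  out
}

#' Intron/exon split of positive-sample occurrences
#'
#' @param occurrences A [scan_occurrences()] result.
#' @return A one-row tibble `fraction_intron, fraction_exon, n` computed
#'   over positive-sample occurrences (fractions sum to 1).
#' @export
intron_exon_ratio <- function(occurrences) {
  pos <- occurrences[occurrences$label == 1L, , drop = FALSE]
  if (!nrow(pos)) {
    bs_abort("No positive-sample occurrences.", "no_occurrences")
  }
  fi <- mean(pos$side == "intron")
  tibble(fraction_intron = fi, fraction_exon = 1 - fi, n = nrow(pos))
}

#' @export
autoplot.backsplicer_density <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$position, y = .data$density,
                               colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = FLANK_LEN, colour = "red",
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(positive = "#2166ac",
                                            negative = "#ef8a62")) +
    ggplot2::labs(x = "window position (0-based start)",
                  y = "occurrences per sequence",
                  colour = NULL,
                  title = "Motif occurrence density around the splice site") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.backsplicer_ppm <- function(object, ...) {
  d <- as_tibble(object$matrix)
  d$position <- seq_len(nrow(d)) - 1L
  d <- tidyr::pivot_longer(d, dplyr::all_of(RNA_BASES),
                           names_to = "base", values_to = "probability")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$base,
                                  fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#2166ac",
                                 limits = c(0, 1)) +
    ggplot2::labs(title = object$name %||% "position probability matrix",
                  x = "motif position", y = NULL) +
    ggplot2::theme_minimal()
}
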