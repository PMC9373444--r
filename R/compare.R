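## Mean per-column Pearson correlation of two PPM blocks at one ungapped
## alignment; columns with zero variance contribute 0.
ppm_align_score <- function(ma, mb, offset) {
  La <- nrow(ma); Lb <- nrow(mb)
  a_from <- max(1L, 1L + offset)
  a_to <- min(La, Lb + offset)
  if (a_to < a_from) return(list(score = -Inf, overlap = 0L))
  rows_a <- a_from:a_to
  rows_b <- rows_a - offset
  cors <- vapply(seq_along(rows_a), function(i) {
    x <- ma[rows_a[i], ]; y <- mb[rows_b[i], ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) 0
    else stats::cor(x, y)
  }, numeric(1L))
  list(score = mean(cors), overlap = length(rows_a))
}

#' Best ungapped alignment score between two PPMs
#'
#' Slides `b` along `a` over every ungapped offset with overlap at least
#' `min_overlap`; the score of an offset is the mean per-column Pearson
#' correlation of the aligned probability columns.
#'
#' @param a,b `backsplicer_ppm` objects (or bare L x 4 matrices).
#' @param min_overlap Minimum aligned columns.
#' @return A list `score, offset, overlap` for the best offset (`offset`
#'   is the position of `b`'s first column relative to `a`'s, 0-based;
#'   negative means `b` starts left of `a`).
#' @export
ppm_best_alignment <- function(a, b, min_overlap = 5L) {
  ma <- if (inherits(a, "backsplicer_ppm")) a$matrix else as.matrix(a)
  mb <- if (inherits(b, "backsplicer_ppm")) b$matrix else as.matrix(b)
  La <- nrow(ma); Lb <- nrow(mb)
  if (La < min_overlap || Lb < min_overlap) {
    warn(sprintf("PPM width below min_overlap (%d); pair skipped.", min_overlap))
    return(list(score = NA_real_, offset = NA_integer_, overlap = 0L))
  }
  best <- list(score = -Inf, offset = NA_integer_, overlap = 0L)
  for (off in (min_overlap - Lb):(La - min_overlap)) {
    al <- ppm_align_score(ma, mb, off)
    if (al$overlap >= min_overlap && al$score > best$score) {
      best <- list(score = al$score, offset = off, overlap = al$overlap)
    }
  }
  best
}

#' Compare two motif sets by best ungapped PPM alignment
#'
#' The internal stand-in for cross-species motif sharing analysis: every
#' pair `(a, b)` is aligned at all ungapped offsets with overlap at least
#' `min_overlap`, scored by mean per-column Pearson correlation, and
#' reported when the best score reaches `score_threshold`.  The relation
#' is symmetric: `compare(a, b)` mirrors `compare(b, a)` with offsets
#' negated.
#'
#' @param set_a,set_b Named lists of `backsplicer_ppm`.
#' @param min_overlap Minimum aligned columns (default 5).
#' @param score_threshold Minimum best score to report (default 0.8).
#' @return A tibble `a, b, offset, score, overlap` with one row per
#'   matched pair.
#' @export
compare_ppm_sets <- function(set_a, set_b, min_overlap = 5L,
                             score_threshold = 0.8) {
  if (inherits(set_a, "backsplicer_ppm")) set_a <- list(set_a)
  if (inherits(set_b, "backsplicer_ppm")) set_b <- list(set_b)
  na <- names(set_a) %||% as.character(seq_along(set_a))
  nb <- names(set_b) %||% as.character(seq_along(set_b))
  out <- list()
  for (i in seq_along(set_a)) {
    for (j in seq_along(set_b)) {
      al <- ppm_best_alignment(set_a[[i]], set_b[[j]], min_overlap)
      if (!is.na(al$score) && al$score >= score_threshold) {
        out[[length(out) + 1L]] <- tibble(
          a = na[i], b = nb[j], offset = al$offset,
          score = al$score, overlap = al$overlap)
      }
    }
  }
  if (!length(out)) {
    return(tibble(a = character(), b = character(), offset = integer(),
                  score = numeric(), overlap = integer()))
  }
  dplyr::bind_rows(out)
}
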