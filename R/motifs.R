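#' Select the maximally activating subsequence per sequence and filter
#'
#' For every (positive) sequence and every first-layer filter, takes the
#' kernel-width subsequence at the filter's maximum activation, provided
#' that activation is strictly positive (DeepBind-style argmax rule).
#' Ties go to the leftmost position; subsequences containing `N` are
#' skipped.
#'
#' @param cmem A `backsplicer_cmem` from [first_layer_activations()].
#' @param positives_only Restrict to label-1 sequences (the default, and
#'   the convention of the extraction pipeline)?
#' @return A tibble `filter, seq_id, start, score, subseq` with 0-based
#'   `start`; at most one row per (sequence, filter).
#' @export
select_subsequences <- function(cmem, positives_only = TRUE) {
  stopifnot(inherits(cmem, "backsplicer_cmem"))
  take <- seq_along(cmem$ids)
  if (positives_only) {
    if (is.null(cmem$labels)) {
      bs_abort("positives_only requires labels in the activation record.",
               "degenerate_labels")
    }
    take <- which(cmem$labels == 1L)
  }
  w <- cmem$width
  n_filt <- dim(cmem$scores)[2L]
  out <- vector("list", length(take))
  for (i in seq_along(take)) {
    b <- take[i]
    A <- cmem$scores[, , b]
    p_star <- max.col(t(A), ties.method = "first")
    score <- A[cbind(p_star, seq_len(n_filt))]
    keep <- score > 0
    if (!any(keep)) next
    subseq <- substr(rep(cmem$seqs[b], sum(keep)),
                     p_star[keep], p_star[keep] + w - 1L)
    ok <- !grepl("N", subseq, fixed = TRUE)
    if (!any(ok)) next
    out[[i]] <- tibble(
      filter = which(keep)[ok], seq_id = cmem$ids[b],
      start = p_star[keep][ok] - 1L, score = score[keep][ok],
      subseq = subseq[ok]
    )
  }
  res <- dplyr::bind_rows(out)
  if (!nrow(res)) {
    res <- tibble(filter = integer(), seq_id = character(), start = integer(),
                  score = numeric(), subseq = character())
  }
  dplyr::arrange(res, .data$filter, .data$seq_id)
}

#' Build a position probability matrix from aligned subsequences
#'
#' Entry `(i, b)` is the count of base `b` at position `i` divided by the
#' number of subsequences; no pseudocounts are added.
#'
#' @param subsequences Character vector of N-free, equal-length RNA
#'   subsequences.
#' @param name Optional motif name carried into MEME export.
#' @return A `backsplicer_ppm`: list with `matrix` (L x 4 over A,C,G,U,
#'   rows summing to 1), `support` (number of subsequences), `width`,
#'   `name`.
#' @export
cmem_to_ppm <- function(subsequences, name = NULL) {
  if (length(subsequences) == 0L) {
    bs_abort("No qualifying subsequences: filter has no support.", "no_support")
  }
  L <- unique(nchar(subsequences))
  if (length(L) != 1L) {
    bs_abort("Subsequences must all have the same length.", "length_mismatch")
  }
  chars <- matrix(unlist(strsplit(subsequences, "", fixed = TRUE)),
                  ncol = L, byrow = TRUE)
  if (any(!chars %in% RNA_BASES)) {
    bs_abort("Subsequences must be N-free canonical RNA.", "invalid_alphabet")
  }
  m <- t(vapply(seq_len(L), function(i)
    tabulate(match(chars[, i], RNA_BASES), nbins = 4L), numeric(4L)))
  m <- m / length(subsequences)
  colnames(m) <- RNA_BASES
  structure(list(matrix = m, support = length(subsequences), width = L,
                 name = name),
            class = "backsplicer_ppm")
}

#' One PPM per filter from a subsequence selection
#'
#' @param selection The tibble from [select_subsequences()].
#' @param prefix Name prefix for the motifs (default `"filter"`).
#' @return A named list of `backsplicer_ppm`, one per filter with at least
#'   one supporting subsequence.
#' @export
ppms_from_selection <- function(selection, prefix = "filter") {
  by_f <- split(selection$subseq, selection$filter)
  out <- purrr::imap(by_f, function(subseqs, f)
    cmem_to_ppm(subseqs, name = paste0(prefix, f)))
  setNames(out, paste0(prefix, names(by_f)))
}

#' Trim uninformative PPM edge columns
#'
#' Removes leading and trailing columns whose information content (2 +
#' sum p log2 p, uniform background) is below `min_info` bits, as long as
#' at least `min_width` columns remain.
#'
#' @param ppm A `backsplicer_ppm`.
#' @param min_info Information threshold in bits.
#' @param min_width Minimum retained width.
#' @return The trimmed `backsplicer_ppm`.
#' @export
trim_ppm <- function(ppm, min_info = 0.1, min_width = 5L) {
  m <- ppm$matrix
  info <- apply(m, 1L, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
  lo <- 1L; hi <- nrow(m)
  while (lo < hi - min_width + 2L && info[lo] < min_info) lo <- lo + 1L
  while (hi > lo + min_width - 2L && info[hi] < min_info) hi <- hi - 1L
  ppm$matrix <- m[lo:hi, , drop = FALSE]
  ppm$width <- hi - lo + 1L
  ppm
}

#' Write motifs in MEME minimal format
#'
#' Emits a `MEME version 4` file over the RNA alphabet (`ALPHABET= ACGU`,
#' no strand line) with the given background frequencies and one MOTIF
#' block per PPM, ready for TOMTOM or any MEME-suite consumer.
#'
#' @param ppms Named list of `backsplicer_ppm` (or a single one).
#' @param path Output file path.
#' @param background Length-4 background over (A, C, G, U).
#' @return `path`, invisibly.
#' @export
write_meme <- function(ppms, path, background = rep(0.25, 4)) {
  if (inherits(ppms, "backsplicer_ppm")) ppms <- list(motif1 = ppms)
  stopifnot(length(background) == 4L, all(background >= 0))
  background <- background / sum(background)
  lines <- c(
    "MEME version 4",
    "",
    "ALPHABET= ACGU",
    "",
    "Background letter frequencies",
    paste(sprintf("%s %.6f", RNA_BASES, background), collapse = " "),
    ""
  )
  nm <- names(ppms) %||% paste0("motif", seq_along(ppms))
  for (i in seq_along(ppms)) {
    p <- ppms[[i]]
    lines <- c(lines,
      paste0("MOTIF ", p$name %||% nm[i]),
      sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
              p$width, p$support),
      apply(p$matrix, 1L, function(r) paste(sprintf("%.6f", r), collapse = " ")),
      "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Parse a MEME minimal motif file
#'
#' Inverse of [write_meme()]: `parse_meme(write_meme(ppms))` recovers the
#' PPMs to 6 decimals.
#'
#' @param path A MEME minimal format file.
#' @return A list with `ppms` (named list of `backsplicer_ppm`) and
#'   `background` (length-4 vector).
#' @export
parse_meme <- function(path) {
  if (!file.exists(path)) bs_abort(paste0("File not found: ", path), "parse_error")
  lines <- readLines(path)
  if (!any(grepl("^MEME version", lines))) {
    bs_abort("Missing 'MEME version' header.", "parse_error")
  }
  background <- rep(0.25, 4)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    toks <- strsplit(trimws(lines[bg_at[1L] + 1L]), "\\s+")[[1L]]
    background <- as.numeric(toks[seq(2L, 8L, by = 2L)])
    names(background) <- toks[seq(1L, 7L, by = 2L)]
  }
  motif_at <- grep("^MOTIF\\b", lines)
  ppms <- list()
  for (at in motif_at) {
    name <- trimws(sub("^MOTIF\\s+", "", lines[at]))
    name <- strsplit(name, "\\s+")[[1L]][1L]
    hdr <- lines[at + 1L]
    if (!grepl("^letter-probability matrix:", hdr)) {
      bs_abort(sprintf("Motif '%s': missing letter-probability header.", name),
               "parse_error")
    }
    w <- as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", hdr))
    nsites <- if (grepl("nsites=", hdr))
      as.integer(sub(".*nsites=\\s*(\\d+).*", "\\1", hdr)) else 1L
    rows <- lines[(at + 2L):(at + 1L + w)]
    m <- do.call(rbind, lapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1L]])))
    if (ncol(m) != 4L || nrow(m) != w || anyNA(m)) {
      bs_abort(sprintf("Motif '%s': malformed matrix.", name), "parse_error")
    }
    colnames(m) <- RNA_BASES
    ppms[[name]] <- structure(
      list(matrix = m, support = nsites, width = w, name = name),
      class = "backsplicer_ppm")
  }
  list(ppms = ppms, background = background)
}

#' @export
print.backsplicer_ppm <- function(x, ...) {
  cat(sprintf("<backsplicer_ppm> %s: width %d, support %d\n",
              x$name %||% "(unnamed)", x$width, x$support))
  consensus <- paste(RNA_BASES[max.col(x$matrix, ties.method = "first")],
                     collapse = "")
  cat("  consensus:", consensus, "\n")
  invisible(x)
}
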