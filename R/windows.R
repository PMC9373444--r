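#' Assemble a 100-nt splice-site window from its flanking sequences
#'
#' A splice-acceptor (SA) window reads intron (positions 0-49) then exon
#' (positions 50-99); a splice-donor (SD) window reads exon then intron.
#' Each flank is trimmed to the 50 nt proximal to the splice site, so the
#' boundary always sits between window indices 49 and 50.
#'
#' @param intron_flank,exon_flank Canonicalized RNA strings; each must be at
#'   least 50 nt or the sample is rejected (`backsplicer_flank_too_short`),
#'   mirroring the dataset-construction filter.
#' @param site_kind `"SA"` or `"SD"`.
#' @return An object of class `site_window`: a list with `seq` (100 nt),
#'   `site_kind` and `boundary_index` (always 50, 0-based first nucleotide
#'   3' of the site).
#' @export
build_window <- function(intron_flank, exon_flank, site_kind = c("SA", "SD")) {
  site_kind <- match.arg(site_kind)
  intron_flank <- canonicalize(intron_flank)
  exon_flank <- canonicalize(exon_flank)
  if (nchar(intron_flank) < FLANK_LEN || nchar(exon_flank) < FLANK_LEN) {
    bs_abort(
      sprintf("Flank shorter than %d nt (intron %d, exon %d); sample excluded.",
              FLANK_LEN, nchar(intron_flank), nchar(exon_flank)),
      "flank_too_short"
    )
  }
  keep_tail <- function(x) substr(x, nchar(x) - FLANK_LEN + 1L, nchar(x))
  keep_head <- function(x) substr(x, 1L, FLANK_LEN)
  seq <- if (site_kind == "SA") {
    ## intron ends at the acceptor: keep its 3' tail, then the exon 5' head
    paste0(keep_tail(intron_flank), keep_head(exon_flank))
  } else {
    ## exon ends at the donor: keep its 3' tail, then the intron 5' head
    paste0(keep_tail(exon_flank), keep_head(intron_flank))
  }
  structure(
    list(seq = seq, site_kind = site_kind, boundary_index = FLANK_LEN),
    class = "site_window"
  )
}

#' Which side of the splice site is a window position on?
#'
#' @param position 0-based position(s) within the 100-nt window.
#' @param site_kind `"SA"` (intron left of the boundary) or `"SD"` (exon
#'   left of the boundary).
#' @return Character vector `"intron"`/`"exon"`.
#' @export
window_side <- function(position, site_kind = c("SA", "SD")) {
  site_kind <- match.arg(site_kind)
  left <- position < FLANK_LEN
  if (site_kind == "SA") ifelse(left, "intron", "exon")
  else ifelse(left, "exon", "intron")
}

#' Remove duplicated sample pairs
#'
#' Keeps the first occurrence of each exact `(sa_seq, sd_seq)` pair, in
#' stable order.  The key is the concatenated window pair itself, not any
#' genomic coordinate.
#'
#' @param pairs A tibble with columns `sa_seq` and `sd_seq` (plus any
#'   others, which are carried along).
#' @return The deduplicated tibble.
#' @export
deduplicate_pairs <- function(pairs) {
  pairs <- as_tibble(pairs)
  keep <- !duplicated(paste(pairs$sa_seq, pairs$sd_seq, sep = "|"))
  pairs[keep, , drop = FALSE]
}

validate_pairs <- function(pairs, max_n_frac = 0.1) {
  pairs <- as_tibble(pairs)
  req <- c("id", "sa_seq", "sd_seq", "label")
  missing_cols <- setdiff(req, names(pairs))
  if (length(missing_cols)) {
    bs_abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")),
             "parse_error")
  }
  pairs$sa_seq <- canonicalize(pairs$sa_seq)
  pairs$sd_seq <- canonicalize(pairs$sd_seq)
  bad_len <- nchar(pairs$sa_seq) != WINDOW_LEN | nchar(pairs$sd_seq) != WINDOW_LEN
  if (any(bad_len)) {
    bs_abort(sprintf("Record %d: windows must be exactly %d nt.",
                     which(bad_len)[1L], WINDOW_LEN), "length_mismatch")
  }
  if (!all(pairs$label %in% c(0L, 1L))) {
    bs_abort("Labels must be 0 or 1.", "parse_error")
  }
  pairs$label <- as.integer(pairs$label)
  n_frac <- (stringr::str_count(pairs$sa_seq, "N") +
             stringr::str_count(pairs$sd_seq, "N")) / (2 * WINDOW_LEN)
  drop <- n_frac > max_n_frac
  if (any(drop)) {
    warn(sprintf("Rejected %d record(s) with > %.0f%% N content.",
                 sum(drop), 100 * max_n_frac))
    pairs <- pairs[!drop, , drop = FALSE]
  }
  pairs
}

#' Sample canonical-splice negative pairs from transcript structures
#'
#' A negative instance pairs the splice acceptor of exon `j` with the
#' splice donor of exon `i`, where the pair covers 2 or 3 consecutive
#' exons (`j = i + 1` or `i + 2`) of one transcript — i.e. an ordinary
#' linear splicing context rather than a back-splicing one.  Windows are
#' assembled with [build_window()], so any site whose flank is shorter
#' than 50 nt is ineligible.  Site pairs listed in `positives` are
#' excluded.  Sampling is uniform without replacement over the eligible
#' pairs and deterministic for a fixed seed.
#'
#' @param transcripts Tibble with columns `transcript_id`, `exon_index`
#'   (1-based rank along the transcript), `exon_seq`, and `intron_after`
#'   (the intron following the exon; `NA` for the last exon).
#' @param positives Optional tibble with columns `transcript_id`,
#'   `donor_exon`, `acceptor_exon` naming site pairs to reject.
#' @param n Number of negatives requested.
#' @param seed Integer seed.
#' @return A tibble of sample pairs (`id`, `sa_seq`, `sd_seq`, `label = 0`,
#'   `transcript_id`, `donor_exon`, `acceptor_exon`).  If fewer than `n`
#'   eligible pairs exist, returns all of them with a warning.
#' @export
sample_negatives <- function(transcripts, positives = NULL, n, seed = 1L) {
  stopifnot(n >= 0)
  tx <- as_tibble(transcripts)
  tx <- dplyr::arrange(tx, .data$transcript_id, .data$exon_index)
  cand <- list()
  for (id in unique(tx$transcript_id)) {
    t1 <- tx[tx$transcript_id == id, ]
    ne <- nrow(t1)
    for (i in seq_len(ne)) {
      for (j in c(i + 1L, i + 2L)) {
        if (j > ne) next
        ## donor of exon i needs exon i tail + intron i head;
        ## acceptor of exon j needs intron (j-1) tail + exon j head
        don_ex <- t1$exon_seq[i]; don_in <- t1$intron_after[i]
        acc_in <- t1$intron_after[j - 1L]; acc_ex <- t1$exon_seq[j]
        if (any(is.na(c(don_ex, don_in, acc_in, acc_ex)))) next
        if (nchar(don_ex) < FLANK_LEN || nchar(don_in) < FLANK_LEN ||
            nchar(acc_in) < FLANK_LEN || nchar(acc_ex) < FLANK_LEN) next
        cand[[length(cand) + 1L]] <- tibble(
          transcript_id = id, donor_exon = i, acceptor_exon = j,
          sa_seq = build_window(acc_in, acc_ex, "SA")$seq,
          sd_seq = build_window(don_in, don_ex, "SD")$seq
        )
      }
    }
  }
  cand <- if (length(cand)) dplyr::bind_rows(cand) else
    tibble(transcript_id = character(), donor_exon = integer(),
           acceptor_exon = integer(), sa_seq = character(), sd_seq = character())
  if (!is.null(positives) && nrow(cand)) {
    key <- function(d) paste(d$transcript_id, d$donor_exon, d$acceptor_exon)
    cand <- cand[!key(cand) %in% key(as_tibble(positives)), , drop = FALSE]
  }
  if (nrow(cand) < n) {
    warn(sprintf("Only %d eligible negative pair(s) available (%d requested).",
                 nrow(cand), n))
    take <- seq_len(nrow(cand))
  } else {
    take <- withr::with_seed(seed, sample.int(nrow(cand), n))
  }
  out <- cand[take, , drop = FALSE]
  tibble(
    id = sprintf("neg_%s_e%d_e%d", out$transcript_id, out$donor_exon,
                 out$acceptor_exon),
    sa_seq = out$sa_seq, sd_seq = out$sd_seq, label = 0L,
    transcript_id = out$transcript_id, donor_exon = out$donor_exon,
    acceptor_exon = out$acceptor_exon
  )
}

#' Stratified k-fold assignment
#'
#' Folds are stratified by label: within each class, fold sizes differ by
#' at most one.  Input order does not matter — samples are canonicalized by
#' sorting on `id` before the seeded shuffle — so the same `(ids, labels,
#' k, seed)` always yields the same assignment.
#'
#' @param pairs Tibble with columns `id` and `label`.
#' @param k Number of folds (>= 2, and at most the size of the smaller
#'   class).
#' @param seed Integer seed.
#' @return A tibble (`id`, `label`, `fold`) with folds in `1..k`.
#' @export
kfold_split <- function(pairs, k = 7L, seed = 1L) {
  pairs <- as_tibble(pairs)
  k <- as.integer(k)
  counts <- table(factor(pairs$label, levels = c(0L, 1L)))
  if (k < 2L || any(counts < k)) {
    bs_abort(sprintf(
      "Cannot form %d stratified folds from class sizes %d/%d.",
      k, counts[["0"]], counts[["1"]]), "infeasible_split")
  }
  ord <- order(pairs$id)
  ids <- pairs$id[ord]
  labels <- pairs$label[ord]
  fold <- integer(length(ids))
  withr::with_seed(seed, {
    for (cl in c(0L, 1L)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  tibble(id = ids, label = labels, fold = fold)
}
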