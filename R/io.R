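#' Read a paired-window dataset
#'
#' Three dialects are supported:
#' \describe{
#'   \item{`tsv`}{UTF-8, unquoted, header `id  sa_seq  sd_seq  label`.}
#'   \item{`paired_fasta`}{`<prefix>_sa.fasta` and `<prefix>_sd.fasta` with
#'     identical id sets, plus `<prefix>_labels.tsv` (`id  label`);
#'     `path` is the prefix.  Standard FASTA wrapping is accepted.}
#'   \item{`xlsx_sheets`}{a workbook with one sheet per species and label,
#'     named `<species>_positive` / `<species>_negative`; each sheet must
#'     carry `sa_seq`/`sd_seq` columns (an `id` column is optional).}
#' }
#' All sequences are canonicalized on load and records with more than
#' `max_n_frac` ambiguous bases are rejected with a warning.
#'
#' @param path File path (or prefix for `paired_fasta`).
#' @param format One of `"tsv"`, `"paired_fasta"`, `"xlsx_sheets"`.
#' @param max_n_frac Maximum tolerated fraction of `N` per record.
#' @return A tibble with columns `id`, `sa_seq`, `sd_seq`, `label` (and
#'   `species` for xlsx input).
#' @export
read_pairs <- function(path, format = c("tsv", "paired_fasta", "xlsx_sheets"),
                       max_n_frac = 0.1) {
  format <- match.arg(format)
  out <- switch(format,
    tsv = read_pairs_tsv(path),
    paired_fasta = read_pairs_fasta(path),
    xlsx_sheets = read_pairs_xlsx(path)
  )
  validate_pairs(out, max_n_frac = max_n_frac)
}

read_pairs_tsv <- function(path) {
  if (!file.exists(path)) bs_abort(paste0("File not found: ", path), "parse_error")
  out <- tryCatch(
    readr::read_tsv(path, col_types = readr::cols(
      id = readr::col_character(),
      sa_seq = readr::col_character(),
      sd_seq = readr::col_character(),
      label = readr::col_integer()
    ), quote = "", progress = FALSE),
    error = function(e) bs_abort(conditionMessage(e), "parse_error")
  )
  prob <- readr::problems(out)
  if (nrow(prob)) {
    bs_abort(sprintf("Malformed TSV record at line %d: %s",
                     prob$row[1L] + 1L, prob$expected[1L]), "parse_error")
  }
  out
}

read_fasta_named <- function(path) {
  if (!file.exists(path)) bs_abort(paste0("File not found: ", path), "parse_error")
  x <- Biostrings::readBStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

read_pairs_fasta <- function(prefix) {
  sa <- read_fasta_named(paste0(prefix, "_sa.fasta"))
  sd <- read_fasta_named(paste0(prefix, "_sd.fasta"))
  if (!setequal(names(sa), names(sd))) {
    bs_abort(sprintf(
      "SA/SD FASTA id sets differ (e.g. %s).",
      paste(head(c(setdiff(names(sa), names(sd)),
                   setdiff(names(sd), names(sa))), 3L), collapse = ", ")),
      "parse_error")
  }
  labels <- readr::read_tsv(paste0(prefix, "_labels.tsv"),
                            col_types = "ci", quote = "", progress = FALSE)
  if (!setequal(labels$id, names(sa))) {
    bs_abort("Label table ids do not match the FASTA ids.", "parse_error")
  }
  tibble(id = labels$id, sa_seq = unname(sa[labels$id]),
         sd_seq = unname(sd[labels$id]), label = labels$label)
}

read_pairs_xlsx <- function(path) {
  if (!requireNamespace("readxl", quietly = TRUE)) {
    bs_abort("xlsx import requires the 'readxl' package.", "parse_error")
  }
  sheets <- readxl::excel_sheets(path)
  sheets <- sheets[grepl("_(positive|negative)$", sheets)]
  if (!length(sheets)) {
    bs_abort("No '<species>_positive'/'<species>_negative' sheets found.",
             "parse_error")
  }
  purrr::map_dfr(sheets, function(s) {
    d <- readxl::read_excel(path, sheet = s)
    names(d) <- tolower(names(d))
    if (!all(c("sa_seq", "sd_seq") %in% names(d))) {
      bs_abort(sprintf("Sheet '%s' lacks sa_seq/sd_seq columns.", s),
               "parse_error")
    }
    species <- sub("_(positive|negative)$", "", s)
    label <- as.integer(grepl("_positive$", s))
    tibble(
      id = if ("id" %in% names(d)) as.character(d$id)
           else sprintf("%s_%d_%s", species, label, seq_len(nrow(d))),
      sa_seq = d$sa_seq, sd_seq = d$sd_seq, label = label, species = species
    )
  })
}

#' Write a paired-window dataset
#'
#' Inverse of [read_pairs()] for the `tsv` and `paired_fasta` dialects;
#' `write_pairs()` then `read_pairs()` is the identity on canonicalized
#' data.
#'
#' @param pairs Tibble with `id`, `sa_seq`, `sd_seq`, `label`.
#' @inheritParams read_pairs
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path, format = c("tsv", "paired_fasta")) {
  format <- match.arg(format)
  pairs <- as_tibble(pairs)
  if (format == "tsv") {
    readr::write_tsv(pairs[, c("id", "sa_seq", "sd_seq", "label")], path,
                     progress = FALSE)
  } else {
    write_one <- function(seqs, suffix) {
      Biostrings::writeXStringSet(
        Biostrings::BStringSet(setNames(seqs, pairs$id)),
        paste0(path, suffix))
    }
    write_one(pairs$sa_seq, "_sa.fasta")
    write_one(pairs$sd_seq, "_sd.fasta")
    readr::write_tsv(pairs[, c("id", "label")], paste0(path, "_labels.tsv"),
                     progress = FALSE)
  }
  invisible(path)
}
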