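#' Canonicalize nucleotide sequences to the RNA alphabet
#'
#' Uppercases and maps T to U so that DNA- or mixed-case input becomes an
#' RNA string over `{A, C, G, U, N}`.  Length is always preserved.
#'
#' @param seq Character vector of nucleotide sequences.  Allowed characters
#'   are `A, C, G, T, U, N` in either case.
#' @return Character vector of the same length, uppercase RNA.
#' @examples
#' canonicalize("acgt")
#' @export
canonicalize <- function(seq) {
  if (length(seq) == 0L) return(character())
  if (!is.character(seq) || any(is.na(seq)) || any(!nzchar(seq))) {
    bs_abort("`seq` must be a character vector of non-empty strings.",
             "invalid_alphabet")
  }
  out <- chartr("acgtun", "ACGUUN", chartr("T", "U", seq))
  bad <- regexpr("[^ACGUN]", out)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    pos <- as.integer(bad[i])
    bs_abort(
      sprintf(
        "Invalid nucleotide '%s' at position %d of sequence %d (0-based position %d).",
        substr(seq[i], pos, pos), pos, i, pos - 1L
      ),
      "invalid_alphabet"
    )
  }
  out
}

#' One-hot encode a 100-nt RNA window
#'
#' Channel order is fixed as (A, C, G, U); an `N` becomes an all-zero row,
#' every determinate nucleotide an indicator row.
#'
#' @param seq A single canonicalized RNA string of length 100.
#' @return A 100 x 4 integer matrix of 0/1 with column names `A,C,G,U`.
#' @export
one_hot_encode <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) != WINDOW_LEN) {
    bs_abort(
      sprintf("Expected a %d-nt sequence, got %d nt.", WINDOW_LEN, nchar(seq)),
      "length_mismatch"
    )
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  idx <- match(chars, RNA_BASES)  # NA for N
  m <- matrix(0L, nrow = WINDOW_LEN, ncol = 4L,
              dimnames = list(NULL, RNA_BASES))
  hit <- which(!is.na(idx))
  m[cbind(hit, idx[hit])] <- 1L
  m
}

#' Decode a one-hot matrix back to a sequence
#'
#' Inverse of [one_hot_encode()] on N-free input: the argmax channel of each
#' row is read back as its base; all-zero rows decode to `N`.
#'
#' @param mat A matrix with 4 columns in (A, C, G, U) channel order.
#' @return A single RNA string.
#' @export
decode_one_hot <- function(mat) {
  stopifnot(is.matrix(mat), ncol(mat) == 4L)
  zero <- rowSums(mat) == 0
  base <- RNA_BASES[max.col(mat, ties.method = "first")]
  base[zero] <- "N"
  paste(base, collapse = "")
}

## Encode many windows at once into an (L, 4, n) array; the workhorse behind
## the network's input layer.
encode_batch <- function(seqs) {
  n <- length(seqs)
  arr <- array(0, dim = c(WINDOW_LEN, 4L, n))
  split_all <- strsplit(seqs, "", fixed = TRUE)
  for (b in seq_len(n)) {
    idx <- match(split_all[[b]], RNA_BASES)
    hit <- which(!is.na(idx))
    arr[cbind(hit, idx[hit], b)] <- 1
  }
  arr
}
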