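make_cmem <- function(scores, seqs, labels = NULL, width = 4L) {
  structure(
    list(scores = scores, ids = sprintf("s%d", seq_along(seqs)),
         labels = labels, seqs = seqs, branch = "SA", width = width),
    class = "backsplicer_cmem")
}

test_that("subsequence selection follows the argmax rule with leftmost ties", {
  ## 2 filters over 2 sequences of length 7, width 4 -> 4 positions
  seqs <- c("ACGUACG", "GGGGGGG")
  scores <- array(0, c(4, 2, 2))
  scores[, 1, 1] <- c(1, 3, 3, 0)   # tie at positions 2 and 3 -> leftmost
  scores[, 2, 1] <- 0               # never active -> no row
  scores[, 1, 2] <- c(0, 0, 0, 2)
  cmem <- make_cmem(scores, seqs, labels = c(1L, 1L))
  sel <- select_subsequences(cmem)
  expect_identical(nrow(sel), 2L)
  s1 <- sel[sel$seq_id == "s1", ]
  expect_identical(s1$start, 1L)          # 0-based leftmost maximum
  expect_identical(s1$subseq, "CGUA")
  expect_identical(sel$filter, c(1L, 1L))
  ## positives_only drops unlabeled-negative sequences
  cmem2 <- make_cmem(scores, seqs, labels = c(1L, 0L))
  expect_identical(unique(select_subsequences(cmem2)$seq_id), "s1")
  ## N-containing subsequences are skipped
  cmem3 <- make_cmem(scores, c("ANGUACG", "GGGGGGG"), labels = c(1L, 1L))
  sel3 <- select_subsequences(cmem3)
  expect_identical(sel3$seq_id, "s2")
  ## at most one subsequence per (sequence, filter)
  expect_lte(max(table(paste(sel$filter, sel$seq_id))), 1L)
})

test_that("selection agrees with an independent convolution scan", {
  sim <- tiny_sim(10, seed = 23)
  cfg <- model_config(conv1_kernels = 4, conv1_size = 6, conv2_kernels = 2,
                      conv2_size = 5, seed = 3)
  m <- build_model(cfg)
  pos <- sim$pairs[sim$pairs$label == 1, ]
  cmem <- first_layer_activations(m, pos, "SA")
  sel <- select_subsequences(cmem)
  for (b in seq_len(nrow(pos))) {
    ref <- brute_conv1(pos$sa_seq[b], m$par$W1_sa, m$par$b1_sa, 6L)
    for (k in 1:4) {
      rows <- sel[sel$seq_id == pos$id[b] & sel$filter == k, ]
      if (max(ref[, k]) > 0) {
        expect_identical(rows$start, which.max(ref[, k]) - 1L)
        expect_equal(rows$score, max(ref[, k]))
      } else {
        expect_identical(nrow(rows), 0L)
      }
    }
  }
})

test_that("PPMs implement the per-position counting formula", {
  p1 <- cmem_to_ppm("AC")
  expect_equal(p1$matrix,
               rbind(c(1, 0, 0, 0), c(0, 1, 0, 0)), ignore_attr = TRUE)
  expect_identical(p1$support, 1L)

  p2 <- cmem_to_ppm(c("AAC", "AGC"))
  expect_equal(p2$matrix,
               rbind(c(1, 0, 0, 0), c(0.5, 0, 0.5, 0), c(0, 1, 0, 0)),
               ignore_attr = TRUE)

  expect_error(cmem_to_ppm(character()), class = "backsplicer_no_support")
  expect_error(cmem_to_ppm(c("AC", "ACG")),
               class = "backsplicer_length_mismatch")
  expect_error(cmem_to_ppm("ANC"), class = "backsplicer_invalid_alphabet")
})

test_that("PPMs estimated from a known PWM converge at the binomial rate", {
  pwm <- default_sim_config()$plants[[1]]$pwm
  n <- 1000
  withr::with_seed(41, {
    draws <- vapply(seq_len(n), function(i)
      paste(c("A", "C", "G", "U")[vapply(seq_len(nrow(pwm)), function(r)
        sample.int(4, 1, prob = pwm[r, ]), 1L)], collapse = ""), "")
  })
  est <- cmem_to_ppm(draws)
  bound <- 3 * sqrt(pwm * (1 - pwm) / n) + 1e-9
  expect_true(all(abs(est$matrix - pwm) <= bound))
  expect_equal(rowSums(est$matrix), rep(1, nrow(pwm)), ignore_attr = TRUE)
})

test_that("MEME export round-trips and emits a valid minimal file", {
  sim <- tiny_sim(10, seed = 27)
  m <- build_model(model_config(conv1_kernels = 3, conv1_size = 12,
                                conv2_kernels = 2, conv2_size = 5, seed = 8))
  sel <- select_subsequences(first_layer_activations(m, sim$pairs, "SA"))
  ppms <- ppms_from_selection(sel)
  path <- withr::local_tempfile(fileext = ".meme")
  write_meme(ppms, path, background = rep(0.25, 4))
  lines <- readLines(path)
  expect_identical(lines[1], "MEME version 4")
  expect_true("ALPHABET= ACGU" %in% lines)
  expect_identical(sum(grepl("^MOTIF ", lines)), length(ppms))
  expect_identical(sum(grepl("^letter-probability matrix: alength= 4 w= 12",
                             lines)), length(ppms))

  back <- parse_meme(path)
  expect_identical(names(back$ppms), names(ppms))
  for (nm in names(ppms)) {
    expect_equal(back$ppms[[nm]]$matrix, ppms[[nm]]$matrix, tolerance = 1e-6)
    expect_identical(back$ppms[[nm]]$support, ppms[[nm]]$support)
    expect_equal(rowSums(back$ppms[[nm]]$matrix), rep(1, 12),
                 ignore_attr = TRUE, tolerance = 1e-5)
  }
  expect_equal(back$background, rep(0.25, 4), ignore_attr = TRUE)

  ## empty motif list -> header-only file that still parses
  path2 <- withr::local_tempfile(fileext = ".meme")
  write_meme(list(), path2)
  empty <- parse_meme(path2)
  expect_identical(length(empty$ppms), 0L)
})

test_that("edge trimming removes only uninformative flanking columns", {
  flat <- matrix(0.25, 2, 4)
  sharp <- consensus <- matrix(0, 3, 4); sharp[, 1] <- 1
  ppm <- structure(list(matrix = rbind(flat, sharp, flat), support = 10L,
                        width = 7L, name = "x"), class = "backsplicer_ppm")
  tr <- trim_ppm(ppm, min_info = 0.1, min_width = 2L)
  expect_identical(tr$width, 3L)
  expect_true(all(tr$matrix[, 1] == 1))
})

test_that("occurrence scanning assigns sides by receptive-field centre", {
  sim <- tiny_sim(15, seed = 33)
  m <- build_model(model_config(conv1_kernels = 2, conv1_size = 12,
                                conv2_kernels = 2, conv2_size = 5, seed = 5))
  occ <- scan_occurrences(m, sim$pairs, "SA", filter = 1,
                          threshold_fraction = 0.5)
  expect_true(all(occ$score > 0))
  ## side follows the centre of the 12-nt receptive field: start 10 ->
  ## centre 16 (intron for SA), start 70 -> centre 76 (exon)
  expect_identical(occ$side, window_side(occ$start + 6L, "SA"))
  expect_identical(window_side(c(10L, 70L) + 6L, "SA"), c("intron", "exon"))
  ## SD layout is mirrored
  occ_sd <- scan_occurrences(m, sim$pairs, "SD", filter = 1)
  expect_identical(occ_sd$side, window_side(occ_sd$start + 6L, "SD"))

  ## threshold 1.0 keeps only global-maximum positions
  occ_max <- scan_occurrences(m, sim$pairs, "SA", filter = 1,
                              threshold_fraction = 1)
  expect_equal(unique(occ_max$score), max(occ$score))

  expect_error(scan_occurrences(m, sim$pairs, "SA", filter = 99),
               class = "backsplicer_parse_error")
})

test_that("density profiles conserve occurrence mass per class", {
  sim <- tiny_sim(15, seed = 34)
  m <- build_model(model_config(conv1_kernels = 2, conv1_size = 12,
                                conv2_kernels = 2, conv2_size = 5, seed = 6))
  occ <- scan_occurrences(m, sim$pairs, "SA", filter = 2)
  dens <- occurrence_density(occ)
  expect_identical(nrow(dens), 2L * (100L - 12L + 1L))
  for (cl in c("positive", "negative")) {
    lbl <- if (cl == "positive") 1L else 0L
    expect_equal(sum(dens$density[dens$class == cl]),
                 sum(occ$label == lbl) / 15)
  }
  ## an empty occurrence set gives an all-zero profile
  dens0 <- occurrence_density(occ[0, ], n_pos = 5, n_neg = 5)
  expect_true(all(dens0$density == 0))
  ## smoothing preserves non-negativity
  denss <- occurrence_density(occ, smooth = TRUE)
  expect_true(all(denss$density >= 0))
})

test_that("intron/exon fractions summarize positive occurrences", {
  occ <- tibble::tibble(filter = 1L, branch = "SA",
                        seq_id = c("a", "b", "c"), label = c(1L, 1L, 0L),
                        start = c(5L, 20L, 80L),
                        side = c("intron", "intron", "exon"), score = 1)
  r <- intron_exon_ratio(occ)
  expect_equal(r$fraction_intron, 1)
  expect_equal(r$fraction_exon, 0)
  expect_identical(r$n, 2L)
  single <- occ[2, ]
  expect_equal(intron_exon_ratio(single)$fraction_intron, 1)
  expect_error(intron_exon_ratio(occ[occ$label == 0, ]),
               class = "backsplicer_no_occurrences")
})

test_that("PPM set comparison scores identity, permutation and symmetry", {
  pwm_a <- default_sim_config()$plants[[1]]$pwm
  pwm_b <- default_sim_config()$plants[[2]]$pwm
  ppm <- function(m, nm) structure(
    list(matrix = m, support = 10L, width = nrow(m), name = nm),
    class = "backsplicer_ppm")
  a <- ppm(pwm_a, "a"); b <- ppm(pwm_b, "b")

  self <- compare_ppm_sets(list(x = a), list(y = a), score_threshold = 0.8)
  expect_equal(self$score, 1)
  expect_identical(self$offset, 0L)

  ## column-permuted copy scores strictly below identity
  perm <- ppm(pwm_a[c(5, 3, 9, 1, 7, 2, 10, 4, 8, 6), ], "p")
  best <- ppm_best_alignment(a, perm)
  expect_lt(best$score, 1)

  ## symmetry: compare(a, b) mirrors compare(b, a) with negated offset
  ab <- ppm_best_alignment(a, b); ba <- ppm_best_alignment(b, a)
  expect_equal(ab$score, ba$score)
  expect_identical(ab$offset, -ba$offset)

  ## widths below the overlap floor are skipped with a warning
  narrow <- ppm(pwm_a[1:3, ], "n")
  expect_warning(sk <- ppm_best_alignment(a, narrow), "skipped")
  expect_true(is.na(sk$score))

  ## unrelated sharp motifs fall below the reporting threshold
  expect_identical(nrow(compare_ppm_sets(list(a = a), list(b = b),
                                         score_threshold = 0.8)), 0L)
})
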