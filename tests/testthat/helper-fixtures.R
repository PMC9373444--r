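## Shared fixtures.  Everything is generated in code under fixed seeds;
## heavy benchmark computations are memoized so several tests can share
## one cross-validation run.

## Small, fast architecture for contract tests (seconds, not minutes).
tiny_cfg <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(conv1_kernels = 6L, conv1_size = 8L,
         conv2_kernels = 4L, conv2_size = 10L,
         dropout1 = 0.1, dropout2 = 0.1,
         batch_size = 64L, max_epochs = 3L,
         early_stopping_patience = 3L, seed = seed),
    list(...))
  do.call(model_config, args)
}

## Benchmark-scale architecture: a reduced network (16 + 16 kernels, conv2
## width 20 -- all values from the tuning grid) that one CPU trains in
## tens of seconds per fold while still separating the planted motifs.
bench_cfg <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(conv1_kernels = 16L, conv2_kernels = 16L, conv2_size = 20L,
         dropout1 = 0.2, dropout2 = 0.2, batch_size = 256L,
         max_epochs = 15L, early_stopping_patience = 15L,
         learning_rate = 2e-3, seed = seed),
    list(...))
  do.call(model_config, args)
}

## Small planted dataset for pipeline tests.
tiny_sim <- function(n = 40L, seed = 5L) {
  simulate_dataset(default_sim_config(seed = seed, n_pos = n, n_neg = n))
}

## Pure-background pairs (no plants).
background_pairs <- function(n, seed = 9L) {
  simulate_dataset(sim_config(n_pos = n, n_neg = 0L, seed = seed))$pairs
}

## Transcript table for negative sampling: exon/intron sequences long
## enough to pass the 50-nt flank filter unless stated otherwise.
make_transcripts <- function(n_exons = 4L, len = 60L, seed = 3L,
                             transcript_id = "tx1") {
  withr::with_seed(seed, {
    rand_seq <- function(l) paste(sample(c("A", "C", "G", "U"), l,
                                         replace = TRUE), collapse = "")
    tibble::tibble(
      transcript_id = transcript_id,
      exon_index = seq_len(n_exons),
      exon_seq = vapply(seq_len(n_exons), function(i) rand_seq(len), ""),
      intron_after = c(vapply(seq_len(n_exons - 1L),
                              function(i) rand_seq(len), ""), NA)
    )
  })
}

## Independent brute-force first-layer convolution: direct position-by-
## position dot product against the one-hot sequence, never touching the
## package's im2col path.
brute_conv1 <- function(seq, W1, b1, width) {
  chars <- strsplit(seq, "")[[1L]]
  base_idx <- match(chars, c("A", "C", "G", "U"))
  P <- nchar(seq) - width + 1L
  K <- ncol(W1)
  out <- matrix(0, P, K)
  for (p in seq_len(P)) {
    for (k in seq_len(K)) {
      s <- b1[k]
      for (j in seq_len(width)) {
        bi <- base_idx[p + j - 1L]
        if (!is.na(bi)) s <- s + W1[(j - 1L) * 4L + bi, k]
      }
      out[p, k] <- max(s, 0)
    }
  }
  out
}

## Memoized heavy benchmark runs shared across acceptance tests.
.bench_cache <- new.env(parent = emptyenv())

bench_recovery <- function() {
  if (!is.null(.bench_cache$recovery)) return(.bench_cache$recovery)
  scfg <- default_sim_config(seed = 7L)
  sim <- simulate_dataset(scfg)
  cv <- cross_validate(sim$pairs, bench_cfg(seed = 7L), k = 7L, seed = 7L,
                       keep_best_model = TRUE)
  .bench_cache$recovery <- list(scfg = scfg, sim = sim, cv = cv)
  .bench_cache$recovery
}

bench_null <- function() {
  if (!is.null(.bench_cache$null)) return(.bench_cache$null)
  sim <- simulate_dataset(default_sim_config(seed = 7L,
                                             plant_probability = 0))
  cv <- cross_validate(sim$pairs,
                       bench_cfg(seed = 7L, max_epochs = 2L,
                                early_stopping_patience = 2L),
                       k = 3L, seed = 7L)
  .bench_cache$null <- cv
  .bench_cache$null
}

bench_ablation <- function() {
  if (!is.null(.bench_cache$ablation)) return(.bench_cache$ablation)
  sim <- simulate_dataset(default_sim_config(seed = 7L, n_pos = 800L,
                                             n_neg = 800L))
  .bench_cache$ablation <- ablation_suite(
    sim$pairs, bench_cfg(seed = 7L, max_epochs = 10L,
                        early_stopping_patience = 10L),
    k = 2L, seed = 7L)
  .bench_cache$ablation
}
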