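test_that("model building is deterministic in the seed", {
  pairs <- tiny_sim(4, seed = 2)$pairs
  m1 <- build_model(tiny_cfg(seed = 5))
  m2 <- build_model(tiny_cfg(seed = 5))
  expect_identical(m1$par, m2$par)
  expect_identical(predict(m1, pairs), predict(m2, pairs))
  m3 <- build_model(tiny_cfg(seed = 6))
  expect_false(identical(m1$par$W1_sa, m3$par$W1_sa))
})

test_that("ablation variants build the advertised parameter sets", {
  m_bn <- build_model(tiny_cfg())
  expect_true(all(c("gamma", "beta") %in% names(m_bn$par)))
  m_nobn <- build_model(tiny_cfg(batchnorm = FALSE))
  expect_false(any(c("gamma", "beta") %in% names(m_nobn$par)))
  expect_null(m_nobn$bn)
  m_drop <- build_model(tiny_cfg(batchnorm = FALSE, bn_as_dropout = TRUE))
  expect_false(any(c("gamma", "beta") %in% names(m_drop$par)))
  expect_error(model_config(batchnorm = TRUE, bn_as_dropout = TRUE),
               class = "backsplicer_architecture_infeasible")
})

test_that("predictions are probabilities, batch-invariant, and serializable", {
  pairs <- tiny_sim(10, seed = 3)$pairs
  m <- build_model(tiny_cfg(seed = 9))
  p <- predict(m, pairs)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(unname(p),
               unname(c(predict(m, pairs[1:7, ]), predict(m, pairs[8:20, ]))))

  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  expect_identical(predict(load_model(path), pairs), p)

  short <- pairs; short$sa_seq[1] <- substr(short$sa_seq[1], 1, 99)
  expect_error(predict(m, short), class = "backsplicer_length_mismatch")
})

test_that("one optimizer step at a small learning rate decreases batch loss", {
  sim <- tiny_sim(16, seed = 12)
  cfg <- tiny_cfg(seed = 4, dropout1 = 0, dropout2 = 0)
  cfg$learning_rate <- 1e-4
  m <- build_model(cfg)
  enc <- backsplicer:::encode_pair_batch(sim$pairs)
  y <- as.numeric(sim$pairs$label)
  fw <- backsplicer:::model_forward(m, enc$sa, enc$sd, train = TRUE, keep = TRUE)
  loss0 <- backsplicer:::bce_loss(y, fw$prob)
  grads <- backsplicer:::model_backward(m, fw, y)
  upd <- backsplicer:::rmsprop_step(m$par, grads,
                                    lapply(m$par, function(p) p * 0),
                                    lr = cfg$learning_rate)
  m$par <- upd$par
  fw1 <- backsplicer:::model_forward(m, enc$sa, enc$sd, train = TRUE)
  expect_lt(backsplicer:::bce_loss(y, fw1$prob), loss0)
})

test_that("analytic gradients match finite differences", {
  sim <- tiny_sim(6, seed = 8)
  cfg <- model_config(conv1_kernels = 4, conv1_size = 6, conv2_kernels = 3,
                      conv2_size = 7, dropout1 = 0, dropout2 = 0, seed = 2)
  m <- build_model(cfg)
  enc <- backsplicer:::encode_pair_batch(sim$pairs)
  y <- as.numeric(sim$pairs$label)
  fw <- backsplicer:::model_forward(m, enc$sa, enc$sd, train = TRUE, keep = TRUE)
  grads <- backsplicer:::model_backward(m, fw, y)
  loss_at <- function(mod) backsplicer:::bce_loss(
    y, backsplicer:::model_forward(mod, enc$sa, enc$sd, train = TRUE)$prob)
  eps <- 1e-6
  withr::with_seed(3, {
    for (nm in names(grads)) {
      for (i in sample(length(m$par[[nm]]), min(4, length(m$par[[nm]])))) {
        up <- m; up$par[[nm]][i] <- up$par[[nm]][i] + eps
        dn <- m; dn$par[[nm]][i] <- dn$par[[nm]][i] - eps
        num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
        expect_equal(grads[[nm]][i], num, tolerance = 1e-4,
                     label = sprintf("d(loss)/d(%s[%d])", nm, i))
      }
    }
  })
})

test_that("training respects the epoch cap, patience and best-weight restore", {
  sim <- tiny_sim(30, seed = 6)
  cfg <- tiny_cfg(seed = 3)
  cfg$max_epochs <- 5L; cfg$early_stopping_patience <- 5L
  fit <- train_model(build_model(cfg), sim$pairs)
  expect_lte(nrow(fit$history), 5L)
  expect_identical(fit$stopped_epoch, nrow(fit$history))
  expect_identical(fit$best_epoch, which.min(fit$history$val_loss))
  expect_lte(fit$stopped_epoch - fit$best_epoch, cfg$early_stopping_patience)
  ## restored weights hash the best-epoch snapshot
  expect_identical(rlang::hash(list(fit$par, fit$bn)), fit$best_hash)

  ## patience 0: stops right after the first epoch that fails to improve
  cfg0 <- tiny_cfg(seed = 3)
  cfg0$max_epochs <- 50L; cfg0$early_stopping_patience <- 0L
  fit0 <- train_model(build_model(cfg0), sim$pairs)
  expect_identical(fit0$stopped_epoch - fit0$best_epoch, 1L)

  ## single-class training data is refused
  one_class <- sim$pairs[sim$pairs$label == 1, ]
  expect_error(train_model(build_model(cfg), one_class),
               class = "backsplicer_degenerate_labels")
})

test_that("training is reproducible for a fixed seed", {
  sim <- tiny_sim(20, seed = 10)
  f1 <- train_model(build_model(tiny_cfg(seed = 21)), sim$pairs)
  f2 <- train_model(build_model(tiny_cfg(seed = 21)), sim$pairs)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$history, f2$history)
})

test_that("a hand-built kernel fires exactly on its consensus sites", {
  consensus <- "ACGUACGU"
  cfg <- model_config(conv1_kernels = 2, conv1_size = 8, conv2_kernels = 2,
                      conv2_size = 5, seed = 1)
  m <- build_model(cfg)
  idx <- match(strsplit(consensus, "")[[1]], c("A", "C", "G", "U"))
  W <- matrix(0, 8 * 4, 2)
  W[cbind((seq_len(8) - 1) * 4 + idx, 1L)] <- 1
  m$par$W1_sa <- W
  m$par$b1_sa <- c(-7.5, 0)  # full 8/8 match scores 0.5, 7/8 scores -0.5

  win <- paste0(strrep("G", 20), consensus, strrep("G", 72))
  pairs <- tibble::tibble(id = "x", sa_seq = win, sd_seq = strrep("A", 100),
                          label = 1L)
  cmem <- first_layer_activations(m, pairs, "SA")
  expect_true(all(cmem$scores >= 0))
  expect_identical(dim(cmem$scores), c(93L, 2L, 1L))
  fires <- which(cmem$scores[, 1, 1] > 0)
  expect_identical(fires, 21L)  # 0-based start 20
  expect_equal(cmem$scores[21, 1, 1], 0.5)
})

test_that("first-layer activations agree with a brute-force scan", {
  sim <- tiny_sim(8, seed = 19)
  cfg <- model_config(conv1_kernels = 3, conv1_size = 5, conv2_kernels = 2,
                      conv2_size = 4, seed = 7)
  m <- build_model(cfg)
  cmem <- first_layer_activations(m, sim$pairs, "SD")
  for (b in c(1L, 5L)) {
    ref <- brute_conv1(sim$pairs$sd_seq[b], m$par$W1_sd, m$par$b1_sd, 5L)
    expect_equal(cmem$scores[, , b], ref, tolerance = 1e-12)
  }
})
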