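test_that("a zero-parameter RBM is uniform over all configurations", {
  lay <- rbm_layer(3, 2, seed = 1)
  lay$W[] <- 0; lay$b[] <- 0; lay$c[] <- 0
  en <- rbm_enumerate(lay)
  expect_equal(en$prob, rep(1 / 2^5, 2^5))
  expect_equal(rbm_energy(lay, c(1, 0, 1), c(1, 1)), 0)
})

test_that("the enumerated joint distribution normalizes and is sign-symmetric", {
  lay <- rbm_layer(2, 2, seed = 3, init_sd = 0.5)
  lay$b <- c(0.2, -0.1); lay$c <- c(0.05, 0.3)
  en <- rbm_enumerate(lay)
  expect_equal(sum(en$prob), 1, tolerance = 1e-12)
  expect_identical(length(en$prob), 16L)
  # the bijection h -> 1-h maps an RBM (W, b, c) onto (-W, b + rowSums(W), -c)
  # up to the constant factor exp(sum(c)); the partition functions obey
  # Y(W, b, c) = exp(sum(c)) * Y(-W, b + W 1, -c)
  lay1 <- lay
  lay1$W <- -lay$W; lay1$b <- lay$b + rowSums(lay$W); lay1$c <- -lay$c
  expect_equal(rbm_enumerate(lay)$Y,
               exp(sum(lay$c)) * rbm_enumerate(lay1)$Y, tolerance = 1e-10)
  expect_error(rbm_energy(lay, c(1, 0, 1), c(1, 1)), "shape")
})

test_that("the exact likelihood gradient matches analytic expected statistics", {
  # 4 visible x 3 hidden toy RBM: compare the enumerated model expectation
  # E[v h'] against the analytic sum over visibles of p(v) v p(h=1|v)'
  lay <- rbm_layer(4, 3, seed = 9, init_sd = 0.4)
  lay$b <- seq(-0.2, 0.1, length.out = 4); lay$c <- c(0.1, 0, -0.3)
  en <- rbm_enumerate(lay)
  pv <- matrix(en$prob, nrow(en$visible), nrow(en$hidden))
  e_joint <- matrix(0, 4, 3)
  for (i in seq_len(nrow(en$visible))) for (j in seq_len(nrow(en$hidden)))
    e_joint <- e_joint + pv[i, j] * en$visible[i, ] %o% en$hidden[j, ]
  p_marg <- rowSums(pv)
  e_analytic <- matrix(0, 4, 3)
  for (i in seq_len(nrow(en$visible))) {
    ph <- mndpipe:::rbm_hidden_prob(lay, matrix(en$visible[i, ], 1))
    e_analytic <- e_analytic + p_marg[i] * en$visible[i, ] %o% as.numeric(ph)
  }
  expect_equal(e_joint, e_analytic, tolerance = 1e-8)
})

test_that("contrastive divergence reduces reconstruction error on structured data", {
  make_protos <- function(seed, n = 200) {
    set.seed(seed)
    protos <- rbind(rep(c(1, 0), each = 8), rep(c(0, 1), each = 8))
    x <- protos[sample(1:2, n, replace = TRUE), ]
    flip <- matrix(runif(n * 16) < 0.05, n, 16)
    abs(x - flip)
  }
  improved <- sapply(1:10, function(s) {
    lay <- rbm_layer(16, 8, seed = s)
    tr <- rbm_train(lay, make_protos(s), cd_k = 1, epochs = 30, lr = 0.05, seed = s)
    h <- attr(tr, "recon_error")
    tail(h, 1) < h[1]
  })
  expect_true(all(improved))
  # zero learning rate freezes the error
  lay <- rbm_layer(16, 8, seed = 1)
  tr0 <- rbm_train(lay, make_protos(1), epochs = 5, lr = 0, seed = 1)
  h0 <- attr(tr0, "recon_error")
  expect_equal(max(h0) - min(h0), 0, tolerance = 1e-12)
  # CD-1 and CD-5 both learn, with separate histories
  tr1 <- rbm_train(lay, make_protos(2), cd_k = 1, epochs = 20, seed = 2)
  tr5 <- rbm_train(lay, make_protos(2), cd_k = 5, epochs = 20, seed = 2)
  expect_lt(tail(attr(tr1, "recon_error"), 1), attr(tr1, "recon_error")[1])
  expect_lt(tail(attr(tr5, "recon_error"), 1), attr(tr5, "recon_error")[1])
})

test_that("fine-tuning recovers labels on separable features", {
  ft <- make_feature_table(400, 12, 6, seed = 21, gap = 3)
  x <- scale_unit(ft$x)
  split <- mndpipe:::stratified_folds(ft$labels, 4, seed = 1) == 1
  model <- dbn_pretrain(x[!split, ], layer_sizes = c(32, 16), epochs = 15, seed = 3)
  model <- dbn_finetune(model, x[!split, ], ft$labels[!split], epochs = 80,
                        seed = 3)
  pred <- dbn_predict(model, x[split, ])
  expect_gte(mean(pred$label == ft$labels[split]), 0.95)
  expect_true(all(diff(model$finetune_loss[c(1, 80)]) < 0))
})

test_that("fine-tuning is deterministic and a zero-epoch run leaves layers untouched", {
  ft <- make_feature_table(100, 8, 4, seed = 2, gap = 2)
  x <- scale_unit(ft$x)
  m0 <- dbn_pretrain(x, layer_sizes = c(16, 8), epochs = 5, seed = 7)
  m_zero <- dbn_finetune(m0, x, ft$labels, epochs = 0, seed = 7)
  expect_identical(m_zero$layers, m0$layers)
  expect_length(m_zero$finetune_loss, 0)
  m1 <- dbn_finetune(m0, x, ft$labels, epochs = 10, seed = 7)
  m2 <- dbn_finetune(m0, x, ft$labels, epochs = 10, seed = 7)
  expect_identical(m1$finetune_loss, m2$finetune_loss)
  expect_error(dbn_finetune(m0, x, ft$labels + 10, epochs = 1), "label")
})

test_that("prediction is simplex-valued, tie-broken low, and batch-invariant", {
  ft <- make_feature_table(50, 6, 3, seed = 4)
  x <- scale_unit(ft$x)
  m <- dbn_pretrain(x, layer_sizes = c(8, 4), epochs = 3, seed = 1)
  m <- dbn_finetune(m, x, ft$labels, epochs = 5, seed = 1)
  pr <- dbn_predict(m, x)
  expect_equal(rowSums(pr$prob), rep(1, 50), tolerance = 1e-6)
  # zero head: uniform probabilities, label 0 by the tie rule
  mz <- m; mz$head$W[] <- 0; mz$head$b[] <- 0
  pz <- dbn_predict(mz, x[1:3, ])
  expect_equal(as.numeric(pz$prob), rep(0.2, 15), tolerance = 1e-12)
  expect_identical(pz$label, rep(0L, 3))
  # duplicating a sample changes nothing about its prediction
  pd <- dbn_predict(m, x[c(1, 1, 2), ])
  expect_identical(pd$prob[1, ], pd$prob[2, ])
  expect_error(dbn_predict(m, x[, 1:3]), "mismatch")
})

test_that("unit scaling clamps to [0,1] and reuses training ranges", {
  x <- matrix(c(0, 5, 10, -2, 0, 2), 3, 2)
  s <- scale_unit(x)
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(s[, 1], c(0, 0.5, 1))
  s2 <- scale_unit(matrix(c(20, -4), 1, 2), from = s)
  expect_equal(as.numeric(s2), c(1, 0))
})
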