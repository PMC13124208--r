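test_that("channel attention matches its closed form and stays inside (0,1)", {
  C <- 8; r <- 4
  fm <- array(0.7, c(6, 6, C))           # constant map: avg pool == max pool
  set.seed(1)
  W0 <- matrix(rnorm(C * C / r, 0, 0.5), C, C / r)
  W1 <- matrix(rnorm(C / r * C, 0, 0.5), C / r, C)
  mc <- channel_attention(fm, W0, W1)
  # dense hand computation: sigmoid(2 * MLP(c * 1))
  v <- rep(0.7, C)
  hand <- 1 / (1 + exp(-2 * (pmax(v %*% W0, 0.01 * (v %*% W0)) %*% W1)))
  expect_equal(mc, as.numeric(hand), tolerance = 1e-12)
  # zero weights: sigmoid(0) = 0.5 everywhere
  expect_equal(channel_attention(fm, W0 * 0, W1 * 0), rep(0.5, C))
  # arbitrary input stays strictly inside (0,1)
  fm2 <- array(rnorm(6 * 6 * C, 0, 10), c(6, 6, C))
  mc2 <- channel_attention(fm2, W0, W1)
  expect_true(all(mc2 > 0 & mc2 < 1))
})

test_that("spatial attention has the right shape, neutral zero case, and peak routing", {
  fm <- array(0.3, c(10, 10, 4))
  w0 <- array(0, c(3, 3, 2, 1))
  expect_equal(spatial_attention(fm, w0, 0), matrix(0.5, 10, 10))
  set.seed(2)
  fm2 <- array(rnorm(10 * 10 * 4), c(10, 10, 4))
  for (k in c(3, 7)) {
    w <- array(rnorm(k * k * 2), c(k, k, 2, 1))
    expect_identical(dim(spatial_attention(fm2, w, 0.1)), c(10L, 10L))
  }
  # identity-like conv on the max map: the single bright pixel wins
  fm3 <- array(0, c(9, 9, 4)); fm3[5, 5, 2] <- 3
  wid <- array(0, c(3, 3, 2, 1)); wid[2, 2, 2, 1] <- 1
  ms <- spatial_attention(fm3, wid, 0)
  expect_identical(which(ms == max(ms)), which(matrix(seq_len(81), 9, 9) == 41))
})

test_that("the attention pair composes multiplicatively and contracts sup-norm", {
  C <- 8
  set.seed(3)
  fm <- array(runif(5 * 5 * C), c(5, 5, C))
  zero <- list(W0 = matrix(0, C, 2), b0 = 0, W1 = matrix(0, 2, C), b1 = 0,
               sw = array(0, c(3, 3, 2, 1)), sb = 0)
  expect_equal(cbam_block(fm, zero), 0.25 * fm, tolerance = 1e-12)
  # saturated attention approximates the identity
  sat <- list(W0 = matrix(0, C, 2), b0 = 0, W1 = matrix(0, 2, C), b1 = 40,
              sw = array(0, c(3, 3, 2, 1)), sb = 40)
  expect_equal(cbam_block(fm, sat), fm, tolerance = 1e-3)
  set.seed(4)
  p <- list(W0 = matrix(rnorm(C * 2), C, 2), b0 = 0,
            W1 = matrix(rnorm(2 * C), 2, C), b1 = 0,
            sw = array(rnorm(9 * 2), c(3, 3, 2, 1)), sb = 0)
  expect_lte(max(abs(cbam_block(fm, p))), max(abs(fm)))
})

test_that("forward inference yields simplex probabilities deterministically", {
  cfg <- tiny_net_config()
  net <- res4net_init(cfg)
  img <- matrix(runif(16 * 16), 16, 16)
  p1 <- res4net_predict(net, img)
  p2 <- res4net_predict(net, img)
  expect_equal(rowSums(p1$prob), 1, tolerance = 1e-6, ignore_attr = TRUE)
  expect_true(all(p1$prob >= 0))
  expect_identical(p1$prob, p2$prob)
  expect_length(p1$features, cfg$fc_units)
  # zeroed head gives equal logits, hence uniform probabilities
  net$params$out_w[] <- 0; net$params$out_b[] <- 0
  expect_equal(as.numeric(res4net_predict(net, img)$prob), rep(0.2, 5),
               tolerance = 1e-12)
})

test_that("softmax probabilities are invariant to constant logit shifts", {
  set.seed(5)
  z <- matrix(rnorm(15), 3, 5)
  expect_equal(mndpipe:::softmax_rows(z), mndpipe:::softmax_rows(z + 7.3),
               tolerance = 1e-12)
})

test_that("analytic gradients agree with finite differences on a tiny network", {
  cfg <- tiny_net_config(seed = 11)
  net <- res4net_init(cfg)
  set.seed(21)
  x <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  y <- c(1L, 4L)
  onehot <- matrix(0, 2, 5); onehot[cbind(1:2, y + 1)] <- 1
  mask <- matrix(TRUE, 2, cfg$fc_units)
  loss_of <- function(nn) {
    fwd <- mndpipe:::res4net_forward(nn, x, mode = "train", dropout_mask = mask)
    -sum(log(fwd$prob[onehot == 1])) / 2
  }
  fwd <- mndpipe:::res4net_forward(net, x, mode = "train", keep_cache = TRUE,
                                   dropout_mask = mask)
  g <- mndpipe:::res4net_backward(net, fwd$cache, (fwd$prob - onehot) / 2)
  fg <- mndpipe:::flatten_params(g)
  fp <- mndpipe:::flatten_params(net$params)
  set.seed(31)
  checks <- c("block2.c1w", "block3.caW0", "block4.saw", "fc_w", "tbn.g")
  for (key in checks) {
    i <- sample(length(fp[[key]]), 1)
    eps <- 1e-4
    up <- fp; up[[key]][i] <- up[[key]][i] + eps
    dn <- fp; dn[[key]][i] <- dn[[key]][i] - eps
    nu <- net; nu$params <- mndpipe:::unflatten_into(nu$params, up)
    nd <- net; nd$params <- mndpipe:::unflatten_into(nd$params, dn)
    num <- (loss_of(nu) - loss_of(nd)) / (2 * eps)
    expect_equal(fg[[key]][i], num, tolerance = 1e-4)
  }
})

test_that("training is seeded-deterministic and a zero learning rate freezes parameters", {
  ds <- make_dataset(2, phantom_spec(size = 16), seed = 3, modality_mode = "fixed")
  cfg <- tiny_net_config()
  cfg$dropout <- 0  # a stochastic dropout mask would vary the frozen loss
  n0 <- train_res4net(ds$images, ds$labels, cfg, epochs = 2, lr = 0,
                      batch_size = 10, seed = 5)
  init <- res4net_init({cfg2 <- cfg; cfg2$seed <- mndpipe:::derive_seed(5, 1); cfg2})
  expect_equal(mndpipe:::flatten_params(n0$params),
               mndpipe:::flatten_params(init$params), tolerance = 1e-12)
  expect_equal(n0$history$loss[1], n0$history$loss[2], tolerance = 1e-9)
  n1 <- train_res4net(ds$images, ds$labels, cfg, epochs = 2, lr = 1e-3,
                      batch_size = 5, seed = 9)
  n2 <- train_res4net(ds$images, ds$labels, cfg, epochs = 2, lr = 1e-3,
                      batch_size = 5, seed = 9)
  expect_identical(n1$history, n2$history)
  expect_error(train_res4net(ds$images[1:2], c(0L, 0L), cfg), "2 classes")
})

test_that("the extractor separates constructed-separable phantoms", {
  ds <- make_dataset(6, phantom_spec(size = 32, contrast = 1), seed = 17,
                     modality_mode = "fixed")
  cfg <- net_config(input_size = 32L, block_channels = c(16L, 16L, 32L, 32L),
                    reduction_ratio = 4L, spatial_kernel = 3L, seed = 1L)
  net <- train_res4net(ds$images, ds$labels, cfg, epochs = 20, lr = 2e-3,
                       batch_size = 10, seed = 2)
  expect_gte(tail(net$history$accuracy, 1), 0.9)
  expect_lt(tail(net$history$loss, 1), net$history$loss[1])
  f <- extract_features(net, ds$images)
  expect_identical(dim(f), c(30L, cfg$fc_units))
  expect_true(all(is.finite(f)))
  expect_identical(dim(attr(f, "gap")), c(30L, 32L))
})
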