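#' Residual attention network configuration
#'
#' Architecture: a 7x7 stride-2 convolutional stem, a batch-norm +
#' LeakyReLU transition, four stride-2 residual blocks (two 3x3 conv + BN
#' layers each, convolutional skip) each followed by a convolutional block
#' attention module (channel then spatial attention), global average
#' pooling, a 32-unit fully connected layer with 30\% dropout, and a
#' 5-class softmax. The attention output of each block is multiplied with
#' that block's output and added to it before entering the next block.
#'
#' @param input_size input image side (default 128)
#' @param input_channels input channels (default 3; grayscale images are
#'   replicated)
#' @param block_channels output channels of the four residual blocks
#' @param reduction_ratio channel-attention MLP bottleneck divisor
#' @param spatial_kernel spatial-attention convolution size (odd)
#' @param leaky_slope LeakyReLU negative slope
#' @param fc_units penultimate fully connected width (default 32; this
#'   layer's activations are the per-image feature vector)
#' @param dropout dropout rate before the softmax head (default 0.30)
#' @param n_classes number of classes (default 5)
#' @param seed seed for parameter initialization
#' @return a `net_config` list
#' @export
net_config <- function(input_size = 128L, input_channels = 3L,
                       block_channels = c(32L, 64L, 128L, 256L),
                       reduction_ratio = 8L, spatial_kernel = 7L,
                       leaky_slope = 0.01, fc_units = 32L, dropout = 0.30,
                       n_classes = 5L, seed = 1L) {
  if (length(block_channels) != 4) stop("net_config: need 4 block channel widths")
  if (any(block_channels %% reduction_ratio != 0))
    stop("net_config: block channels must be divisible by reduction_ratio")
  if (spatial_kernel %% 2 != 1) stop("net_config: spatial_kernel must be odd")
  structure(list(input_size = as.integer(input_size),
                 input_channels = as.integer(input_channels),
                 stem_channels = as.integer(block_channels[1]),
                 block_channels = as.integer(block_channels),
                 reduction_ratio = as.integer(reduction_ratio),
                 spatial_kernel = as.integer(spatial_kernel),
                 leaky_slope = leaky_slope, fc_units = as.integer(fc_units),
                 dropout = dropout, n_classes = as.integer(n_classes),
                 seed = as.integer(seed)),
            class = "net_config")
}

# ---- low-level helpers -----------------------------------------------------

leaky <- function(x, slope) ifelse(x > 0, x, slope * x)
leaky_grad <- function(pre, slope) ifelse(pre > 0, 1, slope)

# scale channel c of an (H,W,C,N) array by v[c]
ch_scale <- function(x, v) {
  d <- dim(x)
  m <- matrix(x, d[1] * d[2])
  m <- sweep(m, 2, rep(v, times = d[4]), "*")
  array(m, d)
}

# per-channel mean over (H,W,N)
ch_mean <- function(x) {
  d <- dim(x)
  rowMeans(matrix(colMeans(matrix(x, d[1] * d[2])), d[3], d[4]))
}

he_init <- function(dims, fan_in) array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)

bn_new <- function(C) list(g = rep(1, C), b = numeric(C))
bn_state_new <- function(C) list(rm = numeric(C), rv = rep(1, C))

# Batch normalization over (H,W,N) per channel.
bn_forward <- function(x, g, b, st, training, momentum = 0.9, eps = 1e-5) {
  if (training) {
    mu <- ch_mean(x)
    xc <- x - array(rep(rep(mu, each = dim(x)[1] * dim(x)[2]), times = dim(x)[4]), dim(x))
    va <- ch_mean(xc * xc)
    st$rm <- momentum * st$rm + (1 - momentum) * mu
    st$rv <- momentum * st$rv + (1 - momentum) * va
  } else {
    mu <- st$rm; va <- st$rv
    xc <- x - array(rep(rep(mu, each = dim(x)[1] * dim(x)[2]), times = dim(x)[4]), dim(x))
  }
  inv <- 1 / sqrt(va + eps)
  xhat <- ch_scale(xc, inv)
  y <- ch_scale(xhat, g)
  y <- y + array(rep(rep(b, each = dim(x)[1] * dim(x)[2]), times = dim(x)[4]), dim(x))
  list(y = y, cache = list(xhat = xhat, inv = inv, g = g), state = st)
}

bn_backward <- function(dy, cache) {
  d <- dim(dy)
  m <- d[1] * d[2] * d[4]
  xhat <- cache$xhat
  dg <- ch_mean(dy * xhat) * m
  db <- ch_mean(dy) * m
  dxhat <- ch_scale(dy, cache$g)
  mean_dxhat <- ch_mean(dxhat)
  mean_dxhat_xhat <- ch_mean(dxhat * xhat)
  t1 <- dxhat -
    array(rep(rep(mean_dxhat, each = d[1] * d[2]), times = d[4]), d) -
    xhat * array(rep(rep(mean_dxhat_xhat, each = d[1] * d[2]), times = d[4]), d)
  dx <- ch_scale(t1, cache$inv)
  list(dx = dx, dg = dg, db = db)
}

# channel-wise spatial pooling: returns (N x C) matrices of means and maxes
# plus the argmax indices needed for the backward pass
pool_spatial <- function(x) {
  d <- dim(x)
  m <- matrix(x, d[1] * d[2])              # HW x (C*N)
  avg <- t(matrix(colMeans(m), d[3], d[4]))  # N x C
  amax_idx <- max.col(t(m), ties.method = "first")
  mx <- t(matrix(m[cbind(amax_idx, seq_len(ncol(m)))], d[3], d[4]))
  list(avg = avg, max = mx, argmax = amax_idx)
}

# per-pixel channel pooling: (H,W,1,N) mean and max maps + argmax channel
pool_channel <- function(x) {
  d <- dim(x)
  m <- matrix(x, d[1] * d[2])
  avg <- array(0, c(d[1], d[2], 1, d[4]))
  mx <- array(0, c(d[1], d[2], 1, d[4]))
  amax <- array(1L, c(d[1], d[2], 1, d[4]))
  for (n in seq_len(d[4])) {
    cols <- (n - 1L) * d[3] + seq_len(d[3])
    sub <- m[, cols, drop = FALSE]
    avg[, , 1, n] <- rowMeans(sub)
    cur <- sub[, 1]; curi <- rep(1L, nrow(sub))
    if (d[3] > 1) for (cc in 2:d[3]) {
      better <- sub[, cc] > cur
      cur[better] <- sub[better, cc]; curi[better] <- cc
    }
    mx[, , 1, n] <- cur
    amax[, , 1, n] <- curi
  }
  list(avg = avg, max = mx, argmax = amax)
}

# ---- attention modules (exported single-image API + batch internals) -------

#' Channel attention map
#'
#' `M_c = sigmoid(MLP(avg-pooled channels) + MLP(max-pooled channels))`,
#' with a shared two-layer MLP (`W0` reduces, LeakyReLU, `W1` expands)
#' applied to both pooled vectors. All outputs are strictly inside (0, 1).
#'
#' @param fm feature map, array `(H, W, C)` or `(H, W, C, N)`
#' @param W0 reduction weights (`C x C/r`)
#' @param W1 expansion weights (`C/r x C`)
#' @param b0,b1 biases (default 0)
#' @param slope LeakyReLU negative slope
#' @return per-channel weights in (0, 1): a vector for a single map, an
#'   `N x C` matrix for a batch
#' @export
channel_attention <- function(fm, W0, W1, b0 = 0, b1 = 0, slope = 0.01) {
  single <- length(dim(fm)) == 3
  if (single) dim(fm) <- c(dim(fm), 1L)
  if (dim(fm)[3] != nrow(W0)) stop("channel_attention: shape mismatch")
  ps <- pool_spatial(fm)
  b0 <- rep_len(b0, ncol(W0)); b1 <- rep_len(b1, ncol(W1))
  mlp <- function(v) sweep(leaky(sweep(v %*% W0, 2, b0, "+"), slope) %*% W1, 2, b1, "+")
  mc <- sigmoid(mlp(ps$avg) + mlp(ps$max))
  if (single) as.numeric(mc) else mc
}

#' Spatial attention map
#'
#' Concatenates the channel-wise average and maximum maps into a 2-channel
#' image, convolves with a `k x k` filter (same padding) and applies the
#' sigmoid.
#'
#' @param fm feature map `(H, W, C)` or `(H, W, C, N)`
#' @param conv_w convolution weights `(k, k, 2, 1)`
#' @param conv_b convolution bias (scalar)
#' @return per-pixel weights in (0, 1): `H x W` matrix for a single map,
#'   `(H, W, 1, N)` array for a batch
#' @export
spatial_attention <- function(fm, conv_w, conv_b = 0) {
  single <- length(dim(fm)) == 3
  if (single) dim(fm) <- c(dim(fm), 1L)
  pc <- pool_channel(fm)
  d <- dim(fm)
  cat2 <- array(0, c(d[1], d[2], 2, d[4]))
  cat2[, , 1, ] <- pc$avg; cat2[, , 2, ] <- pc$max
  k <- dim(conv_w)[1]
  z <- conv2d_forward(cat2, conv_w, as.numeric(conv_b), 1L, (k - 1L) %/% 2L)
  ms <- sigmoid(z)
  if (single) matrix(ms, d[1], d[2]) else ms
}

#' Apply a CBAM attention pair to a feature map
#'
#' `F' = M_c (x) F` (broadcast over space), then `F'' = M_s (x) F'`
#' (broadcast over channels).
#'
#' @param fm feature map `(H, W, C)`
#' @param params list with `W0`, `b0`, `W1`, `b1` (channel MLP) and
#'   `sw`, `sb` (spatial convolution)
#' @param slope LeakyReLU negative slope in the channel MLP
#' @return attended feature map, same shape as `fm`
#' @export
cbam_block <- function(fm, params, slope = 0.01) {
  mc <- channel_attention(fm, params$W0, params$W1, params$b0, params$b1, slope)
  f1 <- fm * array(rep(mc, each = dim(fm)[1] * dim(fm)[2]), dim(fm))
  ms <- spatial_attention(f1, params$sw, params$sb)
  f1 * array(ms, dim(fm))
}

# ---- network construction --------------------------------------------------

#' Initialize a residual attention network
#'
#' He-initialized convolution and linear weights, unit-gain batch norms,
#' all seeded.
#'
#' @param config a [net_config()]
#' @return a `res4net` list: `config`, `params` (trainable arrays),
#'   `state` (batch-norm running statistics)
#' @export
res4net_init <- function(config = net_config()) {
  cfg <- config
  with_seed(cfg$seed, {
    p <- list(); s <- list()
    C0 <- cfg$stem_channels
    p$stem_w <- he_init(c(7, 7, cfg$input_channels, C0), 7 * 7 * cfg$input_channels)
    p$stem_b <- numeric(C0)
    p$tbn <- bn_new(C0); s$tbn <- bn_state_new(C0)
    cin <- C0
    for (i in 1:4) {
      ci <- cfg$block_channels[i]
      bl <- list(
        c1w = he_init(c(3, 3, cin, ci), 9 * cin), c1b = numeric(ci),
        bn1 = bn_new(ci),
        c2w = he_init(c(3, 3, ci, ci), 9 * ci), c2b = numeric(ci),
        bn2 = bn_new(ci),
        skw = he_init(c(1, 1, cin, ci), cin), skb = numeric(ci),
        sbn = bn_new(ci),
        caW0 = he_init(c(ci, ci %/% cfg$reduction_ratio), ci),
        cab0 = numeric(ci %/% cfg$reduction_ratio),
        caW1 = he_init(c(ci %/% cfg$reduction_ratio, ci), ci %/% cfg$reduction_ratio),
        cab1 = numeric(ci),
        saw = he_init(c(cfg$spatial_kernel, cfg$spatial_kernel, 2, 1),
                      2 * cfg$spatial_kernel^2),
        sab = 0)
      p[[paste0("block", i)]] <- bl
      s[[paste0("block", i)]] <- list(bn1 = bn_state_new(ci),
                                      bn2 = bn_state_new(ci),
                                      sbn = bn_state_new(ci))
      cin <- ci
    }
    p$fc_w <- he_init(c(cin, cfg$fc_units), cin)
    p$fc_b <- numeric(cfg$fc_units)
    p$out_w <- he_init(c(cfg$fc_units, cfg$n_classes), cfg$fc_units)
    p$out_b <- numeric(cfg$n_classes)
    structure(list(config = cfg, params = p, state = s), class = "res4net")
  })
}

# label-preserving augmentation: horizontal flip + integer translation with
# edge replication (the class signature is a horizontal band, so vertical
# flips would not be label-preserving and are not used)
augment_batch <- function(xb, max_shift = 3L) {
  d <- dim(xb)
  for (n in seq_len(d[4])) {
    if (runif(1) < 0.5) xb[, , , n] <- xb[, d[2]:1, , n]
    dy <- sample(-max_shift:max_shift, 1)
    dx <- sample(-max_shift:max_shift, 1)
    ri <- pmin(pmax(seq_len(d[1]) + dy, 1L), d[1])
    ci <- pmin(pmax(seq_len(d[2]) + dx, 1L), d[2])
    xb[, , , n] <- xb[ri, ci, , n]
  }
  xb
}

# bilinear resize of a matrix to n x n
resize_bilinear <- function(x, n) {
  h <- nrow(x); w <- ncol(x)
  if (h == n && w == n) return(x)
  yi <- seq(1, h, length.out = n); xi <- seq(1, w, length.out = n)
  y0 <- pmin(floor(yi), h - 1); x0 <- pmin(floor(xi), w - 1)
  fy <- yi - y0; fx <- xi - x0
  a <- x[y0, x0] * outer(1 - fy, 1 - fx) + x[y0 + 1, x0] * outer(fy, 1 - fx) +
    x[y0, x0 + 1] * outer(1 - fy, fx) + x[y0 + 1, x0 + 1] * outer(fy, fx)
  a
}

#' Assemble an input batch for the network
#'
#' Accepts a list of images (matrices, [intensity_image()]s, or
#' `(H, W, 3)` arrays), resizes to the configured input side, and
#' replicates grayscale to the configured channel count.
#'
#' @param images list of images (or a single image)
#' @param config a [net_config()]
#' @return `(size, size, channels, N)` array
#' @export
prep_input <- function(images, config) {
  if (!is.list(images)) images <- list(images)
  n <- length(images)
  sz <- config$input_size
  x <- array(0, c(sz, sz, config$input_channels, n))
  for (i in seq_len(n)) {
    im <- images[[i]]
    if (length(dim(im)) == 3) {
      for (ch in seq_len(config$input_channels))
        x[, , ch, i] <- resize_bilinear(im[, , min(ch, dim(im)[3])], sz)
    } else {
      g <- resize_bilinear(img_pixels(im), sz)
      for (ch in seq_len(config$input_channels)) x[, , ch, i] <- g
    }
  }
  x
}

bcast_sp <- function(mat, d) array(rep(t(mat), each = d[1] * d[2]), d)

# broadcast an (H,W,1,N) map over C channels
bcast_ch <- function(map, C) map[, , rep(1L, C), , drop = FALSE]

# Full forward pass over a batch. mode "train" uses batch statistics and
# dropout; caches every intermediate needed for the backward pass.
res4net_forward <- function(net, x, mode = c("eval", "train"),
                            keep_cache = FALSE, dropout_mask = NULL) {
  mode <- match.arg(mode)
  training <- mode == "train"
  cfg <- net$config; p <- net$params; s <- net$state
  slope <- cfg$leaky_slope
  cache <- list(x = x)

  z <- conv2d_forward(x, p$stem_w, p$stem_b, 2L, 3L)
  bn <- bn_forward(z, p$tbn$g, p$tbn$b, s$tbn, training)
  s$tbn <- bn$state
  cache$stem <- list(z = bn$y, bn = bn$cache)
  a <- leaky(bn$y, slope)
  cache$trans_out <- a

  for (i in 1:4) {
    bl <- p[[paste0("block", i)]]
    st <- s[[paste0("block", i)]]
    bc <- list(x_in = a)
    z1 <- conv2d_forward(a, bl$c1w, bl$c1b, 2L, 1L)
    b1 <- bn_forward(z1, bl$bn1$g, bl$bn1$b, st$bn1, training)
    st$bn1 <- b1$state
    r1 <- leaky(b1$y, slope)
    z2 <- conv2d_forward(r1, bl$c2w, bl$c2b, 1L, 1L)
    b2 <- bn_forward(z2, bl$bn2$g, bl$bn2$b, st$bn2, training)
    st$bn2 <- b2$state
    zk <- conv2d_forward(a, bl$skw, bl$skb, 2L, 0L)
    bk <- bn_forward(zk, bl$sbn$g, bl$sbn$b, st$sbn, training)
    st$sbn <- bk$state
    ssum <- b2$y + bk$y
    Fm <- leaky(ssum, slope)
    d <- dim(Fm)

    # channel attention
    ps <- pool_spatial(Fm)
    pre_a <- sweep(ps$avg %*% bl$caW0, 2, bl$cab0, "+")
    pre_m <- sweep(ps$max %*% bl$caW0, 2, bl$cab0, "+")
    h_a <- leaky(pre_a, slope); h_m <- leaky(pre_m, slope)
    mc <- sigmoid(sweep(h_a %*% bl$caW1, 2, bl$cab1, "+") +
                  sweep(h_m %*% bl$caW1, 2, bl$cab1, "+"))
    F1 <- Fm * bcast_sp(mc, d)
    # spatial attention
    pc <- pool_channel(F1)
    cat2 <- array(0, c(d[1], d[2], 2, d[4]))
    cat2[, , 1, ] <- pc$avg; cat2[, , 2, ] <- pc$max
    kpad <- (cfg$spatial_kernel - 1L) %/% 2L
    zs <- conv2d_forward(cat2, bl$saw, bl$sab, 1L, kpad)
    ms <- sigmoid(zs)
    F2 <- F1 * bcast_ch(ms, d[3])
    a_next <- Fm * F2 + Fm

    if (keep_cache) {
      bc$b1 <- b1$cache; bc$b2 <- b2$cache; bc$bk <- bk$cache
      bc$z1pre <- b1$y; bc$r1 <- r1; bc$ssum <- ssum; bc$Fm <- Fm
      bc$ps <- ps; bc$pre_a <- pre_a; bc$pre_m <- pre_m
      bc$h_a <- h_a; bc$h_m <- h_m; bc$mc <- mc; bc$F1 <- F1
      bc$pc <- pc; bc$cat2 <- cat2; bc$ms <- ms; bc$F2 <- F2
      cache[[paste0("block", i)]] <- bc
    }
    s[[paste0("block", i)]] <- st
    a <- a_next
  }

  d <- dim(a)
  gap <- t(matrix(colMeans(matrix(a, d[1] * d[2])), d[3], d[4]))  # N x C
  fc_pre <- sweep(gap %*% p$fc_w, 2, p$fc_b, "+")
  feat <- leaky(fc_pre, slope)
  if (training) {
    if (is.null(dropout_mask))
      dropout_mask <- matrix(runif(length(feat)) >= cfg$dropout,
                             nrow(feat), ncol(feat))
    dropped <- feat * dropout_mask / (1 - cfg$dropout)
  } else {
    dropout_mask <- NULL
    dropped <- feat
  }
  logits <- sweep(dropped %*% p$out_w, 2, p$out_b, "+")
  prob <- softmax_rows(logits)
  if (keep_cache) {
    cache$top_in <- a; cache$gap <- gap; cache$fc_pre <- fc_pre
    cache$feat <- feat; cache$dropped <- dropped
    cache$dropout_mask <- dropout_mask
  }
  list(prob = prob, logits = logits, features = feat, gap = gap,
       cache = if (keep_cache) cache else NULL, state = s)
}

# Backward pass: given dlogits, return gradients for every trainable array.
res4net_backward <- function(net, cache, dlogits) {
  cfg <- net$config; p <- net$params
  slope <- cfg$leaky_slope
  g <- list()
  g$out_w <- crossprod(cache$dropped, dlogits)
  g$out_b <- colSums(dlogits)
  ddropped <- dlogits %*% t(p$out_w)
  dfeat <- if (!is.null(cache$dropout_mask))
    ddropped * cache$dropout_mask / (1 - cfg$dropout) else ddropped
  dfc_pre <- dfeat * leaky_grad(cache$fc_pre, slope)
  g$fc_w <- crossprod(cache$gap, dfc_pre)
  g$fc_b <- colSums(dfc_pre)
  dgap <- dfc_pre %*% t(p$fc_w)               # N x C
  d <- dim(cache$top_in)
  da <- bcast_sp(dgap, d) / (d[1] * d[2])

  for (i in 4:1) {
    bl <- p[[paste0("block", i)]]
    bc <- cache[[paste0("block", i)]]
    d <- dim(bc$Fm)
    HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
    dF2 <- da * bc$Fm
    dFm <- da * (bc$F2 + 1)
    # spatial attention backward
    dMs_full <- dF2 * bc$F1
    dMs <- array(0, c(d[1], d[2], 1, N))
    m <- matrix(dMs_full, HW)
    for (n in seq_len(N)) dMs[, , 1, n] <- rowSums(m[, (n - 1L) * C + seq_len(C), drop = FALSE])
    dF1 <- dF2 * bcast_ch(bc$ms, C)
    dzs <- dMs * bc$ms * (1 - bc$ms)
    kpad <- (cfg$spatial_kernel - 1L) %/% 2L
    cb <- conv2d_backward(bc$cat2, bl$saw, dzs, 1L, kpad)
    gb <- list(saw = cb$dw, sab = cb$db)
    dcat <- cb$dx
    davg_map <- dcat[, , 1, , drop = FALSE]
    dmax_map <- dcat[, , 2, , drop = FALSE]
    dF1 <- dF1 + bcast_ch(davg_map, C) / C
    # route channel-max gradients to the argmax channel
    mmax <- matrix(0, HW, C * N)
    for (n in seq_len(N)) {
      idx <- as.integer(bc$pc$argmax[, , 1, n])
      mmax[cbind(seq_len(HW), (n - 1L) * C + idx)] <- as.numeric(dmax_map[, , 1, n])
    }
    dF1 <- dF1 + array(mmax, d)
    # channel attention backward
    dmc <- t(matrix(colSums(matrix(dF1 * bc$Fm, HW)), C, N))  # N x C
    dFm <- dFm + dF1 * bcast_sp(bc$mc, d)
    dsig <- dmc * bc$mc * (1 - bc$mc)
    gb$caW1 <- crossprod(bc$h_a, dsig) + crossprod(bc$h_m, dsig)
    gb$cab1 <- 2 * colSums(dsig)
    dh_a <- dsig %*% t(bl$caW1); dh_m <- dsig %*% t(bl$caW1)
    dpre_a <- dh_a * leaky_grad(bc$pre_a, slope)
    dpre_m <- dh_m * leaky_grad(bc$pre_m, slope)
    gb$caW0 <- crossprod(bc$ps$avg, dpre_a) + crossprod(bc$ps$max, dpre_m)
    gb$cab0 <- colSums(dpre_a) + colSums(dpre_m)
    davgc <- dpre_a %*% t(bl$caW0)            # N x C
    dmaxc <- dpre_m %*% t(bl$caW0)
    dFm <- dFm + bcast_sp(davgc, d) / HW
    madd <- matrix(0, HW, C * N)
    madd[cbind(bc$ps$argmax, seq_len(C * N))] <- as.numeric(t(dmaxc))
    dFm <- dFm + array(madd, d)
    # residual block backward
    dssum <- dFm * leaky_grad(bc$ssum, slope)
    bb2 <- bn_backward(dssum, bc$b2)
    gb$bn2 <- list(g = bb2$dg, b = bb2$db)
    cb2 <- conv2d_backward(bc$r1, bl$c2w, bb2$dx, 1L, 1L)
    gb$c2w <- cb2$dw; gb$c2b <- cb2$db
    dr1 <- cb2$dx * leaky_grad(bc$z1pre, slope)
    bb1 <- bn_backward(dr1, bc$b1)
    gb$bn1 <- list(g = bb1$dg, b = bb1$db)
    cb1 <- conv2d_backward(bc$x_in, bl$c1w, bb1$dx, 2L, 1L)
    gb$c1w <- cb1$dw; gb$c1b <- cb1$db
    bbk <- bn_backward(dssum, bc$bk)
    gb$sbn <- list(g = bbk$dg, b = bbk$db)
    cbk <- conv2d_backward(bc$x_in, bl$skw, bbk$dx, 2L, 0L)
    gb$skw <- cbk$dw; gb$skb <- cbk$db
    da <- cb1$dx + cbk$dx
    g[[paste0("block", i)]] <- gb
  }

  dtrans <- da * leaky_grad(cache$stem$z, cfg$leaky_slope)
  bbt <- bn_backward(dtrans, cache$stem$bn)
  g$tbn <- list(g = bbt$dg, b = bbt$db)
  cbs <- conv2d_backward(cache$x, p$stem_w, bbt$dx, 2L, 3L)
  g$stem_w <- cbs$dw; g$stem_b <- cbs$db
  g
}

# flatten nested parameter/gradient lists into a named list of arrays
flatten_params <- function(p, prefix = "") {
  out <- list()
  for (nm in names(p)) {
    v <- p[[nm]]
    key <- paste0(prefix, nm)
    if (is.list(v)) out <- c(out, flatten_params(v, paste0(key, ".")))
    else out[[key]] <- v
  }
  out
}

unflatten_into <- function(p, flat, prefix = "") {
  for (nm in names(p)) {
    v <- p[[nm]]
    key <- paste0(prefix, nm)
    if (is.list(v)) p[[nm]] <- unflatten_into(v, flat, paste0(key, "."))
    else p[[nm]] <- flat[[key]]
  }
  p
}

#' Train the residual attention network
#'
#' Minibatch Adam on the softmax cross-entropy, fully seeded (parameter
#' initialization, shuffling and dropout all derive from `seed`), so a
#' repeated call reproduces the same history and parameters.
#'
#' @param images list of images (see [prep_input()])
#' @param labels integer class labels `0..n_classes-1`
#' @param config a [net_config()]
#' @param epochs training epochs
#' @param lr Adam learning rate (default 1e-3)
#' @param batch_size minibatch size
#' @param seed RNG seed
#' @param net optional pre-initialized `res4net` to continue training
#' @param augment apply label-preserving train-time augmentation (random
#'   horizontal flips and integer translations up to 3 px, edge-replicated);
#'   off by default
#' @param verbose print per-epoch progress
#' @return a trained `res4net`; `$history` holds per-epoch mean loss and
#'   training accuracy
#' @export
train_res4net <- function(images, labels, config = net_config(), epochs = 10L,
                          lr = 1e-3, batch_size = 10L, seed = 1L, net = NULL,
                          augment = FALSE, verbose = FALSE) {
  if (length(unique(labels)) < 2) stop("train_res4net: need at least 2 classes")
  if (is.null(net)) {
    config$seed <- derive_seed(seed, 1)
    net <- res4net_init(config)
  }
  x_all <- prep_input(images, net$config)
  n <- length(labels)
  K <- net$config$n_classes
  adam_m <- NULL; adam_v <- NULL; tstep <- 0
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
  loss_hist <- numeric(epochs); acc_hist <- numeric(epochs)
  with_seed(derive_seed(seed, 2), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = batch_size)
      tot_loss <- 0; tot_correct <- 0
      for (sidx in starts) {
        idx <- ord[sidx:min(sidx + batch_size - 1, n)]
        xb <- x_all[, , , idx, drop = FALSE]
        if (augment) xb <- augment_batch(xb)
        yb <- labels[idx]
        m <- length(idx)
        fwd <- res4net_forward(net, xb, mode = "train", keep_cache = TRUE)
        net$state <- fwd$state
        onehot <- matrix(0, m, K)
        onehot[cbind(seq_len(m), yb + 1L)] <- 1
        tot_loss <- tot_loss - sum(log(pmax(fwd$prob[onehot == 1], 1e-12)))
        tot_correct <- tot_correct + sum(max.col(fwd$prob, ties.method = "first") - 1L == yb)
        grads <- res4net_backward(net, fwd$cache, (fwd$prob - onehot) / m)
        fg <- flatten_params(grads)
        fp <- flatten_params(net$params)
        if (is.null(adam_m)) {
          adam_m <- lapply(fp, function(z) z * 0)
          adam_v <- lapply(fp, function(z) z * 0)
        }
        tstep <- tstep + 1
        for (key in names(fp)) {
          gk <- fg[[key]]
          if (is.null(gk)) next
          adam_m[[key]] <- beta1 * adam_m[[key]] + (1 - beta1) * gk
          adam_v[[key]] <- beta2 * adam_v[[key]] + (1 - beta2) * gk^2
          mhat <- adam_m[[key]] / (1 - beta1^tstep)
          vhat <- adam_v[[key]] / (1 - beta2^tstep)
          fp[[key]] <- fp[[key]] - lr * mhat / (sqrt(vhat) + adam_eps)
        }
        net$params <- unflatten_into(net$params, fp)
      }
      loss_hist[ep] <- tot_loss / n
      acc_hist[ep] <- tot_correct / n
      if (verbose)
        message(sprintf("epoch %d: loss %.4f acc %.3f", ep, loss_hist[ep], acc_hist[ep]))
    }
  })
  net$history <- list(loss = loss_hist, accuracy = acc_hist)
  net
}

#' Forward inference on one or more images
#'
#' Deterministic evaluation-mode pass: batch-norm uses running statistics
#' and dropout is off.
#'
#' @param net a `res4net`
#' @param images list of images or a single image
#' @return list: `prob` (N x classes), `label` (argmax indices),
#'   `features` (N x fc_units penultimate activations), `gap`
#'   (N x last-block-channels pooled activations)
#' @export
res4net_predict <- function(net, images) {
  x <- prep_input(images, net$config)
  fwd <- res4net_forward(net, x, mode = "eval")
  list(prob = fwd$prob, label = max.col(fwd$prob, ties.method = "first") - 1L,
       features = fwd$features, gap = fwd$gap)
}

#' Extract per-image feature vectors
#'
#' Evaluation-mode forward passes returning the 32-unit penultimate
#' activations (and, as an attribute, the global-average-pooled
#' activations).
#'
#' @param net a `res4net`
#' @param images list of images
#' @param batch_size images per forward pass
#' @return `N x fc_units` feature matrix with attribute `"gap"`
#' @export
extract_features <- function(net, images, batch_size = 20L) {
  if (!is.list(images)) images <- list(images)
  n <- length(images)
  feats <- NULL; gaps <- NULL
  for (s in seq(1, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1, n)
    pr <- res4net_predict(net, images[idx])
    feats <- rbind(feats, pr$features)
    gaps <- rbind(gaps, pr$gap)
  }
  attr(feats, "gap") <- gaps
  feats
}
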