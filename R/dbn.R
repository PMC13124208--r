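#' Create an RBM layer
#'
#' A restricted Boltzmann machine over `n_visible` visible and `n_hidden`
#' hidden binary units, with weight matrix `W` (visible x hidden), visible
#' bias `b` and hidden bias `c`.
#'
#' @param n_visible,n_hidden layer sizes
#' @param seed RNG seed for the small Gaussian weight initialization
#' @param init_sd initial weight standard deviation (default 0.01)
#' @return an `rbm_layer` list
#' @export
rbm_layer <- function(n_visible, n_hidden, seed = 1L, init_sd = 0.1) {
  with_seed(seed, {
    structure(list(W = matrix(rnorm(n_visible * n_hidden, 0, init_sd),
                              n_visible, n_hidden),
                   b = numeric(n_visible), c = numeric(n_hidden),
                   n_visible = as.integer(n_visible),
                   n_hidden = as.integer(n_hidden)),
              class = "rbm_layer")
  })
}

#' RBM energy of a joint configuration
#'
#' The bilinear energy `A(v, h) = - v' W h - b' v - c' h`. The joint
#' probability of a configuration is `exp(-A) / Y` with `Y` the partition
#' function (sum over all configurations).
#'
#' @param layer an [rbm_layer()]
#' @param visible visible vector
#' @param hidden hidden vector
#' @return energy (scalar)
#' @export
rbm_energy <- function(layer, visible, hidden) {
  if (length(visible) != layer$n_visible || length(hidden) != layer$n_hidden)
    stop("rbm_energy: shape mismatch")
  -as.numeric(visible %*% layer$W %*% hidden) -
    sum(layer$b * visible) - sum(layer$c * hidden)
}

#' Exact joint distribution of a small RBM by enumeration
#'
#' Enumerates all `2^(n_visible + n_hidden)` binary configurations (allowed
#' up to 20 total units), computes `exp(-A)` for each and normalizes by the
#' partition function `Y`.
#'
#' @param layer an [rbm_layer()] with at most 20 total units
#' @return a list: `Y` (partition function), `prob` (vector over all
#'   configurations), `visible`, `hidden` (configuration matrices)
#' @export
rbm_enumerate <- function(layer) {
  nv <- layer$n_visible; nh <- layer$n_hidden
  if (nv + nh > 20) stop("rbm_enumerate: too many units to enumerate")
  bits <- function(n) {
    m <- as.matrix(expand.grid(rep(list(0:1), n)))
    dimnames(m) <- NULL
    m
  }
  V <- bits(nv); H <- bits(nh)
  en <- matrix(NA_real_, nrow(V), nrow(H))
  for (i in seq_len(nrow(V))) for (j in seq_len(nrow(H)))
    en[i, j] <- rbm_energy(layer, V[i, ], H[j, ])
  un <- exp(-en)
  Y <- sum(un)
  list(Y = Y, prob = as.numeric(un) / Y, visible = V, hidden = H,
       energy = en)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# P(h = 1 | v) and P(v = 1 | h) for a batch (rows = samples)
rbm_hidden_prob <- function(layer, v) sigmoid(sweep(v %*% layer$W, 2, layer$c, "+"))
rbm_visible_prob <- function(layer, h) sigmoid(sweep(h %*% t(layer$W), 2, layer$b, "+"))

#' Train one RBM by contrastive divergence
#'
#' CD-k with Bernoulli-sampled hidden states and mean-field (probability)
#' visible reconstructions; real-valued inputs in `[0, 1]` are treated as
#' Bernoulli probabilities. Records the mean squared one-step mean-field
#' reconstruction error per epoch (deterministic given the weights).
#'
#' @param layer an [rbm_layer()]
#' @param data matrix of training rows in `[0, 1]`
#' @param cd_k number of Gibbs steps (default 1)
#' @param epochs training epochs
#' @param lr learning rate
#' @param batch_size minibatch size
#' @param seed RNG seed
#' @return the trained layer; attribute `"recon_error"` holds the per-epoch
#'   reconstruction-error history
#' @export
rbm_train <- function(layer, data, cd_k = 1L, epochs = 50L, lr = 0.05,
                      batch_size = 32L, seed = 1L) {
  if (nrow(data) == 0) stop("rbm_train: empty data")
  with_seed(seed, {
    n <- nrow(data)
    history <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = batch_size)
      err_sum <- 0
      for (s in starts) {
        idx <- ord[s:min(s + batch_size - 1, n)]
        v0 <- data[idx, , drop = FALSE]
        ph0 <- rbm_hidden_prob(layer, v0)
        h <- matrix(rbinom(length(ph0), 1, ph0), nrow(ph0), ncol(ph0))
        vk <- v0
        for (step in seq_len(cd_k)) {
          vk <- rbm_visible_prob(layer, h)
          phk <- rbm_hidden_prob(layer, vk)
          if (step < cd_k)
            h <- matrix(rbinom(length(phk), 1, phk), nrow(phk), ncol(phk))
        }
        m <- length(idx)
        # mean-field reconstruction error: deterministic in the weights, so a
        # zero learning rate freezes it exactly
        v_mf <- rbm_visible_prob(layer, ph0)
        err_sum <- err_sum + sum((v0 - v_mf)^2)
        layer$W <- layer$W + lr * (crossprod(v0, ph0) - crossprod(vk, phk)) / m
        layer$b <- layer$b + lr * colMeans(v0 - vk)
        layer$c <- layer$c + lr * colMeans(ph0 - phk)
      }
      history[ep] <- err_sum / (n * ncol(data))
    }
    attr(layer, "recon_error") <- history
    layer
  })
}

#' Greedy layer-wise DBN pretraining
#'
#' Stacks RBMs: the first is trained on the `[0, 1]`-scaled input features,
#' each subsequent one on the previous layer's hidden activation
#' probabilities.
#'
#' @param data feature matrix rescaled to `[0, 1]`
#' @param layer_sizes hidden layer sizes, e.g. `c(64, 32)`
#' @param cd_k CD steps (default 1)
#' @param epochs pretraining epochs per layer
#' @param lr learning rate
#' @param batch_size minibatch size
#' @param seed RNG seed
#' @return a `dbn_model` list: `layers` (trained RBMs), `head` (untrained
#'   softmax head, attached by [dbn_finetune()]), `pretrain_recon_error`
#' @export
dbn_pretrain <- function(data, layer_sizes = c(64L, 32L), cd_k = 1L,
                         epochs = 50L, lr = 0.05, batch_size = 32L, seed = 1L) {
  if (nrow(data) == 0) stop("dbn_pretrain: empty data")
  if (any(data < -1e-9) || any(data > 1 + 1e-9))
    stop("dbn_pretrain: features must be rescaled to [0, 1]")
  layers <- list()
  recon <- list()
  inp <- data
  for (li in seq_along(layer_sizes)) {
    lay <- rbm_layer(ncol(inp), layer_sizes[li], seed = derive_seed(seed, li))
    lay <- rbm_train(lay, inp, cd_k = cd_k, epochs = epochs, lr = lr,
                     batch_size = batch_size, seed = derive_seed(seed, 100 + li))
    recon[[li]] <- attr(lay, "recon_error")
    layers[[li]] <- lay
    inp <- rbm_hidden_prob(lay, inp)
  }
  structure(list(layers = layers, head = NULL, layer_sizes = layer_sizes,
                 n_input = ncol(data), n_classes = NA_integer_,
                 pretrain_recon_error = recon),
            class = "dbn_model")
}

# deterministic mean-field forward through the RBM stack; returns a list of
# activations (input first, deepest hidden last)
dbn_forward_stack <- function(model, x) {
  acts <- list(x)
  for (lay in model$layers) acts[[length(acts) + 1L]] <- rbm_hidden_prob(lay, acts[[length(acts)]])
  acts
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Supervised DBN fine-tuning
#'
#' Attaches a softmax head to the deepest hidden layer and optimizes the
#' whole stack (sigmoid mean-field layers plus head) by minibatch gradient
#' descent on the cross-entropy. History records per-epoch loss and
#' training accuracy.
#'
#' @param model a pretrained `dbn_model`
#' @param data feature matrix in `[0, 1]` (same columns as pretraining)
#' @param labels integer class labels `0..n_classes-1`
#' @param n_classes number of classes (default 5)
#' @param epochs fine-tuning epochs
#' @param lr learning rate (Adam step size; default 0.01)
#' @param batch_size minibatch size
#' @param seed RNG seed
#' @return the fine-tuned `dbn_model` with `finetune_loss` and
#'   `finetune_acc` histories
#' @export
dbn_finetune <- function(model, data, labels, n_classes = 5L, epochs = 100L,
                         lr = 0.01, batch_size = 32L, seed = 1L) {
  stopifnot(inherits(model, "dbn_model"))
  if (any(labels < 0 | labels >= n_classes)) stop("dbn_finetune: label outside range")
  n <- nrow(data)
  nh <- model$layer_sizes[length(model$layer_sizes)]
  if (is.null(model$head))
    model$head <- with_seed(derive_seed(seed, 999), list(
      W = matrix(rnorm(nh * n_classes, 0, 0.01), nh, n_classes),
      b = numeric(n_classes)))
  model$n_classes <- n_classes
  loss_hist <- numeric(epochs); acc_hist <- numeric(epochs)
  # Adam state, keyed per parameter array
  am <- list(); av <- list(); at <- 0
  adam_step <- function(key, param, grad) {
    if (is.null(am[[key]])) { am[[key]] <<- param * 0; av[[key]] <<- param * 0 }
    am[[key]] <<- 0.9 * am[[key]] + 0.1 * grad
    av[[key]] <<- 0.999 * av[[key]] + 0.001 * grad^2
    mh <- am[[key]] / (1 - 0.9^at)
    vh <- av[[key]] / (1 - 0.999^at)
    param - lr * mh / (sqrt(vh) + 1e-8)
  }
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = batch_size)
      tot_loss <- 0; tot_correct <- 0
      for (s in starts) {
        idx <- ord[s:min(s + batch_size - 1, n)]
        xb <- data[idx, , drop = FALSE]
        yb <- labels[idx]
        m <- length(idx)
        acts <- dbn_forward_stack(model, xb)
        top <- acts[[length(acts)]]
        logits <- sweep(top %*% model$head$W, 2, model$head$b, "+")
        p <- softmax_rows(logits)
        onehot <- matrix(0, m, n_classes)
        onehot[cbind(seq_len(m), yb + 1L)] <- 1
        tot_loss <- tot_loss - sum(log(pmax(p[onehot == 1], 1e-12)))
        tot_correct <- tot_correct + sum(max.col(p, ties.method = "first") - 1L == yb)
        dlogits <- (p - onehot) / m
        dW_head <- crossprod(top, dlogits)
        db_head <- colSums(dlogits)
        dact <- dlogits %*% t(model$head$W)
        grads <- vector("list", length(model$layers))
        for (li in rev(seq_along(model$layers))) {
          a <- acts[[li + 1L]]
          dz <- dact * a * (1 - a)
          grads[[li]] <- list(W = crossprod(acts[[li]], dz), c = colSums(dz))
          dact <- dz %*% t(model$layers[[li]]$W)
        }
        at <- at + 1
        model$head$W <- adam_step("hW", model$head$W, dW_head)
        model$head$b <- adam_step("hb", model$head$b, db_head)
        for (li in seq_along(model$layers)) {
          model$layers[[li]]$W <- adam_step(paste0("W", li),
                                            model$layers[[li]]$W, grads[[li]]$W)
          model$layers[[li]]$c <- adam_step(paste0("c", li),
                                            model$layers[[li]]$c, grads[[li]]$c)
        }
      }
      loss_hist[ep] <- tot_loss / n
      acc_hist[ep] <- tot_correct / n
    }
  })
  model$finetune_loss <- loss_hist
  model$finetune_acc <- acc_hist
  model
}

#' DBN class probabilities and labels
#'
#' Deterministic mean-field forward pass through the sigmoid stack and
#' softmax head. Ties in the argmax go to the lowest class index.
#'
#' @param model a fine-tuned `dbn_model`
#' @param features matrix (or vector) of inputs in `[0, 1]`
#' @return a list: `prob` (rows on the class simplex), `label` (integer
#'   class indices)
#' @export
dbn_predict <- function(model, features) {
  stopifnot(inherits(model, "dbn_model"))
  if (is.null(model$head)) stop("dbn_predict: model has no classification head")
  x <- if (is.null(dim(features))) matrix(features, nrow = 1) else as.matrix(features)
  if (ncol(x) != model$n_input) stop("dbn_predict: feature length mismatch")
  acts <- dbn_forward_stack(model, x)
  logits <- sweep(acts[[length(acts)]] %*% model$head$W, 2, model$head$b, "+")
  p <- softmax_rows(logits)
  list(prob = p, label = max.col(p, ties.method = "first") - 1L)
}

#' Min-max rescale columns to the unit interval
#'
#' Helper for the DBN contract that inputs live in `[0, 1]`. Constant
#' columns map to 0.5. When `from` (a previous scaling) is supplied its
#' ranges are reused, with clipping, so train and test share one scale.
#'
#' @param x numeric matrix
#' @param from optional result of a previous `scale_unit()` call
#' @return matrix in `[0, 1]` with attribute `"scaling"` (per-column ranges)
#' @export
scale_unit <- function(x, from = NULL) {
  x <- as.matrix(x)
  rngs <- if (!is.null(from)) attr(from, "scaling") else
    apply(x, 2, range)
  lo <- rngs[1, ]; hi <- rngs[2, ]
  span <- ifelse(hi > lo, hi - lo, 1)
  out <- sweep(sweep(x, 2, lo, "-"), 2, span, "/")
  out[, hi <= lo] <- 0.5
  out <- pmin(pmax(out, 0), 1)
  attr(out, "scaling") <- rngs
  out
}
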