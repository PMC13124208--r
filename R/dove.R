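#' Dove swarm configuration
#'
#' The swarm is an `A x B` grid of doves, each holding a position (weight
#' vector) in the box `[lower, upper]^M` and a satisfaction accumulator.
#'
#' @param grid_rows,grid_cols grid dimensions `A`, `B` (each >= 2);
#'   `N = A * B` doves
#' @param dim search-space dimension `M`
#' @param lower,upper per-dimension bounds (scalars are recycled);
#'   `lower < upper` elementwise
#' @param eta0 initial learning rate (default 0.1, decaying linearly to 0)
#' @param max_epochs epoch budget `T` (default 100)
#' @param satisfaction_decay satisfaction decay in `[0, 1)` (default 0.9)
#' @param target_value optional known objective target; when given,
#'   optimization stops once the most-satisfied dove's fitness is within
#'   `epsilon` of it
#' @param epsilon termination tolerance for `target_value`
#' @param init `"interpolate"` (interior doves bilinearly interpolated from
#'   the four bound-anchored corners; fully deterministic) or `"random"`
#'   (corners anchored as always, interior doves uniform in the box)
#' @param seed RNG seed (used by `"random"` initialization)
#' @return a `swarm_config` list
#' @export
swarm_config <- function(grid_rows = 5L, grid_cols = 5L, dim = 2L,
                         lower = 0, upper = 1, eta0 = 0.1, max_epochs = 100L,
                         satisfaction_decay = 0.9, target_value = NULL,
                         epsilon = 1e-3, init = c("interpolate", "random"),
                         seed = 1L) {
  init <- match.arg(init)
  A <- as.integer(grid_rows); B <- as.integer(grid_cols); M <- as.integer(dim)
  if (A < 2 || B < 2) stop("swarm_config: grid must be at least 2x2")
  lower <- rep_len(as.numeric(lower), M); upper <- rep_len(as.numeric(upper), M)
  if (any(lower >= upper)) stop("swarm_config: need lower < upper elementwise")
  if (eta0 <= 0 || eta0 > 1) stop("swarm_config: eta0 must be in (0, 1]")
  if (satisfaction_decay < 0 || satisfaction_decay >= 1)
    stop("swarm_config: satisfaction_decay must be in [0, 1)")
  structure(list(grid_rows = A, grid_cols = B, dim = M, lower = lower,
                 upper = upper, eta0 = eta0,
                 max_epochs = as.integer(max_epochs),
                 satisfaction_decay = satisfaction_decay,
                 target_value = target_value, epsilon = epsilon,
                 init = init, seed = as.integer(seed)),
            class = "swarm_config")
}

#' Initialize the dove swarm
#'
#' The four grid corners are anchored to the box corners: `w[1,1] = lower`,
#' `w[A,B] = upper`, `w[1,B]` takes the lower bound on the first
#' `floor(M/2)` coordinates and the upper bound on the rest, and `w[A,1]`
#' the reverse. Interior doves are bilinearly interpolated from the corners
#' by grid position (default) or drawn uniformly in the box. Satisfactions
#' start at zero, the epoch counter at zero.
#'
#' @param config a [swarm_config()]
#' @return a `swarm_state` list: `positions` (N x M matrix, rows in
#'   grid-row-major order), `grid` (N x 2 grid coordinates),
#'   `satisfaction`, `fitness`, `epoch`, plus best-ever trackers
#' @export
swarm_initialize <- function(config) {
  stopifnot(inherits(config, "swarm_config"))
  A <- config$grid_rows; B <- config$grid_cols; M <- config$dim
  l <- config$lower; u <- config$upper
  half <- floor(M / 2)
  corner_11 <- l
  corner_AB <- u
  corner_1B <- c(l[seq_len(half)], u[seq_len(M - half) + half])
  corner_A1 <- c(u[seq_len(half)], l[seq_len(M - half) + half])
  N <- A * B
  pos <- matrix(NA_real_, N, M)
  grid <- cbind(a = rep(seq_len(A), each = B), b = rep(seq_len(B), times = A))
  if (config$init == "random") {
    pos <- with_seed(config$seed,
      matrix(runif(N * M, rep(l, each = N), rep(u, each = N)), N, M))
  } else {
    for (k in seq_len(N)) {
      al <- (grid[k, 1] - 1) / (A - 1)  # 0 at row 1, 1 at row A
      be <- (grid[k, 2] - 1) / (B - 1)  # 0 at col 1, 1 at col B
      pos[k, ] <- (1 - al) * (1 - be) * corner_11 + (1 - al) * be * corner_1B +
        al * (1 - be) * corner_A1 + al * be * corner_AB
    }
  }
  # corners are anchored under either scheme
  pos[grid[, 1] == 1 & grid[, 2] == 1, ] <- corner_11
  pos[grid[, 1] == A & grid[, 2] == B, ] <- corner_AB
  pos[grid[, 1] == 1 & grid[, 2] == B, ] <- corner_1B
  pos[grid[, 1] == A & grid[, 2] == 1, ] <- corner_A1
  structure(list(positions = pos, grid = grid,
                 satisfaction = numeric(N), fitness = rep(NA_real_, N),
                 epoch = 0L, best_fitness_idx = NA_integer_,
                 best_satisfaction_idx = NA_integer_,
                 best_ever_fitness = -Inf, best_ever_position = rep(NA_real_, M)),
            class = "swarm_state")
}

#' Learning-rate schedule
#'
#' Linear decay `eta(t) = eta0 * (1 - t / T)`; with the defaults,
#' `0.1 * (1 - t/100)`, so 0.1 at epoch 0 and exactly 0 at epoch `T`.
#'
#' @param epoch current epoch `t` in `0..T`
#' @param config a [swarm_config()]
#' @return the learning rate
#' @export
dove_learning_rate <- function(epoch, config) {
  stopifnot(epoch >= 0, epoch <= config$max_epochs)
  config$eta0 * (1 - epoch / config$max_epochs)
}

#' Update dove satisfactions from this epoch's fitness values
#'
#' With `d_f` the best-fitness dove (ties to the lowest index), each dove's
#' satisfaction becomes
#' `S_j <- decay * S_j + exp(f(w_j) - f(w_df))`: the fitness gap to the best
#' dove is non-positive, so increments lie in `(0, 1]` and the best-fed dove
#' always receives the largest one. The most-satisfied dove `d_s` is then
#' the satisfaction argmax (ties to the lowest index).
#'
#' @param state a `swarm_state`
#' @param fitnesses numeric vector of this epoch's fitness values (finite)
#' @param config a [swarm_config()]
#' @return updated `swarm_state`
#' @export
swarm_update_satisfaction <- function(state, fitnesses, config) {
  if (any(is.na(fitnesses)) || any(fitnesses == Inf))
    stop("swarm_update_satisfaction: non-finite fitness")
  state$fitness <- fitnesses
  d_f <- which.max(fitnesses)  # lowest index on ties
  state$best_fitness_idx <- d_f
  gaps <- fitnesses - fitnesses[d_f]
  gaps[is.nan(gaps)] <- 0  # doves tied at -Inf (e.g. empty masks) get the neutral gap
  state$satisfaction <- config$satisfaction_decay * state$satisfaction +
    exp(gaps)
  state$best_satisfaction_idx <- which.max(state$satisfaction)
  if (fitnesses[d_f] > state$best_ever_fitness) {
    state$best_ever_fitness <- fitnesses[d_f]
    state$best_ever_position <- state$positions[d_f, ]
  }
  state
}

#' Move doves towards the most-satisfied dove
#'
#' Each dove takes the step `w_j <- w_j + eta * beta_j * (w_ds - w_j)` with
#' `beta_j = ((S_ds - S_j)/S_ds) * (1 - ||w_j - w_ds|| / maxDistance)`,
#' where `maxDistance` is the maximum pairwise distance among current
#' positions (recomputed every epoch). The most-satisfied dove and any dove
#' at maximum distance from it are stationary. If all doves coincide or
#' `S_ds = 0`, every `beta` is 0 and the state only advances its epoch.
#' Positions are clipped to the box after the move.
#'
#' @param state a `swarm_state` with satisfactions updated this epoch
#' @param config a [swarm_config()]
#' @return updated `swarm_state` (epoch incremented)
#' @export
swarm_move <- function(state, config) {
  ds <- state$best_satisfaction_idx
  if (is.na(ds)) stop("swarm_move: satisfactions not yet updated")
  S <- state$satisfaction
  pos <- state$positions
  max_dist <- max(stats::dist(pos))
  eta <- dove_learning_rate(state$epoch, config)
  if (max_dist > 0 && S[ds] != 0) {
    d_to_ds <- sqrt(rowSums((pos - matrix(pos[ds, ], nrow(pos), ncol(pos),
                                          byrow = TRUE))^2))
    beta <- ((S[ds] - S) / S[ds]) * (1 - d_to_ds / max_dist)
    step <- eta * beta * (matrix(pos[ds, ], nrow(pos), ncol(pos), byrow = TRUE) - pos)
    pos <- pos + step
    pos <- pmin(pmax(pos, matrix(config$lower, nrow(pos), ncol(pos), byrow = TRUE)),
                matrix(config$upper, nrow(pos), ncol(pos), byrow = TRUE))
    state$positions <- pos
  }
  state$epoch <- state$epoch + 1L
  state
}

#' Run the dove swarm optimizer
#'
#' Repeats evaluate -> satisfaction update -> move. Every epoch evaluates
#' the objective once per dove, so the total number of objective evaluations
#' is exactly `N * epochs_used` (linear in swarm size and epochs). Stops
#' when the most-satisfied dove's fitness is within `epsilon` of
#' `target_value` (when a target is configured) or after `max_epochs`
#' move steps.
#'
#' @param objective function mapping a position vector to a finite fitness
#'   (maximized)
#' @param config a [swarm_config()]
#' @return a list: `best_position`, `best_fitness` (best ever seen),
#'   `history` (per-epoch best fitness), `epochs_used` (number of
#'   evaluation sweeps), `evaluations`, `state` (final swarm state)
#' @export
dso_optimize <- function(objective, config) {
  state <- swarm_initialize(config)
  N <- nrow(state$positions)
  history <- numeric(0)
  evals <- 0L
  epochs_used <- 0L
  repeat {
    fit <- apply(state$positions, 1, objective)
    evals <- evals + N
    epochs_used <- epochs_used + 1L
    state <- swarm_update_satisfaction(state, fit, config)
    history <- c(history, fit[state$best_fitness_idx])
    ds_fit <- fit[state$best_satisfaction_idx]
    if (!is.null(config$target_value) &&
        abs(ds_fit - config$target_value) <= config$epsilon) break
    if (state$epoch >= config$max_epochs) break
    state <- swarm_move(state, config)
  }
  list(best_position = state$best_ever_position,
       best_fitness = state$best_ever_fitness,
       history = history, epochs_used = epochs_used,
       evaluations = evals, state = state)
}

# Closed-form ridge "one-hot" multinomial classifier: cheap, deterministic
# light model used as the wrapper fitness inside feature selection.
ridge_fit <- function(x, y, n_classes = 5L, lambda = 1) {
  X <- cbind(1, x)
  Y <- matrix(0, nrow(X), n_classes)
  Y[cbind(seq_len(nrow(X)), y + 1L)] <- 1
  P <- diag(ncol(X)) * lambda
  P[1, 1] <- 0  # do not penalize the intercept
  solve(crossprod(X) + P, crossprod(X, Y))
}

ridge_predict <- function(W, x) {
  sc <- cbind(1, x) %*% W
  max.col(sc, ties.method = "first") - 1L
}

# Stratified k-fold assignment, seeded and deterministic.
stratified_folds <- function(labels, k, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

# Stratified k-fold CV accuracy of the ridge classifier on masked features.
masked_cv_accuracy <- function(x, labels, mask, k = 5L, seed = 1L) {
  if (!any(mask)) return(-Inf)
  xs <- x[, mask, drop = FALSE]
  fold <- stratified_folds(labels, k, seed)
  correct <- 0L
  for (f in seq_len(k)) {
    tr <- fold != f; te <- fold == f
    if (!any(te)) next
    W <- ridge_fit(xs[tr, , drop = FALSE], labels[tr],
                   n_classes = length(unique(labels)))
    pred <- ridge_predict(W, xs[te, , drop = FALSE])
    correct <- correct + sum(pred == labels[te])
  }
  correct / length(labels)
}

#' Wrapper feature selection with the dove swarm
#'
#' Doves live in `[0, 1]^M`; a position is thresholded at 0.5 into a binary
#' feature mask. Mask fitness is the stratified k-fold cross-validated
#' accuracy of a closed-form ridge multinomial classifier on the masked
#' features, minus `sparsity_alpha * (selected / M)`; the empty mask scores
#' `-Inf`. Interior doves are initialized by seeded random dispersion (the
#' corner doves stay bound-anchored) so that initial masks span diverse
#' feature subsets.
#'
#' @param x numeric feature matrix (rows = samples)
#' @param labels integer class labels `0..K-1`
#' @param config optional [swarm_config()]; dimensions and bounds are forced
#'   to `[0, 1]^ncol(x)`
#' @param sparsity_alpha penalty weight on the selected fraction (default 0.05)
#' @param cv_folds cross-validation folds (default 5)
#' @param seed RNG seed (swarm init and CV folds)
#' @return a list: `mask` (logical), `selected` (indices), `cv_score`
#'   (CV accuracy of the best mask, without the sparsity penalty),
#'   `fitness`, `history`, `evaluations`
#' @export
dso_select_features <- function(x, labels, config = NULL,
                                sparsity_alpha = 0.05, cv_folds = 5L,
                                seed = 1L) {
  M <- ncol(x)
  if (M < 2) stop("dso_select_features: need at least 2 features")
  if (length(unique(labels)) < 2) stop("dso_select_features: single-class labels")
  if (is.null(config))
    config <- swarm_config(grid_rows = 5L, grid_cols = 5L, dim = M,
                           max_epochs = 40L, init = "random", seed = seed)
  config$dim <- M
  config$lower <- rep(0, M); config$upper <- rep(1, M)
  config$init <- "random"; config$seed <- as.integer(seed)
  fitness_of_mask <- function(mask) {
    if (!any(mask)) return(-Inf)
    acc <- masked_cv_accuracy(x, labels, mask, k = cv_folds, seed = seed)
    acc - sparsity_alpha * sum(mask) / M
  }
  cache <- new.env(parent = emptyenv())
  objective <- function(w) {
    mask <- w > 0.5
    key <- paste0("m", paste(which(mask), collapse = "_"))
    if (is.null(cache[[key]])) cache[[key]] <- fitness_of_mask(mask)
    cache[[key]]
  }
  res <- dso_optimize(objective, config)
  best_mask <- res$best_position > 0.5
  list(mask = best_mask, selected = which(best_mask),
       cv_score = masked_cv_accuracy(x, labels, best_mask, k = cv_folds,
                                     seed = seed),
       fitness = res$best_fitness, history = res$history,
       evaluations = res$evaluations)
}
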