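#' Initialise a shallow feedforward regression network
#'
#' One hidden tanh layer, identity output: `y = W2 tanh(W1 x + b1) + b2`.
#' Weights are drawn uniformly from `+/- sqrt(6 / (fan_in + fan_out))`
#' (small-magnitude symmetric initialisation). Hidden biases are drawn
#' uniformly from `+/- 0.5` so that units start at varied operating points
#' of the tanh nonlinearity (zero biases would make every unit an odd
#' function of its input, leaving the network initially blind to even
#' structure in the data); the output bias starts at zero.
#'
#' @param input_dim number of inputs (3600 for the default montage).
#' @param hidden_dim hidden units (default 100).
#' @param seed optional seed for reproducible initialisation.
#' @return A `shallow_net`: list of `W1`, `b1`, `W2`, `b2`.
#' @export
init_network <- function(input_dim = 3600, hidden_dim = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  r1 <- sqrt(6 / (input_dim + hidden_dim))
  r2 <- sqrt(6 / (hidden_dim + 1))
  structure(list(
    W1 = matrix(stats::runif(hidden_dim * input_dim, -r1, r1),
                nrow = hidden_dim),
    b1 = stats::runif(hidden_dim, -0.5, 0.5),
    W2 = matrix(stats::runif(hidden_dim, -r2, r2), nrow = 1),
    b2 = 0
  ), class = "shallow_net")
}

#' Forward pass of a shallow network
#'
#' @param net a `shallow_net`.
#' @param x numeric vector of length `input_dim`, or an
#'   `input_dim x n` matrix of column samples.
#' @return Numeric vector of predictions (one per column).
#' @export
forward <- function(net, x) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  if (nrow(x) != ncol(net$W1)) {
    stop("input has ", nrow(x), " features; network expects ", ncol(net$W1),
         call. = FALSE)
  }
  a1 <- tanh(net$W1 %*% x + net$b1)
  as.numeric(net$W2 %*% a1 + net$b2)
}

# forward + gradients of MSE w.r.t. all parameters (full batch)
net_loss_grad <- function(net, x, y) {
  a1 <- tanh(net$W1 %*% x + net$b1)
  pred <- as.numeric(net$W2 %*% a1 + net$b2)
  err <- pred - y
  n <- length(y)
  mse <- mean(err^2)
  d_out <- matrix(2 * err / n, nrow = 1)            # dL/d pred
  dW2 <- d_out %*% t(a1)
  db2 <- sum(d_out)
  d_h <- (t(net$W2) %*% d_out) * (1 - a1^2)          # back through tanh
  dW1 <- d_h %*% t(x)
  db1 <- rowSums(d_h)
  list(mse = mse, pred = pred,
       grad = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

net_mse <- function(net, x, y) mean((forward(net, x) - y)^2)

#' Training configuration for variable-learning-rate backpropagation
#'
#' Constants of the classical adaptive-rate gradient-descent-with-momentum
#' trainer: after an epoch whose error decreased the learning rate is
#' multiplied by `lr_inc`; a step that increases the error by more than the
#' factor `max_perf_inc` is rejected, the rate multiplied by `lr_dec`, and
#' momentum suppressed for that step. Early stopping halts training after
#' `patience` consecutive epochs without a new best validation error and the
#' best-validation parameters are returned.
#'
#' @param lr0 initial learning rate.
#' @param lr_inc,lr_dec rate multipliers (`lr_inc > 1 > lr_dec > 0`).
#' @param max_perf_inc maximum tolerated error growth ratio per step.
#' @param momentum momentum coefficient in `[0, 1)`.
#' @param max_epochs epoch budget.
#' @param patience consecutive validation failures tolerated (>= 1).
#' @return A `train_config` list.
#' @export
train_config <- function(lr0 = 0.01, lr_inc = 1.05, lr_dec = 0.7,
                         max_perf_inc = 1.04, momentum = 0.9,
                         max_epochs = 300, patience = 6) {
  stopifnot(lr_inc > 1, lr_dec > 0, lr_dec < 1, lr0 > 0,
            momentum >= 0, momentum < 1, patience >= 1, max_epochs >= 1)
  structure(list(lr0 = lr0, lr_inc = lr_inc, lr_dec = lr_dec,
                 max_perf_inc = max_perf_inc, momentum = momentum,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience)),
            class = "train_config")
}

#' Train a shallow network with adaptive-rate backpropagation and early
#' stopping
#'
#' Full-batch gradient descent on the mean squared error with momentum and
#' the variable-learning-rate rule of [train_config()]. Validation error is
#' monitored every epoch; training stops at `max_epochs` or after
#' `patience` consecutive epochs without improving the best validation
#' error, and the parameters from the best-validation epoch are returned.
#'
#' @param net a `shallow_net` (fresh from [init_network()]).
#' @param x_train,y_train training inputs (features x samples) and targets.
#' @param x_val,y_val validation inputs and targets (disjoint from
#'   training).
#' @param cfg a [train_config()].
#' @return List: `net` (best-validation parameters), `trace` (data.frame
#'   per epoch: `epoch`, `train_mse`, `val_mse`, `lr`, `accepted`),
#'   `best_val_mse`, `epochs_run`, `stop_reason`.
#' @export
train_network <- function(net, x_train, y_train, x_val, y_val,
                          cfg = train_config()) {
  if (length(y_train) == 0L || length(y_val) == 0L) {
    stop("training and validation sets must be non-empty", call. = FALSE)
  }
  lr <- cfg$lr0
  vel <- list(W1 = net$W1 * 0, b1 = net$b1 * 0, W2 = net$W2 * 0, b2 = 0)
  prev_mse <- net_mse(net, x_train, y_train)
  best_val <- net_mse(net, x_val, y_val)
  best_net <- net
  fails <- 0L
  trace <- vector("list", cfg$max_epochs)
  stop_reason <- "max_epochs"
  epochs_run <- 0L

  for (epoch in seq_len(cfg$max_epochs)) {
    lg <- net_loss_grad(net, x_train, y_train)
    g <- lg$grad
    step <- list(W1 = cfg$momentum * vel$W1 - lr * g$W1,
                 b1 = cfg$momentum * vel$b1 - lr * g$b1,
                 W2 = cfg$momentum * vel$W2 - lr * g$W2,
                 b2 = cfg$momentum * vel$b2 - lr * g$b2)
    cand <- net
    cand$W1 <- net$W1 + step$W1; cand$b1 <- net$b1 + step$b1
    cand$W2 <- net$W2 + step$W2; cand$b2 <- net$b2 + step$b2
    new_mse <- net_mse(cand, x_train, y_train)
    if (!is.finite(new_mse)) {
      stop("non-finite training loss at epoch ", epoch,
           " (learning rate ", signif(lr, 3), ")", call. = FALSE)
    }
    accepted <- new_mse <= cfg$max_perf_inc * prev_mse
    if (accepted) {
      net <- cand
      vel <- step
      if (new_mse < prev_mse) lr <- lr * cfg$lr_inc
      prev_mse <- new_mse
    } else {
      lr <- lr * cfg$lr_dec
      vel <- list(W1 = vel$W1 * 0, b1 = vel$b1 * 0, W2 = vel$W2 * 0, b2 = 0)
    }
    val_mse <- net_mse(net, x_val, y_val)
    if (val_mse < best_val) {
      best_val <- val_mse
      best_net <- net
      fails <- 0L
    } else {
      fails <- fails + 1L
    }
    trace[[epoch]] <- c(epoch = epoch, train_mse = prev_mse,
                        val_mse = val_mse, lr = lr, accepted = accepted)
    epochs_run <- epoch
    if (fails >= cfg$patience) {
      stop_reason <- "early_stopping"
      break
    }
  }
  list(net = best_net,
       trace = as.data.frame(do.call(rbind, trace[seq_len(epochs_run)])),
       best_val_mse = best_val, epochs_run = epochs_run,
       stop_reason = stop_reason)
}

#' Per-feature affine scaling to [-1, 1], fitted on training data only
#'
#' Maps each feature's training range `[min, max]` linearly onto `[-1, 1]`.
#' Constant features map to 0. The transform is fitted on the training set
#' and applied unchanged to validation/test data (values outside the
#' training range are not clipped).
#'
#' @param x_train features x samples training matrix.
#' @return A `feature_scaler` with `$apply(x)` and `$invert(x)` closures and
#'   the fitted `center`/`halfrange`.
#' @export
fit_feature_scaler <- function(x_train) {
  mn <- apply(x_train, 1, min)
  mx <- apply(x_train, 1, max)
  center <- (mn + mx) / 2
  halfrange <- (mx - mn) / 2
  degenerate <- halfrange < .Machine$double.eps
  scale_fac <- ifelse(degenerate, 0, 1 / ifelse(degenerate, 1, halfrange))
  structure(list(
    center = center, halfrange = halfrange,
    apply = function(x) (x - center) * scale_fac,
    invert = function(z) z * ifelse(degenerate, 0, halfrange) + center
  ), class = "feature_scaler")
}

#' Random train/validation/test split of trial indices
#'
#' @param n number of trials.
#' @param fractions train/validation/test fractions summing to 1
#'   (default 0.85 / 0.05 / 0.10: 204 / 12 / 24 trials of 240).
#' @return List of disjoint index vectors `train`, `val`, `test` whose
#'   union is `1:n`.
#' @export
make_split <- function(n, fractions = c(0.85, 0.05, 0.10)) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9)
  n_train <- round(fractions[1] * n)
  n_val <- round(fractions[2] * n)
  if (n_val < 1L || n_train < 1L || n_train + n_val >= n) {
    stop("fractions leave an empty train, validation or test set for n = ",
         n, " trials", call. = FALSE)
  }
  perm <- sample.int(n)
  list(train = sort(perm[seq_len(n_train)]),
       val = sort(perm[n_train + seq_len(n_val)]),
       test = sort(perm[(n_train + n_val + 1):n]))
}

#' Iterated random-split training and test-set prediction averaging
#'
#' The multivariate evaluation procedure: in each iteration the trials are
#' split at random into training (85%), validation (5%) and test (10%)
#' sets; a freshly initialised 3600-100-1 network is trained with early
#' stopping; predictions and the Pearson r between predicted and actual
#' coupling index are recorded for the held-out test set only. After all
#' iterations each trial's prediction is the mean over the iterations in
#' which it was in the test set, and the headline statistic is the mean
#' test r across iterations. Coverage (every trial tested at least
#' `min_appearances` times) is enforced by extending the iteration budget
#' if necessary.
#'
#' Inputs are scaled per feature to `[-1, 1]`, and targets are
#' variance-stabilised (square root, taming the reciprocal index's heavy
#' right tail) and standardised, all fitted on the training portion of
#' each split only; predictions are mapped back to the original
#' coupling-index scale before anything is recorded.
#'
#' @param features `n_features x n_trials` matrix (columns = trials).
#' @param ci numeric vector of per-trial coupling index values, aligned
#'   with the columns of `features`.
#' @param n_iter number of split iterations (the reference procedure uses
#'   1000; smaller values trade precision of the mean r for runtime).
#' @param fractions split fractions, see [make_split()].
#' @param cfg a [train_config()].
#' @param hidden_dim hidden-layer size.
#' @param seed master seed; iteration `i` uses a seed derived from it.
#' @param min_appearances required minimum test appearances per trial.
#' @param max_extra_iter extra iterations allowed to satisfy coverage.
#' @return List: `predictions` (data.frame `trial_id`, `ci`,
#'   `predicted_ci`, `n_test_appearances`), `iterations` (data.frame
#'   `iteration`, `r_test`, `epochs_run`, `stop_reason`), `mean_r`,
#'   `n_iter_total`, and `test_index_log` (list of test-set index vectors,
#'   for leakage audits).
#' @export
iterate_splits <- function(features, ci, n_iter = 1000,
                           fractions = c(0.85, 0.05, 0.10),
                           cfg = train_config(), hidden_dim = 100,
                           seed = 1L, min_appearances = 5L,
                           max_extra_iter = 5L * n_iter) {
  stopifnot(ncol(features) == length(ci))
  n <- length(ci)
  trial_ids <- colnames(features)
  if (is.null(trial_ids)) trial_ids <- as.character(seq_len(n))

  pred_sum <- numeric(n)
  pred_count <- integer(n)
  iter_log <- list()
  test_index_log <- list()

  y_all <- sqrt(ci)
  run_iteration <- function(i) {
    set.seed((substream_seed(seed, "split") + i * 7919L) %% 2147483647L)
    sp <- make_split(n, fractions)
    x_tr <- features[, sp$train, drop = FALSE]
    scaler <- fit_feature_scaler(x_tr)
    y_mu <- mean(y_all[sp$train]); y_sd <- stats::sd(y_all[sp$train])
    if (y_sd < .Machine$double.eps) y_sd <- 1
    net <- init_network(nrow(features), hidden_dim)
    fit <- train_network(net,
                         scaler$apply(x_tr), (y_all[sp$train] - y_mu) / y_sd,
                         scaler$apply(features[, sp$val, drop = FALSE]),
                         (y_all[sp$val] - y_mu) / y_sd,
                         cfg)
    z_test <- forward(fit$net,
                      scaler$apply(features[, sp$test, drop = FALSE])) *
      y_sd + y_mu
    pred_test <- pmax(z_test, 0)^2
    r <- suppressWarnings(stats::cor(pred_test, ci[sp$test]))
    pred_sum[sp$test] <<- pred_sum[sp$test] + pred_test
    pred_count[sp$test] <<- pred_count[sp$test] + 1L
    iter_log[[length(iter_log) + 1L]] <<- data.frame(
      iteration = i, r_test = r, epochs_run = fit$epochs_run,
      stop_reason = fit$stop_reason)
    test_index_log[[length(test_index_log) + 1L]] <<- sp$test
  }

  for (i in seq_len(n_iter)) run_iteration(i)

  extra <- 0L
  while (min(pred_count) < min_appearances && extra < max_extra_iter) {
    extra <- extra + 1L
    run_iteration(n_iter + extra)
  }
  if (min(pred_count) < min_appearances) {
    stop("coverage not reached: trial(s) ",
         paste(trial_ids[pred_count < min_appearances], collapse = ", "),
         " appeared in fewer than ", min_appearances,
         " test sets after ", n_iter + extra, " iterations", call. = FALSE)
  }
  if (extra > 0L) {
    message("coverage required ", extra, " extra iteration(s)")
  }

  iterations <- do.call(rbind, iter_log)
  list(
    predictions = data.frame(
      trial_id = trial_ids, ci = ci,
      predicted_ci = pred_sum / pred_count,
      n_test_appearances = pred_count),
    iterations = iterations,
    mean_r = mean(iterations$r_test, na.rm = TRUE),
    n_iter_total = n_iter + extra,
    test_index_log = test_index_log
  )
}
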