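#' Multilayer-perceptron configuration
#'
#' Feed-forward network trained by full-batch backpropagation with
#' momentum. Two published architectures are of particular interest: a
#' 3-8-5 network (composition in, release at 1/2/4/6/8 h out, all-linear
#' activations) and a 4-(5,5,6,5,6)-4 network (composition plus exposure
#' time in, release at 2/4/6/8 h out, log-sigmoid hidden layers with a
#' linear output).
#'
#' Inputs and outputs are min-max scaled to \[0, 1\] internally (scaling
#' parameters are learned from the training data and stored with the
#' network); root-mean-square errors are reported on that scaled scale.
#'
#' @param layer_sizes Integer vector of unit counts from input to output,
#'   length at least 2, all at least 1.
#' @param activations Character vector, one per non-input layer, each
#'   `"linear"` or `"log_sigmoid"`; a single value is recycled.
#' @param learning_rate Gradient step size in (0, 1].
#' @param momentum Momentum coefficient in \[0, 1).
#' @param max_epochs Training epoch cap.
#' @param patience Early-stopping patience: training stops when the
#'   validation RMS has not improved for this many epochs.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `mlp_config`.
#' @export
mlp_config <- function(layer_sizes, activations = "linear",
                       learning_rate = 0.6, momentum = 0.6,
                       max_epochs = 20000, patience = 200, seed = 1L) {
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2 || any(layer_sizes < 1)) {
    stop("layer_sizes must have length >= 2 with all sizes >= 1",
         call. = FALSE)
  }
  n_act <- length(layer_sizes) - 1
  if (length(activations) == 1) activations <- rep(activations, n_act)
  if (length(activations) != n_act) {
    stop("need one activation per non-input layer (", n_act, ")",
         call. = FALSE)
  }
  if (!all(activations %in% c("linear", "log_sigmoid"))) {
    stop("activations must be 'linear' or 'log_sigmoid'", call. = FALSE)
  }
  if (learning_rate <= 0 && learning_rate != 0 || learning_rate > 1) {
    stop("learning_rate must be in (0, 1] (0 allowed for diagnostics)",
         call. = FALSE)
  }
  if (momentum < 0 || momentum >= 1) {
    stop("momentum must be in [0, 1)", call. = FALSE)
  }
  structure(list(layer_sizes = layer_sizes, activations = activations,
                 learning_rate = learning_rate, momentum = momentum,
                 max_epochs = max_epochs, patience = patience,
                 seed = as.integer(seed)),
            class = "mlp_config")
}

#' Initialize network weights
#'
#' Weights and biases are drawn uniform(-0.5, 0.5) from the seeded
#' generator, so identical seeds give identical networks.
#'
#' @param config An [mlp_config()].
#' @return An object of class `mlp` with per-layer weight matrices `W`
#'   (in-size x out-size) and bias vectors `b`; scaling parameters are
#'   unset until training.
#' @export
init_mlp <- function(config) {
  set.seed(config$seed)
  sizes <- config$layer_sizes
  L <- length(sizes) - 1
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1], -0.5, 0.5),
                     sizes[l], sizes[l + 1])
    b[[l]] <- stats::runif(sizes[l + 1], -0.5, 0.5)
  }
  structure(list(config = config, W = W, b = b, scaling = NULL,
                 history = NULL, metrics = NULL),
            class = "mlp")
}

#' @export
print.mlp <- function(x, ...) {
  cat("MLP", paste(x$config$layer_sizes, collapse = "-"),
      "| activations:", paste(x$config$activations, collapse = ","), "\n")
  if (!is.null(x$metrics)) {
    cat(sprintf("trained %d epochs | validation RMS %.4g | R2 %.4f\n",
                length(x$history), x$metrics$rms, x$metrics$r2))
  }
  invisible(x)
}

act_fun <- function(z, kind) {
  if (kind == "linear") z else 1 / (1 + exp(-z))
}

act_deriv <- function(a, kind) {
  if (kind == "linear") array(1, dim(a)) else a * (1 - a)
}

# forward pass on the scaled scale; X is n x d. Returns the list of
# post-activation matrices (first element = X) for backprop.
mlp_forward_pass <- function(net, X) {
  A <- list(X)
  for (l in seq_along(net$W)) {
    Z <- sweep(A[[l]] %*% net$W[[l]], 2, net$b[[l]], "+")
    A[[l + 1]] <- act_fun(Z, net$config$activations[l])
  }
  A
}

# Mean squared error over all entries, halved so the output delta is
# (pred - y) / (n * m).
mlp_loss <- function(pred, Y) sum((pred - Y)^2) / (2 * length(Y))

# Analytic gradients of mlp_loss w.r.t. every weight and bias.
mlp_gradients <- function(net, X, Y) {
  A <- mlp_forward_pass(net, X)
  L <- length(net$W)
  delta <- (A[[L + 1]] - Y) / length(Y) *
    act_deriv(A[[L + 1]], net$config$activations[L])
  gW <- vector("list", L)
  gb <- vector("list", L)
  for (l in L:1) {
    gW[[l]] <- crossprod(A[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- (delta %*% t(net$W[[l]])) *
        act_deriv(A[[l]], net$config$activations[l - 1])
    }
  }
  list(W = gW, b = gb, loss = mlp_loss(A[[L + 1]], Y))
}

fit_scaling <- function(M) {
  mn <- apply(M, 2, min)
  mx <- apply(M, 2, max)
  rng <- mx - mn
  rng[rng == 0] <- 1  # constant feature maps to 0
  list(min = mn, range = rng)
}

apply_scaling <- function(M, s) sweep(sweep(M, 2, s$min), 2, s$range, "/")
undo_scaling <- function(M, s) sweep(sweep(M, 2, s$range, "*"), 2, s$min, "+")

#' Train a network by full-batch backpropagation with momentum
#'
#' Each epoch takes one full-batch gradient step
#' `dW_t = -lr * grad + momentum * dW_{t-1}`. Training stops at
#' `max_epochs` or when the validation RMS has not improved for
#' `config$patience` epochs; the weights at the best validation epoch are
#' returned. Scaling to \[0, 1\] is fitted on the training inputs and
#' targets and applied to both sets.
#'
#' @param net An [init_mlp()] network (untrained).
#' @param x_train,y_train Training inputs/targets, rows = samples, in
#'   original units.
#' @param x_val,y_val Optional validation set; defaults to the training
#'   set (then early stopping monitors training RMS).
#' @return The trained `mlp`, with `history` (per-epoch training loss) and
#'   `metrics`: `rms` (validation root-mean-square error on the scaled
#'   scale) and `r2` (squared correlation of observed vs predicted
#'   validation outputs).
#' @export
train_backprop <- function(net, x_train, y_train, x_val = NULL,
                           y_val = NULL) {
  x_train <- as.matrix(x_train); y_train <- as.matrix(y_train)
  stopifnot(nrow(x_train) > 0, nrow(x_train) == nrow(y_train))
  if (is.null(x_val)) { x_val <- x_train; y_val <- y_train }
  x_val <- as.matrix(x_val); y_val <- as.matrix(y_val)
  cfg <- net$config
  net$scaling <- list(x = fit_scaling(x_train), y = fit_scaling(y_train))
  Xtr <- apply_scaling(x_train, net$scaling$x)
  Ytr <- apply_scaling(y_train, net$scaling$y)
  Xva <- apply_scaling(x_val, net$scaling$x)
  Yva <- apply_scaling(y_val, net$scaling$y)

  vel_W <- lapply(net$W, function(w) w * 0)
  vel_b <- lapply(net$b, function(v) v * 0)
  history <- numeric(0)
  best <- list(rms = Inf, W = net$W, b = net$b, epoch = 0L)
  stale <- 0L
  val_rms <- function() {
    pred <- mlp_forward_pass(net, Xva)[[length(net$W) + 1]]
    sqrt(mean((pred - Yva)^2))
  }
  for (epoch in seq_len(cfg$max_epochs)) {
    g <- mlp_gradients(net, Xtr, Ytr)
    if (!is.finite(g$loss)) {
      stop("training diverged (non-finite loss) at epoch ", epoch,
           call. = FALSE)
    }
    history[epoch] <- g$loss
    for (l in seq_along(net$W)) {
      vel_W[[l]] <- -cfg$learning_rate * g$W[[l]] +
        cfg$momentum * vel_W[[l]]
      vel_b[[l]] <- -cfg$learning_rate * g$b[[l]] +
        cfg$momentum * vel_b[[l]]
      net$W[[l]] <- net$W[[l]] + vel_W[[l]]
      net$b[[l]] <- net$b[[l]] + vel_b[[l]]
    }
    rms <- val_rms()
    if (rms < best$rms - 1e-12) {
      best <- list(rms = rms, W = net$W, b = net$b, epoch = epoch)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= cfg$patience) break
    }
  }
  net$W <- best$W
  net$b <- best$b
  net$history <- history
  pred <- mlp_forward_pass(net, Xva)[[length(net$W) + 1]]
  r2 <- if (length(Yva) >= 2 && stats::sd(as.numeric(Yva)) > 0 &&
            stats::sd(as.numeric(pred)) > 0) {
    stats::cor(as.numeric(Yva), as.numeric(pred))^2
  } else NA_real_
  net$metrics <- list(rms = best$rms, r2 = r2, best_epoch = best$epoch)
  net
}

#' Forward prediction in original units
#'
#' @param net A trained `mlp`.
#' @param x Input matrix (rows = samples) or vector, original units.
#' @return Prediction matrix in original output units (un-scaled).
#' @export
mlp_predict <- function(net, x) {
  if (is.null(net$scaling)) stop("network is untrained", call. = FALSE)
  x <- if (is.null(dim(x))) matrix(x, 1) else as.matrix(x)
  if (ncol(x) != net$config$layer_sizes[1]) {
    stop("input has ", ncol(x), " columns; network expects ",
         net$config$layer_sizes[1], call. = FALSE)
  }
  Xs <- apply_scaling(x, net$scaling$x)
  pred <- mlp_forward_pass(net, Xs)[[length(net$W) + 1]]
  undo_scaling(pred, net$scaling$y)
}

#' Predict a cumulative release profile for a formulation
#'
#' A 3-input network takes the composition (PEGDA, PEG 400, water); a
#' 4-input network additionally requires the exposure time in seconds.
#' Outputs are clipped to \[0, 100\] percent and associated with the
#' network's configured time grid.
#'
#' @param net A trained `mlp` (3 or 4 inputs).
#' @param formulation One-row formulation (list or data frame row).
#' @param exposure_time Exposure time in seconds; required iff the network
#'   has 4 inputs.
#' @param times Time grid in hours, one per output unit; defaults to the
#'   grid stored on the network (`net$times`) when present, else to the
#'   published grids for 5- and 4-output networks.
#' @return A tibble with `time_h` and `released_pct`.
#' @export
predict_release <- function(net, formulation, exposure_time = NULL,
                            times = NULL) {
  n_in <- net$config$layer_sizes[1]
  x <- c(formulation$pegda, formulation$peg400, formulation$water)
  if (n_in == 4) {
    if (is.null(exposure_time)) {
      stop("this network takes exposure time as its fourth input; ",
           "supply exposure_time (seconds)", call. = FALSE)
    }
    x <- c(x, exposure_time)
  } else if (n_in != 3) {
    stop("release networks have 3 or 4 inputs; this one has ", n_in,
         call. = FALSE)
  }
  n_out <- net$config$layer_sizes[length(net$config$layer_sizes)]
  if (is.null(times)) times <- net$times
  if (is.null(times)) {
    times <- if (n_out == 5) c(1, 2, 4, 6, 8) else if (n_out == 4)
      c(2, 4, 6, 8) else seq_len(n_out)
  }
  if (length(times) != n_out) {
    stop("times must have one entry per output unit (", n_out, ")",
         call. = FALSE)
  }
  pred <- pmin(pmax(as.numeric(mlp_predict(net, x)), 0), 100)
  tibble::tibble(time_h = times, released_pct = pred)
}

#' Trial-and-error architecture search
#'
#' Trains one network per (hidden-layer count, nodes-per-layer)
#' combination on a fixed seed schedule and ranks them by validation RMS,
#' ties broken by higher squared correlation. Equal node counts in every
#' hidden layer are used, matching the coarse grid such a manual search
#' walks.
#'
#' @param x_train,y_train,x_val,y_val Data matrices in original units.
#' @param hidden_layers Integer vector of hidden-layer counts to try.
#' @param nodes Integer vector of nodes-per-hidden-layer values to try.
#' @param template An [mlp_config()] whose activations and training
#'   hyperparameters are reused; its layer sizes are ignored.
#' @return A list with `best` (trained `mlp`), `best_config`, and
#'   `leaderboard` (tibble: hidden_layers, nodes, rms, r2, error).
#'   Failed cells are recorded, not fatal.
#' @export
architecture_search <- function(x_train, y_train, x_val, y_val,
                                hidden_layers = 1:2, nodes = 4:10,
                                template = mlp_config(c(1, 1))) {
  x_train <- as.matrix(x_train); y_train <- as.matrix(y_train)
  grid <- expand.grid(hidden_layers = hidden_layers, nodes = nodes)
  rows <- vector("list", nrow(grid))
  best <- NULL
  best_key <- c(Inf, -Inf)
  for (i in seq_len(nrow(grid))) {
    hl <- grid$hidden_layers[i]
    nd <- grid$nodes[i]
    sizes <- c(ncol(x_train), rep(nd, hl), ncol(y_train))
    cfg <- mlp_config(sizes, activations = template$activations[1],
                      learning_rate = template$learning_rate,
                      momentum = template$momentum,
                      max_epochs = template$max_epochs,
                      patience = template$patience,
                      seed = template$seed + i)
    res <- tryCatch(
      train_backprop(init_mlp(cfg), x_train, y_train, x_val, y_val),
      error = function(e) e)
    if (inherits(res, "error")) {
      rows[[i]] <- tibble::tibble(hidden_layers = hl, nodes = nd,
                                  rms = NA_real_, r2 = NA_real_,
                                  error = conditionMessage(res))
    } else {
      rows[[i]] <- tibble::tibble(hidden_layers = hl, nodes = nd,
                                  rms = res$metrics$rms,
                                  r2 = res$metrics$r2,
                                  error = NA_character_)
      key <- c(res$metrics$rms,
               -ifelse(is.na(res$metrics$r2), -Inf, res$metrics$r2))
      if (key[1] < best_key[1] ||
          (key[1] == best_key[1] && key[2] < best_key[2])) {
        best <- res
        best_key <- key
      }
    }
  }
  leaderboard <- do.call(rbind, rows)
  leaderboard <- leaderboard[order(leaderboard$rms), ]
  list(best = best,
       best_config = if (!is.null(best)) best$config,
       leaderboard = leaderboard)
}

#' Serialize a trained network to a portable YAML bundle
#'
#' @param net A trained `mlp`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mlp <- function(net, path) {
  bundle <- list(
    layer_sizes = net$config$layer_sizes,
    activations = net$config$activations,
    learning_rate = net$config$learning_rate,
    momentum = net$config$momentum,
    seed = net$config$seed,
    weights = lapply(net$W, function(w) apply(w, 1, as.numeric,
                                              simplify = FALSE)),
    biases = lapply(net$b, as.numeric),
    scaling = list(
      x_min = as.numeric(net$scaling$x$min),
      x_range = as.numeric(net$scaling$x$range),
      y_min = as.numeric(net$scaling$y$min),
      y_range = as.numeric(net$scaling$y$range))
  )
  yaml::write_yaml(bundle, path, precision = 17)
  invisible(path)
}

#' Load a serialized network
#'
#' @param path A YAML bundle written by [write_mlp()].
#' @return A trained `mlp`.
#' @export
read_mlp <- function(path) {
  bundle <- yaml::read_yaml(path)
  cfg <- mlp_config(bundle$layer_sizes, bundle$activations,
                    learning_rate = bundle$learning_rate,
                    momentum = bundle$momentum, seed = bundle$seed)
  net <- init_mlp(cfg)
  sizes <- cfg$layer_sizes
  net$W <- lapply(seq_along(bundle$weights), function(l) {
    matrix(unlist(bundle$weights[[l]]), sizes[l], sizes[l + 1],
           byrow = TRUE)
  })
  net$b <- lapply(bundle$biases, as.numeric)
  net$scaling <- list(
    x = list(min = bundle$scaling$x_min, range = bundle$scaling$x_range),
    y = list(min = bundle$scaling$y_min, range = bundle$scaling$y_range))
  net
}
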