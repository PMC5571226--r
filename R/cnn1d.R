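# Compact 2-channel 1D CNN, the personal classifier.  Topology: input
# 2 x 128 -> three hidden conv layers (32, 16, 16 neurons, kernel 7, valid
# mode, tanh, average sub-sampling by 3) -> global average pool -> fully
# connected 16 -> 32 -> 5 (tanh).  Trained by full-batch back-propagation
# on an MSE loss against +/-1 target encoding, with multiplicative
# learning-rate adaptation and shallow-training stopping rules.

#' CNN configuration
#'
#' Defaults are the reference setup of the method: 32/16/16 hidden conv
#' neurons, 32 fully-connected hidden neurons, 5 outputs (the AAMI
#' classes), 2 input channels (single-beat and beat-trio), kernel size 7,
#' sub-sampling factor 3; shallow training capped at 50 back-propagation
#' iterations or a 3% train classification error, learning factor starting
#' at 0.001 and multiplied by 1.05 after an MSE decrease, by 0.70
#' otherwise.
#'
#' @param conv_neurons hidden conv layer widths.
#' @param fc_neurons hidden fully-connected width.
#' @param n_outputs output classes.
#' @param n_input_channels input channels.
#' @param kernel_size conv kernel taps.
#' @param subsample average-pooling factor.
#' @param max_iters maximum BP iterations.
#' @param min_train_error train classification-error floor in (0,1).
#' @param eps0 initial learning factor.
#' @param eps_up,eps_down multiplicative adaptation factors.
#' @param pool `"avg"` (default) or `"max"`.
#' @param seed integer seed for weight initialization.
#' @return An object of class `cnn_config`.
#' @export
cnn_config <- function(conv_neurons = c(32L, 16L, 16L), fc_neurons = 32L,
                       n_outputs = 5L, n_input_channels = 2L,
                       kernel_size = 7L, subsample = 3L, max_iters = 50L,
                       min_train_error = 0.03, eps0 = 0.001,
                       eps_up = 1.05, eps_down = 0.70,
                       pool = c("avg", "max"), seed = 1L) {
  pool <- match.arg(pool)
  cfg <- list(conv_neurons = as.integer(conv_neurons),
              fc_neurons = as.integer(fc_neurons),
              n_outputs = as.integer(n_outputs),
              n_input_channels = as.integer(n_input_channels),
              kernel_size = as.integer(kernel_size),
              subsample = as.integer(subsample),
              max_iters = as.integer(max_iters),
              min_train_error = min_train_error,
              eps0 = eps0, eps_up = eps_up, eps_down = eps_down,
              pool = pool, seed = as.integer(seed))
  stopifnot(all(cfg$conv_neurons > 0L), cfg$fc_neurons > 0L,
            cfg$n_outputs > 0L, cfg$n_input_channels > 0L,
            cfg$kernel_size > 0L, cfg$subsample > 0L, cfg$max_iters >= 0L,
            cfg$min_train_error > 0, cfg$min_train_error < 1,
            cfg$eps0 > 0, cfg$eps_up > 0, cfg$eps_down > 0)
  structure(cfg, class = "cnn_config")
}

#' Layer-length arithmetic of the network
#'
#' Walks the conv stack computing the sequence length after each valid-mode
#' convolution and sub-sampling; the last conv layer is globally pooled to
#' one scalar per neuron, which makes the fully-connected input width
#' independent of the input length. With the defaults:
#' 128 -> 122 -> 40 -> 34 -> 11 -> 5 -> 1.
#'
#' @param cfg a [cnn_config()].
#' @param input_length input sequence length (default 128).
#' @return List with `conv_out` (length after each convolution),
#'   `pooled_out` (after each sub-sampling; the last entry is 1) and
#'   `fc_input` (fully-connected input width).
#' @export
cnn_layer_dims <- function(cfg, input_length = beat_length()) {
  L <- as.integer(input_length)
  nl <- length(cfg$conv_neurons)
  conv_out <- integer(nl); pooled_out <- integer(nl)
  for (i in seq_len(nl)) {
    P <- L - cfg$kernel_size + 1L
    if (P < 1L)
      stop("layer ", i, ": input length ", L, " shorter than kernel ",
           cfg$kernel_size, call. = FALSE)
    conv_out[i] <- P
    if (i < nl) {
      L <- P %/% cfg$subsample
      if (L < 1L) stop("layer ", i, ": sub-sampling empties the sequence",
                       call. = FALSE)
    } else L <- 1L  # global average pool of the remaining P samples
    pooled_out[i] <- L
  }
  list(conv_out = conv_out, pooled_out = pooled_out,
       fc_input = cfg$conv_neurons[nl])
}

#' Initialize a CNN with seeded, fan-scaled uniform weights
#'
#' Weights are drawn uniformly from \[-a, a\] with
#' `a = sqrt(6 / (fan_in + fan_out))` per layer (fan-scaled/Glorot
#' initialization; for a conv layer `fan_in = in_channels * kernel_size`),
#' biases uniformly from \[-0.1, 0.1\]. Fan scaling keeps the signal
#' amplitude roughly constant through the five tanh stages, which is what
#' lets the network train at the small shallow-training learning factor; a
#' flat small init attenuates the input ~100-fold by the fully-connected
#' stage and cannot escape the majority class within the iteration budget.
#' All draws come from a seeded generator, so initialization (and hence
#' the whole deterministic training) is reproducible from the seed alone;
#' the global RNG state is left untouched.
#'
#' @param cfg a [cnn_config()].
#' @param seed integer seed; defaults to `cfg$seed`.
#' @return An object of class `cnn_model` holding per-layer weight
#'   matrices/biases, the config and the layer dimensions.
#' @export
cnn_init <- function(cfg = cnn_config(), seed = cfg$seed) {
  dims <- cnn_layer_dims(cfg)
  withr::with_seed(as.integer(seed), {
    glorot <- function(fan_in, fan_out) {
      a <- sqrt(6 / (fan_in + fan_out))
      matrix(stats::runif(fan_in * fan_out, -a, a), fan_in, fan_out)
    }
    ub <- function(n) stats::runif(n, -0.1, 0.1)
    n_in <- cfg$n_input_channels
    conv <- vector("list", length(cfg$conv_neurons))
    for (i in seq_along(cfg$conv_neurons)) {
      n_out <- cfg$conv_neurons[i]
      # weight row (k-1)*n_in + c holds tap k of input channel c
      conv[[i]] <- list(W = glorot(n_in * cfg$kernel_size, n_out),
                        b = ub(n_out))
      n_in <- n_out
    }
    fc1 <- list(W = glorot(dims$fc_input, cfg$fc_neurons),
                b = ub(cfg$fc_neurons))
    fc2 <- list(W = glorot(cfg$fc_neurons, cfg$n_outputs),
                b = ub(cfg$n_outputs))
    structure(list(conv = conv, fc1 = fc1, fc2 = fc2, config = cfg,
                   dims = dims, seed = as.integer(seed)),
              class = "cnn_model")
  })
}

#' @export
print.cnn_model <- function(x, ...) {
  np <- sum(vapply(c(lapply(x$conv, `[[`, "W"), lapply(x$conv, `[[`, "b"),
                     list(x$fc1$W, x$fc1$b, x$fc2$W, x$fc2$b)),
                   length, 1L))
  cat(sprintf("<cnn_model> conv %s, fc %d->%d, kernel %d, pool %d: %d parameters (seed %d)\n",
              paste(x$config$conv_neurons, collapse = "/"),
              x$dims$fc_input, x$config$fc_neurons, x$config$kernel_size,
              x$config$subsample, np, x$seed))
  invisible(x)
}

## internal: gather sliding windows — x (B x C x L) -> (B*P) x (C*K) with
## column index (k-1)*C + c, matching the weight layout
im2col <- function(x, K) {
  d <- dim(x); B <- d[1]; C <- d[2]; L <- d[3]
  P <- L - K + 1L
  out <- array(0, c(B, P, C, K))
  for (k in seq_len(K))
    out[, , , k] <- aperm(x[, , k:(k + P - 1L), drop = FALSE], c(1, 3, 2))
  dim(out) <- c(B * P, C * K)
  out
}

## internal: scatter-add inverse of im2col
col2im <- function(dXc, B, C, L, K) {
  P <- L - K + 1L
  dim(dXc) <- c(B, P, C, K)
  dX <- array(0, c(B, C, L))
  for (k in seq_len(K)) {
    idx <- k:(k + P - 1L)
    sl <- dXc[, , , k, drop = FALSE]
    dim(sl) <- dim(sl)[1:3]
    dX[, , idx] <- dX[, , idx, drop = FALSE] + aperm(sl, c(1, 3, 2))
  }
  dX
}

## internal: forward through the whole net with caches for backprop.
## X: B x C x 128 array. Returns outputs (B x n_outputs) + caches.
cnn_forward_cached <- function(model, X) {
  cfg <- model$config
  K <- cfg$kernel_size; s <- cfg$subsample
  nl <- length(model$conv)
  caches <- vector("list", nl)
  a <- X
  for (i in seq_len(nl)) {
    d <- dim(a); B <- d[1]; C <- d[2]; L <- d[3]
    P <- L - K + 1L
    Xc <- im2col(a, K)
    Y <- tanh(sweep(Xc %*% model$conv[[i]]$W, 2, model$conv[[i]]$b, "+"))
    N <- cfg$conv_neurons[i]
    y <- aperm(array(Y, c(B, P, N)), c(1, 3, 2))     # B x N x P
    if (i < nl) {
      Q <- P %/% s
      if (cfg$pool == "avg") {
        yt <- y[, , seq_len(Q * s), drop = FALSE]
        dim(yt) <- c(B, N, s, Q)
        pooled <- colMeans(aperm(yt, c(3, 1, 2, 4)))  # B x N x Q
        argmax <- NULL
      } else {
        yt <- y[, , seq_len(Q * s), drop = FALSE]
        dim(yt) <- c(B, N, s, Q)
        pooled <- apply(yt, c(1, 2, 4), max)
        argmax <- apply(yt, c(1, 2, 4), which.max)
      }
    } else {
      Q <- 1L
      if (cfg$pool == "avg") {
        pooled <- array(rowMeans(matrix(aperm(y, c(3, 1, 2)), P, B * N) |>
                                   t()), c(B, N, 1L))
        argmax <- NULL
      } else {
        pooled <- array(apply(y, c(1, 2), max), c(B, N, 1L))
        argmax <- array(apply(y, c(1, 2), which.max), c(B, N, 1L))
      }
    }
    caches[[i]] <- list(Xc = Xc, y = y, in_dim = d, P = P, Q = Q,
                        argmax = argmax)
    a <- pooled
  }
  B <- dim(a)[1]
  flat <- matrix(a, B, model$dims$fc_input)  # Q == 1 on the last layer
  h <- tanh(sweep(flat %*% model$fc1$W, 2, model$fc1$b, "+"))
  out <- tanh(sweep(h %*% model$fc2$W, 2, model$fc2$b, "+"))
  list(out = out, h = h, flat = flat, caches = caches)
}

#' Forward pass over a batch of beats
#'
#' @param model a [cnn_init()]/[train_cnn()] model.
#' @param X numeric array `B x n_input_channels x 128`, or for a single
#'   beat, two 128-sample vectors via `single`/`trio`.
#' @param single,trio alternative single-observation interface: 128-sample
#'   numeric vectors (or [beat_vector()]s) for the two channels.
#' @return A `B x n_outputs` matrix of tanh outputs in (-1, 1); for the
#'   single-observation interface, a length-5 vector.
#' @export
cnn_forward <- function(model, X = NULL, single = NULL, trio = NULL) {
  stopifnot(inherits(model, "cnn_model"))
  if (is.null(X)) {
    if (inherits(single, "beat_vector")) single <- single$samples
    if (inherits(trio, "beat_vector")) trio <- trio$samples
    if (length(single) != beat_length() || length(trio) != beat_length())
      stop("input layer: both channels must have ", beat_length(),
           " samples", call. = FALSE)
    X <- array(0, c(1L, 2L, beat_length()))
    X[1, 1, ] <- single; X[1, 2, ] <- trio
    return(as.numeric(cnn_forward_cached(model, X)$out))
  }
  if (length(dim(X)) != 3L || dim(X)[2] != model$config$n_input_channels ||
      dim(X)[3] != beat_length())
    stop("input layer: X must be B x ", model$config$n_input_channels,
         " x ", beat_length(), call. = FALSE)
  cnn_forward_cached(model, X)$out
}

#' Straight-loop reference forward pass
#'
#' An independent, deliberately unvectorized implementation of the forward
#' pass (explicit loops over neurons, positions and taps) used to
#' cross-check the batched implementation. Average pooling only.
#'
#' @param model a `cnn_model`.
#' @param single,trio 128-sample numeric vectors.
#' @return Length-5 numeric output vector.
#' @export
cnn_forward_loop <- function(model, single, trio) {
  cfg <- model$config
  if (cfg$pool != "avg") stop("loop oracle implements average pooling only")
  K <- cfg$kernel_size; s <- cfg$subsample
  act <- rbind(single, trio)               # C x L
  nl <- length(model$conv)
  for (i in seq_len(nl)) {
    C <- nrow(act); L <- ncol(act); P <- L - K + 1L
    N <- cfg$conv_neurons[i]
    y <- matrix(0, N, P)
    for (n in seq_len(N)) {
      for (p in seq_len(P)) {
        z <- model$conv[[i]]$b[n]
        for (c in seq_len(C))
          for (k in seq_len(K))
            z <- z + model$conv[[i]]$W[(k - 1L) * C + c, n] *
              act[c, p + k - 1L]
        y[n, p] <- tanh(z)
      }
    }
    if (i < nl) {
      Q <- P %/% s
      pooled <- matrix(0, N, Q)
      for (n in seq_len(N))
        for (q in seq_len(Q))
          pooled[n, q] <- mean(y[n, ((q - 1L) * s + 1L):(q * s)])
      act <- pooled
    } else {
      act <- matrix(rowMeans(y), N, 1L)
    }
  }
  flat <- act[, 1]
  h <- numeric(cfg$fc_neurons)
  for (j in seq_len(cfg$fc_neurons))
    h[j] <- tanh(sum(flat * model$fc1$W[, j]) + model$fc1$b[j])
  out <- numeric(cfg$n_outputs)
  for (o in seq_len(cfg$n_outputs))
    out[o] <- tanh(sum(h * model$fc2$W[, o]) + model$fc2$b[o])
  out
}

#' MSE loss and analytic gradients over a batch
#'
#' Targets use the +/-1 encoding matched to the tanh output range: +1 at
#' the true class, -1 elsewhere. The loss is the mean squared error over
#' all batch items and output units; gradients are returned for every
#' parameter in the same structure as the model.
#'
#' @param model a `cnn_model`.
#' @param X `B x channels x 128` input array.
#' @param targets `B x n_outputs` matrix of +/-1 targets (see
#'   [class_targets()]).
#' @return List with `mse`, `outputs` and `grads` (elements `conv` — list
#'   of `W`/`b` — `fc1`, `fc2`).
#' @export
loss_and_gradients <- function(model, X, targets) {
  cfg <- model$config
  fw <- cnn_forward_cached(model, X)
  B <- dim(X)[1]
  err <- fw$out - targets
  mse <- mean(err^2)
  n_el <- length(err)

  d_out <- (2 / n_el) * err * (1 - fw$out^2)          # through output tanh
  g_fc2 <- list(W = crossprod(fw$h, d_out), b = colSums(d_out))
  d_h <- (d_out %*% t(model$fc2$W)) * (1 - fw$h^2)
  g_fc1 <- list(W = crossprod(fw$flat, d_h), b = colSums(d_h))
  d_flat <- d_h %*% t(model$fc1$W)                     # B x fc_input

  K <- cfg$kernel_size; s <- cfg$subsample
  nl <- length(model$conv)
  g_conv <- vector("list", nl)
  d_pooled <- array(d_flat, c(B, model$dims$fc_input, 1L))
  for (i in rev(seq_len(nl))) {
    cache <- caches_i <- fw$caches[[i]]
    N <- cfg$conv_neurons[i]; P <- cache$P; Q <- cache$Q
    # un-pool: spread each pooled gradient over its window
    d_y <- array(0, c(B, N, P))
    if (i < nl) {
      if (cfg$pool == "avg") {
        for (j in seq_len(s))
          d_y[, , (seq_len(Q) - 1L) * s + j] <- d_pooled / s
      } else {
        for (q in seq_len(Q)) {
          pos <- (q - 1L) * s + cache$argmax[, , q]
          for (b_i in seq_len(B)) for (n in seq_len(N))
            d_y[b_i, n, pos[b_i, n]] <- d_pooled[b_i, n, q]
        }
      }
    } else {
      if (cfg$pool == "avg") {
        d_y <- array(rep(d_pooled[, , 1] / P, P), c(B, N, P))
      } else {
        for (b_i in seq_len(B)) for (n in seq_len(N))
          d_y[b_i, n, cache$argmax[b_i, n, 1]] <- d_pooled[b_i, n, 1]
      }
    }
    # through tanh and the convolution
    y_mat <- matrix(aperm(cache$y, c(1, 3, 2)), B * P, N)
    d_z <- matrix(aperm(d_y, c(1, 3, 2)), B * P, N) * (1 - y_mat^2)
    g_conv[[i]] <- list(W = crossprod(cache$Xc, d_z), b = colSums(d_z))
    if (i > 1L) {
      d_in <- col2im(d_z %*% t(model$conv[[i]]$W),
                     B, cache$in_dim[2], cache$in_dim[3], K)
      d_pooled <- d_in  # becomes the pooled-output gradient of layer i-1
    }
  }
  list(mse = mse, outputs = fw$out,
       grads = list(conv = g_conv, fc1 = g_fc1, fc2 = g_fc2))
}

#' Target encoding for a label vector
#' @param labels character vector of AAMI symbols.
#' @param n_outputs number of output units (default 5).
#' @return `length(labels) x n_outputs` matrix of -1 with +1 at the true
#'   class column (column order [aami_classes()]).
#' @export
class_targets <- function(labels, n_outputs = 5L) {
  idx <- match(labels, aami_classes())
  if (anyNA(idx)) stop("unknown labels", call. = FALSE)
  t_mat <- matrix(-1, length(labels), n_outputs)
  t_mat[cbind(seq_along(labels), idx)] <- 1
  t_mat
}

#' Convert a training set to input arrays
#' @param ts a `training_set`.
#' @return List with `X` (`B x 2 x 128`: channel 1 the single beat, channel
#'   2 the trio) and `labels`.
#' @export
training_set_to_arrays <- function(ts) {
  stopifnot(inherits(ts, "training_set"))
  B <- length(ts$items)
  X <- array(0, c(B, 2L, beat_length()))
  labels <- character(B)
  for (i in seq_len(B)) {
    X[i, 1, ] <- ts$items[[i]]$single$samples
    X[i, 2, ] <- ts$items[[i]]$trio$samples
    labels[i] <- ts$items[[i]]$label
  }
  list(X = X, labels = labels)
}

## internal: one epoch of per-sample BP in R — the reference engine.
## Returns the updated model and the summed squared error (accumulated
## before each item's update, as in the C++ engine).
train_epoch_r <- function(model, X, targets, order, eps) {
  sse <- 0
  n_out <- ncol(targets)
  for (b in order) {
    lg <- loss_and_gradients(model, X[b, , , drop = FALSE],
                             targets[b, , drop = FALSE])
    sse <- sse + lg$mse * n_out
    # convert the batch-mean gradient of a 1-item batch to the per-item
    # sum-of-squares gradient
    sc <- n_out
    for (i in seq_along(model$conv)) {
      model$conv[[i]]$W <- model$conv[[i]]$W - eps * sc * lg$grads$conv[[i]]$W
      model$conv[[i]]$b <- model$conv[[i]]$b - eps * sc * lg$grads$conv[[i]]$b
    }
    model$fc1$W <- model$fc1$W - eps * sc * lg$grads$fc1$W
    model$fc1$b <- model$fc1$b - eps * sc * lg$grads$fc1$b
    model$fc2$W <- model$fc2$W - eps * sc * lg$grads$fc2$W
    model$fc2$b <- model$fc2$b - eps * sc * lg$grads$fc2$b
  }
  list(model = model, sse = sse)
}

## internal: one epoch of per-sample BP via the compiled kernel
train_epoch_cpp <- function(model, Xflat, targets, order, eps) {
  cfg <- model$config
  res <- cpp_train_epoch(lapply(model$conv, `[[`, "W"),
                         lapply(model$conv, `[[`, "b"),
                         model$fc1$W, model$fc1$b,
                         model$fc2$W, model$fc2$b,
                         Xflat, targets, order - 1L, eps,
                         cfg$n_input_channels, beat_length(),
                         cfg$kernel_size, cfg$subsample)
  for (i in seq_along(model$conv)) {
    model$conv[[i]]$W <- res$convW[[i]]
    model$conv[[i]]$b <- as.numeric(res$convb[[i]])
  }
  model$fc1$W <- res$fc1W; model$fc1$b <- as.numeric(res$fc1b)
  model$fc2$W <- res$fc2W; model$fc2$b <- as.numeric(res$fc2b)
  list(model = model, sse = res$sse)
}

#' Train the personal CNN by shallow back-propagation
#'
#' Weights are initialized by [cnn_init()] from the seed; each BP
#' iteration is then one deterministic per-sample sweep over the training
#' set (the item order is a seeded shuffle, fixed by the seed and the
#' iteration number), with each item's squared-error gradient applied
#' immediately at the current learning factor. Training stops after
#' `max_iters` iterations or as soon as the train classification error
#' (argmax over the full set, evaluated after the sweep) reaches
#' `min_train_error`.
#'
#' The learning factor starts at `eps0` and after each iteration is
#' multiplied by `eps_up` (1.05) if that iteration's MSE decreased
#' relative to the previous iteration (the first iteration always counts
#' as a decrease), by `eps_down` (0.70) otherwise — the factor recorded
#' for iteration i is the one its sweep used. The reported MSE is the mean
#' of the per-item squared output errors accumulated during the sweep.
#' Training is fully deterministic given the dataset and seed.
#'
#' @param dataset a `training_set`, or a list with `X` (`B x 2 x 128`) and
#'   `labels`; must contain at least two classes.
#' @param cfg a [cnn_config()].
#' @param seed initialization seed; defaults to `cfg$seed`.
#' @param engine `"cpp"` (compiled per-sample sweep, default) or `"r"`
#'   (pure-R reference sweep; identical arithmetic, much slower).
#' @return List with `model` (a `cnn_model`), `history` (data frame with
#'   per-iteration `iter`, `mse`, `train_error`, `eps`) and `stop_reason`
#'   (`"max_iters"` or `"error_floor"`).
#' @export
train_cnn <- function(dataset, cfg = cnn_config(), seed = cfg$seed,
                      engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (inherits(dataset, "training_set"))
    dataset <- training_set_to_arrays(dataset)
  X <- dataset$X; labels <- dataset$labels
  if (length(unique(labels)) < 2L)
    stop("training refused: dataset contains a single class ('",
         unique(labels), "'); the filter library provided no synthetic ",
         "abnormal beats", call. = FALSE)
  targets <- class_targets(labels, cfg$n_outputs)
  model <- cnn_init(cfg, seed)
  B <- dim(X)[1]
  true_idx <- match(labels, aami_classes())
  # epoch item orders: seeded shuffles, drawn once so both engines and
  # reruns see identical orders
  orders <- withr::with_seed((as.integer(seed) %% 1000000000L) + 7L,
    lapply(seq_len(cfg$max_iters), function(i) sample.int(B)))
  # column b = column-major (channel-fastest) flattening of item b
  Xflat <- if (engine == "cpp")
    matrix(aperm(X, c(2, 3, 1)),
           model$config$n_input_channels * beat_length(), B)
  eps <- cfg$eps0
  mse_prev <- Inf
  hist <- vector("list", cfg$max_iters)
  stop_reason <- "max_iters"
  for (it in seq_len(cfg$max_iters)) {
    ep <- if (engine == "cpp")
      train_epoch_cpp(model, Xflat, targets, orders[[it]], eps)
    else train_epoch_r(model, X, targets, orders[[it]], eps)
    model <- ep$model
    mse <- ep$sse / (B * cfg$n_outputs)
    out <- if (engine == "cpp")
      cpp_forward_batch(lapply(model$conv, `[[`, "W"),
                        lapply(model$conv, `[[`, "b"),
                        model$fc1$W, model$fc1$b, model$fc2$W, model$fc2$b,
                        Xflat, cfg$n_input_channels, beat_length(),
                        cfg$kernel_size, cfg$subsample)
    else cnn_forward(model, X)
    train_err <- mean(max.col(out, ties.method = "first") != true_idx)
    hist[[it]] <- data.frame(iter = it, mse = mse, train_error = train_err,
                             eps = eps)
    if (train_err <= cfg$min_train_error) {
      stop_reason <- "error_floor"
      break
    }
    eps <- eps * if (mse < mse_prev) cfg$eps_up else cfg$eps_down
    mse_prev <- mse
  }
  history <- do.call(rbind, hist[!vapply(hist, is.null, TRUE)])
  if (is.null(history))
    history <- data.frame(iter = integer(), mse = numeric(),
                          train_error = numeric(), eps = numeric())
  list(model = model, history = history, stop_reason = stop_reason)
}

#' Classify one beat
#'
#' Argmax over the five outputs; exact ties go to the lowest class index
#' (the order of [aami_classes()]).
#'
#' @param model a `cnn_model`.
#' @param single,trio the two 128-sample channels.
#' @return One AAMI class symbol.
#' @export
cnn_predict <- function(model, single, trio) {
  out <- cnn_forward(model, single = single, trio = trio)
  aami_classes()[which.max(out)]
}

#' Classify a batch of beats
#' @param model a `cnn_model`.
#' @param X `B x 2 x 128` input array.
#' @return Character vector of AAMI class symbols.
#' @export
cnn_predict_batch <- function(model, X) {
  out <- cnn_forward(model, X)
  aami_classes()[max.col(out, ties.method = "first")]
}

#' Train an ensemble of CNNs from consecutive seeds
#'
#' Back-propagation is deterministic, so its outcome depends on the random
#' initialization; the reference protocol trains 10 independent runs per
#' subject and cumulates their confusion matrices. Run `i` uses seed
#' `seed + i - 1`.
#'
#' @param dataset as in [train_cnn()].
#' @param cfg a [cnn_config()].
#' @param n_runs number of runs (default 10).
#' @param seed master seed; defaults to `cfg$seed`.
#' @return List of [train_cnn()] results, one per run.
#' @export
run_ensemble <- function(dataset, cfg = cnn_config(), n_runs = 10L,
                         seed = cfg$seed) {
  if (n_runs < 1L) stop("n_runs must be >= 1", call. = FALSE)
  lapply(seq_len(n_runs) - 1L, function(k)
    train_cnn(dataset, cfg, seed = as.integer(seed) + k))
}

# --- model serialization: JSON with full-precision numbers

#' Write a CNN model to JSON
#'
#' Full-precision JSON (no rounding) with a config echo and format version;
#' the round-trip through [read_cnn()] is bit-exact.
#'
#' @param model a `cnn_model`.
#' @param path output file path.
#' @param config_hash optional provenance hash echoed into the file.
#' @return Invisibly, `path`.
#' @export
write_cnn <- function(model, path, config_hash = NULL) {
  stopifnot(inherits(model, "cnn_model"))
  obj <- list(
    format = "abswarn-cnn", version = 1L, config_hash = config_hash,
    config = unclass(model$config), seed = model$seed,
    conv = lapply(model$conv, function(l)
      list(W = as.numeric(l$W), dim = dim(l$W), b = l$b)),
    fc1 = list(W = as.numeric(model$fc1$W), dim = dim(model$fc1$W),
               b = model$fc1$b),
    fc2 = list(W = as.numeric(model$fc2$W), dim = dim(model$fc2$W),
               b = model$fc2$b))
  # I(17) = 17 significant digits, enough to round-trip IEEE doubles exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a CNN model written by [write_cnn()]
#' @param path file path.
#' @return A `cnn_model`.
#' @export
read_cnn <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "abswarn-cnn"))
    stop("not a CNN model file: ", path, call. = FALSE)
  cfg <- do.call(cnn_config, obj$config[setdiff(names(obj$config), NULL)])
  model <- cnn_init(cfg, obj$seed)
  for (i in seq_along(model$conv)) {
    model$conv[[i]]$W <- matrix(obj$conv$W[[i]], obj$conv$dim[[i]][1],
                                obj$conv$dim[[i]][2])
    model$conv[[i]]$b <- obj$conv$b[[i]]
  }
  model$fc1$W <- matrix(obj$fc1$W, obj$fc1$dim[1], obj$fc1$dim[2])
  model$fc1$b <- obj$fc1$b
  model$fc2$W <- matrix(obj$fc2$W, obj$fc2$dim[1], obj$fc2$dim[2])
  model$fc2$b <- obj$fc2$b
  model$config_hash <- obj$config_hash
  model
}
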