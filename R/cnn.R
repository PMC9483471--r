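#' Architecture of the SpO2 regression network
#'
#' Three convolutional stages followed by two fully connected stages mapping
#' a standardized `input_len x 3` window to a single SpO2 scalar. The first
#' convolution is two-dimensional over (time, color) with a 3 x 3 kernel and
#' no padding, collapsing the color axis (90 x 3 in -> 88 x 1 out per
#' filter); convolutions 2 and 3 are one-dimensional over time with kernel 3,
#' stride 1, no padding. All hidden activations are ReLU.
#'
#' @param conv_channels filter counts of the three convolutional stages
#'   (default `c(16, 32, 64)`).
#' @param conv_kernel kernel length over time for every stage (default 3;
#'   stage 1 also spans all 3 colors).
#' @param fc_width width of the penultimate fully connected layer
#'   (default 64); the final layer always has width 1.
#' @param input_len window length in frames (default 90 = 3 s at 30 fps).
#' @param n_colors number of color channels (3).
#' @return List of class `model_spec`.
#' @export
model_spec <- function(conv_channels = c(16, 32, 64), conv_kernel = 3,
                       fc_width = 64, input_len = 90, n_colors = 3) {
  stopifnot(length(conv_channels) == 3, all(conv_channels >= 1),
            conv_kernel >= 1, fc_width >= 1, n_colors >= 1)
  min_len <- 3 * (conv_kernel - 1) + 1
  if (input_len < min_len) {
    stop(sprintf("input_len = %d too short for three no-padding convolutions; minimum is %d",
                 input_len, min_len))
  }
  structure(list(conv_channels = as.integer(conv_channels),
                 conv_kernel = as.integer(conv_kernel),
                 fc_width = as.integer(fc_width),
                 input_len = as.integer(input_len),
                 n_colors = as.integer(n_colors)),
            class = "model_spec")
}

# Output lengths of the three conv stages.
conv_out_lens <- function(spec) {
  k <- spec$conv_kernel
  t1 <- spec$input_len - k + 1
  c(t1, t1 - k + 1, t1 - 2 * (k - 1))
}

#' Build an untrained network
#'
#' Weights use He (fan-in) initialization appropriate for ReLU; biases start
#' at zero. Initialization is deterministic given `seed`.
#'
#' @param spec a [model_spec()].
#' @param seed integer seed for the weight draw.
#' @return List of class `cnn_model` holding the parameter arrays and the
#'   spec.
#' @export
build_model <- function(spec = model_spec(), seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  k <- spec$conv_kernel
  ch <- spec$conv_channels
  lens <- conv_out_lens(spec)
  he <- function(dims, fan_in) {
    array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
  }
  params <- with_seed(seed, list(
    W1 = he(c(k, spec$n_colors, ch[1]), k * spec$n_colors),
    b1 = numeric(ch[1]),
    W2 = he(c(k, ch[1], ch[2]), k * ch[1]),
    b2 = numeric(ch[2]),
    W3 = he(c(k, ch[2], ch[3]), k * ch[2]),
    b3 = numeric(ch[3]),
    W4 = he(c(lens[3] * ch[3], spec$fc_width), lens[3] * ch[3]),
    b4 = numeric(spec$fc_width),
    W5 = he(c(spec$fc_width, 1), spec$fc_width),
    b5 = 0
  ))
  structure(list(params = params, spec = spec), class = "cnn_model")
}

#' Parameter count of a network
#' @param model a `cnn_model` or `trained_model`.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

# --- forward / backward -----------------------------------------------------
# Convolutions are computed as k accumulated matrix products: for kernel
# offset dt, the time-sliced input (n*Tout x Cin) is multiplied by the
# dt-th kernel slice (Cin x Cout). This keeps every heavy operation inside
# BLAS and needs no explicit im2col buffer.

conv_fwd <- function(X, W, b) {
  d <- dim(X)                                # n x T x Cin
  k <- dim(W)[1]
  cin <- dim(W)[2]
  cout <- dim(W)[3]
  tout <- d[2] - k + 1
  out <- matrix(rep(b, each = d[1] * tout), d[1] * tout, cout)
  for (dt in seq_len(k)) {
    Xs <- X[, dt:(dt + tout - 1), , drop = FALSE]
    dim(Xs) <- c(d[1] * tout, cin)
    out <- out + Xs %*% matrix(W[dt, , ], cin, cout)
  }
  array(out, dim = c(d[1], tout, cout))
}

conv_bwd <- function(X, W, dOut) {
  d <- dim(X)
  k <- dim(W)[1]
  cin <- dim(W)[2]
  cout <- dim(W)[3]
  tout <- dim(dOut)[2]
  dOutM <- dOut
  dim(dOutM) <- c(d[1] * tout, cout)
  dW <- array(0, dim = dim(W))
  dX <- array(0, dim = d)
  for (dt in seq_len(k)) {
    Xs <- X[, dt:(dt + tout - 1), , drop = FALSE]
    dim(Xs) <- c(d[1] * tout, cin)
    dW[dt, , ] <- crossprod(Xs, dOutM)
    dXs <- dOutM %*% t(matrix(W[dt, , ], cin, cout))
    dim(dXs) <- c(d[1], tout, cin)
    dX[, dt:(dt + tout - 1), ] <- dX[, dt:(dt + tout - 1), ] + dXs
  }
  list(dW = dW, db = colSums(dOutM), dX = dX)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Forward pass over a batch. X: n x input_len x 3 (standardized).
# Returns predictions and, when keep_cache, the activations for backprop.
cnn_forward <- function(params, X, keep_cache = FALSE) {
  n <- dim(X)[1]
  Z1 <- conv_fwd(X, params$W1, params$b1); A1 <- relu(Z1)
  Z2 <- conv_fwd(A1, params$W2, params$b2); A2 <- relu(Z2)
  Z3 <- conv_fwd(A2, params$W3, params$b3); A3 <- relu(Z3)
  Fm <- A3
  dim(Fm) <- c(n, prod(dim(A3)[2:3]))
  Z4 <- sweep(Fm %*% params$W4, 2, params$b4, `+`); A4 <- relu(Z4)
  pred <- drop(A4 %*% params$W5) + params$b5
  if (!keep_cache) return(list(pred = pred))
  list(pred = pred,
       cache = list(X = X, Z1 = Z1, A1 = A1, Z2 = Z2, A2 = A2,
                    Z3 = Z3, A3 = A3, Fm = Fm, Z4 = Z4, A4 = A4))
}

# Gradients of mean squared error w.r.t. all parameters.
cnn_backward <- function(params, cache, pred, y) {
  n <- length(y)
  dpred <- matrix(2 * (pred - y) / n, n, 1)
  dW5 <- crossprod(cache$A4, dpred)
  db5 <- sum(dpred)
  dA4 <- dpred %*% t(params$W5)
  dZ4 <- dA4 * (cache$Z4 > 0)
  dW4 <- crossprod(cache$Fm, dZ4)
  db4 <- colSums(dZ4)
  dFm <- dZ4 %*% t(params$W4)
  dA3 <- dFm
  dim(dA3) <- dim(cache$A3)
  dZ3 <- dA3 * (cache$Z3 > 0)
  g3 <- conv_bwd(cache$A2, params$W3, dZ3)
  dZ2 <- g3$dX * (cache$Z2 > 0)
  g2 <- conv_bwd(cache$A1, params$W2, dZ2)
  dZ1 <- g2$dX * (cache$Z1 > 0)
  g1 <- conv_bwd(cache$X, params$W1, dZ1)
  list(W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db,
       W3 = g3$dW, b3 = g3$db, W4 = dW4, b4 = db4,
       W5 = dW5, b5 = db5)
}

# --- optimizer --------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, l2 = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (l2 > 0 && startsWith(nm, "W")) g <- g + l2 * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Training configuration
#'
#' Defaults follow the reference protocol for this model family: Adam at
#' learning rate 1e-5 with a one-time decay by 0.1 after epoch 80 and L2
#' regularization of strength 0.1 (applied as optimizer weight decay on
#' weights, not biases). `max_epochs` and `batch_size` are not dictated by
#' that protocol; the defaults here (120, 256) pair with best-validation
#' checkpointing. Optional minority-range upsampling duplicates
#' low-saturation samples within each epoch's batch pool so their errors
#' weigh more; off by default.
#'
#' @param learning_rate Adam learning rate.
#' @param lr_decay_factor multiplicative decay applied once.
#' @param lr_decay_epoch epoch after which the decay applies.
#' @param l2_strength weight-decay coefficient.
#' @param max_epochs training epochs.
#' @param batch_size minibatch size.
#' @param upsample_minority logical flag.
#' @param minority_range `c(lo, hi)` SpO2 range considered minority.
#' @param grad_clip global gradient-norm ceiling per step (`Inf` disables).
#'   Clipping guards minibatch training against the occasional exploding
#'   step at aggressive learning rates.
#' @param seed seed for initialization and batch shuffling.
#' @return List of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-5, lr_decay_factor = 0.1,
                         lr_decay_epoch = 80, l2_strength = 0.1,
                         max_epochs = 120, batch_size = 256,
                         upsample_minority = FALSE,
                         minority_range = c(70, 85),
                         grad_clip = 10, seed = 1L) {
  stopifnot(learning_rate > 0, lr_decay_factor > 0, l2_strength >= 0,
            max_epochs >= 1, batch_size >= 1, lr_decay_epoch >= 1,
            grad_clip > 0)
  structure(list(learning_rate = learning_rate,
                 lr_decay_factor = lr_decay_factor,
                 lr_decay_epoch = lr_decay_epoch,
                 l2_strength = l2_strength,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 upsample_minority = upsample_minority,
                 minority_range = minority_range,
                 grad_clip = grad_clip,
                 seed = as.integer(seed)),
            class = "train_config")
}

# Scale gradients so their global L2 norm does not exceed `clip`.
clip_gradients <- function(grads, clip) {
  if (!is.finite(clip)) return(grads)
  total <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (total > clip) grads <- lapply(grads, function(g) g * (clip / total))
  grads
}

# Effective learning rate at a given epoch (single step decay).
lr_at_epoch <- function(config, epoch) {
  if (epoch > config$lr_decay_epoch) {
    config$learning_rate * config$lr_decay_factor
  } else {
    config$learning_rate
  }
}

#' Train the SpO2 regression network
#'
#' Minimizes mean squared error with Adam under the configured schedule.
#' Normalization statistics are computed from the training partition only
#' ([compute_norm_stats()]) and bundled into the returned model; validation
#' windows are standardized with those same statistics, never their own. The
#' checkpoint with the lowest validation MAE is returned. The output bias is
#' initialized at the training-label mean, so the untrained network starts
#' as the mean predictor and learns deviations from it.
#'
#' @param spec a [model_spec()] (or a prebuilt `cnn_model`, whose weights
#'   are then used as the starting point).
#' @param train_set,val_set raw (unstandardized) [sample_set()]s from
#'   disjoint subjects.
#' @param config a [train_config()].
#' @return List of class `trained_model`: `params` (best checkpoint),
#'   `spec`, `norm_stats`, `train_log` (per-epoch data frame), `best_epoch`.
#' @export
train_cnn <- function(spec, train_set, val_set, config = train_config()) {
  if (inherits(spec, "cnn_model")) {
    model <- spec
    spec <- model$spec
  } else {
    model <- build_model(spec, seed = config$seed)
  }
  stopifnot(inherits(train_set, "sample_set"), inherits(val_set, "sample_set"))
  if (n_samples(train_set) == 0 || n_samples(val_set) == 0) {
    stop("training and validation partitions must be non-empty")
  }
  if (length(intersect(unique(train_set$subject_id),
                       unique(val_set$subject_id))) > 0) {
    stop("training and validation partitions must come from disjoint subjects")
  }
  if (dim(train_set$windows)[2] != spec$input_len) {
    stop("window length does not match model input_len")
  }
  stats <- compute_norm_stats(train_set)
  tr <- standardize(train_set, stats)
  va <- standardize(val_set, stats)

  params <- model$params
  params$b5 <- mean(tr$label)
  opt <- adam_init(params)
  n <- n_samples(tr)
  y <- tr$label
  log <- data.frame(epoch = integer(0), lr = numeric(0),
                    train_mse = numeric(0), val_mae = numeric(0))
  best <- list(mae = Inf, params = params, epoch = 0L)

  with_seed(derive_seed(config$seed, "train/shuffle"), {
    for (epoch in seq_len(config$max_epochs)) {
      lr <- lr_at_epoch(config, epoch)
      pool <- seq_len(n)
      if (isTRUE(config$upsample_minority)) {
        lo <- config$minority_range[1]
        hi <- config$minority_range[2]
        minority <- which(y >= lo & y < hi)
        extra <- length(pool) - 2L * length(minority)
        if (length(minority) > 0 && extra > 0) {
          pool <- c(pool, sample(minority, extra, replace = TRUE))
        }
      }
      pool <- sample(pool)
      mse_sum <- 0
      nb <- 0L
      for (start in seq(1, length(pool), by = config$batch_size)) {
        idx <- pool[start:min(start + config$batch_size - 1L, length(pool))]
        Xb <- tr$windows[idx, , , drop = FALSE]
        fw <- cnn_forward(params, Xb, keep_cache = TRUE)
        grads <- cnn_backward(params, fw$cache, fw$pred, y[idx])
        grads <- clip_gradients(grads, config$grad_clip %||% Inf)
        step <- adam_step(params, grads, opt, lr, config$l2_strength)
        params <- step$params
        opt <- step$state
        mse_sum <- mse_sum + mean((fw$pred - y[idx])^2)
        nb <- nb + 1L
      }
      val_pred <- cnn_forward_batched(params, va$windows)
      val_mae <- mean(abs(val_pred - va$label))
      log <- rbind(log, data.frame(epoch = epoch, lr = lr,
                                   train_mse = mse_sum / nb,
                                   val_mae = val_mae))
      if (val_mae < best$mae) {
        best <- list(mae = val_mae, params = params, epoch = epoch)
      }
    }
  })
  structure(list(params = best$params, spec = spec, norm_stats = stats,
                 config = config, train_log = log, best_epoch = best$epoch,
                 best_val_mae = best$mae),
            class = "trained_model")
}

# Forward pass in manageable chunks (keeps the flattened activation matrix
# small for large sample sets).
cnn_forward_batched <- function(params, X, chunk = 512L) {
  n <- dim(X)[1]
  pred <- numeric(n)
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    pred[idx] <- cnn_forward(params, X[idx, , , drop = FALSE])$pred
  }
  pred
}

#' Predict SpO2 for a sample set
#'
#' Accepts raw (unstandardized) samples; the model applies its own bundled
#' normalization statistics, so prediction can never silently re-estimate
#' them from test data.
#'
#' @param model a `trained_model` from [train_cnn()].
#' @param samples a raw [sample_set()].
#' @return Numeric vector of SpO2 predictions, one per sample.
#' @export
predict_spo2 <- function(model, samples) {
  stopifnot(inherits(model, "trained_model"), inherits(samples, "sample_set"))
  if (samples$standardized) {
    stop("predict_spo2 expects raw samples; the model applies its bundled stats")
  }
  if (dim(samples$windows)[2] != model$spec$input_len) {
    stop(sprintf("window length %d does not match model input_len %d",
                 dim(samples$windows)[2], model$spec$input_len))
  }
  std <- standardize(samples, model$norm_stats)
  cnn_forward_batched(model$params, std$windows)
}
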