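#' Predictor hyperparameter configuration
#'
#' Defaults are the settings used throughout the analyses in this package:
#' a single GRU layer of 30 hidden units fed 50-sample input sequences,
#' trained for 10 epochs in mini-batches of 32 with AdaBound (learning rate
#' 1e-3, first-moment decay 0.9, weight decay 1e-3) on an MSE next-step
#' loss, dropout 0.5 between the recurrent output and the linear readout,
#' and the whole causality estimate repeated `n_repeats = 10` times with
#' distinct seeds and averaged.
#'
#' @param num_layers number of recurrent layers (only 1 is supported).
#' @param dropout dropout probability before the readout, in `[0, 1)`.
#' @param lr_rate optimizer learning rate.
#' @param momentum first moment-decay coefficient of the optimizer.
#' @param weight_decay L2 weight decay added to the gradient.
#' @param bt_sz mini-batch size.
#' @param seq_len GRU input sequence length in samples.
#' @param hidden_dim GRU hidden-state dimension.
#' @param num_epoch training epochs.
#' @param n_repeats causality repetitions averaged into the final matrix.
#' @param seed master seed; every repetition derives its own seed from it.
#' @param stride window stride in samples.
#' @param zscore z-score each channel per epoch before training.
#' @param optimizer `"adabound"` (default) or `"adam"` (AdaBound with its
#'   bound band disabled).
#' @param restricted_mode `"retrain"` fits each source-excluded model from
#'   scratch (the Wiener-Granger definition); `"zero_mask"` reuses the full
#'   model with the excluded channel zeroed at input - a cheaper screen, not
#'   equivalent.
#' @param per_target fit one scalar-output model per target channel instead
#'   of a joint multivariate readout.
#' @return A named list of class `predictor_config`.
#' @export
predictor_config <- function(num_layers = 1L, dropout = 0.5, lr_rate = 0.001,
                             momentum = 0.9, weight_decay = 0.001,
                             bt_sz = 32L, seq_len = 50L, hidden_dim = 30L,
                             num_epoch = 10L, n_repeats = 10L, seed = 1L,
                             stride = 1L, zscore = TRUE,
                             optimizer = c("adabound", "adam"),
                             restricted_mode = c("retrain", "zero_mask"),
                             per_target = FALSE) {
  cfg <- list(num_layers = as.integer(num_layers), dropout = dropout,
              lr_rate = lr_rate, momentum = momentum,
              weight_decay = weight_decay, bt_sz = as.integer(bt_sz),
              seq_len = as.integer(seq_len),
              hidden_dim = as.integer(hidden_dim),
              num_epoch = as.integer(num_epoch),
              n_repeats = as.integer(n_repeats), seed = as.integer(seed),
              stride = as.integer(stride), zscore = isTRUE(zscore),
              optimizer = match.arg(optimizer),
              restricted_mode = match.arg(restricted_mode),
              per_target = isTRUE(per_target))
  validate_predictor_config(cfg)
  structure(cfg, class = "predictor_config")
}

validate_predictor_config <- function(cfg) {
  if (cfg$num_layers != 1L)
    stop("only a single recurrent layer is supported (num_layers = 1)")
  if (cfg$dropout < 0 || cfg$dropout >= 1)
    stop("dropout must lie in [0, 1)")
  for (f in c("lr_rate", "momentum", "weight_decay"))
    if (cfg[[f]] <= 0) stop(f, " must be positive")
  for (f in c("bt_sz", "seq_len", "hidden_dim", "num_epoch", "n_repeats",
              "stride"))
    if (cfg[[f]] < 1L) stop(f, " must be a positive integer")
  invisible(cfg)
}

#' One GRU time step
#'
#' Reference (pure R) evaluation of a single gated-recurrent-unit update:
#' reset gate `R = sigmoid(X W_xr + H_prev W_hr + e_r)`, update gate
#' `Z = sigmoid(X W_xz + H_prev W_hz + e_z)`, candidate state
#' `H~ = tanh(X W_xh + (R * H_prev) W_hh + e_h)`, and new state
#' `H = Z * H_prev + (1 - Z) * H~` (`*` element-wise). With `Z -> 1` the old
#' state is retained unchanged; with `Z -> 0` the new state equals the
#' candidate.
#'
#' @param weights named list with `W_xr`, `W_xz`, `W_xh` (d x h), `W_hr`,
#'   `W_hz`, `W_hh` (h x h) and bias rows `e_r`, `e_z`, `e_h` (1 x h), as
#'   returned by [train_predictor()].
#' @param X_t input at time t, n x d matrix.
#' @param H_prev previous hidden state, n x h matrix.
#' @return List with the new state `H` and the gate activations `R`, `Z`,
#'   `H_tilde`.
#' @export
gru_step <- function(weights, X_t, H_prev) {
  X_t <- as.matrix(X_t); H_prev <- as.matrix(H_prev)
  w <- weights
  d <- nrow(w$W_xr); h <- ncol(w$W_xr)
  if (ncol(X_t) != d) stop("X_t has ", ncol(X_t), " columns; weights expect ", d)
  if (ncol(H_prev) != h || nrow(H_prev) != nrow(X_t))
    stop("H_prev must be ", nrow(X_t), " x ", h)
  sig <- function(x) 1 / (1 + exp(-x))
  bias <- function(A, e) sweep(A, 2L, as.numeric(e), `+`)
  R <- sig(bias(X_t %*% w$W_xr + H_prev %*% w$W_hr, w$e_r))
  Z <- sig(bias(X_t %*% w$W_xz + H_prev %*% w$W_hz, w$e_z))
  H_tilde <- tanh(bias(X_t %*% w$W_xh + (R * H_prev) %*% w$W_hh, w$e_h))
  H <- Z * H_prev + (1 - Z) * H_tilde
  list(H = H, R = R, Z = Z, H_tilde = H_tilde)
}

# batch inputs (n x seq_len x d) -> n x d x seq_len cube for the C++ kernel,
# restricted to the `keep` input channels
batch_cube <- function(batch, keep) {
  inputs <- batch$inputs[, , keep, drop = FALSE]
  aperm(inputs, c(1L, 3L, 2L))
}

#' Train a GRU next-step predictor
#'
#' Fits one GRU layer plus a linear readout to predict the sample following
#' each window, by mini-batch AdaBound on the mean-squared error, and
#' returns the per-output-channel variance (mean squared error, dropout
#' off) of the next-step prediction on the training windows. The full model
#' uses all channels as input; a restricted model for candidate source `i`
#' is obtained by excluding `i` from `input_mask`.
#'
#' @param batch a `training_batch` from [make_windows()].
#' @param input_mask channels (names or indices) to use as inputs; default
#'   all.
#' @param config a [predictor_config()].
#' @param output_mask channels to predict; default all.
#' @param seed training seed; default `config$seed`.
#' @return List with `weights` (named matrices, see [gru_step()]), `sigma2`
#'   (named residual variance per output channel), `loss_history` (mean
#'   training loss per epoch).
#' @export
train_predictor <- function(batch, input_mask = NULL, config = predictor_config(),
                            output_mask = NULL, seed = NULL) {
  stopifnot(inherits(batch, "training_batch"))
  validate_predictor_config(config)
  nms <- batch$channel_names
  resolve <- function(mask) {
    if (is.null(mask)) return(seq_along(nms))
    if (is.character(mask)) {
      bad <- setdiff(mask, nms)
      if (length(bad)) stop("unknown channel(s): ", paste(bad, collapse = ", "))
      return(match(mask, nms))
    }
    stopifnot(all(mask %in% seq_along(nms)))
    as.integer(mask)
  }
  keep_in <- resolve(input_mask)
  keep_out <- resolve(output_mask)
  if (length(keep_in) < 1L) stop("input_mask must keep at least one channel")
  seed <- as.integer(seed %||% config$seed)
  X <- batch_cube(batch, keep_in)
  Y <- batch$targets[, keep_out, drop = FALSE]
  final_lr <- if (config$optimizer == "adam") Inf else 0.1
  fit <- .gru_train_cpp(X, Y, config$hidden_dim, config$num_epoch,
                        config$bt_sz, config$lr_rate, config$momentum,
                        0.999, config$weight_decay, config$dropout,
                        final_lr, 1e-3, 1e-8, seed)
  sigma2 <- stats::setNames(as.numeric(fit$sigma2), nms[keep_out])
  list(weights = fit$weights, sigma2 = sigma2,
       loss_history = as.numeric(fit$loss_history),
       input_channels = nms[keep_in], output_channels = nms[keep_out])
}

#' Predict next-step values with a trained GRU
#'
#' @param fit result of [train_predictor()].
#' @param batch a `training_batch` whose input channels match the fit.
#' @return n x d_out matrix of predictions.
#' @export
predict_next_step <- function(fit, batch) {
  keep <- match(fit$input_channels, batch$channel_names)
  if (anyNA(keep)) stop("batch lacks channels the model was trained on")
  out <- .gru_forward_cpp(fit$weights, batch_cube(batch, keep))
  pred <- out$prediction
  colnames(pred) <- fit$output_channels
  pred
}

#' Wiener-Granger causality matrix from GRU predictors
#'
#' For every target channel j the full model (all m channels as input) gives
#' a residual variance `s2_full(j)`; excluding candidate source i and
#' retraining gives `s2_-i(j)`. The causal strength is the Wiener-Granger
#' index `c_ij = max(0, ln(s2_-i(j) / s2_full(j)))` with `c_ii = 0`: the
#' log-loss in predictability of j when i's history is withheld. The whole
#' procedure is repeated `n_repeats` times with distinct derived seeds and
#' the raw matrices are averaged element-wise.
#'
#' One joint multivariate model is fitted per input mask (m + 1 trainings
#' per repeat); set `config$per_target = TRUE` for scalar per-target models.
#'
#' @param rec an `mc_recording` (typically one epoch slice).
#' @param config a [predictor_config()].
#' @param verbose print per-repeat progress.
#' @return An m x m `causal_matrix`: nonnegative matrix with channel
#'   dimnames, zero diagonal, and attributes `repeats` (list of per-repeat
#'   matrices) and `config`.
#' @export
wgci_matrix <- function(rec, config = predictor_config(), verbose = FALSE) {
  stopifnot(inherits(rec, "mc_recording"))
  validate_predictor_config(config)
  m <- n_channels(rec)
  if (m < 2L) stop("causality needs at least 2 channels")
  if (config$zscore) rec <- zscore_channels(rec)
  batch <- make_windows(rec, config$seq_len, config$stride)
  nms <- rec$channel_names

  reps <- vector("list", config$n_repeats)
  for (r in seq_len(config$n_repeats)) {
    base_seed <- derive_seed(config$seed, r)
    reps[[r]] <- wgci_single(batch, config, base_seed, verbose = verbose,
                             label = sprintf("repeat %d/%d", r, config$n_repeats))
  }
  values <- Reduce(`+`, reps) / length(reps)
  dimnames(values) <- list(nms, nms)
  structure(values, class = c("causal_matrix", class(values)),
            repeats = reps, config = config)
}

# deterministic per-repeat / per-mask seed derivation, kept within 32-bit
# integer range
derive_seed <- function(master, repeat_idx, mask_idx = 0L) {
  ((as.numeric(master) * 7919 + repeat_idx * 104729 + mask_idx * 131) %%
     2147483629) + 1
}

wgci_single <- function(batch, config, base_seed, verbose = FALSE, label = "") {
  nms <- batch$channel_names
  m <- length(nms)
  train_mask <- function(keep_in, keep_out, mask_idx) {
    seed <- derive_seed(base_seed, 0L, mask_idx)
    if (config$per_target && length(keep_out) > 1L) {
      s2 <- vapply(seq_along(keep_out), function(k) {
        fit <- train_predictor(batch, keep_in, config,
                               output_mask = keep_out[k],
                               seed = derive_seed(seed, k))
        fit$sigma2
      }, 0)
      return(stats::setNames(s2, nms[keep_out]))
    }
    train_predictor(batch, keep_in, config, output_mask = keep_out,
                    seed = seed)$sigma2
  }

  if (verbose) message("wgci ", label, ": full model")
  if (config$restricted_mode == "zero_mask") {
    seed <- derive_seed(base_seed, 0L, 0L)
    full_fit <- train_predictor(batch, NULL, config, seed = seed)
    s2_full <- full_fit$sigma2
    s2_restricted <- matrix(NA_real_, m, m, dimnames = list(nms, nms))
    for (i in seq_len(m)) {
      zb <- batch
      zb$inputs[, , i] <- 0
      s2_restricted[i, ] <- predict_sigma2(full_fit, zb)
    }
  } else {
    s2_full <- train_mask(seq_len(m), seq_len(m), 0L)
    s2_restricted <- matrix(NA_real_, m, m, dimnames = list(nms, nms))
    for (i in seq_len(m)) {
      if (verbose) message("wgci ", label, ": excluding ", nms[i])
      s2_restricted[i, -i] <- train_mask(setdiff(seq_len(m), i),
                                         setdiff(seq_len(m), i), i)[nms[-i]]
    }
  }
  if (any(s2_full <= 0))
    stop("degenerate signal: zero full-model residual variance for channel(s) ",
         paste(nms[s2_full <= 0], collapse = ", "))
  values <- matrix(0, m, m, dimnames = list(nms, nms))
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i == j) next
    values[i, j] <- max(0, log(s2_restricted[i, j] / s2_full[j]))
  }
  values
}

predict_sigma2 <- function(fit, batch) {
  pred <- predict_next_step(fit, batch)
  resid <- pred - batch$targets[, fit$output_channels, drop = FALSE]
  colMeans(resid^2)
}

#' @export
print.causal_matrix <- function(x, ...) {
  cat(sprintf("<causal_matrix> %d x %d, averaged over %d repeat(s)\n",
              nrow(x), ncol(x), length(attr(x, "repeats") %||% list(1))))
  print(round(unclass(x)[,], 4))
  invisible(x)
}

#' Write / read a causal matrix as delimited text
#'
#' Channel names appear as both header row and first column.
#'
#' @param G causal (or normalized) matrix with channel dimnames.
#' @param path file path.
#' @param sep separator.
#' @export
write_causal_matrix <- function(G, path, sep = ",") {
  tab <- data.frame(channel = rownames(G), unclass(G)[,], check.names = FALSE)
  utils::write.table(tab, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_causal_matrix
#' @export
read_causal_matrix <- function(path, sep = ",") {
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  G <- as.matrix(tab[, -1, drop = FALSE])
  rownames(G) <- tab[[1]]
  if (!identical(rownames(G), colnames(G)))
    stop("causal matrix file has mismatched row/column channel names")
  structure(G, class = c("causal_matrix", class(G)))
}

#' Linear Granger causality matrix (OLS baseline)
#'
#' Classical vector-autoregressive Wiener-Granger index: for each target j,
#' an order-p OLS regression of x_j(t) on p lags of all channels (full)
#' versus all channels except i (restricted); `c_ij = max(0,
#' ln(rss_-i / rss_full))`. Used as an independent linear reference for the
#' GRU-based estimator.
#'
#' @param rec an `mc_recording`.
#' @param order VAR model order p (number of lags).
#' @return m x m nonnegative matrix with channel dimnames, zero diagonal.
#' @export
linear_wgci <- function(rec, order = 2L) {
  stopifnot(inherits(rec, "mc_recording"))
  x <- t(rec$data)                       # T x m
  Tn <- nrow(x); m <- ncol(x); p <- as.integer(order)
  if (Tn <= p + 1L) stop("recording too short for order ", p)
  # design: columns are lag-l copies of each channel
  idx <- (p + 1L):Tn
  lagmat <- do.call(cbind, lapply(seq_len(p), function(l) x[idx - l, , drop = FALSE]))
  rss <- function(cols, y) {
    X <- cbind(1, lagmat[, cols, drop = FALSE])
    fit <- stats::lm.fit(X, y)
    sum(fit$residuals^2)
  }
  all_cols <- seq_len(m * p)
  chan_of_col <- rep(seq_len(m), times = p)
  G <- matrix(0, m, m, dimnames = list(colnames(x), colnames(x)))
  for (j in seq_len(m)) {
    y <- x[idx, j]
    rss_full <- rss(all_cols, y)
    for (i in seq_len(m)) {
      if (i == j) next
      rss_r <- rss(all_cols[chan_of_col != i], y)
      G[i, j] <- max(0, log(rss_r / rss_full))
    }
  }
  G
}
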