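# hand-set GRU weights for d inputs, h hidden units, all entries explicit
hand_weights <- function(d, h, val = 0.1) {
  list(W_xr = matrix(val, d, h), W_xz = matrix(val, d, h),
       W_xh = matrix(val, d, h),
       W_hr = matrix(val, h, h), W_hz = matrix(val, h, h),
       W_hh = matrix(val, h, h),
       e_r = matrix(0, 1, h), e_z = matrix(0, 1, h), e_h = matrix(0, 1, h),
       W_out = matrix(val, h, d), b_out = matrix(0, 1, d))
}

test_that("gru_step limits: update gate freezes or replaces the state", {
  set.seed(1)
  w <- hand_weights(2, 3, val = 0.3)
  X <- matrix(rnorm(8), 4, 2)
  H <- matrix(rnorm(12), 4, 3)

  # e_z very large positive -> Z ~ 1 -> old state retained
  w_keep <- w; w_keep$e_z <- matrix(50, 1, 3)
  out <- gru_step(w_keep, X, H)
  expect_equal(out$H, H, tolerance = 1e-12)

  # e_z and e_r very large negative -> Z ~ 0, R ~ 0 ->
  # H = tanh(X W_xh + e_h)
  w_new <- w; w_new$e_z <- matrix(-50, 1, 3); w_new$e_r <- matrix(-50, 1, 3)
  out2 <- gru_step(w_new, X, H)
  expect_equal(out2$H, tanh(X %*% w$W_xh), tolerance = 1e-10)

  expect_error(gru_step(w, matrix(0, 4, 3), H), "columns")
  expect_error(gru_step(w, X, matrix(0, 3, 3)), "H_prev")
})

test_that("gru_step matches scalar arithmetic on a hand-worked example", {
  # d = 1, h = 2, one sample; every quantity computed with plain scalars
  w <- list(W_xr = matrix(c(0.5, -0.2), 1, 2),
            W_xz = matrix(c(0.1, 0.4), 1, 2),
            W_xh = matrix(c(-0.3, 0.8), 1, 2),
            W_hr = matrix(c(0.2, 0, -0.1, 0.3), 2, 2),
            W_hz = matrix(c(0, 0.25, 0.15, 0), 2, 2),
            W_hh = matrix(c(0.6, -0.4, 0.05, 0.2), 2, 2),
            e_r = matrix(c(0.01, -0.02), 1, 2),
            e_z = matrix(c(0.03, 0.04), 1, 2),
            e_h = matrix(c(-0.05, 0.06), 1, 2),
            W_out = matrix(c(1, -1), 2, 1), b_out = matrix(0.5, 1, 1))
  x <- 0.7; h1 <- -0.4; h2 <- 0.9
  sig <- function(u) 1 / (1 + exp(-u))
  r1 <- sig(x * 0.5 + h1 * 0.2 + h2 * 0 + 0.01)
  r2 <- sig(x * -0.2 + h1 * -0.1 + h2 * 0.3 - 0.02)
  z1 <- sig(x * 0.1 + h1 * 0 + h2 * 0.25 + 0.03)
  z2 <- sig(x * 0.4 + h1 * 0.15 + h2 * 0 + 0.04)
  hc1 <- tanh(x * -0.3 + (r1 * h1) * 0.6 + (r2 * h2) * -0.4 - 0.05)
  hc2 <- tanh(x * 0.8 + (r1 * h1) * 0.05 + (r2 * h2) * 0.2 + 0.06)
  hn1 <- z1 * h1 + (1 - z1) * hc1
  hn2 <- z2 * h2 + (1 - z2) * hc2

  out <- gru_step(w, matrix(x, 1, 1), matrix(c(h1, h2), 1, 2))
  expect_equal(as.numeric(out$R), c(r1, r2), tolerance = 1e-14)
  expect_equal(as.numeric(out$Z), c(z1, z2), tolerance = 1e-14)
  expect_equal(as.numeric(out$H_tilde), c(hc1, hc2), tolerance = 1e-14)
  expect_equal(as.numeric(out$H), c(hn1, hn2), tolerance = 1e-14)
})

test_that("frozen-state identity holds for random weights whenever Z = 1", {
  set.seed(8)
  for (i in 1:5) {
    d <- sample(1:4, 1); h <- sample(2:6, 1)
    w <- lapply(hand_weights(d, h), function(m) matrix(rnorm(length(m)), nrow(m)))
    names(w) <- names(hand_weights(d, h))
    w$e_z <- matrix(100, 1, h)
    X <- matrix(rnorm(3 * d), 3, d)
    H <- matrix(rnorm(3 * h), 3, h)
    expect_equal(gru_step(w, X, H)$H, H, tolerance = 1e-10)
  }
})

test_that("the R reference step reproduces the compiled forward pass", {
  rec <- noise_recording(m = 2, n = 120, seed = 4)
  cfg <- tiny_config(num_epoch = 2L)
  batch <- make_windows(rec, cfg$seq_len)
  fit <- train_predictor(batch, config = cfg, seed = 99L)
  k <- 3L   # one window, stepped through manually
  H <- matrix(0, 1, cfg$hidden_dim)
  for (t in seq_len(cfg$seq_len))
    H <- gru_step(fit$weights, matrix(batch$inputs[k, t, ], 1), H)$H
  manual <- H %*% fit$weights$W_out + as.numeric(fit$weights$b_out)
  expect_equal(as.numeric(predict_next_step(fit, batch)[k, ]),
               as.numeric(manual), tolerance = 1e-10)
})

test_that("training on white noise leaves residual variance at input variance", {
  rec <- noise_recording(m = 2, n = 500, seed = 10)
  cfg <- tiny_config()
  fit <- train_predictor(make_windows(rec, cfg$seq_len), config = cfg)
  # nothing is predictable: residual variance stays near var(channel) = 1
  expect_true(all(fit$sigma2 > 0.8 & fit$sigma2 < 1.2))
})

test_that("a lagged copy is learnable, and unlearnable without its source", {
  set.seed(12)
  n <- 600
  x <- rnorm(n)
  y <- c(0, head(x, -1))      # y_t = x_{t-1}, exactly
  rec <- recording(rbind(x = x, y = y), 100, c("x", "y"))
  cfg <- tiny_config(num_epoch = 30L, dropout = 0)
  batch <- make_windows(rec, cfg$seq_len)

  fit_full <- train_predictor(batch, config = cfg)
  expect_lt(fit_full$sigma2[["y"]], 0.05)   # copy task solved

  # excluding the only informative channel leaves target variance
  fit_rest <- train_predictor(batch, input_mask = "y", config = cfg)
  expect_gt(fit_rest$sigma2[["y"]], 0.7)
})

test_that("wgci on independent noise is near zero everywhere", {
  rec <- noise_recording(m = 2, n = 500, seed = 20)
  cfg <- tiny_config(n_repeats = 2L)
  G <- wgci_matrix(rec, cfg)
  expect_equal(unname(diag(unclass(G)[, ])), c(0, 0))
  expect_lt(max(G), 0.15)
})

test_that("wgci recovers the dominant direction and agrees with OLS Granger", {
  set.seed(30)
  n <- 2000
  x <- rnorm(n + 1)
  y <- 0.5 * c(0, head(x, -1)) + rnorm(n + 1)
  rec <- recording(rbind(x = x, y = y), 256, c("x", "y"))
  G <- wgci_matrix(rec, predictor_config(n_repeats = 1L, seed = 5L))
  expect_gt(G["x", "y"], G["y", "x"])

  L <- linear_wgci(rec, order = 2)
  expect_gt(L["x", "y"], L["y", "x"])   # oracle agrees on the direction
  expect_gt(G["x", "y"], 0.05)          # and the strength is material
})

test_that("causal estimates are stable under channel permutation", {
  spec <- network_spec(3, data.frame(from = c(1, 2, 3), to = c(2, 3, 1),
                                     lag = 1L, coef = 0.9))
  rec <- simulate_var(spec, 800, seed = 3)
  cfg <- tiny_config(seq_len = 20L, n_repeats = 2L)
  G1 <- wgci_matrix(rec, cfg)
  perm <- c("Ch3", "Ch1", "Ch2")
  G2 <- wgci_matrix(select_channels(rec, perm), cfg)
  nms <- rec$channel_names
  # the dominant structure is the same up to relabelling: in both channel
  # orders the three strongest entries are exactly the true edges
  top_edges <- function(G, k = 3) {
    v <- unclass(G)[, ]
    idx <- order(v, decreasing = TRUE)[seq_len(k)]
    sort(paste(rownames(v)[row(v)[idx]], colnames(v)[col(v)[idx]]))
  }
  truth <- sort(c("Ch1 Ch2", "Ch2 Ch3", "Ch3 Ch1"))
  expect_equal(top_edges(G1), truth)
  expect_equal(top_edges(G2), truth)
  # and the estimates themselves agree within Monte-Carlo tolerance
  expect_lt(max(abs(unclass(G1)[, ] - unclass(G2)[nms, nms])), 0.3)
})

test_that("averaging repeats shrinks between-run variability", {
  rec <- noise_recording(m = 2, n = 300, seed = 40)
  set.seed(41)
  rec$data[2, ] <- rec$data[2, ] + 0.5 * c(0, head(rec$data[1, ], -1))
  cfg <- tiny_config(seq_len = 10L, num_epoch = 5L, hidden_dim = 8L,
                     n_repeats = 12L)
  G <- wgci_matrix(rec, cfg)
  singles <- vapply(attr(G, "repeats"), function(r) r["Ch1", "Ch2"], 0)
  sd_single <- sd(singles)
  triples <- vapply(1:4, function(g) mean(singles[(3 * g - 2):(3 * g)]), 0)
  expect_lt(sd(triples), sd_single)
})

test_that("wgci runs are reproducible and repeats differ by seed", {
  rec <- noise_recording(m = 2, n = 300, seed = 50)
  cfg <- tiny_config(n_repeats = 2L, seed = 7L)
  G1 <- wgci_matrix(rec, cfg)
  G2 <- wgci_matrix(rec, cfg)
  expect_identical(unclass(G1)[, ], unclass(G2)[, ])
  reps <- attr(G1, "repeats")
  expect_false(identical(reps[[1]], reps[[2]]))
})

test_that("causal matrix text round trip preserves values and names", {
  set.seed(60)
  G <- matrix(runif(16), 4, 4, dimnames = rep(list(c("Cp1", "Cp4", "Pp1", "Pp4")), 2))
  diag(G) <- 0
  path <- withr::local_tempfile(fileext = ".csv")
  write_causal_matrix(G, path)
  back <- read_causal_matrix(path)
  expect_equal(unclass(back)[, ], G, tolerance = 1e-12)
})

test_that("configuration defaults and validation match the reference settings", {
  cfg <- predictor_config()
  expect_equal(cfg$num_layers, 1L)
  expect_equal(cfg$dropout, 0.5)
  expect_equal(cfg$lr_rate, 0.001)
  expect_equal(cfg$momentum, 0.9)
  expect_equal(cfg$weight_decay, 0.001)
  expect_equal(cfg$bt_sz, 32L)
  expect_equal(cfg$seq_len, 50L)
  expect_equal(cfg$hidden_dim, 30L)
  expect_equal(cfg$num_epoch, 10L)
  expect_equal(cfg$n_repeats, 10L)
  expect_error(predictor_config(dropout = 1), "dropout")
  expect_error(predictor_config(num_layers = 2), "single recurrent layer")
  expect_error(predictor_config(bt_sz = 0), "bt_sz")
})
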