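test_that("network specification validates edges and stability", {
  expect_error(network_spec(3, data.frame(from = 1, to = 1, lag = 1,
                                          coef = 0.5)), "self-edges")
  expect_error(network_spec(3, data.frame(from = 1, to = 2, lag = 0,
                                          coef = 0.5)), "lags")
  # a 2-cycle with gain 1.1 * 1.1 > 1 is unstable
  expect_error(network_spec(2, data.frame(from = c(1, 2), to = c(2, 1),
                                          lag = 1, coef = 1.1)), "unstable")
  # the same cycle with gain < 1 is fine
  expect_s3_class(network_spec(2, data.frame(from = c(1, 2), to = c(2, 1),
                                             lag = 1, coef = 0.9)),
                  "network_spec")
  # long-lag single edge: always stable regardless of coefficient < radius
  expect_s3_class(network_spec(3, data.frame(from = 1, to = 2, lag = 15,
                                             coef = 0.95)), "network_spec")
  expect_error(network_spec(2, data.frame(from = 1, to = 2, lag = 1,
                                          coef = 1.2,
                                          nonlinearity = "square")),
               "square")
})

test_that("an edgeless system is white noise at the requested level", {
  spec <- network_spec(4, data.frame(), noise_sd = 2.5)
  rec <- simulate_var(spec, 4000, seed = 2)
  expect_equal(n_samples(rec), 4000)
  sds <- apply(rec$data, 1, sd)
  expect_true(all(abs(sds - 2.5) < 0.15))
  # channels are mutually uncorrelated
  cors <- cor(t(rec$data))
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.1)
})

test_that("lag-1 coupling reproduces the analytic cross-covariance", {
  # y_t = 0.9 x_{t-1} + e_t with x white: corr(x_{t-1}, y_t) =
  # 0.9 sd(x) / sd(y), sd(y) = sqrt(0.81 + 1)
  spec <- network_spec(2, data.frame(from = 1, to = 2, lag = 1, coef = 0.9))
  rec <- simulate_var(spec, 20000, seed = 3)
  x <- rec$data[1, ]; y <- rec$data[2, ]
  emp <- cor(head(x, -1), tail(y, -1))
  expect_equal(emp, 0.9 / sqrt(1.81), tolerance = 0.02)
  expect_equal(sd(y), sqrt(1.81), tolerance = 0.05)
})

test_that("simulation is bit-reproducible from its seed", {
  spec <- default_network_spec()
  r1 <- simulate_var(spec, 500, seed = 11)
  r2 <- simulate_var(spec, 500, seed = 11)
  expect_identical(r1$data, r2$data)
  r3 <- simulate_var(spec, 500, seed = 12)
  expect_false(identical(r1$data, r3$data))
})

test_that("nonlinear transfer is applied per edge", {
  # y_t = 0.8 tanh(x_{t-1}) + e: regression of y on tanh(lag x) gives 0.8
  spec <- network_spec(2, data.frame(from = 1, to = 2, lag = 1, coef = 0.8,
                                     nonlinearity = "tanh"))
  rec <- simulate_var(spec, 20000, seed = 5)
  x <- rec$data[1, ]; y <- rec$data[2, ]
  beta <- coef(lm(tail(y, -1) ~ tanh(head(x, -1))))[2]
  expect_equal(unname(beta), 0.8, tolerance = 0.03)
})

test_that("seizure course concatenates phases with the expected geometry", {
  spec <- default_network_spec()
  out <- simulate_seizure_course(spec, spec, spec,
                                 durations_s = c(16, 32, 16), rate_hz = 256,
                                 seed = 9)
  expect_equal(n_samples(out$recording), 16384)   # 64 s at 256 Hz
  sch <- out$scheme
  expect_equal(sch$epochs$name,
               c("pre-ictal", "ictal 1", "ictal 2", "ictal 3", "post-ictal"))
  expect_equal(unname(sch$phase_boundaries), c(16, 48))
  expect_true(all(sch$epochs$end_s - sch$epochs$start_s == 16))
  # ictal epochs stay inside the ictal phase
  ict <- sch$epochs[grepl("^ictal", sch$epochs$name), ]
  expect_true(all(ict$start_s >= 16 & ict$end_s <= 48))

  # identical phase specs give a statistically homogeneous recording
  v <- vapply(segment_epochs(out$recording, sch),
              function(s) mean(apply(s$data, 1, var)), 0)
  expect_lt(max(v) / min(v), 1.6)

  spec3 <- network_spec(3, data.frame(from = 1, to = 2, lag = 1, coef = 0.5))
  expect_error(simulate_seizure_course(spec, spec3, spec), "same number")
})

test_that("recovery scores match entry-by-entry counting", {
  truth <- random_adjacency(5, p = 0.3, seed = 61)
  # perfect recovery
  perfect <- recovery_scores(truth, truth)
  expect_equal(perfect[c("precision", "recall", "f1", "hamming")],
               list(precision = 1, recall = 1, f1 = 1, hamming = 0))
  # empty estimate: recall 0, hamming = number of true edges
  empty <- matrix(0, 5, 5)
  sc0 <- recovery_scores(empty, truth)
  expect_equal(sc0$recall, 0)
  expect_equal(sc0$f1, 0)
  expect_equal(sc0$hamming, sum(truth))

  # random pair vs counting oracle
  est <- random_adjacency(5, p = 0.4, seed = 62)
  sc <- recovery_scores(est, truth)
  tp <- fp <- fn <- ham <- 0
  for (i in 1:5) for (j in 1:5) {
    if (i == j) next
    if (est[i, j] == 1 && truth[i, j] == 1) tp <- tp + 1
    if (est[i, j] == 1 && truth[i, j] == 0) fp <- fp + 1
    if (est[i, j] == 0 && truth[i, j] == 1) fn <- fn + 1
    if (est[i, j] != truth[i, j]) ham <- ham + 1
  }
  expect_equal(sc$precision, tp / (tp + fp))
  expect_equal(sc$recall, tp / (tp + fn))
  expect_equal(sc$hamming, ham)
  expect_error(recovery_scores(est, truth[1:4, 1:4]), "same shape")
})

test_that("network specs round-trip through YAML", {
  spec <- default_network_spec()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_network_spec(spec, path)
  back <- read_network_spec(path)
  expect_equal(back$m, spec$m)
  expect_equal(back$edges$coef, spec$edges$coef)
  expect_equal(back$edges$lag, spec$edges$lag)
  expect_equal(back$edges$nonlinearity, spec$edges$nonlinearity)
  expect_identical(back$channel_names, spec$channel_names)
})

test_that("an added ictal driver raises the driver's causal out-flow", {
  # pre: sparse background; ictal: node 1 drives everything
  base_edges <- data.frame(from = 2, to = 3, lag = 1, coef = 0.6)
  drive_edges <- rbind(base_edges,
                       data.frame(from = c(1, 1), to = c(2, 3),
                                  lag = c(1, 2), coef = c(0.8, 0.8)))
  spec_pre <- network_spec(3, base_edges)
  spec_ict <- network_spec(3, drive_edges)
  cfg <- tiny_config(seq_len = 20L)
  gain <- vapply(1:3, function(s) {
    out <- simulate_seizure_course(spec_pre, spec_ict, spec_pre,
                                   durations_s = c(16, 32, 16), rate_hz = 64,
                                   seed = 70 + s)
    sl <- segment_epochs(out$recording, out$scheme)
    cfg$seed <- 70 + s
    g_pre <- wgci_matrix(sl[["pre-ictal"]], cfg)
    g_ict <- wgci_matrix(sl[["ictal 2"]], cfg)
    sum(g_ict["Ch1", ]) - sum(g_pre["Ch1", ])
  }, 0)
  expect_gt(mean(gain), 0)
})

test_that("recovery improves with sample size through the full pipeline", {
  spec <- network_spec(3, data.frame(from = c(1, 2, 3), to = c(2, 3, 1),
                                     lag = c(1, 3, 1), coef = 0.9))
  cfg <- tiny_config(seq_len = 20L, num_epoch = 6L)
  f1_at <- function(n, seed) {
    rec <- simulate_var(spec, n, seed = seed)
    cfg$seed <- seed
    adj <- binarize(normalize_rows(wgci_matrix(rec, cfg)), 0.1)
    recovery_scores(adj, truth_adjacency(spec))$f1
  }
  sizes <- c(500, 2000, 8000)
  f1 <- vapply(sizes, function(n) mean(vapply(1:2, function(s)
    f1_at(n, 80 + s), 0)), 0)
  # monotone in expectation; small slack absorbs Monte-Carlo noise
  expect_gte(f1[2], f1[1] - 0.1)
  expect_gte(f1[3], f1[2] - 0.1)
  expect_gte(f1[3], f1[1])
})

test_that("a long-delay edge is seen by the GRU but not a short linear model", {
  # learning an isolated 15-step dependency needs the concentrated
  # per-target loss and a longer schedule than the multivariate default
  spec <- network_spec(3, data.frame(from = 1, to = 2, lag = 15, coef = 0.95))
  rec <- simulate_var(spec, 2500, seed = 91)
  cfg <- predictor_config(n_repeats = 1L, num_epoch = 30L,
                          per_target = TRUE, seed = 91)
  adj_gru <- binarize(normalize_rows(wgci_matrix(rec, cfg)), 0.1)
  adj_lin <- binarize(normalize_rows(linear_wgci(rec, order = 2)), 0.1)
  f1_gru <- recovery_scores(adj_gru, truth_adjacency(spec))$f1
  f1_lin <- recovery_scores(adj_lin, truth_adjacency(spec))$f1
  # the under-ordered linear model cannot express a lag-15 dependency
  expect_gt(f1_gru, f1_lin)
  expect_equal(adj_gru["Ch1", "Ch2"], 1)   # the true edge itself is found
})
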