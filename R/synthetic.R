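#' Specification of a directed causal network for simulation
#'
#' Defines an m-node system x_j(t) = sum over edges into j of
#' `coef * g(x_i(t - lag))` plus Gaussian innovation noise, where `g` is an
#' optional per-edge nonlinear transfer (`"none"`, `"tanh"` or `"square"`).
#' Long transmission delays (lags up to ~20) are supported. Stability of
#' the linear part is checked at construction: the spectral radius of the
#' companion matrix built from `|coef|` per edge must be below 1 (for
#' `tanh` edges `|coef|` bounds the slope; `square` edges are included on
#' the same best-effort basis and additionally require `|coef| < 1`).
#'
#' @param m number of nodes (channels).
#' @param edges data.frame with columns `from`, `to` (1-based node indices
#'   or channel names), `lag` (positive integer), `coef`, and optionally
#'   `nonlinearity` (default `"none"`).
#' @param noise_sd innovation standard deviation, shared by all channels.
#' @param channel_names optional names, default `Ch1..Chm`.
#' @return Object of class `network_spec`.
#' @export
network_spec <- function(m, edges, noise_sd = 1, channel_names = NULL) {
  m <- as.integer(m)
  stopifnot(m >= 2L, noise_sd > 0)
  channel_names <- channel_names %||% paste0("Ch", seq_len(m))
  stopifnot(length(channel_names) == m)
  edges <- as.data.frame(edges)
  if (!nrow(edges)) {
    edges <- data.frame(from = integer(), to = integer(), lag = integer(),
                        coef = numeric(), nonlinearity = character())
  }
  stopifnot(all(c("from", "to", "lag", "coef") %in% names(edges)))
  if (is.null(edges$nonlinearity)) edges$nonlinearity <- "none"
  to_idx <- function(x) {
    if (is.character(x)) match(x, channel_names) else as.integer(x)
  }
  edges$from <- to_idx(edges$from)
  edges$to <- to_idx(edges$to)
  if (anyNA(edges$from) || anyNA(edges$to))
    stop("edge endpoints must be valid node indices or channel names")
  if (any(edges$from == edges$to)) stop("self-edges are not allowed")
  if (any(edges$lag < 1L)) stop("edge lags must be >= 1")
  if (!all(edges$nonlinearity %in% c("none", "tanh", "square")))
    stop("nonlinearity must be one of none, tanh, square")
  if (any(edges$nonlinearity == "square" & abs(edges$coef) >= 1))
    stop("square edges require |coef| < 1 for the stability bound")
  max_lag <- if (nrow(edges)) max(edges$lag) else 1L
  spec <- structure(list(m = m, edges = edges, noise_sd = noise_sd,
                         max_lag = as.integer(max_lag),
                         channel_names = channel_names),
                    class = "network_spec")
  rho <- companion_spectral_radius(spec)
  if (rho >= 1)
    stop(sprintf("unstable network: companion spectral radius %.3f >= 1", rho))
  spec
}

# spectral radius of the companion matrix of the linear(ized) system
companion_spectral_radius <- function(spec) {
  m <- spec$m; p <- spec$max_lag
  if (!nrow(spec$edges)) return(0)
  A <- array(0, dim = c(m, m, p))
  for (k in seq_len(nrow(spec$edges))) {
    e <- spec$edges[k, ]
    A[e$to, e$from, e$lag] <- A[e$to, e$from, e$lag] + abs(e$coef)
  }
  comp <- matrix(0, m * p, m * p)
  comp[1:m, ] <- do.call(cbind, lapply(seq_len(p), function(l) A[, , l]))
  if (p > 1L)
    comp[(m + 1):(m * p), 1:(m * (p - 1))] <- diag(m * (p - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Default 5-node validation network
#'
#' A stable directed cycle of 5 strong edges with mixed transmission lags
#' (1, 3 and 8 samples) and one tanh edge, exercising both nonlinearity
#' and delay spread at desk scale. Every node has exactly one outgoing
#' edge, so the ground-truth adjacency is a 5-cycle.
#'
#' @param noise_sd innovation standard deviation.
#' @return A [network_spec()].
#' @export
default_network_spec <- function(noise_sd = 1) {
  network_spec(5L, data.frame(
    from = c(1L, 2L, 3L, 4L, 5L),
    to   = c(2L, 3L, 4L, 5L, 1L),
    lag  = c(1L, 3L, 8L, 1L, 3L),
    coef = c(0.9, 0.9, 0.9, 0.9, 0.9),
    nonlinearity = c("none", "none", "none", "tanh", "none")),
    noise_sd = noise_sd)
}

#' Ground-truth adjacency of a network specification
#'
#' @param spec a [network_spec()].
#' @return Binary m x m matrix: entry (i, j) is 1 iff at least one edge
#'   i -> j exists at any lag.
#' @export
truth_adjacency <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  adj <- matrix(0, spec$m, spec$m,
                dimnames = list(spec$channel_names, spec$channel_names))
  for (k in seq_len(nrow(spec$edges)))
    adj[spec$edges$from[k], spec$edges$to[k]] <- 1
  adj
}

edge_transfer <- function(x, kind) {
  switch(kind, none = x, tanh = tanh(x), square = x^2,
         stop("unknown nonlinearity: ", kind))
}

#' Simulate a multichannel recording from a causal network
#'
#' Generates `x_j(t) = sum_{edges i->j} coef * g(x_i(t - lag)) + eps_j(t)`
#' with iid Gaussian innovations, discards a burn-in of `10 * max_lag`
#' samples, and returns the remaining `n_samples` as a recording. Fully
#' reproducible from `seed`.
#'
#' @param spec a [network_spec()].
#' @param n_samples samples to keep after burn-in.
#' @param seed RNG seed.
#' @param rate_hz nominal sampling rate attached to the recording.
#' @return An [recording()] with `n_samples` samples.
#' @export
simulate_var <- function(spec, n_samples, seed = 1L, rate_hz = 256) {
  stopifnot(inherits(spec, "network_spec"))
  n_samples <- as.integer(n_samples)
  if (n_samples <= spec$max_lag)
    stop("n_samples must exceed the maximum lag (", spec$max_lag, ")")
  burn <- 10L * spec$max_lag
  total <- n_samples + burn
  x <- run_var(spec, total, seed, init = NULL)
  recording(t(x[(burn + 1L):total, , drop = FALSE]), rate_hz,
            spec$channel_names)
}

# core recursion; init (optional) = matrix of max_lag starting rows
run_var <- function(spec, total, seed, init = NULL) {
  m <- spec$m; p <- spec$max_lag
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(seed)
    expr
  }
  eps <- withr_seed(matrix(stats::rnorm(total * m, 0, spec$noise_sd), total, m))
  x <- matrix(0, total + p, m)
  if (!is.null(init)) x[seq_len(p), ] <- init
  ed <- spec$edges
  for (t in seq_len(total)) {
    row <- eps[t, ]
    tt <- t + p
    for (k in seq_len(nrow(ed))) {
      row[ed$to[k]] <- row[ed$to[k]] +
        ed$coef[k] * edge_transfer(x[tt - ed$lag[k], ed$from[k]],
                                   ed$nonlinearity[k])
    }
    x[tt, ] <- row
  }
  x[(p + 1L):(total + p), , drop = FALSE]
}

#' Simulate a piecewise seizure course with switching coupling
#'
#' Concatenates three phases (pre-ictal, ictal, post-ictal), each generated
#' from its own network specification, with signal state carried across
#' phase boundaries (the ictal phase starts from the last pre-ictal
#' samples, not from rest). Burn-in is applied only before the first
#' phase. The returned epoch scheme marks the phase boundaries and, in the
#' style of clinical epoch tables, one pre-ictal epoch, three overlapping
#' ictal epochs and one post-ictal epoch of up to 16 s each.
#'
#' @param spec_pre,spec_ictal,spec_post [network_spec()]s sharing `m` and
#'   channel names.
#' @param durations_s phase durations in seconds, length 3.
#' @param rate_hz sampling rate.
#' @param seed RNG seed.
#' @return List with `recording` (an [recording()]) and `scheme` (an
#'   [epoch_scheme()]).
#' @export
simulate_seizure_course <- function(spec_pre, spec_ictal, spec_post,
                                    durations_s = c(16, 32, 16),
                                    rate_hz = 256, seed = 1L) {
  specs <- list(spec_pre, spec_ictal, spec_post)
  for (s in specs) stopifnot(inherits(s, "network_spec"))
  m <- spec_pre$m
  if (spec_ictal$m != m || spec_post$m != m)
    stop("all phase specifications must share the same number of channels")
  if (!identical(spec_pre$channel_names, spec_ictal$channel_names) ||
      !identical(spec_pre$channel_names, spec_post$channel_names))
    stop("all phase specifications must share channel names")
  stopifnot(length(durations_s) == 3L, all(durations_s > 0))
  ns <- as.integer(floor(durations_s * rate_hz))

  p_max <- max(vapply(specs, function(s) s$max_lag, 0L))
  # phase 1 with burn-in
  burn <- 10L * spec_pre$max_lag
  x1 <- run_var(spec_pre, ns[1] + burn, seed)
  x1 <- x1[(burn + 1L):nrow(x1), , drop = FALSE]
  carry <- function(x_prev, spec, n, seed) {
    init_rows <- utils::tail(x_prev, spec$max_lag)
    if (nrow(init_rows) < spec$max_lag)
      init_rows <- rbind(matrix(0, spec$max_lag - nrow(init_rows), m), init_rows)
    run_var(spec, n, seed, init = init_rows)
  }
  x2 <- carry(x1, spec_ictal, ns[2], seed + 1L)
  x3 <- carry(rbind(x1, x2), spec_post, ns[3], seed + 2L)
  x <- rbind(x1, x2, x3)
  rec <- recording(t(x), rate_hz, spec_pre$channel_names)

  s1 <- ns[1] / rate_hz; s2 <- (ns[1] + ns[2]) / rate_hz
  total_s <- nrow(x) / rate_hz
  L <- min(16, durations_s)
  ictal_starts <- seq(s1, s2 - L, length.out = 3L)
  epochs <- data.frame(
    name = c("pre-ictal", "ictal 1", "ictal 2", "ictal 3", "post-ictal"),
    start_s = c(s1 - L, ictal_starts, s2),
    end_s = c(s1, ictal_starts + L, s2 + L))
  list(recording = rec,
       scheme = epoch_scheme(epochs, ictal_start_s = s1, ictal_end_s = s2))
}

#' Edge-recovery scores of an estimated adjacency against ground truth
#'
#' Precision, recall and F1 over the directed off-diagonal entries, and the
#' Hamming distance (number of differing entries). F1 is 0 when precision
#' and recall are both 0.
#'
#' @param estimated,truth binary adjacency matrices of the same shape with
#'   zero diagonals.
#' @return List with `precision`, `recall`, `f1`, `hamming`.
#' @export
recovery_scores <- function(estimated, truth) {
  est <- as_causal_values(estimated)
  tru <- as_causal_values(truth)
  if (!identical(dim(est), dim(tru)))
    stop("estimated and truth adjacency must have the same shape")
  off <- row(est) != col(est)
  e <- est[off] != 0
  t_ <- tru[off] != 0
  tp <- sum(e & t_); fp <- sum(e & !t_); fn <- sum(!e & t_)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1,
       hamming = sum(e != t_))
}

#' Read / write a network specification as YAML
#'
#' @param spec a [network_spec()].
#' @param path YAML file.
#' @export
write_network_spec <- function(spec, path) {
  stopifnot(inherits(spec, "network_spec"))
  y <- list(m = spec$m, noise_sd = spec$noise_sd,
            channel_names = spec$channel_names,
            edges = lapply(seq_len(nrow(spec$edges)), function(k) {
              e <- spec$edges[k, ]
              list(from = e$from, to = e$to, lag = e$lag, coef = e$coef,
                   nonlinearity = e$nonlinearity)
            }))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' @rdname write_network_spec
#' @export
read_network_spec <- function(path) {
  y <- yaml::read_yaml(path)
  edges <- do.call(rbind, lapply(y$edges, function(e)
    data.frame(from = e$from, to = e$to, lag = e$lag, coef = e$coef,
               nonlinearity = e$nonlinearity %||% "none")))
  network_spec(y$m, edges %||% data.frame(), noise_sd = y$noise_sd %||% 1,
               channel_names = unlist(y$channel_names))
}
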