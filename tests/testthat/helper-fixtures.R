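# Shared fixtures and independent oracles for the test suite.

# small deterministic recording: m channels of Gaussian noise
noise_recording <- function(m = 3, n = 400, rate = 256, seed = 1) {
  set.seed(seed)
  recording(matrix(rnorm(m * n), m, n), rate,
            paste0("Ch", seq_len(m)))
}

# fast training configuration for unit tests (not the study conditions)
tiny_config <- function(...) {
  args <- utils::modifyList(list(seq_len = 10L, hidden_dim = 12L,
                                 num_epoch = 8L, n_repeats = 1L,
                                 dropout = 0.2), list(...))
  do.call(predictor_config, args)
}

# random binary adjacency with zero diagonal
random_adjacency <- function(m, p = 0.3, seed = 1) {
  set.seed(seed)
  adj <- matrix(rbinom(m * m, 1, p), m, m)
  diag(adj) <- 0
  dimnames(adj) <- list(paste0("n", 1:m), paste0("n", 1:m))
  adj
}

# --- independent betweenness oracle -----------------------------------------
# BFS from s: shortest-path distances and path counts to every node
bfs_counts <- function(adj, s) {
  m <- nrow(adj)
  dist <- rep(Inf, m); sigma <- rep(0, m)
  dist[s] <- 0; sigma[s] <- 1
  frontier <- s
  while (length(frontier)) {
    nxt <- integer()
    for (u in frontier) {
      for (v in which(adj[u, ] != 0)) {
        if (is.infinite(dist[v])) {
          dist[v] <- dist[u] + 1
          nxt <- c(nxt, v)
        }
        if (dist[v] == dist[u] + 1) sigma[v] <- sigma[v] + sigma[u]
      }
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, sigma = sigma)
}

# exhaustive betweenness: sum over ordered pairs (j, k), endpoints excluded,
# using the count identity sigma_jk(i) = sigma_ji * sigma_ik when
# d(j,i) + d(i,k) == d(j,k)
brute_betweenness <- function(adj) {
  m <- nrow(adj)
  b <- lapply(seq_len(m), function(s) bfs_counts(adj, s))
  dist <- do.call(rbind, lapply(b, `[[`, "dist"))   # dist[s, ] from s
  sigma <- do.call(rbind, lapply(b, `[[`, "sigma"))
  bc <- rep(0, m)
  for (j in seq_len(m)) for (k in seq_len(m)) {
    if (j == k || is.infinite(dist[j, k])) next
    for (i in seq_len(m)) {
      if (i == j || i == k) next
      if (dist[j, i] + dist[i, k] == dist[j, k])
        bc[i] <- bc[i] + sigma[j, i] * sigma[i, k] / sigma[j, k]
    }
  }
  names(bc) <- rownames(adj)
  bc
}

# --- minimal EDF writer (test fixture only) ---------------------------------
# writes a single-record-duration EDF file with int16 quantization
write_edf_fixture <- function(path, data, rate, channel_names,
                              record_s = 1) {
  m <- nrow(data)
  spr <- as.integer(rate * record_s)
  stopifnot(ncol(data) %% spr == 0)
  n_rec <- ncol(data) %/% spr
  pmin <- apply(data, 1, min) - 1e-6
  pmax <- apply(data, 1, max) + 1e-6
  dmin <- -32768L; dmax <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(x, w) {
    s <- formatC(as.character(x), width = w, flag = "-")
    writeChar(substr(s, 1, w), con, eos = NULL)
  }
  pad("0", 8); pad("test patient", 80); pad("test recording", 80)
  pad("01.01.24", 8); pad("00.00.00", 8)
  pad(256 + 256 * m, 8); pad("", 44); pad(n_rec, 8)
  pad(format(record_s), 8); pad(m, 4)
  for (nm in channel_names) pad(nm, 16)
  for (i in 1:m) pad("", 80)
  for (i in 1:m) pad("uV", 8)
  for (i in 1:m) pad(formatC(pmin[i], format = "g", digits = 6), 8)
  for (i in 1:m) pad(formatC(pmax[i], format = "g", digits = 6), 8)
  for (i in 1:m) pad(dmin, 8)
  for (i in 1:m) pad(dmax, 8)
  for (i in 1:m) pad("", 80)
  for (i in 1:m) pad(spr, 8)
  for (i in 1:m) pad("", 32)
  # re-read the header's printed physical range so quantization round-trips
  pmin_r <- as.numeric(formatC(pmin, format = "g", digits = 6))
  pmax_r <- as.numeric(formatC(pmax, format = "g", digits = 6))
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * spr + 1):(r * spr)
    for (i in 1:m) {
      dig <- round((data[i, cols] - pmin_r[i]) /
                     (pmax_r[i] - pmin_r[i]) * (dmax - dmin) + dmin)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
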