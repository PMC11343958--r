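#' Betweenness centrality of every node
#'
#' For every ordered pair (j, k) of distinct nodes with at least one
#' directed path, node i (with j != i != k) accumulates the fraction of
#' shortest directed unweighted paths from j to k that pass through i;
#' unreachable pairs contribute nothing. Endpoints are excluded (the
#' Freeman definition). Computation is delegated to
#' [igraph::betweenness()].
#'
#' @param adj binary adjacency matrix with channel dimnames.
#' @return Named numeric vector of betweenness scores.
#' @export
betweenness_scores <- function(adj) {
  v <- as_causal_values(adj)
  g <- igraph::graph_from_adjacency_matrix(v, mode = "directed")
  bc <- igraph::betweenness(g, directed = TRUE)
  stats::setNames(as.numeric(bc),
                  rownames(v) %||% as.character(seq_len(nrow(v))))
}

#' Causal-weighted PageRank transition matrix
#'
#' `M = f(t(G) * t(adj))` where `*` is the element-wise product - the
#' binary adjacency masks which raw causal weights survive - and `f`
#' L1-normalizes each column, so `M[i, j]` is the probability of stepping
#' from node j to node i and every nonzero column sums to 1. When all
#' retained out-weights of a node are equal this reduces to the unweighted
#' random walk `1 / d_out(j)`. A node with no retained out-edges leaves an
#' all-zero column, which would leak probability mass from the walk; by
#' default such columns are replaced with the uniform distribution `1/m`
#' (`dangling = "uniform"`); `dangling = "zero"` keeps the literal guarded
#' normalization.
#'
#' @param G raw causal matrix (weights).
#' @param adj binary adjacency of the same shape and channel names.
#' @param dangling treatment of zero out-degree nodes, `"uniform"` or
#'   `"zero"`.
#' @return m x m column-stochastic matrix of class `transition_matrix`.
#' @export
build_transition <- function(G, adj, dangling = c("uniform", "zero")) {
  dangling <- match.arg(dangling)
  Gv <- as_causal_values(G)
  av <- as_causal_values(adj)
  if (!identical(dim(Gv), dim(av)))
    stop("causal matrix and adjacency must have the same shape")
  if (!is.null(rownames(Gv)) && !is.null(rownames(av)) &&
      !identical(rownames(Gv), rownames(av)))
    stop("causal matrix and adjacency must have the same channel names")
  M <- t(Gv) * t(av)
  cs <- colSums(M)
  nz <- cs > 0
  M[, nz] <- sweep(M[, nz, drop = FALSE], 2L, cs[nz], `/`)
  if (dangling == "uniform" && any(!nz))
    M[, !nz] <- 1 / nrow(M)
  structure(M, class = c("transition_matrix", "matrix", "array"),
            dangling = dangling)
}

#' PageRank centrality by damped power iteration
#'
#' Iterates `PR_{t+1} = lambda * M %*% PR_t + (1 - lambda) / m` from the
#' uniform vector until the L1 change drops below `tol`. On a
#' column-stochastic M (no dangling columns) the converged scores are
#' nonnegative and sum to 1; the iteration is a contraction with factor
#' `lambda`, so convergence is guaranteed.
#'
#' @param M column-stochastic transition matrix (columns may also sum to 0
#'   when built with `dangling = "zero"`).
#' @param lambda damping coefficient in `(0, 1)`, default 0.85.
#' @param tol L1 convergence tolerance.
#' @param max_iter iteration cap; exceeded -> error.
#' @return Named numeric vector of PageRank scores.
#' @export
pagerank_scores <- function(M, lambda = 0.85, tol = 1e-10, max_iter = 200L) {
  v <- as_causal_values(M)
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0 || lambda >= 1)
    stop("lambda must lie strictly inside (0, 1)")
  cs <- colSums(v)
  ok <- abs(cs - 1) < 1e-8 | abs(cs) < 1e-12
  if (any(!ok))
    stop("transition matrix columns must sum to 1 (or 0 for dangling nodes); ",
         "offending column(s): ", paste(which(!ok), collapse = ", "))
  m <- nrow(v)
  pr <- rep(1 / m, m)
  for (it in seq_len(max_iter)) {
    pr_new <- as.numeric(lambda * (v %*% pr) + (1 - lambda) / m)
    delta <- sum(abs(pr_new - pr))
    pr <- pr_new
    if (delta < tol) {
      names(pr) <- rownames(v) %||% as.character(seq_len(m))
      return(pr)
    }
  }
  stop("PageRank did not converge within ", max_iter, " iterations ",
       "(last L1 change ", format(delta), ")")
}

#' Betweenness and PageRank of an epoch's causal graph
#'
#' Convenience wrapper: betweenness on the binary adjacency and PageRank on
#' the causal-weighted transition matrix.
#'
#' @param G raw causal matrix.
#' @param adj binary adjacency derived from it.
#' @param lambda PageRank damping coefficient.
#' @return data.frame with columns `node`, `bc`, `pr`.
#' @export
centrality_scores <- function(G, adj, lambda = 0.85) {
  bc <- betweenness_scores(adj)
  pr <- pagerank_scores(build_transition(G, adj), lambda = lambda)
  data.frame(node = names(bc), bc = as.numeric(bc),
             pr = as.numeric(pr[names(bc)]),
             row.names = NULL, stringsAsFactors = FALSE)
}
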