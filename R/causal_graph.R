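#' Row-normalize a causal matrix
#'
#' Divides every row of the nonnegative causal matrix by its sum so the
#' outgoing strengths of each source are comparable across sources. The
#' diagonal is zeroed first (self-causality is undefined in the
#' Wiener-Granger index and would distort row sums). A row whose sum is
#' zero - a channel with no detected outgoing influence - is left all-zero
#' rather than raising an error, mirroring the guarded normalization used
#' for the PageRank transition matrix.
#'
#' @param G m x m nonnegative causal matrix with channel dimnames.
#' @return Normalized matrix of class `normalized_causal_matrix`: rows with
#'   nonzero sum add to 1, entries in `[0, 1]`.
#' @export
normalize_rows <- function(G) {
  G <- as_causal_values(G)
  if (any(G < 0)) stop("causal matrix must be nonnegative")
  diag(G) <- 0
  rs <- rowSums(G)
  nz <- rs > 0
  G[nz, ] <- G[nz, , drop = FALSE] / rs[nz]
  structure(G, class = c("normalized_causal_matrix", "matrix", "array"))
}

as_causal_values <- function(G) {
  v <- as.matrix(G)
  attributes(v) <- attributes(v)[c("dim", "dimnames")]
  if (nrow(v) != ncol(v)) stop("causal matrix must be square")
  if (!all(is.finite(v))) stop("causal matrix has non-finite entries")
  v
}

#' Binarize a normalized causal matrix into a directed adjacency matrix
#'
#' An edge i -> j is kept iff the normalized strength `c*_ij >= phi_G`
#' (ties at the threshold are kept); all other entries, and the diagonal,
#' become 0. The resulting binary matrix is the adjacency matrix underlying
#' all graph analysis.
#'
#' @param G_star normalized causal matrix (entries in `[0, 1]`).
#' @param phi_G binarization threshold, strictly inside `(0, 1)`.
#' @return Binary m x m matrix of class `binary_adjacency` with attribute
#'   `threshold`.
#' @export
binarize <- function(G_star, phi_G = 0.1) {
  if (!is.numeric(phi_G) || length(phi_G) != 1L || phi_G <= 0 || phi_G >= 1)
    stop("phi_G must lie strictly inside (0, 1)")
  v <- as_causal_values(G_star)
  adj <- (v >= phi_G) * 1
  diag(adj) <- 0
  structure(adj, class = c("binary_adjacency", "matrix", "array"),
            threshold = phi_G)
}

#' Directed edge list of a binary adjacency matrix
#'
#' @param adj binary adjacency matrix with channel dimnames.
#' @return data.frame with columns `from`, `to` (channel names).
#' @export
adjacency_edges <- function(adj) {
  v <- as_causal_values(adj)
  idx <- which(v != 0, arr.ind = TRUE)
  nms <- rownames(v) %||% as.character(seq_len(nrow(v)))
  data.frame(from = nms[idx[, 1]], to = nms[idx[, 2]],
             stringsAsFactors = FALSE)[order(idx[, 1], idx[, 2]), ,
                                       drop = FALSE]
}

#' Write a directed adjacency as an edge list or GraphML
#'
#' @param adj binary adjacency matrix.
#' @param path output file.
#' @param format `"edgelist"` (two-column delimited text) or `"graphml"`.
#' @export
write_adjacency <- function(adj, path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    utils::write.table(adjacency_edges(adj), path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  } else {
    g <- igraph::graph_from_adjacency_matrix(as_causal_values(adj),
                                             mode = "directed")
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
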