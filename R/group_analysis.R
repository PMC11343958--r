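#' In/out degrees of every node of a directed graph
#'
#' In-degree is the column sum and out-degree the row sum of the binary
#' adjacency (self-loops excluded; the adjacency diagonal is zero by
#' construction).
#'
#' @param adj binary adjacency matrix with channel dimnames.
#' @return data.frame with columns `node`, `d_in`, `d_out`.
#' @export
node_degrees <- function(adj) {
  v <- as_causal_values(adj)
  if (any(v != 0 & v != 1)) stop("adjacency must be binary")
  diag(v) <- 0
  nms <- rownames(v) %||% as.character(seq_len(nrow(v)))
  data.frame(node = nms, d_in = colSums(v), d_out = rowSums(v),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Degree centrality of a node
#'
#' `dc = (d_in - d_out) / (d_in + d_out)`, in `[-1, 1]`: -1 for a pure
#' source (only outgoing edges), +1 for a pure sink. An isolated node
#' (`d_in = d_out = 0`) is assigned 0 - the formula is 0/0 there and an
#' unconnected node carries no directional evidence.
#'
#' @param d_in,d_out nonnegative integer degree vectors.
#' @return Numeric vector of degree centralities.
#' @export
degree_centrality <- function(d_in, d_out) {
  tot <- d_in + d_out
  dc <- ifelse(tot == 0, 0, (d_in - d_out) / tot)
  as.numeric(dc)
}

#' Classify nodes into onset-source / propagation-internal / target roles
#'
#' Nodes with degree centrality `dc <= -phi_dc` are onset sources (`O_S`,
#' out-degree dominated), nodes with `dc >= phi_dc` are propagation targets
#' (`P_T`, in-degree dominated), and everything strictly between is
#' propagation-internal (`P_I`). Boundary values belong to the outer
#' classes. Lowering `phi_dc` moves nodes out of `P_I` into `O_S`/`P_T`.
#'
#' @param degrees data.frame from [node_degrees()] (or anything with
#'   columns `node`, `d_in`, `d_out`).
#' @param phi_dc classification threshold, strictly inside `(0, 1)`.
#' @return data.frame with columns `node`, `d_in`, `d_out`, `dc`, `cls`
#'   (factor with levels `O_S`, `P_I`, `P_T`).
#' @export
classify_nodes <- function(degrees, phi_dc = 0.1) {
  if (!is.numeric(phi_dc) || length(phi_dc) != 1L || phi_dc <= 0 || phi_dc >= 1)
    stop("phi_dc must lie strictly inside (0, 1)")
  stopifnot(all(c("node", "d_in", "d_out") %in% names(degrees)))
  dc <- degree_centrality(degrees$d_in, degrees$d_out)
  cls <- ifelse(dc <= -phi_dc, "O_S", ifelse(dc >= phi_dc, "P_T", "P_I"))
  out <- degrees[, c("node", "d_in", "d_out")]
  out$dc <- dc
  out$cls <- factor(cls, levels = c("O_S", "P_I", "P_T"))
  out
}

#' Read an expert channel grouping from YAML
#'
#' Expected layout: a mapping `groups:` with keys `O`, `P`, `N`, each a
#' list of channel names (onset, propagation, not-involved).
#'
#' @param path YAML file.
#' @return Named character vector: channel -> group label (`"O"`, `"P"`,
#'   `"N"`).
#' @export
read_expert_grouping <- function(path) {
  y <- yaml::read_yaml(path)
  g <- y$groups %||% y
  labels <- intersect(c("O", "P", "N"), names(g))
  if (!length(labels)) stop("no O/P/N groups found in ", path)
  out <- unlist(lapply(labels, function(l)
    stats::setNames(rep(l, length(g[[l]])), as.character(g[[l]]))))
  if (anyDuplicated(names(out)))
    stop("channel(s) assigned to more than one group: ",
         paste(unique(names(out)[duplicated(names(out))]), collapse = ", "))
  out
}

#' Mark node classifications against the expert grouping
#'
#' A node classified `O_S` whose expert label is `O`, or classified `P_T`
#' with expert label `P`, is marked `"T"` (consistent); `O_S` against `P`
#' or `P_T` against `O` is `"F"` (misclassified); any `P_I` node is marked
#' `"M"` (undecided - its group is left to the expert). Channels in the
#' not-involved group must be excluded before this stage.
#'
#' @param classification data.frame from [classify_nodes()].
#' @param expert named character vector channel -> `"O"`/`"P"` (see
#'   [read_expert_grouping()]).
#' @return data.frame with columns `node`, `cls`, `expert`, `mark`.
#' @export
mark_against_expert <- function(classification, expert) {
  stopifnot(all(c("node", "cls") %in% names(classification)))
  nodes <- classification$node
  missing <- setdiff(nodes, names(expert))
  if (length(missing))
    stop("no expert label for channel(s): ", paste(missing, collapse = ", "))
  lab <- expert[nodes]
  if (any(lab == "N"))
    stop("not-involved (N) channel(s) must be excluded before marking: ",
         paste(nodes[lab == "N"], collapse = ", "))
  cls <- as.character(classification$cls)
  mark <- ifelse(cls == "P_I", "M",
                 ifelse((cls == "O_S" & lab == "O") |
                        (cls == "P_T" & lab == "P"), "T", "F"))
  data.frame(node = nodes, cls = cls, expert = unname(lab), mark = mark,
             stringsAsFactors = FALSE)
}

#' Strict and lenient classification accuracy
#'
#' `Acc1 = #T / N` counts undecided (`M`) channels as incorrect; `Acc2 =
#' (#T + #M) / N` counts them as correct (their group is resolved by the
#' expert). `Acc1 <= Acc2` always, with equality iff there are no `M`
#' marks.
#'
#' @param marks character vector of `"T"`/`"F"`/`"M"` marks, or a
#'   data.frame from [mark_against_expert()].
#' @return Named numeric vector `c(acc1 = , acc2 = )`.
#' @export
accuracy_scores <- function(marks) {
  if (is.data.frame(marks)) marks <- marks$mark
  marks <- as.character(marks)
  if (!length(marks)) stop("empty mark list")
  bad <- setdiff(unique(marks), c("T", "F", "M"))
  if (length(bad)) stop("invalid mark(s): ", paste(bad, collapse = ", "))
  n <- length(marks)
  c(acc1 = sum(marks == "T") / n,
    acc2 = sum(marks %in% c("T", "M")) / n)
}
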