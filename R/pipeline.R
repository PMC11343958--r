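#' Full pipeline configuration
#'
#' Extends [predictor_config()] with the graph-analysis thresholds and
#' bookkeeping: binarization threshold `phi_G` (default 0.1), node
#' classification threshold `phi_dc` (default 0.1), PageRank damping
#' `lambda` (default 0.85), the expert group excluded from analysis
#' (default `"N"`, the not-involved channels), and an optional output
#' directory for per-epoch reports.
#'
#' @param ... arguments forwarded to [predictor_config()].
#' @param phi_G binarization threshold in `(0, 1)`.
#' @param phi_dc classification threshold in `(0, 1)`.
#' @param lambda PageRank damping coefficient in `(0, 1)`.
#' @param excluded_group expert group label dropped before analysis.
#' @param output_dir directory for written reports, or `NULL` to skip
#'   writing.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(..., phi_G = 0.1, phi_dc = 0.1, lambda = 0.85,
                            excluded_group = "N", output_dir = NULL) {
  pc <- predictor_config(...)
  for (nm in c("phi_G", "phi_dc", "lambda")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v >= 1)
      stop(nm, " must lie strictly inside (0, 1)")
  }
  cfg <- c(unclass(pc), list(phi_G = phi_G, phi_dc = phi_dc, lambda = lambda,
                             excluded_group = excluded_group,
                             output_dir = output_dir))
  structure(cfg, class = c("pipeline_config", "predictor_config"))
}

#' Read a pipeline configuration from YAML
#'
#' Keys are named exactly as in [pipeline_config()] /
#' [predictor_config()]; missing keys take their defaults.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- union(names(formals(predictor_config)),
                 c("phi_G", "phi_dc", "lambda", "excluded_group",
                   "output_dir"))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, y)
}

#' Run the full effective-connectivity pipeline on a recording
#'
#' Drops channels of the excluded expert group, slices the recording into
#' the scheme's epochs, and for each epoch independently: estimates the
#' causal matrix ([wgci_matrix()]), row-normalizes and binarizes it,
#' computes node degrees, classifies nodes, marks them against the expert
#' grouping, scores Acc1/Acc2, and computes betweenness and causal-weighted
#' PageRank. An error in one epoch is recorded in that epoch's report and
#' the remaining epochs still run.
#'
#' @param config a [pipeline_config()].
#' @param rec an `mc_recording`.
#' @param scheme an [epoch_scheme()].
#' @param expert named channel -> group vector ([read_expert_grouping()]);
#'   `NULL` skips channel exclusion and marking.
#' @param verbose print progress.
#' @return List of class `pipeline_result`: one report per epoch, each with
#'   elements `epoch`, `causal`, `normalized`, `adjacency`,
#'   `classification`, `marks`, `accuracy`, `centrality`, `meta` (or
#'   `error`).
#' @export
run_pipeline <- function(config, rec, scheme, expert = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"),
            inherits(rec, "mc_recording"),
            inherits(scheme, "epoch_scheme"))
  if (!is.null(expert)) {
    covered <- intersect(rec$channel_names, names(expert))
    analyzed <- covered[expert[covered] != config$excluded_group]
    if (length(analyzed) < 2L)
      stop("fewer than 2 analyzed channels after excluding group ",
           config$excluded_group)
    rec <- select_channels(rec, analyzed)
  }
  epochs <- segment_epochs(rec, scheme)
  out_dir <- config$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  reports <- lapply(names(epochs), function(ep_name) {
    if (verbose) message("epoch: ", ep_name)
    t0 <- Sys.time()
    tryCatch({
      G <- wgci_matrix(epochs[[ep_name]], config, verbose = verbose)
      G_star <- normalize_rows(G)
      adj <- binarize(G_star, config$phi_G)
      degrees <- node_degrees(adj)
      classification <- classify_nodes(degrees, config$phi_dc)
      marks <- NULL; accuracy <- NULL
      if (!is.null(expert)) {
        marks <- mark_against_expert(classification, expert)
        accuracy <- accuracy_scores(marks)
      }
      cent <- centrality_scores(G, adj, lambda = config$lambda)
      rep <- list(epoch = ep_name, causal = G, normalized = G_star,
                  adjacency = adj, classification = classification,
                  marks = marks, accuracy = accuracy, centrality = cent,
                  meta = list(seed = config$seed,
                              n_repeats = config$n_repeats,
                              phi_G = config$phi_G, phi_dc = config$phi_dc,
                              lambda = config$lambda,
                              elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                              units = "secs"))))
      if (!is.null(out_dir)) write_epoch_report(rep, out_dir)
      rep
    }, error = function(e) {
      list(epoch = ep_name, error = conditionMessage(e))
    })
  })
  names(reports) <- names(epochs)
  failed <- names(reports)[vapply(reports, function(r) !is.null(r$error), TRUE)]
  structure(reports, class = "pipeline_result", failed = failed)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>", length(x), "epoch(s)\n")
  for (r in x) {
    if (!is.null(r$error)) {
      cat(sprintf("  %-12s FAILED: %s\n", r$epoch, r$error))
    } else if (!is.null(r$accuracy)) {
      cat(sprintf("  %-12s %d edges, Acc1 = %.3f, Acc2 = %.3f\n", r$epoch,
                  sum(r$adjacency), r$accuracy["acc1"], r$accuracy["acc2"]))
    } else {
      cat(sprintf("  %-12s %d edges\n", r$epoch, sum(r$adjacency)))
    }
  }
  invisible(x)
}

write_epoch_report <- function(rep, out_dir) {
  slug <- gsub("[^A-Za-z0-9]+", "_", rep$epoch)
  pre <- file.path(out_dir, slug)
  write_causal_matrix(rep$causal, paste0(pre, "_causal.csv"))
  write_causal_matrix(rep$normalized, paste0(pre, "_normalized.csv"))
  write_causal_matrix(rep$adjacency, paste0(pre, "_adjacency.csv"))
  utils::write.table(rep$classification, paste0(pre, "_classification.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(rep$marks)) {
    mk <- rep$marks
    mk$acc1 <- rep$accuracy["acc1"]; mk$acc2 <- rep$accuracy["acc2"]
    utils::write.table(mk, paste0(pre, "_marks.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  utils::write.table(rep$centrality, paste0(pre, "_centrality.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(pre)
}

#' Export an epoch's directed graph for external viewers
#'
#' Writes the adjacency as GraphML or DOT with per-node attributes (class,
#' betweenness, PageRank, and the expert label when available). With
#' `simplified = TRUE`, only edges incident to an onset-source (`O_S`) or
#' propagation-target (`P_T`) node are kept - edges running purely between
#' propagation-internal nodes are dropped.
#'
#' @param report one epoch report from [run_pipeline()].
#' @param path output file.
#' @param format `"graphml"` or `"dot"`.
#' @param simplified keep only edges touching `O_S`/`P_T` nodes.
#' @export
export_graph <- function(report, path, format = c("graphml", "dot"),
                         simplified = FALSE) {
  format <- match.arg(format)
  if (!is.null(report$error)) stop("cannot export a failed epoch report")
  adj <- as_causal_values(report$adjacency)
  cls <- report$classification
  if (simplified) {
    keep_nodes <- cls$node[cls$cls %in% c("O_S", "P_T")]
    mask <- outer(rownames(adj) %in% keep_nodes,
                  colnames(adj) %in% keep_nodes, `|`)
    adj <- adj * mask
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "directed")
  ord <- match(igraph::V(g)$name, cls$node)
  g <- igraph::set_vertex_attr(g, "class", value = as.character(cls$cls)[ord])
  cent <- report$centrality
  g <- igraph::set_vertex_attr(g, "bc",
                               value = cent$bc[match(igraph::V(g)$name, cent$node)])
  g <- igraph::set_vertex_attr(g, "pr",
                               value = cent$pr[match(igraph::V(g)$name, cent$node)])
  if (!is.null(report$marks))
    g <- igraph::set_vertex_attr(g, "expert",
                                 value = report$marks$expert[
                                   match(igraph::V(g)$name, report$marks$node)])
  igraph::write_graph(g, path, format = format)
  invisible(path)
}

#' Table-style mark summary of a pipeline result
#'
#' One row per epoch: per-channel T/F/M marks and the strict/lenient
#' accuracies, mirroring the layout of per-seizure accuracy tables.
#'
#' @param result a `pipeline_result` with expert marks.
#' @param group restrict to channels with this expert label (e.g. `"O"`),
#'   or `NULL` for all.
#' @return data.frame with columns `epoch`, one column per channel, `acc1`,
#'   `acc2`.
#' @export
mark_table <- function(result, group = NULL) {
  rows <- lapply(result, function(r) {
    if (!is.null(r$error) || is.null(r$marks)) return(NULL)
    mk <- r$marks
    if (!is.null(group)) mk <- mk[mk$expert == group, , drop = FALSE]
    if (!nrow(mk)) return(NULL)
    acc <- accuracy_scores(mk)
    cbind(data.frame(epoch = r$epoch),
          as.data.frame(as.list(stats::setNames(mk$mark, mk$node)),
                        check.names = FALSE),
          data.frame(acc1 = acc["acc1"], acc2 = acc["acc2"],
                     row.names = NULL))
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}
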