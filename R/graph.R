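# Homology graph assembly, inter-organism normalization, components,
# and graph export (ABC, GML, TSV).

#' Build a weighted homology graph from best hits
#'
#' Creates an undirected graph whose nodes are sequences and whose edges
#' carry all four edge-weighting metrics for the best hit between each
#' unordered pair. Every graph derived from one hit table is topologically
#' identical across metrics; only the weights differ.
#'
#' @param best Best-hit data.frame from [best_hits()] (E-value-filtered).
#' @param self_scores Named SBS vector from [extract_self_scores()].
#' @param stats Database statistics from [database_stats()].
#' @param node_info Optional data.frame with columns `id`, `organism` and
#'   (optionally) `group`; when `NULL`, labels are parsed from
#'   `"organism|group|serial"` record ids.
#' @param config A [metric_config()]; hits above `config$evalue_cutoff`
#'   are a contract violation and raise an error.
#' @return An object of class `homology_graph`: list with `nodes`
#'   (id, organism, group), `edges` (id1, id2, bs, nle, bsr, bal) and
#'   `normalization` (`"raw"` or `"inter_organism"`).
#' @export
build_graph <- function(best, self_scores, stats, node_info = NULL,
                        config = metric_config()) {
  edges <- compute_edge_weights(best, self_scores, stats, config)
  ids <- sort(unique(c(edges$id1, edges$id2)))
  if (is.null(node_info)) {
    nodes <- if (length(ids)) parse_seq_ids(ids) else
      data.frame(id = character(0), organism = character(0),
                 group = character(0), stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("id", "organism") %in% names(node_info)))
    missing <- setdiff(ids, node_info$id)
    if (length(missing)) stopf("node_info lacks sequence '%s'", missing[1L])
    nodes <- node_info[node_info$id %in% ids,
                       intersect(c("id", "organism", "group"), names(node_info)),
                       drop = FALSE]
    if (is.null(nodes$group)) nodes$group <- NA_character_
    nodes <- nodes[order(nodes$id), , drop = FALSE]
  }
  rownames(nodes) <- NULL
  new_homology_graph(nodes, edges, "raw")
}

new_homology_graph <- function(nodes, edges, normalization) {
  if (any(edges$id1 == edges$id2)) stopf("self edges are not allowed")
  for (m in intersect(metric_names(), names(edges))) {
    if (any(edges[[m]] <= 0)) stopf("non-positive '%s' edge weight", m)
  }
  structure(list(nodes = nodes, edges = edges, normalization = normalization),
            class = "homology_graph")
}

#' @export
print.homology_graph <- function(x, ...) {
  cat(sprintf("homology_graph: %d nodes, %d edges, %d organisms [%s]\n",
              nrow(x$nodes), nrow(x$edges),
              length(unique(x$nodes$organism)), x$normalization))
  invisible(x)
}

edge_organism_pairs <- function(graph) {
  org <- setNames(graph$nodes$organism, graph$nodes$id)
  o1 <- org[graph$edges$id1]
  o2 <- org[graph$edges$id2]
  if (anyNA(o1) || anyNA(o2)) stopf("edge endpoint without an organism label")
  pair_key(o1, o2)
}

#' Per-organism-pair average edge weights
#'
#' For each metric, the mean edge weight over the whole graph and over the
#' edges connecting each unordered pair of organisms (intra-organism edges
#' count as the pair (x, x)).
#'
#' @param graph A `homology_graph`.
#' @param metrics Metric columns to summarize.
#' @return List with `pair_means` (data.frame: organism pair key + one
#'   column per metric) and `global_means` (named numeric).
#' @export
organism_pair_means <- function(graph, metrics = metric_names()) {
  op <- edge_organism_pairs(graph)
  pm <- aggregate(graph$edges[metrics], by = list(org_pair = op), FUN = mean)
  gm <- vapply(metrics, function(m) mean(graph$edges[[m]]), numeric(1))
  list(pair_means = pm, global_means = gm)
}

#' Inter-organism edge-weight normalization
#'
#' Multiplies each edge weight by the ratio of the graph-wide average edge
#' weight to the average weight between the edge's two organisms. This
#' boosts edges between organisms whose sequences are relatively divergent
#' and shrinks edges between close organisms; after normalization every
#' organism pair's mean weight equals the original global mean. The
#' operation is not idempotent: a second application acts on the already
#' scaled weights.
#'
#' @param graph A `homology_graph` with organism labels on every node.
#' @param metrics Metric columns to normalize (default all four).
#' @param direction `"global_over_pair"` (default) multiplies by
#'   global mean / pair mean; `"pair_over_global"` is the reciprocal
#'   variant, provided for comparison with implementations that state the
#'   ratio in the opposite orientation.
#' @return A new `homology_graph` with `normalization = "inter_organism"`;
#'   the input graph is unmodified.
#' @export
normalize_inter_organism <- function(graph, metrics = metric_names(),
                                     direction = c("global_over_pair",
                                                   "pair_over_global")) {
  direction <- match.arg(direction)
  op <- edge_organism_pairs(graph)
  edges <- graph$edges
  for (m in metrics) {
    pair_mean <- tapply(edges[[m]], op, mean)
    global_mean <- mean(edges[[m]])
    ratio <- global_mean / as.numeric(pair_mean[op])
    if (direction == "pair_over_global") ratio <- 1 / ratio
    edges[[m]] <- edges[[m]] * ratio
  }
  new_homology_graph(graph$nodes, edges, "inter_organism")
}

as_igraph <- function(graph, metric = NULL) {
  el <- graph$edges[, c("id1", "id2"), drop = FALSE]
  g <- igraph::graph_from_data_frame(el, directed = FALSE,
                                     vertices = graph$nodes$id)
  if (!is.null(metric)) igraph::E(g)$weight <- graph$edges[[metric]]
  g
}

#' Connected components of the homology graph
#'
#' Each connected component of the best-hit graph is a "BLAST cluster":
#' the pre-MCL baseline partition. MCL can only subdivide components,
#' never merge them, so component purity bounds what clustering can fix.
#'
#' @param graph A `homology_graph`.
#' @return A [clustering()] object with provenance `"components"`.
#' @export
connected_components <- function(graph) {
  if (nrow(graph$nodes) == 0L) {
    return(clustering(list(), provenance = list(method = "components")))
  }
  comp <- igraph::components(as_igraph(graph))
  clusters <- split(names(comp$membership), comp$membership)
  clustering(unname(clusters), provenance = list(method = "components"))
}

#' Write / read a single-metric ABC edge list
#'
#' The three-column `id1 TAB id2 TAB weight` text format consumed by the
#' external MCL program. Weights are serialized at full double precision
#' so they survive a round trip.
#'
#' @param graph A `homology_graph`.
#' @param metric Which metric column to export.
#' @param file Output path.
#' @return `write_abc`: invisibly, the path written. `read_abc`: a
#'   `homology_graph` whose single weight column is named `weight`
#'   (organism labels parsed from ids where possible, else `NA`).
#' @export
write_abc <- function(graph, metric, file) {
  stopifnot(metric %in% names(graph$edges))
  w <- vapply(graph$edges[[metric]], format_num, character(1))
  writeLines(paste(graph$edges$id1, graph$edges$id2, w, sep = "\t"), file)
  invisible(file)
}

#' @rdname write_abc
#' @export
read_abc <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 3L)
  if (length(bad)) stopf("line %d: expected 3 tab-separated fields", bad[1L])
  id1 <- vapply(fields, `[`, character(1), 1L)
  id2 <- vapply(fields, `[`, character(1), 2L)
  w <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3L)))
  if (anyNA(w)) stopf("line %d: non-numeric weight", which(is.na(w))[1L])
  if (any(w <= 0)) stopf("line %d: non-positive weight", which(w <= 0)[1L])
  edges <- data.frame(id1 = pmin(id1, id2), id2 = pmax(id1, id2),
                      weight = w, stringsAsFactors = FALSE)
  ids <- sort(unique(c(edges$id1, edges$id2)))
  nodes <- tryCatch(parse_seq_ids(ids),
                    error = function(e) data.frame(id = ids,
                                                   organism = NA_character_,
                                                   group = NA_character_,
                                                   stringsAsFactors = FALSE))
  new_homology_graph(nodes, edges, "raw")
}

#' Write an annotated GML graph
#'
#' Nodes carry `organism`, `eck` (reference group) and `cluster` attributes
#' where available; edges carry the selected metric's weight. The output
#' parses with standard GML readers (e.g. Cytoscape, igraph).
#'
#' @param graph A `homology_graph`.
#' @param file Output path.
#' @param metric Metric used for the edge `weight` attribute.
#' @param clustering Optional [clustering()]; adds an integer `cluster`
#'   attribute per node.
#' @param reference Optional named vector id -> reference group; adds an
#'   `eck` attribute per node.
#' @return Invisibly, the path written.
#' @export
write_gml <- function(graph, file, metric = "bs", clustering = NULL,
                      reference = NULL) {
  ids <- graph$nodes$id
  idx <- setNames(seq_along(ids) - 1L, ids)
  memb <- if (!is.null(clustering)) cluster_membership(clustering) else NULL
  quote_gml <- function(x) paste0('"', gsub('"', "'", x), '"')
  node_block <- function(i) {
    id <- ids[i]
    lines <- c("  node [",
               sprintf("    id %d", idx[[id]]),
               sprintf("    label %s", quote_gml(id)),
               sprintf("    organism %s", quote_gml(graph$nodes$organism[i])))
    grp <- if (!is.null(reference)) unname(reference[id]) else graph$nodes$group[i]
    if (!is.na(grp) && !is.null(grp)) {
      lines <- c(lines, sprintf("    eck %s", quote_gml(grp)))
    }
    if (!is.null(memb) && !is.na(memb[id])) {
      lines <- c(lines, sprintf("    cluster %d", as.integer(memb[id])))
    }
    c(lines, "  ]")
  }
  edge_block <- function(i) {
    c("  edge [",
      sprintf("    source %d", idx[[graph$edges$id1[i]]]),
      sprintf("    target %d", idx[[graph$edges$id2[i]]]),
      sprintf("    weight %s", format_num(graph$edges[[metric]][i])),
      "  ]")
  }
  lines <- c("graph [", "  directed 0",
             unlist(lapply(seq_along(ids), node_block)),
             unlist(lapply(seq_len(nrow(graph$edges)), edge_block)),
             "]")
  writeLines(lines, file)
  invisible(file)
}

#' Write the four-metric edge table as TSV
#'
#' Fixed column order `id1, id2, bs, nle, bsr, bal` for downstream plotting.
#'
#' @param graph A `homology_graph`.
#' @param file Output path.
#' @return Invisibly, the path written.
#' @export
write_graph_tsv <- function(graph, file) {
  write.table(graph$edges[, c("id1", "id2", metric_names())], file,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
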