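# Scoring clusterings against reference homology groups, and edge-weight
# distribution summaries.

check_reference <- function(clust, reference) {
  ids <- unlist(clust$clusters, use.names = FALSE)
  missing <- ids[!(ids %in% names(reference))]
  if (length(missing)) {
    stopf("clustered item '%s' has no reference group mapping", missing[1L])
  }
  invisible(TRUE)
}

#' Map fragments to their parents' reference groups
#'
#' Extends a parent-level reference mapping to fragment ids via the sidecar
#' fragment table (never by parsing ids).
#'
#' @param reference Named vector parent id -> group.
#' @param fragments FragmentRecord data.frame.
#' @return Named vector fragment id -> group.
#' @export
fragment_reference <- function(reference, fragments) {
  grp <- unname(reference[fragments$parent_id])
  if (anyNA(grp)) {
    stopf("parent '%s' has no reference group",
          fragments$parent_id[which(is.na(grp))[1L]])
  }
  setNames(grp, fragments$fragment_id)
}

#' Sensitivity: clusters per reference group
#'
#' For each reference group, the number of distinct clusters containing at
#' least one of its members — 1 when the group is held together, larger
#' when it has been split. Groups whose members were all filtered out
#' before clustering are reported with count 0 and flagged in `surviving`.
#'
#' @param clust A [clustering()].
#' @param reference Named vector item id -> group.
#' @return data.frame with `group`, `n_clusters`, `surviving`.
#' @export
sensitivity_counts <- function(clust, reference) {
  check_reference(clust, reference)
  memb <- cluster_membership(clust)
  groups <- sort(unique(unname(reference)))
  n <- vapply(groups, function(g) {
    members <- names(reference)[reference == g]
    length(unique(memb[members][!is.na(memb[members])]))
  }, integer(1))
  data.frame(group = groups, n_clusters = n, surviving = n > 0L,
             stringsAsFactors = FALSE)
}

#' Specificity: reference groups per cluster
#'
#' For each cluster, the number of distinct reference groups among its
#' members — 1 for a pure cluster.
#'
#' @inheritParams sensitivity_counts
#' @return data.frame with `cluster_id`, `n_groups`, `size`.
#' @export
specificity_counts <- function(clust, reference) {
  check_reference(clust, reference)
  n <- vapply(clust$clusters, function(m) length(unique(unname(reference[m]))),
              integer(1))
  data.frame(cluster_id = seq_along(clust$clusters), n_groups = n,
             size = lengths(clust$clusters))
}

#' Perfectly reconstructed groups
#'
#' Counts clusters that contain every member of exactly one reference
#' group and no member of any other (the strict "perfectly reconstructed"
#' criterion).
#'
#' @inheritParams sensitivity_counts
#' @return Integer count.
#' @export
perfect_cluster_count <- function(clust, reference) {
  check_reference(clust, reference)
  group_members <- split(names(reference), unname(reference))
  sum(vapply(clust$clusters, function(m) {
    g <- unique(unname(reference[m]))
    length(g) == 1L && setequal(m, group_members[[g]])
  }, logical(1)))
}

#' Coefficient of variation
#'
#' Population standard deviation divided by the mean, \eqn{c_v = \sigma/\mu}.
#'
#' @param values Non-empty numeric vector with positive mean.
#' @return The ratio (0 iff all values are equal).
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) == 0L) stopf("empty sample")
  mu <- mean(values)
  if (mu <= 0) stopf("coefficient of variation needs a positive mean (got %g)", mu)
  sqrt(mean((values - mu)^2)) / mu
}

#' Intra- vs inter-group edge-weight distributions
#'
#' For each metric, edges are split into same-group (intra) and
#' different-group (inter) samples and scaled by that metric's overall
#' mean edge weight, so the pooled mean of each metric is 1.
#'
#' @param graph A `homology_graph`.
#' @param reference Named vector node id -> group (defaults to the graph's
#'   own `group` column).
#' @return List with `samples` (long data.frame: metric, class, weight
#'   scaled by the metric mean) and `summary` (per metric and class: n,
#'   mean, sd, cv, quartiles). An empty inter (or intra) sample appears in
#'   the summary with n = 0.
#' @export
edge_weight_distributions <- function(graph, reference = NULL) {
  if (is.null(reference)) {
    reference <- setNames(graph$nodes$group, graph$nodes$id)
  }
  g1 <- unname(reference[graph$edges$id1])
  g2 <- unname(reference[graph$edges$id2])
  if (anyNA(g1) || anyNA(g2)) stopf("edge endpoint without a reference label")
  cls <- ifelse(g1 == g2, "intra", "inter")
  samples <- do.call(rbind, lapply(metric_names(), function(m) {
    data.frame(metric = m, class = cls,
               weight = graph$edges[[m]] / mean(graph$edges[[m]]),
               stringsAsFactors = FALSE)
  }))
  grid <- expand.grid(metric = metric_names(), class = c("intra", "inter"),
                      stringsAsFactors = FALSE)
  summary <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    x <- samples$weight[samples$metric == grid$metric[i] &
                          samples$class == grid$class[i]]
    data.frame(metric = grid$metric[i], class = grid$class[i],
               n = length(x),
               mean = if (length(x)) mean(x) else NA_real_,
               sd = if (length(x) > 0) sqrt(mean((x - mean(x))^2)) else NA_real_,
               cv = if (length(x) && mean(x) > 0) coefficient_of_variation(x) else NA_real_,
               q25 = if (length(x)) unname(quantile(x, 0.25)) else NA_real_,
               median = if (length(x)) median(x) else NA_real_,
               q75 = if (length(x)) unname(quantile(x, 0.75)) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(samples = samples, summary = summary)
}

#' Bridge-edge retention on a fragmented graph
#'
#' On an evenly halved database the breakpoints of homologous sequences
#' line up, so fragments of the same rank form disjoint subclusters and
#' the only edges able to hold a group together are "bridges": hits
#' between fragments of different piece index from different parents,
#' which exist only where sequence lengths vary within a group. A bridge
#' is counted as retained under a metric when its weight is at least
#' `rel_threshold` times the median weight of that metric's ordinary
#' same-group, same-rank edges — i.e. when it stays within the dynamic
#' range MCL can act on rather than down in the spurious regime.
#'
#' @param graph Fragment-level `homology_graph`.
#' @param fragments FragmentRecord data.frame.
#' @param reference Parent-level reference mapping (named vector).
#' @param rel_threshold Retention threshold relative to the median
#'   non-bridge intra-group weight. The default 0.25 marks the point below
#'   which a single expansion-inflation round at moderate inflation drives
#'   an edge's flow to a negligible share of its competing backbone flow.
#' @return data.frame per metric: `n_bridges`, `retained`.
#' @export
bridge_edge_retention <- function(graph, fragments, reference,
                                  rel_threshold = 0.25) {
  fref <- fragment_reference(reference, fragments)
  info <- fragments[match(c(graph$edges$id1, graph$edges$id2),
                          fragments$fragment_id), ]
  n <- nrow(graph$edges)
  p1 <- info$parent_id[seq_len(n)]
  p2 <- info$parent_id[n + seq_len(n)]
  i1 <- info$piece_index[seq_len(n)]
  i2 <- info$piece_index[n + seq_len(n)]
  same_group <- unname(fref[graph$edges$id1]) == unname(fref[graph$edges$id2])
  bridge <- same_group & p1 != p2 & i1 != i2
  backbone <- same_group & !bridge
  do.call(rbind, lapply(metric_names(), function(m) {
    w <- graph$edges[[m]]
    ref_w <- median(w[backbone])
    data.frame(metric = m, n_bridges = sum(bridge),
               retained = sum(w[bridge] >= rel_threshold * ref_w),
               stringsAsFactors = FALSE)
  }))
}

#' Write an evaluation summary as TSV
#' @param df Any evaluation data.frame.
#' @param file Output path.
#' @return Invisibly, the path.
#' @export
write_eval_tsv <- function(df, file) {
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
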