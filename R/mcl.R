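# Native Markov Clustering (MCL) engine and the inflation sweep.
#
# The engine implements the canonical Markov Cluster process on a
# column-stochastic matrix: alternate expansion (matrix squaring) and
# inflation (entrywise power followed by column renormalization), prune
# tiny entries, and at convergence read clusters from the attractor
# systems of the limit matrix. Clustering runs independently per connected
# component, so even large sparse graphs reduce to small dense blocks.

#' Clustering container
#'
#' A partition of sequence identifiers into disjoint non-empty clusters,
#' tagged with its provenance (connected-component baseline or MCL with a
#' given metric, normalization state and inflation).
#'
#' @param clusters List of character vectors (disjoint, non-empty).
#' @param provenance Named list; conventionally `method` (`"components"` or
#'   `"mcl"`), and for MCL also `metric`, `normalization`, `inflation`.
#' @return Object of class `clustering`.
#' @export
clustering <- function(clusters, provenance = list()) {
  clusters <- lapply(clusters, function(x) sort(as.character(x)))
  if (any(lengths(clusters) == 0L)) stopf("empty cluster")
  all_ids <- unlist(clusters, use.names = FALSE)
  if (anyDuplicated(all_ids)) stopf("clusters are not disjoint")
  firsts <- vapply(clusters, `[`, character(1), 1L)
  clusters <- clusters[order(firsts)]
  structure(list(clusters = clusters, provenance = provenance),
            class = "clustering")
}

#' @export
print.clustering <- function(x, ...) {
  prov <- x$provenance
  tag <- if (identical(prov$method, "mcl")) {
    sprintf("mcl(%s, %s, I=%.2f)", prov$metric, prov$normalization, prov$inflation)
  } else {
    prov$method %||% "unknown"
  }
  cat(sprintf("clustering: %d clusters over %d items [%s]\n",
              length(x$clusters), sum(lengths(x$clusters)), tag))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Membership vector of a clustering
#' @param clust A [clustering()].
#' @return Named integer vector mapping item id to 1-based cluster index.
#' @export
cluster_membership <- function(clust) {
  n <- lengths(clust$clusters)
  setNames(rep.int(seq_along(clust$clusters), n),
           unlist(clust$clusters, use.names = FALSE))
}

#' MCL parameters
#'
#' @param inflation Granularity parameter (> 1); larger values give smaller
#'   clusters. Values around 1.5 are popular for sequence homology.
#' @param max_iterations Iteration cap before a non-convergence error.
#' @param convergence_tol Maximal absolute entry change between successive
#'   matrices at which iteration stops.
#' @param prune_threshold Entries below this are zeroed (then columns are
#'   renormalized) to keep the matrix sparse.
#' @param self_loop `"max_incident"` gives each node a loop weighted by its
#'   maximum incident edge weight (damps period-2 oscillations; falls back
#'   to 1 for isolated nodes); `"unit"` uses weight 1.
#' @return List of class `mcl_params`.
#' @export
mcl_params <- function(inflation = 1.5, max_iterations = 200,
                       convergence_tol = 1e-8, prune_threshold = 1e-7,
                       self_loop = c("max_incident", "unit")) {
  if (!is.numeric(inflation) || inflation <= 1.0) {
    stopf("inflation must be > 1.0 (got %s)", format(inflation))
  }
  stopifnot(convergence_tol > 0, prune_threshold >= 0, max_iterations >= 1)
  structure(list(inflation = inflation, max_iterations = max_iterations,
                 convergence_tol = convergence_tol,
                 prune_threshold = prune_threshold,
                 self_loop = match.arg(self_loop)),
            class = "mcl_params")
}

# Core iteration on one dense adjacency block. `ids` names the rows/cols.
# Returns a list of character vectors (the clusters within this block).
mcl_engine <- function(adj, ids, params) {
  n <- length(ids)
  if (n == 1L) return(list(ids))
  diag(adj) <- 0
  loops <- switch(params$self_loop,
                  max_incident = {
                    mx <- apply(adj, 2L, max)
                    ifelse(mx > 0, mx, 1.0)
                  },
                  unit = rep(1.0, n))
  diag(adj) <- loops
  M <- normalize_columns(adj)
  r <- params$inflation
  converged <- FALSE
  change <- NA_real_
  for (it in seq_len(params$max_iterations)) {
    M2 <- M %*% M                       # expansion
    M2 <- normalize_columns(M2^r)       # inflation
    if (params$prune_threshold > 0) {   # prune + renormalize
      M2[M2 < params$prune_threshold] <- 0
      M2 <- normalize_columns(M2)
    }
    change <- max(abs(M2 - M))
    M <- M2
    if (change < params$convergence_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stopf("MCL did not converge after %d iterations (residual %.3g)",
          params$max_iterations, change)
  }
  interpret_mcl_matrix(M, ids)
}

normalize_columns <- function(M) {
  cs <- colSums(M)
  zero <- cs == 0
  if (any(zero)) {
    # a column emptied by pruning keeps probability on its own node
    M[cbind(which(zero), which(zero))] <- 1
    cs[zero] <- 1
  }
  sweep(M, 2L, cs, "/")
}

# Read clusters from the limit matrix: nodes with diagonal mass are
# attractors; attractor systems (weakly connected sets of attractors) seed
# clusters; every other node joins the system(s) its column mass flows to,
# ties broken toward the cluster with the lexicographically smallest member.
# Entries at or below attractor_tol are numerical residue of the iteration
# (the exact limit has hard zeros) and carry no structure.
interpret_mcl_matrix <- function(M, ids, attractor_tol = 1e-6) {
  n <- length(ids)
  attractors <- which(diag(M) > attractor_tol)
  if (length(attractors) == 0L) {
    # degenerate limit (should not happen with self loops); treat the
    # nonzero structure's components as clusters
    attractors <- seq_len(n)
  }
  A <- M[attractors, attractors, drop = FALSE]
  link <- (A > attractor_tol) | (t(A) > attractor_tol)
  ga <- igraph::graph_from_adjacency_matrix(link, mode = "undirected",
                                            diag = FALSE)
  sys_of_attractor <- igraph::components(ga)$membership
  n_sys <- max(sys_of_attractor)
  members <- vector("list", n_sys)
  for (s in seq_len(n_sys)) {
    members[[s]] <- ids[attractors[sys_of_attractor == s]]
  }
  assigned <- integer(n)
  assigned[attractors] <- sys_of_attractor
  for (j in setdiff(seq_len(n), attractors)) {
    flows <- which(M[attractors, j] > attractor_tol)
    if (length(flows) == 0L) {
      # no attractor mass: isolated transient, becomes a singleton
      members <- c(members, list(ids[j]))
      assigned[j] <- length(members)
    } else {
      sys <- unique(sys_of_attractor[flows])
      if (length(sys) > 1L) {
        smallest <- vapply(members[sys], min, character(1))
        sys <- sys[order(smallest)][1L]
      }
      members[[sys]] <- c(members[[sys]], ids[j])
      assigned[j] <- sys
    }
  }
  members
}

#' Markov clustering of a homology graph
#'
#' Runs the native MCL engine on the selected metric's weights. Each
#' connected component is clustered independently (MCL can subdivide
#' components but never merges them), so every output cluster is contained
#' within one component. Deterministic for fixed input and parameters.
#'
#' @param graph A `homology_graph` (or a single-metric graph from
#'   [read_abc()], with `metric = "weight"`).
#' @param metric Edge-weight column to cluster on.
#' @param params An [mcl_params()].
#' @return A [clustering()] with provenance
#'   `mcl(metric, normalization, inflation)`.
#' @export
mcl_cluster <- function(graph, metric = "bs", params = mcl_params()) {
  if (nrow(graph$nodes) == 0L) stopf("empty graph")
  blocks <- component_blocks(graph, metric)
  clusters <- unlist(lapply(blocks, function(b) mcl_engine(b$adj, b$ids, params)),
                     recursive = FALSE)
  clustering(clusters,
             provenance = list(method = "mcl", metric = metric,
                               normalization = graph$normalization,
                               inflation = params$inflation))
}

# Decompose the graph into per-component dense adjacency blocks once, so an
# inflation sweep does not repeat the component search.
component_blocks <- function(graph, metric) {
  stopifnot(metric %in% names(graph$edges))
  w <- graph$edges[[metric]]
  if (any(w <= 0)) stopf("all '%s' weights must be positive", metric)
  comp <- igraph::components(as_igraph(graph))
  memb <- comp$membership
  edge_comp <- memb[graph$edges$id1]
  lapply(seq_len(comp$no), function(k) {
    ids <- sort(names(memb)[memb == k])
    n <- length(ids)
    adj <- matrix(0, n, n, dimnames = list(ids, ids))
    sel <- which(edge_comp == k)
    if (length(sel)) {
      i <- match(graph$edges$id1[sel], ids)
      j <- match(graph$edges$id2[sel], ids)
      adj[cbind(i, j)] <- w[sel]
      adj[cbind(j, i)] <- w[sel]
    }
    list(ids = ids, adj = adj)
  })
}

#' Inflation grid
#'
#' Inclusive arithmetic grid of inflation values; the default 1.1 to 6.0 in
#' steps of 0.1 yields exactly 50 values.
#'
#' @param start,stop,step Grid limits (inclusive) and spacing.
#' @return Numeric vector of inflation values.
#' @export
inflation_grid <- function(start = 1.1, stop = 6.0, step = 0.1) {
  stopifnot(step > 0, start <= stop, start > 1)
  n <- floor((stop - start) / step + 1e-9) + 1L
  round(start + step * (seq_len(n) - 1L), 10)
}

#' Cluster a graph across an inflation sweep
#'
#' One MCL clustering per inflation value. The component decomposition is
#' computed once and shared across the sweep.
#'
#' @inheritParams mcl_cluster
#' @param inflations Numeric vector of inflation values, default
#'   [inflation_grid()].
#' @param base_params [mcl_params()] supplying the non-inflation settings.
#' @return Named list of [clustering()] objects, names formatted from the
#'   inflation values.
#' @export
inflation_sweep <- function(graph, metric = "bs",
                            inflations = inflation_grid(),
                            base_params = mcl_params()) {
  blocks <- component_blocks(graph, metric)
  res <- lapply(inflations, function(I) {
    p <- base_params
    p$inflation <- I
    clusters <- unlist(lapply(blocks, function(b) mcl_engine(b$adj, b$ids, p)),
                       recursive = FALSE)
    clustering(clusters,
               provenance = list(method = "mcl", metric = metric,
                                 normalization = graph$normalization,
                                 inflation = I))
  })
  names(res) <- sprintf("%.2f", inflations)
  res
}

#' Write clusters in the MCL program's native output dialect
#'
#' One cluster per line, tab-separated member ids.
#'
#' @param clust A [clustering()].
#' @param file Output path.
#' @return Invisibly, the path.
#' @export
write_clusters <- function(clust, file) {
  writeLines(vapply(clust$clusters, paste, character(1), collapse = "\t"), file)
  invisible(file)
}

#' Long-format cluster table
#'
#' @param clust A [clustering()].
#' @return data.frame with `cluster_id`, `sequence_id`, `inflation`,
#'   `metric`, `normalization` (NA where not applicable).
#' @export
clusters_long <- function(clust) {
  prov <- clust$provenance
  data.frame(
    cluster_id = rep.int(seq_along(clust$clusters), lengths(clust$clusters)),
    sequence_id = unlist(clust$clusters, use.names = FALSE),
    inflation = prov$inflation %||% NA_real_,
    metric = prov$metric %||% NA_character_,
    normalization = prov$normalization %||% prov$method %||% NA_character_,
    stringsAsFactors = FALSE
  )
}
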