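# Independent oracles, deliberately implemented with different algorithms
# from the package code paths they check.

# Connected components by boolean transitive closure (Warshall), not by
# graph search.
oracle_components <- function(graph) {
  ids <- graph$nodes$id
  n <- length(ids)
  R <- diag(TRUE, n)
  rownames(R) <- colnames(R) <- ids
  for (k in seq_len(nrow(graph$edges))) {
    R[graph$edges$id1[k], graph$edges$id2[k]] <- TRUE
    R[graph$edges$id2[k], graph$edges$id1[k]] <- TRUE
  }
  for (k in seq_len(n)) {
    R <- R | (R[, k] %o% R[k, ])
  }
  seen <- rep(FALSE, n)
  comps <- list()
  for (i in seq_len(n)) {
    if (seen[i]) next
    members <- which(R[i, ])
    seen[members] <- TRUE
    comps[[length(comps) + 1L]] <- sort(ids[members])
  }
  comps[order(vapply(comps, `[`, character(1), 1L))]
}

# Naive dense MCL reference: expansion/inflation recurrence with no pruning,
# run to a tight fixed point; clusters read as the connected components of
# the limit matrix's nonzero structure (symmetrized). Independent of the
# package engine's attractor-system interpretation.
oracle_mcl <- function(graph, metric, inflation, max_iter = 500,
                       self_loop = c("max_incident", "unit")) {
  self_loop <- match.arg(self_loop)
  ids <- sort(graph$nodes$id)
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (k in seq_len(nrow(graph$edges))) {
    A[graph$edges$id1[k], graph$edges$id2[k]] <- graph$edges[[metric]][k]
    A[graph$edges$id2[k], graph$edges$id1[k]] <- graph$edges[[metric]][k]
  }
  for (j in seq_len(n)) {
    mx <- max(A[, j])
    A[j, j] <- if (self_loop == "unit") 1 else if (mx > 0) mx else 1
  }
  M <- A %*% diag(1 / colSums(A), n)
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2 <- M2 %*% diag(1 / colSums(M2), n)
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < 1e-12) break
  }
  nz <- (M > 1e-6) | (t(M) > 1e-6)
  diag(nz) <- TRUE
  # components of the nonzero structure, by closure
  g <- list(nodes = data.frame(id = ids, stringsAsFactors = FALSE),
            edges = data.frame(id1 = ids[row(nz)[nz & upper.tri(nz)]],
                               id2 = ids[col(nz)[nz & upper.tri(nz)]],
                               stringsAsFactors = FALSE))
  oracle_components(g)
}

# Canonical form of a partition for comparison.
canon <- function(clusters) {
  cl <- lapply(clusters, sort)
  cl[order(vapply(cl, `[`, character(1), 1L))]
}
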