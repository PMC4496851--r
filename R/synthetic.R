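# Seeded synthetic sequence databases and best-hit tables with the
# statistical structure the pipeline assumes: self bit scores tracking
# twice the sequence length, strong full-length intra-group hits, weak
# spurious inter-group hits, and optional shared-domain hits between long
# unrelated sequences. All E-values derive exactly from E = mN / 2^BS.

#' Synthetic benchmark configuration
#'
#' @param num_groups Number of reference homology groups.
#' @param organisms Organism names (each group samples members across them).
#' @param membership_prob Probability that an organism contributes a member
#'   to a group.
#' @param inparalog_prob Probability that a contributing organism adds a
#'   second (inparalogous) member.
#' @param length_range Range (residues) of per-group base sequence lengths.
#' @param within_group_length_cv Relative spread of member lengths around
#'   the group base length; raise it to create the length heterogeneity
#'   that produces bridge hits between fragments.
#' @param intra_identity_range Range of the per-pair identity factor
#'   multiplying the ideal full-length score (2 bits per aligned residue).
#' @param spurious_rate Probability of a weak spurious hit per inter-group
#'   sequence pair.
#' @param spurious_bits_range Bit-score range of spurious hits.
#' @param domain_rate Probability per inter-group pair of long sequences of
#'   a short, high-scoring shared-domain hit.
#' @param domain_length_range Length range (residues) of shared domains.
#' @param sbs_noise Half-width of the uniform relative noise on self bit
#'   scores around `2 * length` (default 0.025, i.e. a tight +/- 2.5%).
#' @param evalue_cutoff Hits with recomputed E-values above this are
#'   omitted, like BLAST's `-evalue` filter.
#' @param seed Integer seed; fixed seed implies fully reproducible output.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(num_groups = 25,
                             organisms = c("orgA", "orgB", "orgC", "orgD"),
                             membership_prob = 0.9,
                             inparalog_prob = 0.1,
                             length_range = c(150, 600),
                             within_group_length_cv = 0.1,
                             intra_identity_range = c(0.55, 0.9),
                             spurious_rate = 0.01,
                             spurious_bits_range = c(40, 60),
                             domain_rate = 0.01,
                             domain_length_range = c(40, 80),
                             sbs_noise = 0.025,
                             evalue_cutoff = 1e-5,
                             seed = 1L) {
  if (any(c(membership_prob, inparalog_prob, spurious_rate, domain_rate) < 0 |
            c(membership_prob, inparalog_prob, spurious_rate, domain_rate) > 1)) {
    stopf("probabilities must lie in [0, 1]")
  }
  if (num_groups < 1 || length(organisms) < 2) {
    stopf("need at least 1 group and 2 organisms")
  }
  if (any(length_range < 1) || diff(length_range) < 0) stopf("bad length range")
  structure(list(num_groups = num_groups, organisms = organisms,
                 membership_prob = membership_prob,
                 inparalog_prob = inparalog_prob,
                 length_range = length_range,
                 within_group_length_cv = within_group_length_cv,
                 intra_identity_range = intra_identity_range,
                 spurious_rate = spurious_rate,
                 spurious_bits_range = spurious_bits_range,
                 domain_rate = domain_rate,
                 domain_length_range = domain_length_range,
                 sbs_noise = sbs_noise, evalue_cutoff = evalue_cutoff,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic reference database
#'
#' Draws a sequence database whose records carry organism and reference
#' group labels (id dialect `organism|group|serial`). Each group is
#' resampled until it has at least two members spanning at least two
#' organisms. Residue content is an arbitrary uniform draw over the amino
#' acid alphabet; scores are assigned downstream, never recomputed from the
#' letters.
#'
#' @param config A [synthetic_config()].
#' @return List with `db` (data.frame: id, organism, group, length, seq)
#'   and `reference` — both a named vector id -> group and a [clustering()]
#'   (`$reference_clustering`).
#' @export
generate_reference_db <- function(config) {
  with_seed(config$seed, {
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
    serial <- setNames(rep(0L, length(config$organisms)), config$organisms)
    rows <- list()
    for (g in seq_len(config$num_groups)) {
      gname <- sprintf("grp%03d", g)
      base_len <- round(runif(1, config$length_range[1], config$length_range[2]))
      repeat {
        member_orgs <- config$organisms[runif(length(config$organisms)) <
                                          config$membership_prob]
        extra <- member_orgs[runif(length(member_orgs)) < config$inparalog_prob]
        member_orgs <- sort(c(member_orgs, extra))
        if (length(member_orgs) >= 2L && length(unique(member_orgs)) >= 2L) break
      }
      for (org in member_orgs) {
        serial[org] <- serial[org] + 1L
        L <- max(30L, round(base_len *
                              (1 + config$within_group_length_cv * rnorm(1))))
        rows[[length(rows) + 1L]] <- data.frame(
          id = sprintf("%s|%s|%04d", org, gname, serial[org]),
          organism = org, group = gname, length = L,
          seq = paste(sample_from(aa, L, replace = TRUE), collapse = ""),
          stringsAsFactors = FALSE
        )
      }
    }
    db <- do.call(rbind, rows)
    reference <- setNames(db$group, db$id)
    list(db = db, reference = reference,
         reference_clustering = clustering(
           unname(split(db$id, db$group)),
           provenance = list(method = "reference")
         ))
  })
}

#' Generate a synthetic best-hit table
#'
#' Emits one self hit per sequence with SBS tracking twice the length
#' (small uniform noise), one full-length hit per intra-group pair with
#' bit score about `2 * min(length) * identity`, spurious weak hits
#' between groups at the configured rate, and short high-scoring
#' shared-domain hits between long inter-group pairs. Every E-value is
#' computed exactly from \eqn{E = mN/2^{BS}}; hits whose E-value exceeds
#' the cutoff are omitted (self hits always survive).
#'
#' @param db,reference From [generate_reference_db()].
#' @param config A [synthetic_config()].
#' @return List with `hits` (14-column hit data.frame, one row per pair,
#'   self hits included), `self_scores`, `stats`.
#' @export
generate_hit_table <- function(db, reference, config) {
  stats <- database_stats(db)
  N <- stats$total_residues
  with_seed(config$seed + 1L, {
    len <- setNames(db$length, db$id)
    rows <- list()
    add <- function(q, s, bits, alen, qs, qe, ss, se, pident) {
      ev <- eq1_evalue(bits, len[[q]], N)
      if (q != s && ev > config$evalue_cutoff) return(invisible())
      rows[[length(rows) + 1L]] <<- data.frame(
        qseqid = q, sseqid = s, pident = pident, length = alen,
        mismatch = as.integer(round(alen * (1 - pident / 100))), gapopen = 0L,
        qstart = qs, qend = qe, sstart = ss, send = se,
        evalue = ev, bitscore = bits, qlen = len[[q]], slen = len[[s]],
        stringsAsFactors = FALSE
      )
      invisible()
    }

    # self hits: SBS = 2L(1 + eps)
    for (id in db$id) {
      L <- len[[id]]
      bits <- 2 * L * (1 + runif(1, -config$sbs_noise, config$sbs_noise))
      add(id, id, bits, L, 1L, L, 1L, L, 100)
    }

    # intra-group full-length hits
    for (g in unique(db$group)) {
      members <- db$id[db$group == g]
      if (length(members) < 2L) next
      prs <- utils::combn(members, 2L)
      for (k in seq_len(ncol(prs))) {
        q <- prs[1L, k]; s <- prs[2L, k]
        alen <- min(len[[q]], len[[s]])
        f <- runif(1, config$intra_identity_range[1], config$intra_identity_range[2])
        bits <- 2 * alen * f
        add(q, s, bits, alen, 1L, alen, 1L, alen, round(100 * f, 2))
      }
    }

    # spurious + shared-domain inter-group hits
    ids <- db$id
    grp <- setNames(db$group, db$id)
    n <- length(ids)
    long_cut <- stats::quantile(db$length, 0.5)
    for (i in seq_len(n - 1L)) {
      # vectorized over j for speed
      j <- (i + 1L):n
      j <- j[grp[ids[j]] != grp[ids[i]]]
      if (!length(j)) next
      u <- runif(length(j))
      spur <- j[u < config$spurious_rate]
      v <- runif(length(j))
      dom <- j[v < config$domain_rate & len[ids[j]] >= long_cut &
                 len[[ids[i]]] >= long_cut]
      for (jj in spur) {
        q <- ids[i]; s <- ids[jj]
        alen <- round(runif(1, 20, min(60, len[[q]], len[[s]])))
        bits <- runif(1, config$spurious_bits_range[1], config$spurious_bits_range[2])
        qs <- sample_from(seq_len(len[[q]] - alen + 1L), 1L)
        ss <- sample_from(seq_len(len[[s]] - alen + 1L), 1L)
        add(q, s, bits, alen, qs, qs + alen - 1L, ss, ss + alen - 1L,
            round(runif(1, 20, 35), 2))
      }
      for (jj in setdiff(dom, spur)) {
        q <- ids[i]; s <- ids[jj]
        dmax <- min(config$domain_length_range[2], len[[q]], len[[s]])
        if (dmax <= config$domain_length_range[1]) next
        dlen <- round(runif(1, config$domain_length_range[1], dmax))
        bits <- 2 * dlen * runif(1, 0.75, 0.95)
        qs <- sample_from(seq_len(len[[q]] - dlen + 1L), 1L)
        ss <- sample_from(seq_len(len[[s]] - dlen + 1L), 1L)
        add(q, s, bits, dlen, qs, qs + dlen - 1L, ss, ss + dlen - 1L,
            round(runif(1, 40, 60), 2))
      }
    }

    hits <- do.call(rbind, rows)
    rownames(hits) <- NULL
    list(hits = hits, self_scores = extract_self_scores(hits), stats = stats)
  })
}

#' One-call synthetic benchmark
#'
#' Generates the database, reference, and best-hit table, and assembles the
#' raw homology graph.
#'
#' @param config A [synthetic_config()].
#' @return List with `db`, `reference`, `reference_clustering`, `hits`,
#'   `best`, `self_scores`, `stats`, `graph`.
#' @export
generate_benchmark <- function(config = synthetic_config()) {
  ref <- generate_reference_db(config)
  tab <- generate_hit_table(ref$db, ref$reference, config)
  best <- best_hits(tab$hits)
  graph <- build_graph(best, tab$self_scores, tab$stats,
                       node_info = ref$db,
                       config = metric_config(evalue_cutoff = config$evalue_cutoff))
  c(ref, tab, list(best = best, graph = graph))
}

#' Even-halves bridge scenario
#'
#' A deterministic benchmark reproducing the aligned-breakpoint regime:
#' every sequence is split into even halves, so the breakpoints of
#' equal-length homologs line up and their fragments share no alignable
#' overlap, partitioning each group into two subclusters. Length variation
#' within each group (pairs of `base_length` and `base_length +
#' length_offset` sequences) shifts the longer sequences' midpoints,
#' creating short opposing-end "bridge" alignments between fragments of
#' different rank. These bridges carry small bit scores but align
#' end-to-end within their anchored region, which is exactly the case the
#' bit-score-over-anchored-length metric is designed to rescue.
#'
#' Scores are exact (self bit score `2 * length`, intra-group hits at
#' `2 * alignment length * identity`); there are no spurious hits, so the
#' scenario isolates the bridge effect.
#'
#' @param num_groups Number of groups (each with 2 short + 2 long members).
#' @param organisms Organism labels, cycled over members.
#' @param base_length Length of the short sequences (residues).
#' @param length_offset Extra length of the long sequences; half of it is
#'   the bridge overlap after even halving.
#' @param identity Identity factor of intra-group hits.
#' @return List as [generate_benchmark()] plus `fragments` (the even-halves
#'   fragment records), `frag_graph` (the fragment-level graph) and
#'   `frag_reference`.
#' @export
generate_bridge_scenario <- function(num_groups = 6,
                                     organisms = c("orgA", "orgB", "orgC", "orgD"),
                                     base_length = 400L,
                                     length_offset = 60L,
                                     identity = 0.8) {
  rows <- list()
  for (g in seq_len(num_groups)) {
    gname <- sprintf("grp%03d", g)
    lens <- c(base_length, base_length,
              base_length + length_offset, base_length + length_offset)
    for (k in seq_along(lens)) {
      org <- organisms[(k - 1L) %% length(organisms) + 1L]
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("%s|%s|%02d%02d", org, gname, g, k),
        organism = org, group = gname, length = lens[k],
        seq = strrep("A", lens[k]), stringsAsFactors = FALSE
      )
    }
  }
  db <- do.call(rbind, rows)
  reference <- setNames(db$group, db$id)
  stats <- database_stats(db)

  len <- setNames(db$length, db$id)
  hit_rows <- list()
  add <- function(q, s, bits, alen) {
    hit_rows[[length(hit_rows) + 1L]] <<- data.frame(
      qseqid = q, sseqid = s, pident = 100 * identity, length = alen,
      mismatch = as.integer(round(alen * (1 - identity))), gapopen = 0L,
      qstart = 1L, qend = alen, sstart = 1L, send = alen,
      evalue = eq1_evalue(bits, len[[q]], stats$total_residues),
      bitscore = bits, qlen = len[[q]], slen = len[[s]],
      stringsAsFactors = FALSE
    )
  }
  for (id in db$id) add(id, id, 2 * len[[id]], len[[id]])
  for (g in unique(db$group)) {
    members <- db$id[db$group == g]
    prs <- utils::combn(members, 2L)
    for (k in seq_len(ncol(prs))) {
      q <- prs[1L, k]; s <- prs[2L, k]
      alen <- min(len[[q]], len[[s]])
      add(q, s, 2 * alen * identity, alen)
    }
  }
  hits <- do.call(rbind, hit_rows)
  self_scores <- extract_self_scores(hits)
  best <- best_hits(hits)

  scheme <- fragmentation_scheme(strrep("2", length(organisms)),
                                 breakpoint_mode = "even")
  fr <- fragment_database(db, scheme)
  frag_hits <- project_hits(best, self_scores, fr$fragments, stats)
  frag_best <- best_hits(frag_hits)
  frag_graph <- build_graph(frag_best, extract_self_scores(frag_hits), stats,
                            node_info = fr$db)
  list(db = db, reference = reference, hits = hits, best = best,
       self_scores = self_scores, stats = stats,
       graph = build_graph(best, self_scores, stats, node_info = db),
       fragments = fr$fragments, frag_graph = frag_graph,
       frag_reference = fragment_reference(reference, fr$fragments))
}
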