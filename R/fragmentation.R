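# Simulated sequence fragmentation: integer-coded schemes, label
# assignment (ordered/shuffled), splitting (even/random breakpoints), and
# BLAST-free projection of parent-level hits onto fragments.

#' Fragmentation scheme
#'
#' A scheme is an integer code whose digits, mapped to organisms in
#' alphabetical order, give the number of pieces each organism's sequences
#' are split into. `label_mode` controls whether the labels follow
#' organismal lines (`"ordered"`) or are shuffled within each reference
#' group (`"shuffled"`); `breakpoint_mode` chooses evenly spaced or
#' randomly placed breakpoints.
#'
#' @param code Digit string, e.g. `"1323"`; every digit >= 1.
#' @param label_mode `"ordered"` or `"shuffled"`.
#' @param breakpoint_mode `"even"` or `"random"`.
#' @param seed Integer seed governing shuffling and random breakpoints.
#' @return List of class `fragmentation_scheme`.
#' @export
fragmentation_scheme <- function(code, label_mode = c("ordered", "shuffled"),
                                 breakpoint_mode = c("even", "random"),
                                 seed = 1L) {
  code <- as.character(code)
  if (!nzchar(code) || !grepl("^[0-9]+$", code)) {
    stopf("scheme code must be a non-empty digit string (got '%s')", code)
  }
  if (grepl("0", code, fixed = TRUE)) stopf("scheme digit 0 is not allowed")
  structure(list(code = code, label_mode = match.arg(label_mode),
                 breakpoint_mode = match.arg(breakpoint_mode),
                 seed = as.integer(seed)),
            class = "fragmentation_scheme")
}

#' Expand a scheme code over the organisms of a database
#'
#' Digit j of the code applies to the j-th organism in alphabetical order.
#' A code shorter than the organism list is repeated until it reaches or
#' exceeds the required length, then truncated.
#'
#' @param code Digit string (or a [fragmentation_scheme()]).
#' @param organisms Character vector of organism names (sorted internally).
#' @return Named integer vector organism -> number of pieces.
#' @examples
#' expand_scheme("1323", c("orgA", "orgB", "orgC", "orgD"))
#' expand_scheme("12", paste0("org", 1:5))  # effective code 12121
#' @export
expand_scheme <- function(code, organisms) {
  if (inherits(code, "fragmentation_scheme")) code <- code$code
  if (grepl("0", code, fixed = TRUE)) stopf("scheme digit 0 is not allowed")
  if (length(organisms) == 0L) stopf("no organisms")
  organisms <- sort(organisms)
  digits <- as.integer(strsplit(code, "")[[1L]])
  n <- length(organisms)
  digits <- rep(digits, length.out = max(n, length(digits)))[seq_len(n)]
  setNames(digits, organisms)
}

#' Assign piece-count labels to every sequence
#'
#' In ordered mode each sequence inherits its organism's digit. In shuffled
#' mode the labels are first mapped along organismal lines within each
#' reference group, then permuted within that group by the scheme's seeded
#' generator, preserving the per-group label multiset.
#'
#' @param db Sequence database data.frame (`id`, `organism`, `group`, ...).
#' @param scheme A [fragmentation_scheme()].
#' @return Named integer vector sequence id -> pieces.
#' @export
assign_labels <- function(db, scheme) {
  pieces <- expand_scheme(scheme$code, unique(db$organism))
  labels <- setNames(unname(pieces[db$organism]), db$id)
  if (scheme$label_mode == "shuffled") {
    labels <- with_seed(scheme$seed, {
      for (g in unique(db$group)) {
        idx <- which(db$group == g)
        labels[idx] <- labels[idx][sample.int(length(idx))]
      }
      labels
    })
  }
  labels
}

#' Split sequences according to their labels
#'
#' A sequence labelled `k` is split into `k` contiguous pieces that tile it
#' exactly. Even mode makes piece lengths differ by at most one, with the
#' remainder going to the leftmost pieces; random mode draws breakpoints
#' uniformly from interior positions subject to a minimum fragment length.
#' Label 1 passes the sequence through intact under its original id.
#'
#' Fragment ids follow the dialect `<parent>_f<i>of<k>`; a sidecar table of
#' `FragmentRecord`s (fragment_id, parent_id, piece_index, piece_count,
#' start, end, organism, group) is always returned so downstream mapping
#' never relies on id parsing.
#'
#' @param db Sequence database data.frame.
#' @param labels Named vector from [assign_labels()].
#' @param breakpoint_mode `"even"` or `"random"`.
#' @param seed Seed for random breakpoints.
#' @param min_fragment_length Minimum piece length in random mode
#'   (default 10 residues; even mode uses 1).
#' @return List with `db` (the fragmented sequence database) and
#'   `fragments` (the FragmentRecord data.frame, one row per piece
#'   including intact label-1 sequences).
#' @export
fragment_sequences <- function(db, labels, breakpoint_mode = c("even", "random"),
                               seed = 1L, min_fragment_length = NULL) {
  breakpoint_mode <- match.arg(breakpoint_mode)
  if (is.null(min_fragment_length)) {
    min_fragment_length <- if (breakpoint_mode == "random") 10L else 1L
  }
  k <- unname(labels[db$id])
  if (anyNA(k)) stopf("sequence '%s' has no label", db$id[which(is.na(k))[1L]])
  infeasible <- which(k > floor(db$length / min_fragment_length))
  if (length(infeasible)) {
    i <- infeasible[1L]
    stopf("sequence '%s' (length %d) cannot be split into %d pieces of >= %d residues",
          db$id[i], db$length[i], k[i], min_fragment_length)
  }

  with_seed(seed, {
    rows <- vector("list", nrow(db))
    for (i in seq_len(nrow(db))) {
      L <- db$length[i]
      ki <- k[i]
      lens <- if (ki == 1L) {
        L
      } else if (breakpoint_mode == "even") {
        base <- L %/% ki
        rem <- L - base * ki
        base + as.integer(seq_len(ki) <= rem)
      } else {
        random_piece_lengths(L, ki, min_fragment_length)
      }
      ends <- cumsum(lens)
      starts <- c(1L, head(ends, -1L) + 1L)
      frag_id <- if (ki == 1L) db$id[i] else
        sprintf("%s_f%dof%d", db$id[i], seq_len(ki), ki)
      rows[[i]] <- data.frame(
        fragment_id = frag_id, parent_id = db$id[i],
        piece_index = seq_len(ki), piece_count = ki,
        start = as.integer(starts), end = as.integer(ends),
        organism = db$organism[i], group = db$group[i],
        stringsAsFactors = FALSE
      )
    }
    fragments <- do.call(rbind, rows)
    frag_db <- data.frame(
      id = fragments$fragment_id,
      organism = fragments$organism,
      group = fragments$group,
      length = fragments$end - fragments$start + 1L,
      stringsAsFactors = FALSE
    )
    if (!is.null(db$seq)) {
      parent_seq <- setNames(db$seq, db$id)
      frag_db$seq <- substr(parent_seq[fragments$parent_id],
                            fragments$start, fragments$end)
    }
    list(db = frag_db, fragments = fragments)
  })
}

# Draw k-1 breakpoints uniformly from interior positions such that every
# piece is at least min_len residues; rejection sampling (the precondition
# guarantees feasibility).
random_piece_lengths <- function(L, k, min_len) {
  lo <- min_len
  hi <- L - min_len
  for (attempt in seq_len(10000L)) {
    cuts <- sort(sample_from(lo:hi, k - 1L))
    lens <- diff(c(0L, cuts, L))
    if (all(lens >= min_len)) return(as.integer(lens))
  }
  stopf("could not place %d breakpoints in a length-%d sequence with min fragment %d",
        k - 1L, L, min_len)
}

#' Fragment a database under a scheme
#'
#' Convenience wrapper: [assign_labels()] then [fragment_sequences()] using
#' the scheme's breakpoint mode and seed.
#'
#' @param db Sequence database data.frame.
#' @param scheme A [fragmentation_scheme()].
#' @param min_fragment_length See [fragment_sequences()].
#' @return As [fragment_sequences()].
#' @export
fragment_database <- function(db, scheme, min_fragment_length = NULL) {
  labels <- assign_labels(db, scheme)
  fragment_sequences(db, labels, scheme$breakpoint_mode, seed = scheme$seed,
                     min_fragment_length = min_fragment_length)
}

#' Write / read the sidecar fragment map
#' @param fragments FragmentRecord data.frame.
#' @param file Path to TSV.
#' @return `write_fragment_map` invisibly returns the path;
#'   `read_fragment_map` returns the data.frame.
#' @export
write_fragment_map <- function(fragments, file) {
  write.table(fragments, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_fragment_map
#' @export
read_fragment_map <- function(file) {
  read.table(file, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Project parent-level best hits onto fragments
#'
#' A BLAST-free surrogate for re-aligning a fragmented database: each
#' parent best hit is intersected with every pair of fragments of its two
#' parents (alignment columns are assumed collinear with both sequences,
#' i.e. gaps are ignored for coordinate mapping). Overlaps of at least one
#' column become fragment hits with coordinates re-based to the fragments,
#' the bit score scaled by the overlapping fraction of the parent
#' alignment, and the E-value recomputed from \eqn{E = mN/2^{BS}} with the
#' fragment's length as `m`. Hits whose recomputed E-value exceeds `cutoff`
#' are dropped. Fragment self hits are emitted with SBS equal to the parent
#' SBS scaled by the fragment's length fraction.
#'
#' This is a linear-score surrogate (about two bits per aligned residue),
#' not a BLAST emulator: it reproduces the geometry of fragment overlaps,
#' not BLAST's seeding and extension heuristics.
#'
#' @param parent_best Best-hit data.frame of the intact parents.
#' @param parent_self Named SBS vector of the parents.
#' @param fragments FragmentRecord data.frame from [fragment_sequences()].
#' @param stats Database statistics ([database_stats()]); the fragmented
#'   database has the same total residue count as its parent.
#' @param cutoff E-value cutoff applied to recomputed E-values.
#' @param recompute_evalue If `FALSE`, projected hits keep the parent
#'   E-value (pass-through mode; with all sequences intact the output then
#'   equals the input).
#' @return Hit data.frame at fragment level, including fragment self hits.
#' @export
project_hits <- function(parent_best, parent_self, fragments, stats,
                         cutoff = 1e-5, recompute_evalue = TRUE) {
  frag_by_parent <- split(fragments, fragments$parent_id)
  plen <- tapply(fragments$end, fragments$parent_id, max)

  out <- list()
  emit <- function(row) out[[length(out) + 1L]] <<- row

  # fragment self hits
  flen <- fragments$end - fragments$start + 1L
  sbs_parent <- unname(parent_self[fragments$parent_id])
  miss <- is.na(sbs_parent)
  sbs_parent[miss] <- 2 * as.numeric(plen[fragments$parent_id[miss]])
  self_bits <- sbs_parent * flen / as.numeric(plen[fragments$parent_id])
  self_ev <- eq1_evalue(self_bits, flen, stats$total_residues)
  emit(data.frame(
    qseqid = fragments$fragment_id, sseqid = fragments$fragment_id,
    pident = 100, length = flen, mismatch = 0L, gapopen = 0L,
    qstart = 1L, qend = flen, sstart = 1L, send = flen,
    evalue = self_ev, bitscore = self_bits, qlen = flen, slen = flen,
    stringsAsFactors = FALSE
  ))

  for (h in seq_len(nrow(parent_best))) {
    hit <- parent_best[h, ]
    fq <- frag_by_parent[[hit$qseqid]]
    fs <- frag_by_parent[[hit$sseqid]]
    if (is.null(fq) || is.null(fs)) {
      stopf("no fragment records for parent '%s'",
            if (is.null(fq)) hit$qseqid else hit$sseqid)
    }
    if (nrow(fq) == 1L && nrow(fs) == 1L) {
      # both parents intact: the hit carries over unchanged (gapped
      # alignments included), modulo the E-value policy
      hit$evalue <- if (recompute_evalue) {
        eq1_evalue(hit$bitscore, hit$qlen, stats$total_residues)
      } else {
        hit$evalue
      }
      if (hit$evalue <= cutoff) emit(hit)
      next
    }
    for (a in seq_len(nrow(fq))) {
      # columns of the parent alignment covered by this query fragment
      qa <- max(hit$qstart, fq$start[a]) - hit$qstart + 1
      qb <- min(hit$qend, fq$end[a]) - hit$qstart + 1
      if (qa > qb) next
      for (b in seq_len(nrow(fs))) {
        sa <- max(hit$sstart, fs$start[b]) - hit$sstart + 1
        sb <- min(hit$send, fs$end[b]) - hit$sstart + 1
        if (sa > sb) next
        o1 <- max(qa, sa)
        o2 <- min(qb, sb)
        ocols <- o2 - o1 + 1
        if (ocols < 1) next
        frac <- ocols / hit$length
        bits <- hit$bitscore * frac
        fqlen <- fq$end[a] - fq$start[a] + 1L
        fslen <- fs$end[b] - fs$start[b] + 1L
        ev <- if (recompute_evalue) {
          eq1_evalue(bits, fqlen, stats$total_residues)
        } else {
          hit$evalue
        }
        if (ev > cutoff) next
        emit(data.frame(
          qseqid = fq$fragment_id[a], sseqid = fs$fragment_id[b],
          pident = hit$pident, length = ocols,
          mismatch = as.integer(round(hit$mismatch * frac)),
          gapopen = as.integer(round(hit$gapopen * frac)),
          qstart = as.integer(hit$qstart + o1 - 1 - (fq$start[a] - 1L)),
          qend = as.integer(hit$qstart + o2 - 1 - (fq$start[a] - 1L)),
          sstart = as.integer(hit$sstart + o1 - 1 - (fs$start[b] - 1L)),
          send = as.integer(hit$sstart + o2 - 1 - (fs$start[b] - 1L)),
          evalue = ev, bitscore = bits, qlen = fqlen, slen = fslen,
          stringsAsFactors = FALSE
        ))
      }
    }
  }
  hits <- do.call(rbind, out)
  rownames(hits) <- NULL
  hits
}

# E-value from the bit-score identity E = m N / 2^BS, computed in log space
# to avoid overflow; underflow below the double range yields 0, mirroring
# BLAST's rounding of tiny E-values.
eq1_evalue <- function(bits, m, N) {
  10^(log10(m) + log10(N) - bits * log10(2))
}
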