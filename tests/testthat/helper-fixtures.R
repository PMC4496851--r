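# Shared fixtures built in code.

# One hit row with sensible defaults; override any field.
make_hit <- function(qseqid = "q1", sseqid = "s1", pident = 90, length = 100,
                     mismatch = 10, gapopen = 0, qstart = 1, qend = 100,
                     sstart = 1, send = 100, evalue = 1e-50, bitscore = 200,
                     qlen = 100, slen = 100) {
  data.frame(qseqid = qseqid, sseqid = sseqid, pident = pident,
             length = length, mismatch = mismatch, gapopen = gapopen,
             qstart = qstart, qend = qend, sstart = sstart, send = send,
             evalue = evalue, bitscore = bitscore, qlen = qlen, slen = slen,
             stringsAsFactors = FALSE)
}

# The three canonical alignment scenarios with proportional bit scores
# (about two bits per aligned residue): (a) full-length vs full-length,
# (b) full-length vs a fragment that is its subsequence, (c) two fragments
# overlapping on opposing ends. Self scores included.
three_scenario_fixture <- function() {
  hits <- rbind(
    # (a) two 300-residue sequences, end-to-end
    make_hit("fullA", "fullB", length = 300, qend = 300, send = 300,
             bitscore = 600, evalue = 1e-170, qlen = 300, slen = 300),
    # (b) 150-residue fragment inside a 300-residue full-length sequence
    make_hit("fragC", "fullA", length = 150, qend = 150,
             sstart = 76, send = 225, bitscore = 300, evalue = 1e-80,
             qlen = 150, slen = 300),
    # (c) two 150-residue fragments overlapping over 75 opposing-end columns
    make_hit("fragC", "fragD", length = 75, qstart = 76, qend = 150,
             sstart = 1, send = 75, bitscore = 150, evalue = 1e-35,
             qlen = 150, slen = 150)
  )
  selfs <- rbind(
    make_hit("fullA", "fullA", length = 300, qend = 300, send = 300,
             bitscore = 600, evalue = 0, qlen = 300, slen = 300),
    make_hit("fullB", "fullB", length = 300, qend = 300, send = 300,
             bitscore = 600, evalue = 0, qlen = 300, slen = 300),
    make_hit("fragC", "fragC", length = 150, qend = 150, send = 150,
             bitscore = 300, evalue = 1e-80, qlen = 150, slen = 150),
    make_hit("fragD", "fragD", length = 150, qend = 150, send = 150,
             bitscore = 300, evalue = 1e-80, qlen = 150, slen = 150)
  )
  list(hits = hits, selfs = selfs,
       self_scores = extract_self_scores(rbind(hits, selfs)),
       stats = list(total_residues = 900, num_sequences = 4))
}

# A small labelled database without sequences (lengths only).
toy_db <- function(lengths = c(100, 200, 300),
                   organisms = c("orgA", "orgB", "orgA"),
                   groups = c("g1", "g1", "g2")) {
  n <- length(lengths)
  data.frame(id = sprintf("%s|%s|%03d", organisms, groups, seq_len(n)),
             organism = organisms, group = groups,
             length = as.integer(lengths), stringsAsFactors = FALSE)
}

# Random edge set over n nodes; returns a homology_graph with all four
# metric columns equal to the given weights (topology-focused tests).
random_graph <- function(n, p = 0.3, weights = NULL) {
  ids <- sprintf("n%02d", seq_len(n))
  prs <- t(utils::combn(ids, 2L))
  keep <- stats::runif(nrow(prs)) < p
  prs <- prs[keep, , drop = FALSE]
  w <- if (is.null(weights)) {
    sample(c(0.1, 1, 10), nrow(prs), replace = TRUE)
  } else {
    weights
  }
  edges <- data.frame(id1 = prs[, 1L], id2 = prs[, 2L],
                      bs = w, nle = w, bsr = w, bal = w,
                      stringsAsFactors = FALSE)
  nodes <- data.frame(id = ids, organism = "orgA", group = NA_character_,
                      stringsAsFactors = FALSE)
  bgmcl:::new_homology_graph(nodes, edges, "raw")
}

# Barbell: two 3-cliques (intra weight 10) joined by one weak bridge (0.1).
barbell_graph <- function() {
  ids <- c("a1", "a2", "a3", "b1", "b2", "b3")
  e <- rbind(
    c("a1", "a2"), c("a1", "a3"), c("a2", "a3"),
    c("b1", "b2"), c("b1", "b3"), c("b2", "b3"),
    c("a3", "b1")
  )
  w <- c(rep(10, 6), 0.1)
  edges <- data.frame(id1 = pmin(e[, 1], e[, 2]), id2 = pmax(e[, 1], e[, 2]),
                      bs = w, nle = w, bsr = w, bal = w,
                      stringsAsFactors = FALSE)
  nodes <- data.frame(id = ids, organism = "orgA", group = NA_character_,
                      stringsAsFactors = FALSE)
  bgmcl:::new_homology_graph(nodes, edges, "raw")
}
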