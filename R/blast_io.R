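# Reading, writing and reducing tab-delimited BLAST hit tables
# (outfmt 6/7, "std qlen slen" column set).

#' Column names of the extended tabular BLAST format
#'
#' The standard 12 columns of `-outfmt 6` followed by the query and subject
#' sequence lengths (`qlen`, `slen`), i.e. the column set produced by
#' `-outfmt '7 std qlen slen'`. Coordinates are 1-based inclusive.
#'
#' @return Character vector of 14 column names.
#' @export
blast_columns <- function() {
  c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
    "qstart", "qend", "sstart", "send", "evalue", "bitscore", "qlen", "slen")
}

.blast_numeric_cols <- function() setdiff(blast_columns(), c("qseqid", "sseqid"))

#' Parse a tab-delimited BLAST hit table
#'
#' Reads the 14-column extended tabular format (`std qlen slen`). Lines
#' beginning with `#` (the outfmt 7 dialect's comment/header lines) are
#' skipped, so both outfmt 6 and outfmt 7 files are accepted.
#'
#' @param file Path to a hit table, or a character vector of raw lines.
#' @param require_lengths If `TRUE` (default) every hit line must carry the
#'   two extra length columns; a 12-column line is an error. If `FALSE`,
#'   12-column lines are accepted and `qlen`/`slen` are set to `NA`.
#' @return A data.frame of hits with the columns of [blast_columns()], one
#'   row per alignment.
#' @examples
#' lines <- c("# BLASTP 2.2.28+",
#'            "q1\ts1\t90.00\t100\t10\t0\t1\t100\t1\t100\t1e-50\t200\t100\t100")
#' parse_blast_table(lines)
#' @export
parse_blast_table <- function(file, require_lengths = TRUE) {
  is_path <- length(file) == 1L && !grepl("[\t\n]", file) &&
    !startsWith(file, "#")
  lines <- if (is_path) readLines(file) else file
  if (length(lines) == 1L && grepl("\n", lines, fixed = TRUE)) {
    lines <- strsplit(lines, "\n", fixed = TRUE)[[1L]]
  }
  keep <- !startsWith(lines, "#") & nzchar(lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(empty_hits())

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  min_cols <- if (require_lengths) 14L else 12L
  bad <- which(nf < min_cols)
  if (length(bad)) {
    stopf("line %d: expected %d tab-separated fields%s, found %d",
          line_no[bad[1L]], min_cols,
          if (require_lengths) " (std qlen slen; qlen/slen missing?)" else "",
          nf[bad[1L]])
  }

  get_col <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_,
                                character(1))
  hits <- data.frame(qseqid = get_col(1L), sseqid = get_col(2L),
                     stringsAsFactors = FALSE)
  num_names <- .blast_numeric_cols()
  for (i in seq_along(num_names)) {
    raw <- get_col(i + 2L)
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !is.na(raw))
    if (length(bad)) {
      stopf("line %d: field '%s' is not numeric: '%s'",
            line_no[bad[1L]], num_names[i], raw[bad[1L]])
    }
    hits[[num_names[i]]] <- val
  }
  validate_hits(hits, line_no)
  hits
}

empty_hits <- function() {
  hits <- data.frame(qseqid = character(0), sseqid = character(0),
                     stringsAsFactors = FALSE)
  for (nm in .blast_numeric_cols()) hits[[nm]] <- numeric(0)
  hits
}

validate_hits <- function(hits, line_no = seq_len(nrow(hits))) {
  bad <- which(hits$evalue < 0 | hits$bitscore <= 0 | hits$length < 1)
  if (length(bad)) {
    stopf("line %d: invalid hit (needs evalue >= 0, bitscore > 0, alignment length >= 1)",
          line_no[bad[1L]])
  }
  with_len <- which(!is.na(hits$qlen))
  coord_bad <- with_len[hits$qstart[with_len] < 1 |
                          hits$qstart[with_len] > hits$qend[with_len] |
                          hits$qend[with_len] > hits$qlen[with_len] |
                          hits$sstart[with_len] < 1 |
                          hits$sstart[with_len] > hits$send[with_len] |
                          hits$send[with_len] > hits$slen[with_len]]
  if (length(coord_bad)) {
    stopf("line %d: alignment coordinates violate 1 <= start <= end <= length",
          line_no[coord_bad[1L]])
  }
  invisible(hits)
}

#' Write a hit table in the 14-column tabular dialect
#'
#' Emits outfmt-6-style lines (no comment lines), tab-separated, in the
#' column order of [blast_columns()]. Numbers are serialized with full
#' precision so that `parse_blast_table(write_blast_table(x))` round-trips.
#'
#' @param hits Hit data.frame as returned by [parse_blast_table()].
#' @param file Output path (or `""` to return the lines invisibly only).
#' @return Invisibly, the character vector of lines written.
#' @export
write_blast_table <- function(hits, file = "") {
  cols <- lapply(blast_columns(), function(nm) {
    v <- hits[[nm]]
    if (is.numeric(v)) vapply(v, format_num, character(1)) else v
  })
  lines <- do.call(paste, c(cols, sep = "\t"))
  if (nzchar(file)) writeLines(lines, file)
  invisible(lines)
}

# Shortest decimal representation that round-trips through as.numeric at
# 15 significant digits.
format_num <- function(x) {
  if (is.na(x)) return("NA")
  s <- format(x, digits = 15, scientific = NA, trim = TRUE)
  s
}

#' Reduce a hit table to the best hit per unordered sequence pair
#'
#' All downstream edge weights use only the single top-scoring hit between
#' each pair of aligned sequences. Reciprocal hits (A vs B and B vs A) and
#' multiple HSPs are collapsed to the hit with the largest bit score;
#' ties break by smaller E-value, then longer alignment, then
#' lexicographically smaller (query, subject). Self hits are excluded
#' (harvest them first with [extract_self_scores()]).
#'
#' @param hits Hit data.frame.
#' @return Hit data.frame with exactly one row per unordered pair, each row
#'   keeping its own original orientation.
#' @export
best_hits <- function(hits) {
  hits <- hits[hits$qseqid != hits$sseqid, , drop = FALSE]
  if (nrow(hits) == 0L) return(hits)
  key <- pair_key(hits$qseqid, hits$sseqid)
  ord <- order(key, -hits$bitscore, hits$evalue, -hits$length,
               hits$qseqid, hits$sseqid)
  hits <- hits[ord, , drop = FALSE]
  hits <- hits[!duplicated(key[ord]), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Collect self bit scores (SBS)
#'
#' For each sequence with at least one self hit (query id equal to subject
#' id), records the maximum self bit score. The SBS of a sequence is
#' approximately twice its length, and consumers may substitute `2 * length`
#' when an entry is absent.
#'
#' @param hits Hit data.frame (pre-reduction; self hits are dropped by
#'   [best_hits()]).
#' @return Named numeric vector mapping sequence id to SBS (bits).
#' @export
extract_self_scores <- function(hits) {
  self <- hits[hits$qseqid == hits$sseqid, , drop = FALSE]
  if (nrow(self) == 0L) return(setNames(numeric(0), character(0)))
  sbs <- tapply(self$bitscore, self$qseqid, max)
  setNames(as.numeric(sbs), names(sbs))
}

#' Search-database size statistics
#'
#' The concatenated database length `N` enters the E-value identity
#' \eqn{E = mN/2^{BS}} used to supplement E-values that BLAST rounded to
#' zero and to recompute E-values for projected fragment hits.
#'
#' @param db Sequence database data.frame with a `length` column
#'   (see [generate_reference_db()] / [read_fasta_db()]).
#' @return List with `total_residues` and `num_sequences`.
#' @export
database_stats <- function(db) {
  if (is.null(db) || nrow(db) == 0L) stopf("empty sequence database")
  list(total_residues = sum(db$length), num_sequences = nrow(db))
}
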