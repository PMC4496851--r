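# FASTA input/output for labelled sequence databases (via Biostrings).
# Record ids use the dialect "organism|group|serial"; organism and group
# labels are parsed from the id on read.

#' Write a sequence database as FASTA
#'
#' @param db Sequence database data.frame (`id`, `seq`, ...).
#' @param file Output path.
#' @param width Line-wrap width for residues.
#' @return Invisibly, the path.
#' @export
write_fasta_db <- function(db, file, width = 70L) {
  if (is.null(db$seq)) stopf("database has no sequence column")
  aas <- Biostrings::AAStringSet(setNames(db$seq, db$id))
  Biostrings::writeXStringSet(aas, file, width = width)
  invisible(file)
}

#' Read a labelled sequence database from FASTA
#'
#' Record ids are expected in the `organism|group|serial` dialect; the
#' organism and group columns are filled from the id.
#'
#' @param file FASTA path.
#' @return Sequence database data.frame (`id`, `organism`, `group`,
#'   `length`, `seq`).
#' @export
read_fasta_db <- function(file) {
  aas <- Biostrings::readAAStringSet(file)
  ids <- sub("\\s.*$", "", names(aas))
  info <- parse_seq_ids(ids)
  data.frame(id = ids, organism = info$organism, group = info$group,
             length = Biostrings::width(aas),
             seq = as.character(aas), stringsAsFactors = FALSE)
}
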