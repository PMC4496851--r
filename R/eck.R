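# Published composition of the ECK (Expanded CEGMA KOGs) benchmark
# database, used for fragmentation-scheme arithmetic at full scale without
# downloading the sequences themselves.

#' ECK database composition
#'
#' Per-organism sequence and group counts of the ECK (Expanded CEGMA KOGs)
#' protein benchmark database: the 458 CEGMA KOGs with inparalogs restored,
#' plus annotations for four additional eukaryotes. The database totals
#' 6,840 sequences across 458 groups. Useful for reasoning about
#' fragmentation schemes (which organisms a digit string touches, and how
#' many sequences that covers) without the sequence data.
#'
#' @return data.frame with `organism` (scientific name), `seqs` (ECK
#'   sequence count) and `groups` (ECK groups the organism contributes to),
#'   ordered alphabetically by organism.
#' @examples
#' eck <- eck_composition()
#' sum(eck$seqs)  # 6840
#' @export
eck_composition <- function() {
  df <- data.frame(
    organism = c("Anopheles gambiae", "Arabidopsis thaliana",
                 "Caenorhabditis elegans", "Chlamydomonas reinhardtii",
                 "Ciona intestinalis", "Drosophila melanogaster",
                 "Encephalitozoon cuniculi", "Homo sapiens",
                 "Saccharomyces cerevisiae", "Schizosaccharomyces pombe",
                 "Toxoplasma gondii"),
    seqs = c(453L, 1175L, 635L, 407L, 432L, 611L, 311L, 1350L, 606L, 557L,
             303L),
    groups = c(453L, 458L, 458L, 407L, 432L, 458L, 291L, 458L, 458L, 458L,
               303L),
    stringsAsFactors = FALSE
  )
  df[order(df$organism), , drop = FALSE]
}

#' Number of ECK reference groups
#' @return 458L
#' @export
eck_num_groups <- function() 458L

#' Sequences covered by each digit of a fragmentation scheme on ECK
#'
#' Expands a scheme code over the eleven ECK organisms (alphabetically) and
#' tallies how many sequences receive each piece-count label.
#'
#' @param code Scheme digit string, e.g. `"11122222112"`.
#' @return data.frame with `pieces` and `seqs` (total sequences labelled
#'   with that piece count).
#' @export
eck_scheme_coverage <- function(code) {
  eck <- eck_composition()
  pieces <- expand_scheme(code, eck$organism)
  tot <- tapply(eck$seqs[match(names(pieces), eck$organism)], pieces, sum)
  data.frame(pieces = as.integer(names(tot)), seqs = as.integer(tot))
}
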