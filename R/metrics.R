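# The four edge-weighting metrics: BS, NLE, BSR, BAL.

#' Metric configuration
#'
#' @param evalue_cutoff Hits with E-values above this are assumed removed
#'   upstream (BLAST's own `-evalue` filter); default 1e-5.
#' @param zero_evalue_policy How to supplement E-values that BLAST rounded
#'   to zero (anything below 1e-180): `"invert_eq1"` recomputes the NLE from
#'   the bit score via \eqn{E = mN/2^{BS}}, `"fixed_cap"` substitutes the
#'   constant `zero_evalue_cap`.
#' @param zero_evalue_cap Constant NLE used under the `"fixed_cap"` policy;
#'   default 181, just past BLAST's rounding threshold.
#' @param bsr_fallback_factor Multiplier of sequence length used as the SBS
#'   proxy when no self hit is available; default 2 (a self alignment earns
#'   about two bits per residue).
#' @return A list of class `bgmcl_config`.
#' @export
metric_config <- function(evalue_cutoff = 1e-5,
                          zero_evalue_policy = c("invert_eq1", "fixed_cap"),
                          zero_evalue_cap = 181,
                          bsr_fallback_factor = 2) {
  stopifnot(evalue_cutoff > 0, zero_evalue_cap > 0, bsr_fallback_factor > 0)
  structure(list(evalue_cutoff = evalue_cutoff,
                 zero_evalue_policy = match.arg(zero_evalue_policy),
                 zero_evalue_cap = zero_evalue_cap,
                 bsr_fallback_factor = bsr_fallback_factor),
            class = "bgmcl_config")
}

#' Negative common log of the E-value (NLE)
#'
#' Returns \eqn{-\log_{10} E} for each hit. BLAST rounds E-values below
#' 1e-180 to zero, and the log of zero is undefined, so zero E-values are
#' supplemented according to the configured policy: `invert_eq1` inverts
#' \eqn{E = mN/2^{BS}} (with `m` the query length and `N` the concatenated
#' database length), giving \eqn{BS \log_{10} 2 - \log_{10}(mN)};
#' `fixed_cap` substitutes a constant.
#'
#' @param hits Hit data.frame (best hits, post E-value cutoff).
#' @param stats Database statistics from [database_stats()] (needed by the
#'   `invert_eq1` policy).
#' @param config A [metric_config()].
#' @return Numeric vector of NLE weights, one per hit.
#' @export
nle_weight <- function(hits, stats = NULL, config = metric_config()) {
  if (any(hits$evalue > 1)) {
    stopf("hit with E-value > 1 seen; apply the E-value cutoff before weighting")
  }
  w <- -log10(hits$evalue)
  zero <- which(hits$evalue == 0)
  if (length(zero)) {
    if (config$zero_evalue_policy == "invert_eq1") {
      if (is.null(stats)) stopf("invert_eq1 policy needs database stats (total residues N)")
      mN <- hits$qlen[zero] * stats$total_residues
      if (any(is.na(mN) | mN <= 0)) {
        stopf("invert_eq1 policy needs positive query length and database size")
      }
      w[zero] <- hits$bitscore[zero] * log10(2) - log10(mN)
    } else {
      w[zero] <- config$zero_evalue_cap
    }
  }
  w
}

#' Bit score weight (BS)
#'
#' Identity passthrough of the hit's bit score (tabular column 12).
#'
#' @param hits Hit data.frame.
#' @return Numeric vector of bit scores.
#' @export
bit_score_weight <- function(hits) hits$bitscore

#' Bit score ratio (BSR)
#'
#' Bit score divided by the smaller of the two self bit scores. When a
#' sequence has no SBS entry, `bsr_fallback_factor * length` (default
#' `2 * length`) is used as its proxy, justified by the tight empirical
#' SBS-vs-length relationship of full self alignments.
#'
#' @param hits Hit data.frame.
#' @param self_scores Named SBS vector from [extract_self_scores()].
#' @param config A [metric_config()].
#' @return Numeric vector of ratios, typically in (0, ~1.2].
#' @export
bsr_weight <- function(hits, self_scores, config = metric_config()) {
  lookup <- function(ids, lens) {
    sbs <- unname(self_scores[ids])
    miss <- is.na(sbs)
    if (any(miss)) {
      proxy <- config$bsr_fallback_factor * lens[miss]
      if (any(is.na(proxy) | proxy <= 0)) {
        stopf("sequence '%s' has neither a self bit score nor a usable length",
              ids[miss][which(is.na(proxy) | proxy <= 0)[1L]])
      }
      sbs[miss] <- proxy
    }
    sbs
  }
  min_sbs <- pmin(lookup(hits$qseqid, hits$qlen), lookup(hits$sseqid, hits$slen))
  hits$bitscore / min_sbs
}

#' Anchored alignment length (AL)
#'
#' The two sequences are anchored relative to each other by the hit
#' coordinates; AL is the alignment length plus the length of the shorter
#' overhang extending from each side of the aligned region:
#' `length + min(qstart-1, sstart-1) + min(qlen-qend, slen-send)`.
#' It is the maximum alignable region anchored by the hit.
#'
#' @param hits Hit data.frame with coordinate and length columns.
#' @return Numeric vector of anchored lengths (residues, >= 1).
#' @export
anchored_length <- function(hits) {
  hits$length +
    pmin(hits$qstart - 1, hits$sstart - 1) +
    pmin(hits$qlen - hits$qend, hits$slen - hits$send)
}

#' Bit score over anchored length (BAL)
#'
#' Bit score divided by [anchored_length()]. Inflates edge weights between
#' fragmented sequences while deflating weights of short conserved-domain
#' hits between long sequences.
#'
#' @inheritParams anchored_length
#' @return Numeric vector of bits-per-residue weights, typically in (0, ~2.2].
#' @export
bal_weight <- function(hits) hits$bitscore / anchored_length(hits)

#' Compute all four edge weights for a best-hit table
#'
#' @param hits Best-hit data.frame (one row per unordered pair, E-value
#'   cutoff already applied).
#' @param self_scores Named SBS vector.
#' @param stats Database statistics from [database_stats()].
#' @param config A [metric_config()].
#' @return data.frame with columns `id1`, `id2` (the unordered pair in
#'   sorted order) and the four weights `bs`, `nle`, `bsr`, `bal`.
#' @export
compute_edge_weights <- function(hits, self_scores, stats,
                                 config = metric_config()) {
  if (any(hits$evalue > config$evalue_cutoff)) {
    stopf("hit with E-value above the cutoff (%g) seen; filter upstream",
          config$evalue_cutoff)
  }
  data.frame(
    id1 = pmin(hits$qseqid, hits$sseqid),
    id2 = pmax(hits$qseqid, hits$sseqid),
    bs = bit_score_weight(hits),
    nle = nle_weight(hits, stats, config),
    bsr = bsr_weight(hits, self_scores, config),
    bal = bal_weight(hits),
    stringsAsFactors = FALSE
  )
}

#' Names of the four edge-weighting metrics
#' @return `c("bs", "nle", "bsr", "bal")`
#' @export
metric_names <- function() c("bs", "nle", "bsr", "bal")
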