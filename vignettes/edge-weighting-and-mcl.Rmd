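---
title: "Edge-weighting metrics and Markov clustering of BLAST graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge-weighting metrics and Markov clustering of BLAST graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bgmcl)
```

## The problem

Grouping protein sequences by inferred homology is the entry point to
comparative genomics: orthologous-group databases, phylogenomic marker
selection, and annotation transfer all start from it. The dominant recipe
is to run all-vs-all BLASTP, keep the best hit per pair of sequences,
interpret the result as a weighted undirected graph, and partition that
graph with the Markov Clustering algorithm (MCL). Pipelines in this family
differ essentially in one place: **how the edges are weighted**. `bgmcl`
implements four candidate weightings over an identical graph topology and
the machinery to compare them, including the case that stresses them the
hardest — databases in which many sequences are fragments of full-length
proteins, as produced by short-read *de novo* transcriptome assembly.

## Edge-weighting metrics

For the best hit between sequences $q$ and $s$ (bit score $BS$, E-value
$E$, alignment length $AL_{hit}$, 1-based coordinates, sequence lengths
$m_q, m_s$):

* **BS** — the bit score itself. Roughly two bits per aligned residue
  pair, so it scales linearly with alignable length.
* **NLE** — $-\log_{10} E$, the traditional weight. BLAST rounds E-values
  below about 1e-180 to zero, whose log is undefined, so strong edges
  must be supplemented heuristically (see below).
* **BSR** — $BS / \min(SBS_q, SBS_s)$, the bit score ratio, where $SBS$
  is the self bit score (the score of a sequence aligned to itself).
  When a self hit is unavailable the proxy $2m$ is used; self alignments
  earn almost exactly two bits per residue, and the empirical SBS-length
  relationship is tight enough (a few percent) that the proxy is safe.
* **BAL** — bit score over *anchored* alignment length. The pair is
  anchored by the hit coordinates and the divisor is the hit length plus
  the shorter overhang on each side:
  $AL = AL_{hit} + \min(q_{start} - 1, s_{start} - 1) + \min(m_q - q_{end},
  m_s - s_{end})$. $AL$ is
  the longest region the two sequences could align given the anchor, so
  $BAL$ rewards hits that use all of their alignable sequence (fragments
  overlapping end-to-end) and penalizes short conserved-domain hits
  between long, otherwise unrelated sequences.

All four weights are attached to every edge of a single graph
(`build_graph()`); exports per metric differ only in the weight column.

### Zero E-values

`nle_weight()` supplements $E = 0$ by inverting the E-value identity
$E = mN/2^{BS}$ ($m$ = query length, $N$ = total residues in the search
database), giving $BS\log_{10}2 - \log_{10}(mN)$. This is the package
default (`zero_evalue_policy = "invert_eq1"`) because it preserves the
ordering of strong edges instead of flattening them onto a cap. A fixed
cap (default 181, just past the rounding threshold) is available as an
alternative dialect; the two dialects diverge exactly where the E-value
no longer carries information, so the choice is logged with each run
config rather than hidden. The identity ignores BLAST's finite-size
length corrections; it is exactness-tested only on tables generated from
the identity itself.

### Reciprocal hits

BLAST reports $q \to s$ and $s \to q$ separately and the two scores
occasionally differ. `best_hits()` keeps the single hit with the larger
bit score (ties: smaller E-value, longer alignment, lexicographic id
order). Taking the maximum rather than the mean is a dialect choice —
implementations in this family differ here — and is documented as such;
it is deterministic and matches "top hit" semantics. Multiple HSPs per
pair are likewise reduced to the single top hit; summing non-overlapping
HSPs is deliberately out of scope.

## Inter-organism normalization

`normalize_inter_organism()` multiplies each edge weight by
(global mean weight) / (mean weight between the edge's two organism
pair), the classic correction that boosts edges between divergent
proteomes and damps edges between close ones. After normalization every
organism pair's mean equals the old global mean (this invariant is
tested). Intra-organism edges participate as the pair $(x,x)$. The
operation is not idempotent and the raw graph is never modified in
place. A `direction = "pair_over_global"` switch exposes the reciprocal
orientation because published descriptions of this correction state the
ratio both ways; only the default orientation produces the intended
boosting effect.

## The MCL engine

`mcl_cluster()` implements the canonical Markov Cluster process natively
on dense per-component blocks:

1. Self loops: each node receives a loop weighted by its maximum incident
   edge (fallback 1.0), damping the period-2 oscillations of bipartite-ish
   structures. A `"unit"` policy is available.
2. Columns are normalized to sum to one; then expansion ($M \leftarrow
   M^2$) alternates with inflation (entrywise power $r$, column
   renormalization).
3. Entries below `prune_threshold` (default 1e-7) are zeroed and columns
   renormalized — on desk-scale graphs this only removes numerical dust.
4. Convergence: maximal absolute entry change below `convergence_tol`
   (default 1e-8), error after `max_iterations` (default 200) with the
   residual reported.
5. Interpretation: nodes with diagonal mass above 1e-6 are attractors;
   weakly connected attractor sets seed clusters; every other node joins
   the system its column mass flows into, ties broken toward the cluster
   with the lexicographically smallest member. Entries at or below the
   1e-6 structural tolerance are treated as numerical residue: the exact
   limit matrix has hard zeros there, and honoring sub-tolerance flow
   would spuriously link systems.

Because each connected component is clustered independently, clusters can
never span components — MCL subdivides but never merges. The engine is
validated against an independently written naive dense reference (no
pruning, fixed-point iteration, components-of-the-limit-matrix
interpretation) on exhaustively sampled small graphs.

`inflation_sweep()` reuses the component decomposition across the default
grid 1.1–6.0 in steps of 0.1 — 50 clusterings per graph; with four
metrics in raw and normalized states that is the full 8 × 50 = 400
clusterings per hit table produced by `run_pipeline()`.

## Simulated fragmentation

`fragmentation_scheme()` encodes a scenario as a digit string: digit $j$
is the number of pieces for the $j$-th organism in alphabetical order,
with short codes repeated then truncated. Labels can also be shuffled
within each reference group (preserving the per-group label multiset) to
decouple fragmentation from organism identity. Breakpoints are either
even (piece lengths within one residue, remainder to the leftmost pieces
— any fixed rule works; leftmost is the easiest to verify) or uniform
random over interior positions with a minimum fragment length (default
10 residues in random mode; the floor avoids degenerate fragments that no
aligner would report on).

### BLAST-free hit projection

Re-running BLAST for every fragmentation scenario is the pipeline's real
cost. `project_hits()` instead intersects each parent-level best hit with
every fragment pair, assuming alignment columns are collinear with both
sequences (gap geometry is ignored). The overlapping column range becomes
a fragment hit with re-based coordinates, bit score scaled by the
overlapping fraction (consistent with the two-bits-per-residue rule), and
E-value recomputed from $E = mN/2^{BS}$ with the fragment length as $m$;
hits above the cutoff are dropped, exactly as BLAST's own `-evalue`
filter would. Fragment self scores are the parent SBS scaled by length
fraction. This is a geometric surrogate, not a BLAST emulator — it cannot
create hits BLAST would find only after fragmentation, and it inherits
the parent hit's identity profile uniformly along its length.

## Synthetic benchmark generator

`generate_reference_db()` / `generate_hit_table()` draw a labelled
database and a best-hit table with the structure the analysis assumes:

* self bit scores $2L(1 \pm 2.5\%)$ — the tight empirical SBS-length
  relationship;
* full-length intra-group hits at $2 \times \min(L) \times$ identity,
  identity uniform on 0.55–0.9 (orthologs detectable but diverged);
* spurious inter-group hits at rate 0.01 per pair with 40–60 bits —
  straddling the 1e-5 cutoff so some survive, 1–2 orders below the
  strong edges;
* shared-domain hits (rate 0.01) between long inter-group pairs: short
  40–80 residue regions at high score density with long overhangs — the
  case BAL is designed to deflate;
* every E-value from $E = mN/2^{BS}$, hits failing the cutoff omitted.

Defaults are 25 groups over four organisms at membership probability 0.9
(≈ 95–100 sequences), lengths 150–600 residues with 10% within-group
spread — small enough to sweep in seconds, large enough for every group
structure to appear. Residue content is an arbitrary uniform draw: no
stage ever recomputes an alignment, so only lengths and scores carry
information, but valid FASTA is still emitted so fragmentation tiles
real strings. The generator does **not** emulate BLAST's seeding
heuristics, compositional score adjustments, alignment-length/identity
correlation structure, or inparalog-rich gene families; passing tests
demonstrate the pipeline's algebra and the metrics' relative behavior
under the stated score model, not performance on real proteomes.

`generate_bridge_scenario()` is the deterministic counterpart for the
aligned-breakpoint regime: groups of two 400- and two 460-residue
sequences, all split into even halves. Equal-length homologs break at the
same alignment column, so same-rank fragments form two disjoint
subclusters per group; the 60-residue length offset leaves 30-column
opposing-end "bridge" hits (≈ 48 bits against a ≈ 300-bit backbone).
A bridge is counted as retained by `bridge_edge_retention()` when its
weight is at least a quarter of the median backbone weight — below that,
one expansion–inflation round at practical inflations reduces its flow to
a negligible share, so the edge is invisible to MCL in practice. Under
BS the bridges sit near 16–21% of backbone and are lost; under BAL they
align end-to-end within their anchored region and sit near 100%, and MCL
on the BAL graph reassembles every group while BS, NLE and BSR graphs
stay split.

## Evaluation

Clusterings are scored against the reference grouping by: the number of
clusters each group was split into (sensitivity), the number of groups
represented in each cluster (specificity), and the count of *perfect*
clusters — containing every member of exactly one group and nothing else
(strict definition; extraneous members disqualify). Groups whose members
were all filtered out before clustering are reported separately rather
than as zero-count histogram rows, so stacked totals always sum to the
number of surviving groups. The coefficient of variation uses the
population standard deviation ($\sigma/\mu$ does not specify a variant;
the population form makes $c_v = 0$ exactly for constant samples).
Fragment-to-parent mapping for evaluation always goes through the sidecar
fragment table, never id parsing.

When comparing metrics across a fragmentation scenario, the package's
summary quantity is the perfect-cluster count summed over the inflation
range 1.5 / 2.5 / 4.0. Aggregating over the range matters: a
length-normalizing metric can lead at a single low inflation through its
rescue effect while degrading faster as inflation grows, and a scenario
verdict should reflect the whole granularity range a practitioner would
scan.

## Numerical and degenerate-input choices

* Pair keys are unordered; a kept best hit retains its own orientation.
* Weight serialization (ABC, hit tables) uses 15-significant-digit
  shortest decimals; round trips are exact to ≥ 6 significant digits
  (tested), which keeps BSR/BAL values intact.
* Isolated nodes cluster as singletons; empty graphs yield empty
  clusterings; an empty database is an error.
* E-values are computed in log space, so bit scores beyond 1024 do not
  overflow; underflow yields 0, mirroring BLAST's own rounding.
* Random-breakpoint placement uses rejection sampling under the minimum
  fragment length; feasibility is guaranteed by the precondition
  `pieces <= floor(length / min_fragment_length)`.

## Problem sizes

The shipped tests and the acceptance script run entirely on generated
data: databases of 4–150 groups (up to ≈ 600 sequences for the SBS-slope
regression), the 100-sequence default benchmark for the full 400-
clustering sweep, and thousands of random ≤ 10-node graphs for the MCL
oracle and refinement properties. These sizes were chosen as the smallest
at which every qualitative regime (multi-component graphs, spurious
survivors, bridges, domain hits) is reliably present.

## Known limitations

* The hit projection surrogate understates what re-running BLAST on
  fragments could find (notably new hits enabled by masking differences),
  and ignores gap geometry when mapping columns.
* The synthetic score model is deliberately simple; conclusions about
  *relative* metric behavior transfer, absolute sensitivity/specificity
  numbers do not.
* Summing of non-overlapping HSPs, XML/pairwise BLAST formats, and the
  external `mcl` program's option surface are out of scope; ABC export
  exists precisely so results can be cross-checked against the external
  program manually.
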