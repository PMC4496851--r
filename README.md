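# bgmcl

Compare BLAST-based edge-weighting metrics for Markov-Clustering (MCL)
protein homology inference — and run the whole graph-clustering pipeline
natively in R.

## The problem

The standard route from proteomes to homologous groups is: all-vs-all
BLASTP, keep the best hit per sequence pair, treat the result as a sparse
weighted undirected graph, and partition it with MCL. Pipelines in this
family (TribeMCL, OrthoMCL, orthAgogue, ...) differ mainly in how they
weight the edges. `bgmcl` implements the four candidate weightings over a
single shared topology:

| metric | definition |
|---|---|
| `bs`  | bit score of the best hit |
| `nle` | −log₁₀ E-value; zero E-values supplemented via E = mN/2^BS |
| `bsr` | bit score / min of the two self bit scores (proxy: 2 × length) |
| `bal` | bit score / anchored alignment length (hit + shorter overhang each side) |

plus optional inter-organism normalization (each edge × global mean /
organism-pair mean), a native MCL engine with the standard
expansion–inflation iteration, an inflation sweep (1.1–6.0 step 0.1 = 50
clusterings per graph; 4 metrics × raw/normalized = 8 graphs = 400
clusterings per hit table), and evaluation against reference homology
groups (split counts, purity counts, perfect reconstructions, intra- vs
inter-group weight distributions).

Because fragmented sequences from short-read assembly are where the
metrics genuinely differ, the package ships a fragmentation simulator
(integer-coded schemes, ordered/shuffled labels, even/random breakpoints)
and a BLAST-free projection of parent-level hits onto fragments, so
fragmentation benchmarks run at desk scale with no BLAST binary. A seeded
synthetic generator produces databases and best-hit tables with the
relevant statistical structure (self bit score ≈ 2 × length, strong
intra-group hits, weak spurious hits, shared-domain hits).

It reads and writes the 14-column tabular BLAST dialect
(`-outfmt '7 std qlen slen'`), FASTA with `organism|group|serial` ids,
MCL-compatible ABC edge lists, GML, and TSV summaries. To regenerate real
input the documented (untested here) command is:

```
blastp -query db.fasta -db db -evalue 1e-5 -soft_masking true \
       -outfmt '7 std qlen slen' > hits.tsv
```

## Worked example

```r
library(bgmcl)

bench <- generate_benchmark(synthetic_config(num_groups = 10, seed = 42))
bench$graph
#> homology_graph: 42 nodes, 78 edges, 4 organisms [raw]

comp <- connected_components(bench$graph)
length(comp$clusters)                          # 3
perfect_cluster_count(comp, bench$reference)   # 2
```

Spurious inter-group hits fused most of the 10 reference groups into 3
connected components, only 2 of which coincide with a group — the
pre-clustering baseline. MCL resolves them:

```r
cl <- mcl_cluster(bench$graph, "bs", mcl_params(inflation = 1.5))
cl
#> clustering: 10 clusters over 42 items [mcl(bs, raw, I=1.50)]
perfect_cluster_count(cl, bench$reference)     # 10 of 10

d <- edge_weight_distributions(bench$graph)
d$summary[d$summary$metric == "bs", c("class", "n", "mean", "cv")]
#>  class  n       mean        cv
#>  intra 71 1.08913029 0.2997744
#>  inter  7 0.09596417 0.2347016
```

All 10 groups are perfectly reconstructed at inflation 1.5, and the
scaled weight summary shows why: the 7 surviving spurious (inter-group)
edges carry about a tenth of the mean intra-group weight, so inflation
starves them of flow.

The full pipeline — fragmentation, hit projection, 8 graph exports, the
50-point inflation sweep per graph, and evaluation TSVs — runs from one
config:

```r
cfg <- run_config(output_dir = "out",
                  synthetic = synthetic_config(seed = 1),
                  scheme_codes = c("1", "11122222112"))
manifest <- run_pipeline(cfg)
```

or from the shell via the installed front end
(`system.file("exec", "bgmcl", package = "bgmcl")`):

```
bgmcl run-all --out out --groups 25 --scheme 22222 --mode random --seed 1
```

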