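# slimclust

Progressive clustering of short peptides into motif clusters with profile
hidden Markov models.

## The problem

High-throughput selection experiments — most prominently phage display
followed by next-generation sequencing — produce datasets of thousands to
millions of short peptides (typically 7–20 residues) in which several
distinct short linear motifs (SLiMs) are hidden among substantial
experimental noise: nonspecific binders and clones selected for growth
rather than affinity. Identifying *multiple* weak motifs at once, without
knowing their number in advance, is the task this package addresses.

`slimclust` grows motif clusters progressively:

1. **Greedy seeding.** Unique sequences (with per-label copy counts
   preserved) are sorted — by default by copy number — and swept once: each
   sequence joins the best-scoring existing cluster representative under a
   gapless, shift-limited BLOSUM62 alignment, or founds a new cluster. The
   largest 2.5 % of clusters (at most 250) become *cores*; all other
   sequences form the *pool*.
2. **Extension.** Each cluster is summarised as a profile HMM built from
   the match columns of its alignment (columns with < 5 % gaps and
   information content ≥ 1.2 bits). The pool is searched by local Viterbi
   alignment (log₂-odds against an i.i.d. background null); sequences
   scoring above the round's threshold are inserted into the alignment of
   their best-scoring cluster along their Viterbi path.
3. **Merging.** Whole clusters are compared by local HMM–HMM alignment of
   their match states under the co-emission score
   `s(i,j) = log₂ Σ_r P_i(r)·P_j(r)/q(r)`; above-threshold pairs are merged
   best-pair-first through a queue, so no above-threshold pair is left
   unmerged. Early rounds confine merging to groups of clusters whose
   relaxed-threshold hit sets overlap (a union-find transitive closure);
   the last round runs the full procedure.

Steps 2–3 alternate (three rounds by default) with thresholds relaxed each
round. Hard *diversity controls* — at least 4 match states, a cap on
alignment width and on inner gaps — veto any insertion or merge that would
make a cluster alignment degenerate. The result is a set of clusters, each
with a multiple sequence alignment, plus the unassigned remainder.

A planted-motif generator (`generate_dataset()`, `sh3_like_fixture()`)
produces display-like synthetic data — degenerate motif patterns such as
`[RK]xxPxxP` at random offsets inside background flanks, power-law copy
numbers, label mixtures, ground truth — so the whole pipeline is testable
without external data.

## A worked example

```r
library(slimclust)

ds <- generate_dataset(
  motifs      = list(motif_spec("[RK]LxPxNP", "m1"),
                     motif_spec("WYxDxEF",    "m2")),
  n_per_motif = c(800, 500), n_noise = 300,
  length = 12, seed = 5)

useqs  <- deduplicate(ds$occurrences)
result <- run_clustering(useqs, clustering_config())
result
#> slimclust_result: 2 clusters, 300 of 1600 unique sequences unassigned
#> pep_cluster 19: 500 sequences, width 17, 5 match states (WYDEF)
#> pep_cluster 20: 800 sequences, width 18, 5 match states (RLPNP)

cluster_purity(result, ds$truth)
#>   cluster_id majority_motif purity   n
#> 1         19             m2      1 500
#> 2         20             m1      1 800
```

Both planted motifs are recovered as single pure clusters — the consensus
over match states shows the informative motif positions (`[RK]LxPxNP` →
`RLPNP`) — and all 300 noise sequences are left unassigned.
`export_results(result, "out/")` writes `clusters.tsv`, one aligned FASTA
per cluster, `unassigned.tsv` and the per-label copy-count matrix;
`dataset_kld(result, "match")` scores the clustering by Kullback–Leibler
divergence from background.

From a shell:

```sh
exec/slimclust --input peptides.tsv --format tabular --out results/
```

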