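# metabin — adaptive metagenome binning in R

`metabin` groups assembled metagenome contigs into putative genome bins.
It is built for researchers who have a multi-sample (or single-sample)
shotgun metagenome assembly plus per-contig read depths and want draft
genomes without hand-tuning sensitivity/specificity parameters.

## The method in brief

Two signals identify contigs from the same genome: tetranucleotide
composition (TNF, strand-collapsed to 136 canonical 4-mers) and read-depth
agreement across samples. For a contig pair, `metabin` computes

* a **TNF score** — a calibrated logistic in the Euclidean distance between
  tetramer frequency vectors, with a length-aware midpoint;
* an **ABD score** — the overlap coefficient of the two depth distributions
  N(mean, variance), geometric-averaged over the *nABD* effective samples
  (those where either contig exceeds 1× coverage);
* a **COR score** — Pearson correlation of depth profiles (≥ 3 samples).

TNF and COR are quantile-normalized against the ABD score distribution so
all evidence shares one scale, then combined into the composite score

    S = TNF^(1-w) * ABD^w,            w = nABD / (nABD + 1)
    S = sqrt(TNF^(1-w) * ABD^w * COR) when >= 3 samples

so coverage evidence automatically gains weight as samples accumulate.
Contigs ≥ 2.5 kb form a sparse graph (per-node edge cap, mutual top-k) in
two stages — a strong-TNF seed graph, then iterative admission of the
highest-S edges down to `minS` — partitioned after each admission step by a
deterministic label propagation algorithm whose membership decisions
combine edge evidence with Fisher's method (1−S as p-values, −2Σln(1−S)
against χ² with 2m df). With ≥ 3 samples, bins under 200 kb dissolve and
their members plus small contigs (1–2.5 kb) are recruited by depth-profile
correlation.

The package also ships a synthetic community simulator with ground truth
(`generate_community()`), a completeness/precision evaluator
(`evaluate_bins()`), and a genetic-algorithm parameter search
(`ga_search()`, `truth_fitness()`).

## Worked example

```r
library(metabin)
com <- generate_community(community_spec(n_genomes = 6,
                                         genome_length = 1e6, seed = 42))
res <- run_binning(com$contigs, com$coverage)
evaluate_bins(res$bins, com$truth)
```

```
contigs: 274 (6e+06 bp), samples: 3
clustering 223 contigs >= 2500 bp
seed graph: 1238 TNF edges
admitted edges per iteration: 1 197 948 2051 2824 3200 3328 3407 3489 3577
recruiting: 54 free contigs (3 from dissolved bins, 51 small) into 6 bins
bins: 6, binned bp: 5,883,536 / 6e+06
eval_report: 6 bins, 6 genomes
recovered-genome counts (completeness x precision):
    p90 p95
c50   6   6
...
c90   6   6
```

Reading this: 223 of 274 contigs were long enough to cluster; the seed
graph admitted 1,238 strong composition edges and the descending-threshold
schedule grew the composite-score graph from its strongest edge to 3,577
edges; all 6 planted genomes came back
as bins, each ≥ 90% complete at ≥ 95% precision, and 5.88 of 6 Mb ended up
binned (the remainder is small contigs whose depth profiles did not beat
their target bin's internal correlation — recruiting deliberately favors
purity).

To bin your own assembly from the shell:

```sh
Rscript inst/scripts/metabin.R bin -i contigs.fa -a depth.tsv -o out/bin
```

`depth.tsv` is the usual depth-summarizer dialect (`contigName`,
`contigLen`, `totalAvgDepth`, then `<sample>` / `<sample>-var` pairs; a
mean-only table is accepted with variance assumed equal to mean).

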