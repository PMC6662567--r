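---
title: "Adaptive metagenome binning: model, scores, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive metagenome binning: model, scores, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A metagenome assembly is a bag of contigs from many organisms.  Binning
groups those contigs into putative genomes using two complementary signals:

* **composition** — tetranucleotide frequencies (TNF) are fairly stable
  along a genome and differ between genomes;
* **coverage** — contigs from the same genome have proportional read depth
  within a sample, and *co-varying* depth across samples.

`metabin` combines both signals adaptively: the more samples carry usable
coverage for a contig pair, the more weight coverage gets relative to
composition.

# Pairwise evidence

## TNF score

Every contig is reduced to frequencies over the 136 canonical tetramers
(each 4-mer merged with its reverse complement, so the score is
strand-independent; windows containing N are skipped).  The raw TNF score
of a pair is a logistic in the Euclidean distance $d$ between the two
frequency vectors,

$$\mathrm{TNF}_{raw} = \frac{\sigma(\beta_0 + \beta_1 d + \beta_2 r)}{\sigma(\beta_0 + \beta_2 r)},
\qquad r = \sqrt{\tfrac{1}{n_A} + \tfrac{1}{n_B}},$$

where $n_A$, $n_B$ are the tetramer window counts and $\sigma$ the logistic
function.  The $r$ term moves the midpoint of the decay with contig length:
frequency estimates from a short contig are noisy (standard error
$\propto 1/\sqrt{L}$), so the same raw distance is weaker evidence of
*different* origin when contigs are short.  The denominator rescales the
curve so that distance 0 scores exactly 1.  The coefficients are frozen in
the source and come from `calibrate_tnf_logistic()`, a shipped,
deterministic procedure that fits a same-genome/different-genome logistic
regression on simulated communities with contigs spanning 1–50 kb.  The
functional form and its calibration are this package's own construction:
they reproduce the *semantics* of a probability that two contigs share a
genome without importing constants from elsewhere.

## ABD score

Per sample, each contig carries a mean depth and a depth variance.  A
sample is **effective** for a pair when either contig's mean depth exceeds
`min_cv` (default 1 — i.e. "more than 1x coverage").  For each effective
sample the two depths are modeled as normal densities and scored by their
overlap coefficient (shared area), computed analytically from the density
intersection points; variances are floored at $10^{-4}$ so zero-variance
rows stay well-defined.  Scores multiply across effective samples as a
geometric mean, and the count of effective samples is `nABD`.  A pair with
`nABD = 0` has *undefined* coverage evidence: it can still enter the
composition-only seed graph but never the composite-score graph, which is a
deliberate choice over dropping such contigs outright.

The overlap coefficient is invariant under rescaling depth (doubling means
while quadrupling variances), so libraries of different size do not distort
the score.

## COR score

With three or more samples, the Pearson correlation of the two mean-depth
profiles adds covariance information that single-sample overlap cannot see.
It is undefined for fewer than three samples or zero-variance profiles;
undefined correlations simply drop the COR term for that pair rather than
punishing it with a 0 (a 0 would be a strong claim of anti-evidence).
Correlation uses raw depths, not log depths; at the typical within-genome
noise levels the rank structure is the same and raw depths need no
pseudocount.

# Score normalization and the composite score

Raw TNF and COR scores have arbitrary, data-dependent distributions, so
they are **quantile-normalized against the ABD score distribution**: a raw
value is mapped to its interpolated rank in a sampled raw-score
distribution, then to the same quantile of the sampled ABD distribution.
After this, all three scores fall within the same range and can be
combined:

$$S = \mathrm{TNF}_n^{\,1-w}\cdot \mathrm{ABD}^{\,w}, \qquad w = \frac{n_{ABD}}{n_{ABD}+1},$$

and, when a correlation score is available,

$$S = \sqrt{\mathrm{TNF}_n^{\,1-w}\cdot \mathrm{ABD}^{\,w}\cdot \mathrm{COR}_n}.$$

With one effective sample $w = 1/2$ and $S$ is the plain geometric mean;
as samples accumulate, $w \to 1$ and coverage dominates.  The three-factor
form is implemented exactly as written — a square root, although the
product has three factors.  A true three-factor geometric mean (cube root)
is available behind `geodesic_mean_3 = TRUE` for sensitivity analysis; the
square root compresses less and slightly favors admitting edges, and is
the default because it is the published form of the statistic.

Distribution fitting does not materialize all $O(N^2)$ pairs: a uniform
random sample of $\min(500N,\,2\times 10^6)$ pairs (seeded, hence
deterministic) estimates the TNF/ABD/COR distributions and the percentile
cutoffs.  Values queried outside the fitted range clamp to the endpoint
quantiles.  The normalization sample is taken over all sampled pairs, not
only admitted edges; the distinction matters little because admission
cutoffs are themselves percentiles of the same sample.

# Graph construction and partitioning

Clustering operates on contigs at least `min_contig` (2500) bp long.

**Stage 1 — seed graph.**  Raw TNF scores alone are unreliable, so only
*strong* TNF links are used: those above the `max_p`-th percentile
(default 95) of the sampled TNF score distribution, capped at `max_edges`
per node.  The cap uses per-node top-k retention with mutual-top-k
finalization: each node keeps its `k` best offers (order-independent), and
an edge survives only if both endpoints kept it.  This yields symmetric
adjacency, degree ≤ k, and memory linear in the contig count.

**Stage 2 — iterative admission.**  Label propagation first runs on the
seed graph itself (raw TNF weights, singleton starting labels): same-genome
TNF scores saturate near 1, which consolidates whole-genome clusters
robustly.  The composite-score threshold then descends from the top of the
sampled S distribution to `min_s`/100 (default 0.60) in `schedule_steps`
(10) equal steps — strongest edges first.  At each step the capped graph is
rebuilt from all pairs with $S$ at or above the threshold and label
propagation runs to a fixed point, warm-started from the previous labels.
The step count is a design choice: the admission schedule only needs to be
gradual enough that tight clusters consolidate before looser edges arrive,
and 10 steps was adopted as a round default (exposed as a parameter).

**Component refinement.**  Label propagation can merge labels but never
split one (a node surrounded by a single label has nothing else to adopt),
so a cluster inherited from composition evidence could survive even when
coverage contradicts it.  The final step therefore intersects labels with
the connected components of the last admitted graph (S ≥ `min_s`/100 edges,
plus the composition-only seed edges of pairs whose S is undefined): a bin
must be connected in the surviving evidence graph.  This is what separates
genomes with indistinguishable tetramer composition but distinct coverage
covariance — their cross edges all fall below `min_s` once coverage
disagrees, the merged label splits into components, while genuinely
connected clusters pass through unchanged.  Quantile normalization keeps
same-genome S in a broad mid-to-high band (it inherits the ABD sample's
spread by construction), which is why the split is decided by graph
connectivity at the `min_s` floor rather than by label propagation alone.

**Label propagation.**  Classic LPA visits nodes in random order; here the
order is decreasing strongest-incident-edge (ties broken by node id), which
makes the partition deterministic.  Each node adopts the label that best
explains its neighborhood under **Fisher's method**: for a candidate label
supported by edges with scores $S_1..S_m$, treat $1-S_i$ as p-values, form
$X = -2\sum\ln(1-S_i)$, and refer $X$ to $\chi^2_{2m}$.  The label with the
smallest combined p wins; exact ties keep the current label, then fall back
to the lexicographically smallest.  Combining p-values rather than summing
scores keeps neighborhoods of different sizes comparable — ten mediocre
edges can legitimately outweigh one excellent edge, and the chi-square
tail quantifies exactly when.

Numerical choices: $1-S$ is floored at $10^{-12}$ so $S = 1$ stays finite,
and combined p-values are compared on the **log scale** — strong
neighborhoods underflow double precision ($p = 0$), and log-scale
comparison preserves their ordering instead of collapsing them into ties
(which can make the propagation oscillate).  A sweep with zero label
changes is the fixed point; a round that has not settled after
`max_lpa_iters` (50) sweeps is accepted as-is with a warning — asynchronous
propagation can 2-cycle on symmetric structures, and accepting the current
labels is preferable to running forever.

Initial labels are singletons (each node its own label), the standard LPA
start when nothing better is known.

# Recruiting small contigs and dissolving small bins

Clustering uses contigs ≥ 2.5 kb.  When **three or more samples** are
available, a post-pass first dissolves bins under `min_cls_size` (200 kb)
and then offers every free contig — dissolved-bin members pooled together
with 1–2.5 kb contigs — to the surviving bins: a contig joins the bin
maximizing its mean depth-profile correlation to the bin's members,
provided that correlation exceeds the bin's own mean pairwise member
correlation.  The rule is self-calibrating: tight bins demand tight
recruits.  Decisions are all taken against the pre-recruitment bin state,
so the pass is order-independent and runs exactly once (it is an additional
step, not an iterated fixed point).  Bins with a single member have no
within-bin correlation and never recruit.  For bins with more than 50
members the within-bin mean is computed on a seeded random subsample of 50
members, turning an $O(m^2)$ computation into a bounded one.  With fewer
than three samples the whole module is a strict no-op; undersized bins are
then simply dropped to unbinned.

# The synthetic community simulator

The simulator emulates exactly the features the binner exploits, with
ground truth attached:

* **composition** — each genome is an order-3 Markov chain whose transition
  logits are perturbed around uniform with sd `markov_bias` (default 0.3).
  The default was chosen once so that between-genome TNF Euclidean
  distances land near the low end of the 0.02–0.1 range observed between
  distinct microbial species — closely related genomes, which is the harder
  and more realistic case.  `bias_groups` can force two genomes to share a
  chain, creating composition-identical genomes separable only by coverage.
* **coverage** — genome-by-sample coverages are lognormal (meanlog
  `log(25)`, sdlog 0.8: median 25x, occasional near-1x samples), or an
  explicit matrix.  Per-contig depth wobbles around the genome-sample
  coverage with relative sd `depth_noise` (0.1) and reported depth variance
  is `dispersion` (2) times the mean — overdispersed-Poisson read depth, as
  depth summarizers report on real alignments.
* **fragmentation** — contig lengths are a mixture: fraction `frac_small`
  (0.15) uniform on 1–2.5 kb, the rest uniform on 2.5–50 kb, covering both
  the clustering population and the recruiting population.

Default scale is 20 genomes × 2 Mb × 3 samples (~1700 contigs, 40 Mb) —
large enough that the capped graph, percentile schedule and recruiting all
operate as they would on a real assembly, small enough to run in about a
minute.  What the simulator does **not** emulate: strain mixtures,
chimeric or misassembled contigs, plasmids/viruses, uneven within-genome
composition (e.g. horizontally transferred islands), and correlated
depth noise from read mapping artifacts.  Passing tests therefore
demonstrate the algorithm's correctness and its behavior under the stated
noise model, not field performance on hostile assemblies.

# Evaluation

`evaluate_bins()` mirrors standard genome-recovery counting: bin
**precision** is the bp share of the bin's majority genome; genome
**completeness** is the bp of the genome inside the single bin holding most
of it (no split credit), over the genome's total contig bp.  A genome is
recovered at thresholds $(c, p)$ iff its best bin has precision ≥ p and
completeness ≥ c; counts are reported on the
$\{0.5..0.9\} \times \{0.9, 0.95\}$ grid.

# Parameter search

Only three parameters materially affect accuracy: `max_edges`, `max_p`,
`min_s`.  `ga_search()` explores their discrete grids with a small genetic
algorithm (population 10, elite 3, binary tournament, one-point crossover
at rate 0.01, per-gene mutation at rate 0.05, 3–10 generations, early stop
after 3 flat generations past the minimum).  The crossover rate is
unusually low relative to mutation; both are exposed as configuration.
Fitness is the count of high-quality bins against simulated truth — ≥ 90%
complete and ≤ 5% contamination.  rRNA/tRNA criteria of the full MIMAG
high-quality definition are out of scope because they require external
annotators; the fitness is documented as completeness/contamination only.

# Worked example

```{r, eval = FALSE}
library(metabin)
com <- generate_community(community_spec(n_genomes = 6,
                                         genome_length = 1e6, seed = 42))
res <- run_binning(com$contigs, com$coverage, out_prefix = "out/bins")
evaluate_bins(res$bins, com$truth)
```

# Known limitations

* The recruiting bar is deliberately strict — a small contig must
  out-correlate the bin's *own mean pairwise correlation*.  Under symmetric
  per-contig depth noise a genuinely native contig clears that bar only
  about two-thirds of the time (slightly above half, by the left skew of
  the correlation distribution near 1), at any noise scale.  Recruiting
  therefore trades completeness for purity by construction: expect roughly
  a third of 1–2.5 kb fragments to stay unbinned, and essentially none to
  be recruited into the wrong bin (the candidate bin is the correlation
  argmax over all bins before the bar is applied).
* Single-sample data loses ABD reliability and all of COR; expect splits of
  genomes with drifting coverage (the algorithm weighs purity over
  completeness).
* The TNF logistic was calibrated on simulated Markov genomes; on real
  genomes the score's *ranking* (which drives everything downstream, via
  quantile normalization and percentile cutoffs) is robust, but the raw
  values should not be read as calibrated probabilities.
* Serial implementation: complexity contracts (linear memory via capped
  adjacency, sampled distribution fitting) are honored, but no
  multi-threading or cache tiling is attempted.
* Chimeric contigs are not detected; garbage in, garbage binned.
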