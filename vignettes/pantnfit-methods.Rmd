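---
title: "Methods: pangenomic Tn-seq essentiality calling and cofitness networks"
author: "pantnfit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pangenomic Tn-seq essentiality calling and cofitness networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`pantnfit` analyses mariner (Himar1) transposon insertion sequencing
(Tn-seq) data across several closely related bacterial strains. The mariner
transposon inserts exclusively at TA dinucleotides, so the unit of
observation is the TA site: each library yields a vector of read counts over
the genome's ordered TA sites, and per-gene mutant abundance measures how
dispensable the gene is for growth. The package covers the full path from
per-library count tracks to a cross-strain cofitness network:

1. TA-site indexing and trimmed per-gene TA assignment;
2. track building, library combination, LOESS positional correction, and
   trimmed-total-reads (TTR) depth normalization;
3. three independent essentiality callers: a four-state hidden Markov model
   (HMM), a Bayesian classifier on the longest insertion-free run (Gumbel
   null), and a Monte Carlo pseudodataset fitness estimator;
4. pangenome bookkeeping (orthogroup parsing, conservation subsets I/II/III,
   the core fitness matrix);
5. a Pearson cofitness network thresholded by random-matrix-theory (RMT)
   spacing statistics, with node topology metrics and module detection;
6. enrichment statistics (exact hypergeometric tests, a permutation Z test,
   Tukey HSD with compact letter display, Benjamini-Hochberg adjustment);
7. a synthetic pangenome generator with planted ground truth that exercises
   everything end to end.

The input formats are the field's usual ones: FASTA genomes, GFF3 or tabular
annotations, variableStep wig tracks of per-TA-site counts, and tab-separated
orthogroup tables. All user-facing functions take and return tibbles so the
pieces compose with the pipe.

# Gene-level count preparation

**TA assignment and end trimming.** Insertions in the extreme 5' and 3' ends
of a gene frequently leave the product functional, so a fraction
(`trim_fraction`, default 0.05) of each end of the genomic span is excluded
before TA sites are assigned to the gene. The trim length is
`floor(trim_fraction * gene_length)` bases per end, so genes shorter than
`1/trim_fraction` bases lose nothing — this avoids emptying very short genes.
Trimming is strand-symmetric (mariner disrupts both strands) and the trim is
measured in bases rather than TA-site count, matching the usual convention of
the Tn-seq literature. A site inside two overlapping genes counts for both.

**Combination and normalization.** Independent libraries of a strain are
combined by raw-count summation, which preserves count semantics and can only
increase insertion density. The combined track is then corrected for
positional bias with a locally weighted degree-1 (tricube) regression of
counts on genomic position per replicon (span 0.1 of the sites); each count
is multiplied by `global_mean / fitted`, with fitted values floored at a tiny
positive epsilon, so zero counts remain exactly zero. Finally TTR
normalization rescales each track so that the mean of its nonzero counts —
after discarding the top and bottom 5% of them — equals 100. The order
(combine, smooth, depth-normalize) is fixed in `prepare_track()`; each knob
is an exported argument. Insertion density (fraction of TA sites hit) is the
library-quality statistic; tracks below 50% trigger a QC warning.

# The three essentiality callers

**Four-state HMM.** States ES (essential), GA (growth advantage: disrupting
the gene costs fitness, mutants depleted), NE (nonessential), and GD (growth
disadvantage: mutants enriched) emit integer counts from geometric
distributions parameterized by their means, `p = 1/(1 + mean)`. The means
are pinned to the genome-wide mean of nonzero counts
\(\bar\lambda\): ES \(0.01\bar\lambda\) (clamped to at least 0.5), GA
\(0.1\bar\lambda\), NE \(\bar\lambda\), GD \(5\bar\lambda\). Counts are
rounded to the nearest integer (ties to even) after normalization.
Transitions keep the current state with probability \(1-\varepsilon\)
(\(\varepsilon = 10^{-3}\), split evenly across the other states); replicons
are independent chains. Decoding is Viterbi in log space — the gene-level
category, not a posterior, is the object of interest — and a gene's call is
the majority state over its trimmed TA sites, ties broken by extremeness
(ES > GA > GD > NE). The suite verifies Viterbi against exhaustive path
enumeration on all short tracks.

**Gumbel longest-run classifier.** For a nonessential gene with \(n\) TA
sites, where each site is insertion-free independently with the genome-wide
probability \(q\), the longest insertion-free run follows approximately a
Gumbel law with mean
\(\mu = \log_{1/q}(n(1-q)) + \gamma/\ln(1/q) - 1/2\) and variance
\(\sigma^2 = \pi^2/(6\ln^2(1/q)) + 1/12\). An essential gene instead shows a
run spanning most of the gene; we model it with a triangular density rising
on \([n/2, n]\) and zero below. A Gibbs sampler over the per-gene
essentiality indicators and a Beta(1,1) mixture weight yields the posterior
probability `zbar` per gene; calls are ES at `zbar >= 0.99`, NE at
`zbar <= 0.05`, Uncertain in between, and TooShort below 4 TA sites. This is
a deliberately self-contained re-interpretation of the longest-gap idea, not
a clone of any released tool. The asymptotic mean is accurate to under 1% by
simulation; the asymptotic SD overshoots the finite-\(n\) SD by several
percent below \(n \approx 500\) (a known finite-size truncation of
extreme-value asymptotics), which the test suite measures and reports
honestly.

**Monte Carlo pseudodataset fitness.** 2000 "expected" pseudodatasets are
drawn by placing the observed multiset of nonzero counts at uniformly random
distinct TA sites — conserving total reads, the count multiset, and the
insertion density, so the ensemble is a faithful genome-wide null. Per-gene
fitness is \(\log_2\bigl((\text{obs}+c)/(\overline{\text{exp}}+c)\bigr)\)
with pseudocount \(c = 0.5\); significance is the two-sided empirical tail
with add-one correction, BH-adjusted across genes, and a gene is flagged
essential when \(\log_2\text{FC} < -1\) with adjusted \(p < 0.05\). The plain
log-ratio-plus-empirical-tail estimator replaces the published
negative-binomial shrinkage machinery deliberately: the pseudodataset
ensemble *is* the null, the estimator is exactly testable, and both \(c\) and
the ensemble size are configurable. Counts are placed without site
collisions; a with-replacement variant would only matter at extreme depth.
Because the null is genome-wide, genes untouched in an otherwise depleted
genome sit slightly above zero — fitness values are relative, which is also
why strongly depleted growth-advantage genes can cross the essentiality
threshold (a known behaviour of two-class Monte Carlo calls).

# Pangenome and cofitness network

Orthogroup tables (one column per strain, comma-joined gene lists) are
parsed into a long map; conservation subsets are **I** (orthogroup spans all
`n_strains_total` reference strains), **III** (strain-specific), and **II**
(in between). `n_strains_total` is a declared property of the reference
pangenome, not inferred, so subsets can be defined against a wider strain
panel than was assayed. The core fitness matrix keeps orthogroups with a
member in every test strain; when a strain has several copies, the copy with
the lowest fitness represents the orthogroup (configurable: `min`, `mean`,
or single-copy-only). Rows constant across strains make correlation
undefined and are rejected by name.

Pairwise Pearson correlation of fitness profiles gives the cofitness
matrix. The network threshold is chosen by the RMT transition: for each
cutoff on a grid, entries below the cutoff are zeroed, the spectrum of the
surviving submatrix is unfolded (cubic smoothing spline through the
empirical cumulative eigenvalue density at 21 support points), and the
nearest-neighbour spacing distribution (NNSD) is tested against Poisson
spacings \(e^{-s}\) by a chi-square on bins of width 0.1 over [0, 3] with a
pooled tail. Correlated (signal-bearing) matrices show GOE-like Wigner
repulsion; once only noise survives, spacings become Poisson. The chosen
`r_star` is the smallest cutoff whose Poisson fit is not rejected
(\(p > 0.05\)) and whose submatrix meets a size floor. Edges use signed
`r >= r_star` (strong positive cofitness), matching the convention of
correlation-network practice; an absolute-value mode is a flag. Node metrics
are connectivity degree, average shortest path length (mean over reachable
nodes), closeness (its inverse; 0 for isolates), and the topological
coefficient (mean shared-neighbour count, plus adjacency, over the node's
degree) — all verified against a brute-force BFS oracle. The strongest-edge
subnetwork keeps the top fraction (default 1%) of all gene pairs ranked by
correlation (the base set is configurable to retained-edges-only), and
modules come from deterministic greedy modularity maximization, numbered by
decreasing size.

Three upstream ambiguities are deliberately config-exposed rather than
guessed silently: the base set of the "top 1% of edges", the module
algorithm, and signed-versus-absolute thresholding.

# Enrichment statistics

Label enrichment in a gene set is the one-sided exact hypergeometric tail
(two-sided available), with Haldane-corrected odds ratios and BH adjustment
across labels; genes with several functional labels count once per label.
The permutation Z test draws `|category|` genes without replacement from the
background 5000 times, computes \(z = (\text{obs}-\bar x)/s\), and reports
the two-tailed Gaussian p; because the draw count is exactly hypergeometric,
the Gaussian p approximates the exact mid-p (half the point mass in each
tail), and the suite checks agreement with the exact test at that
convention. Tukey HSD runs on a one-way fit with the studentized range
(Tukey-Kramer for unbalanced groups); the compact letter display assigns one
letter per maximal clique of the not-significantly-different graph, so
groups share a letter exactly when they are statistically
indistinguishable.

# The synthetic generator and what it does (not) show

`simulate_pangenome()` plants the full study design: five strains by
default, 500 single-copy core orthogroups, 120 partially shared accessory
orthogroups, 40 strain-specific genes per strain, two replicons per strain
(chromosome and plasmid), genes of 900 bp carrying a Poisson(55) number of
TA sites on a CG background, and three libraries per strain at 85% target
insertion density. Core genes draw a base category
(ES/GA/GD/NE = 0.08/0.06/0.04/0.82); with probability `rewire_prob` (0.1)
per strain a core gene's category is independently redrawn — the planted
fuzzy essential zone. Accessory and specific genes are NE-dominated
(0.02/0.03/0.02/0.93).

Insertion is modelled as independent Poisson transposition events: site
\(i\) with category weight \(w_i\) is hit with probability
\(1-e^{-\Lambda w_i}\), with the pressure \(\Lambda\) solved so the expected
genome-wide density equals the target. Weights are ES 0.005 (the
non-disruptive leak rate), GA 0.4, NE 1, GD 1.8. The saturation model is the
physically standard description of pooled mutagenesis (a site is occupied
when at least one independent event lands there), and it implies that the
effective ES leak grows super-linearly with density — which is exactly the
regime where longest-run classifiers lose essential genes, as the robustness
comparison reproduces. Read counts at inserted sites are
`1 + Geometric` with category means ES 5, GA 10, NE 50, GD 250: count
effects are stronger than insertion-probability effects because competitive
outgrowth acts multiplicatively on mutant abundance.

Each strain carries a selection-severity multiplier
\(e^{N(0, 1.5)}\), clamped to \([1/6, 6]\), applied to both the ES leak
weight and the ES escaper count mean. This shared strain effect is what
makes essential-gene fitness profiles correlate across strains (the planted
co-essentiality signal picked up by the network); the clamp keeps leaky
strains from turning essential genes into apparent nonessentials. The
resulting cross-strain SDs of essential-gene fitness (roughly 2-4 log2
units) sit inside the empirically observed range for real pangenomic
Tn-seq.

What the generator does **not** emulate: sequencing error and read-level
artifacts, PCR jackpots, realistic base composition (spacers are CG so the
planted TA count is exact), operon-level polar effects, or correlated
rewiring of whole pathways. Passing the suite therefore demonstrates that
the algorithms recover planted structure under a well-specified generative
model — not that any particular biological dataset will behave as cleanly.

# Numerical choices and degenerate inputs

* Counts are rounded ties-to-even before geometric emission evaluation;
  emissions and Viterbi run entirely in log space.
* TTR errors on all-zero tracks; LOESS errors below 50 sites or when all
  fitted values are non-positive; fitted values are floored at
  \(10^{-9}\times\) the global mean.
* The Gumbel classifier refuses densities of exactly 0 or 1 (degenerate
  \(\hat q\)); genes below 4 TA sites are TooShort rather than silently
  misclassified.
* The NNSD unfolding drops (rare) negative spacings produced by tiny spline
  non-monotonicities and renormalizes to unit mean; the spacing histogram
  pools its tail above 3.
* The RMT scan needs at least five strain columns in practice: with four,
  thresholded matrices decompose into 2x2 blocks whose point-clustered
  spectra never look Poisson. The scan raises a clear error instead of
  returning a fabricated threshold.
* Tie-breaks are deterministic everywhere (stable pair order in the top-edge
  ranking, extremeness priority in gene calls, vertex order in module
  detection), so identical seeds give byte-identical results.

# Problem sizes used by the validation suite

The test suite and the acceptance script run entirely on synthetic data at
desk scale, chosen to finish in minutes while leaving every statistical
check well powered: 500-gene single-strain experiments for depletion
recovery (20 TA sites per gene, 2000 pseudodatasets), the full default
five-strain pangenome for the fitness-ordering check, three seeds times two
densities times three libraries (200 core genes, one assayed strain) for the
caller-robustness contrast, 500x500 matrices for the RMT discrimination
check, and a 300-core-gene five-strain pangenome for the end-to-end network
(about 300 orthogroups by 5 strains). Full study-scale datasets
(hundred-thousand-site genomes, fifteen libraries, orthology over a
nineteen-genome panel) run through exactly the same code paths with linear
cost.

# Known limitations

* With only five strain columns, pairwise Pearson correlations are heavy
  tailed; the RMT threshold typically lands near 0.9 simply because noise
  correlations at \(n = 5\) reach high values. That is faithful to the
  method at this design size, not a defect, but degrees should be read
  comparatively, never as absolute interaction counts.
* The Gumbel classifier's asymptotic SD is biased upward for genes under a
  few hundred TA sites; its calls are threshold-based on the posterior, so
  the practical effect is mild Uncertain-zone widening.
* The Monte Carlo estimator measures fitness relative to the genome-wide
  average; genome-level shifts (e.g. a globally sick library) are absorbed
  by the null rather than detected.
* Viterbi gene calls are hard labels; posterior state marginals
  (forward-backward) are intentionally out of scope.
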