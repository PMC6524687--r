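---
title: "RMT-thresholded molecular ecological networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RMT-thresholded molecular ecological networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmena)
```

## The problem

Gut microbial communities are not collections of independent taxa: OTUs
co-occur when they cooperate or share niches and co-exclude when they
compete.  A phylogenetic molecular ecological network (pMEN) summarises
these dependencies as a signed, weighted graph over OTUs, inferred from the
correlation of their relative abundances across replicate samples within a
group (for instance, a healthy cohort and successive chemotherapy stages of
a colorectal-cancer cohort).  The scientific questions such networks serve
are structural: how connected and how modular is the community, which taxa
occupy keystone positions, and how do these properties shift between
groups.

The statistical crux is the similarity threshold: which |Pearson r| values
constitute evidence of an interaction rather than sampling noise.  `pmena`
implements the random-matrix-theory (RMT) answer: scan thresholds and watch
the eigenvalue-spacing statistics of the pruned correlation matrix switch
from the Gaussian-orthogonal-ensemble (GOE) regime characteristic of noise
to the Poisson regime characteristic of modular, system-specific structure.

## Pipeline

For each group the pipeline applies, in order:

1. **Rarefaction** (`rarefy`): each sample is subsampled without
   replacement to a common depth (default 39,796 sequences, a typical
   post-QC depth for fecal 16S libraries of this design), so retained
   counts are hypergeometric.  Samples below the target are dropped, never
   resampled with replacement.  Rarefaction precedes the prevalence screen;
   "detected" therefore means present after depth standardisation.
2. **Prevalence filter** (`prevalence_filter`): an OTU is kept only if
   detected in *strictly more than* half of the group's samples (an OTU in
   exactly half is removed).  The strict reading keeps the rule unambiguous
   at even group sizes.
3. **Relative abundance** (`relative_abundance`): columns are closed to
   proportions.  Correlations are computed on these proportions without a
   log transform; a log transform is easy to apply upstream if desired, but
   the default matches the plain reading of a relative-abundance pipeline.
4. **Similarity** (`pearson_similarity`): the similarity is |r| with the
   sign retained separately, so thresholding operates on magnitude while
   the network remembers co-occurrence (+) versus co-exclusion (−).
5. **Threshold selection** (`scan_threshold`), described below.
6. **Network, modules, indices, roles, null models, associations.**

## RMT threshold selection

At each candidate threshold $s$ (default grid 0.30–0.99, step 0.01) the
similarity matrix is pruned: entries below $s$ are zeroed and rows with no
surviving off-diagonal entry are removed.  The eigenvalues of the pruned
weighted matrix (surviving |r| values, unit diagonal — not a binarised
matrix) are *unfolded* and their nearest-neighbour spacing distribution
(NNSD) is tested against two universal laws:

* Poisson, $P(d) = e^{-d}$ — uncorrelated level spacings, the signature of
  a system decomposed into independent modular blocks;
* GOE (Wigner surmise), $P(d) = \frac{\pi d}{2} e^{-\pi d^2/4}$ — level
  repulsion, the signature of noise.

The chosen threshold $S_t$ is the smallest grid value whose Poisson
chi-square p-value exceeds `alpha` (default 0.05) and remains above it for
the next two grid points.  The two-point stability requirement guards
against single-point acceptances produced by chance in the transition
region; because acceptance is one-sided in $s$, raising `alpha` can only
raise the chosen threshold on a fixed trace.

### Numerical choices

* **Unfolding** maps eigenvalues through $e_i = N\,\hat F(\lambda_i)$, with
  $\hat F$ a Hyman-filtered monotone cubic spline through the empirical
  cumulative spectral function at `max(5, ceiling(N/8))` knot eigenvalues.
  The knot density matters: with substantially fewer knots (e.g. $N/20$)
  the spline under-fits composite spectral densities — superposed module
  blocks plus their Perron eigenvalues — and the systematic spacing
  distortion masquerades as a deviation from the Poisson law, so the scan
  rejects genuinely modular spectra.  At $N/8$ the unfolding still averages
  over ~8 levels per knot, leaving local fluctuations intact: on simulated
  data the exponential-spacing calibration accepts Poisson in 96% of
  replicates and pure GOE spectra are rejected in 50/50 draws, while
  planted five-block similarity matrices are accepted inside their
  construction gap in 18/20 seeds.
* **Degeneracies**: eigenvalue gaps below $10^{-10}$ are collapsed before
  unfolding; exact degeneracies carry no spacing information and would pin
  the histogram at zero.
* **Chi-square binning**: spacings are binned on $[0, 3]$ with width 0.1;
  expected masses are renormalised over that range and adjacent bins are
  pooled left-to-right until each pooled bin has expected count ≥ 5 (the
  usual validity condition), with degrees of freedom = pooled bins − 1.
* The scan stops when the pruned matrix order drops below 30 (below that,
  spacing statistics are meaningless), and a scan that never satisfies the
  acceptance rule fails loudly with its trace.

## Network and indices

An edge joins every pair with $|r| \ge S_t$ (the threshold is the *minimal*
retained strength, so the boundary is included); isolated OTUs are
excluded.  All topological indices are computed on the unweighted topology
(distances in hops); weights enter only through OTU strength-degrees:

* average degree $2E/N$; average path distance (mean over connected pairs);
* average harmonic geodesic distance $N(N-1)/\sum_{i\neq j} d_{ij}^{-1}$,
  with disconnected pairs contributing zero reciprocal — finite on
  fragmented graphs, which is exactly why both distance summaries are
  reported;
* average local clustering, with $C_i = 0$ for nodes of degree < 2,
  averaged over all nodes;
* the $R^2$ of an ordinary least-squares fit of $\log_{10} f(k)$ on
  $\log_{10} k$ over observed degrees (raw frequencies, not the CCDF —
  matching the reporting style of molecular-ecology network pipelines);
  undefined (NA, with a message) when fewer than 3 distinct degrees exist;
* modularity and module count; the fraction of negative links.

### Module detection

`detect_modules` maximises modularity greedily on the unweighted topology.
The default is the multilevel (Louvain) optimiser with a fixed internal
traversal seed, so results are deterministic for a given graph.  The purely
agglomerative CNM optimiser is available as `method = "fast_greedy"`, but
it is not the default: on planted five-module benchmarks its early merges
occasionally lock two dense modules together and it returns a modularity
*below* that of the planted partition itself (0.706 versus 0.755 in one
benchmark seed), i.e. it can underperform the very objective it optimises,
while the multilevel optimiser recovered the planted modules exactly in
all benchmark seeds and never returned the lower Q.  Reported Q is always
recomputed from the partition by the direct formula
$Q = \sum_s [\,l_s/E - (d_s/2E)^2\,]$, which doubles as an internal
consistency check on the optimiser.

## Node roles (Zi–Pi)

Within-module connectivity $z_i$ is the z-score of a node's intra-module
degree within its module, using the *population* standard deviation, with
$z_i = 0$ when the module is degree-homogeneous (cliques, singletons) —
this convention keeps every value finite.  Among-module connectivity
$p_i = 1 - \sum_s (k_{is}/k_i)^2$.  The classification uses the standard
cut-offs with both boundaries inclusive on the "≤" side: module hubs
($p_i \le 0.62$, $z_i > 2.5$), connectors ($p_i > 0.62$, $z_i \le 2.5$),
network hubs (both exceeded), peripherals (neither).  Module hubs,
connectors and network hubs are flagged as putative keystone taxa.

## Null models and group comparison

Significance of the topology indices is assessed against 100
degree-preserving randomisations (Maslov–Sneppen double-edge swaps, 10
attempts per edge, per-member seeds derived from a master seed by a
counter).  Signs and weights are not permuted: the null concerns topology
only.  Two groups are compared index-by-index with a Student t statistic
whose dispersions come from the two null ensembles,
$t = (a - b)/\sqrt{s_a^2/n_a + s_b^2/n_b}$, with a two-sided p-value on
Welch–Satterthwaite degrees of freedom.  Welch rather than pooled df is
used because ensemble variances can differ by orders of magnitude between
sparse and dense networks; the pooled df is also reported so either
convention can be audited.  If both ensembles are degenerate (zero SD), the
comparison is flagged and p is 0 or 1 by exact agreement.

## Clinical-marker association

`otu_degree` sums link strengths (|r|) per node — all links, positive only,
or negative only ("positive OTU links" and "positive OTU degree" are
treated as the same strength-mode quantity; a count mode exists for
sensitivity analysis).  `degree_marker_table` correlates per-unit summaries
of the three degree variants with per-unit tumour-marker summaries (CA242,
CEA, CA199, CA724) by mid-rank Spearman correlation with a t-approximation
p-value on $n-2$ df.  The sampling unit is deliberately the caller's
choice — the natural unit for a staged design is the treatment group, so
`run_pipeline` uses per-group means — because published correlation tables
of this kind rarely state the unit, and baking one in would hide the
choice.  P-values are reported raw; with 12 cells a Benjamini–Hochberg
adjustment via `p.adjust` is one line for callers who want it.
`keystone_marker_association` correlates individual keystone OTU abundances
with markers across samples.

## The synthetic-data generator

Because raw sequencing data for studies of this design are typically not
deposited, every pipeline stage is exercised against
`generate_table(synthetic_spec(...))`, which plants known structure:

* a block-structured latent multivariate normal realised by a factor
  construction (module factors, a shared background factor), giving exact
  within-module correlation `rho_w` (default 0.85) and between-module
  correlation `rho_b` (default 0.1);
* axis reflection of a fraction of module members, so within-module
  couplings split into co-occurrence and co-exclusion with negative
  fraction `f_neg` (default 0.45, inside the 45–75% range reported for
  intestinal networks; reflection can plant at most ~50%);
* "broker" OTUs loading evenly on four modules — planted connector
  candidates.  Four-way spreading is deliberate: an even $k$-way broker's
  participation coefficient is capped at $1 - 1/k$, so a two-way broker
  (cap 0.5) can never cross the 0.62 connector cut-off and a three-way
  broker (cap 2/3) leaves no margin for sampling noise.  Even so, a
  broker's correlation with each of $k$ near-orthogonal modules is bounded
  near $\sqrt{\rho_w/k} \approx 0.45$–0.55, which is close to where the RMT
  scan places $S_t$ on such data — so planted brokers are *structurally*
  near-threshold, and connector recovery is expected in most but not all
  simulated studies (9/10 benchmark seeds).  The tests assert exactly that.
* per-module designated hubs (pure-factor members, the most strongly
  connected member of each module in expectation);
* a lognormal-Poisson count model: latent values pass through an
  exponential link onto a lognormal baseline across OTUs and are realised
  as Poisson counts at a target depth of 41,000 (comfortably above the
  39,796 rarefaction default, so rarefaction is genuinely exercised).
  Log-scale within-OTU dispersion defaults to 0.35, small enough that the
  exponential link stays near-linear and the planted Pearson signs and
  magnitudes survive the transform; a lognormal-Poisson rather than
  Dirichlet-multinomial model keeps the planted correlation structure
  interpretable, with compositional closure applied only at the
  relative-abundance step, as in the real pipeline.

What the generator does **not** emulate: the heavy-tailed dispersion and
zero-inflation of real 16S data (a structural-zero rate is available but
defaults to 0), taxonomy assignment noise, and chimera/clustering
artefacts.  Passing recovery tests therefore demonstrates correctness of
the algorithms under the planted model, not performance guarantees on real
stool samples.

`generate_markers` couples tumour-marker variables linearly (plus Gaussian
noise) to any per-sample or per-group quantity, so planted monotone
marker–network associations of known sign can be re-detected downstream.

## Reference panel and percentage conventions

`reference_indices()` carries the published topology panel of seven
intestinal microbiota networks (healthy H and chemotherapy stages T0–T5,
all at the common RMT threshold 0.660) with their random-network means and
SDs.  Two arithmetic families are recomputed from it: the identity
(average degree) = 2·(links)/(size) for all seven columns, and the four
group-contrast percentage statements.  Published contrasts of this kind
mix conventions — degree contrasts are expressed relative to the CRC-stage
value, the modularity T5–T0 contrast relative to T0, and the modularity
CRC-versus-healthy contrast relative to H — so `percent_change(value,
reference)` takes the reference explicitly and each statement is pinned to
its verified formula rather than to a single global convention.

## Problem sizes

The test suite and the acceptance script are sized to run comfortably on a
single CPU: planted threshold-recovery matrices are 150×150 (five modules
of 30) over 20 seeds; end-to-end studies use 152 OTUs × 40 samples over 10
master seeds; the scripted seven-group study uses 200 OTUs × 147 samples
with 100-network null ensembles per group.  These sizes sit inside the
range of real filtered 16S group tables (tens to a few hundred network
nodes) while keeping the full suite under a minute.

## Known limitations

* Pearson-on-proportions inherits compositional artefacts; the generator
  quantifies them only lightly (closure is applied, but dispersion is
  mild).  Alternative association measures (SparCC, proportionality) are
  out of scope by design.
* The NNSD chi-square has finite power at small matrix orders; below ~30
  distinct eigenvalues the scan refuses to proceed rather than guess.
* Greedy modularity maximisation (either method) is a heuristic; module
  *counts* are not treated as reproducible quantities, and only planted
  or closed-form partitions are asserted in tests.
* Reported p-values for the 4×3 marker grid are raw, matching the
  reporting style the panel reproduces; callers comparing many groups or
  markers should adjust.
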