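---
title: "Integrative chromatin domain annotation: models, parameters and design choices"
author: "HiCdomains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative chromatin domain annotation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Chromatin is organized in at least two distinguishable layers at the
megabase scale. The *functional* layer is visible in 1D assays — histone
modification ChIP-seq, DNase-seq — as domains with coherent chromatin-state
signatures. The *structural* layer is visible in Hi-C contact maps as
compartments and subcompartments: groups of genomic bins with similar
genome-wide interaction profiles. The two layers are correlated but not
redundant, so an annotation built from either alone misses part of the
organization. HiCdomains infers *combinatorial* domain types by (i)
summarizing the Hi-C contact graph into a small number of per-bin structural
features with a graph node embedding and (ii) feeding those features,
together with the binned 1D signals, into one Gaussian-emission hidden
Markov model.

Everything operates on a shared coordinate system of fixed-width genomic
bins (`BinnedGenome`, default resolution 100 kb — the scale at which
compartmental organization is defined; configurable). Coordinates are
0-based half-open in all files, matching the UCSC BED/bedGraph/BEDPE
dialects.

# The observed/expected interaction graph

Raw Hi-C counts are dominated by the polymer distance decay, so the graph
edge weights are observed/expected (O/E) enrichments:

* **intra-chromosomal** pairs: the expected count for a pair at bin distance
  $d$ is the mean observed count over all unmasked pairs of the *same
  chromosome* at distance $d$, zeros included. Including zeros matters: an
  unobserved pair is an observation of zero, and dropping them would inflate
  expectations on sparse chromosomes.
* **inter-chromosomal** pairs: a single genome-wide mean over unmasked inter
  pairs.

Distance strata with fewer than `minPairs = 10` unmasked pairs are pooled
with the adjacent longer-distance stratum so a stratum mean is never
estimated from a handful of pairs; a trailing short group merges backward.
Within any stratum the mean O/E is exactly 1 by construction, a property the
test suite checks. Bins whose raw marginal falls below a quarter of their
chromosome's median marginal are masked before normalization
(`filterBins`); low-coverage bins otherwise produce wild O/E ratios.

Edges are kept when O/E $\ge$ 1 by default: the embedding should be driven
by enriched contacts. The threshold is a flag (`threshold = 0` keeps every
observed pair) and weights enter the sampler linearly — no log transform.
The diagonal is excluded. Self-interaction carries no compartmental
information.

# Structural features by second-order-proximity embedding

Two bins belong to the same subcompartment when their *interaction
profiles* are similar, not necessarily when they touch each other often.
This is second-order proximity in the contact graph $G = (V, E)$ with
weights $w_{ij}$ and degrees $d_i = \sum_j w_{ij}$. Each node carries an
embedding $u_i$ and a context vector $u'_i$; the model distribution

$$p_2(v_j \mid v_i) = \frac{\exp({u'_j}^\top u_i)}{\sum_k \exp({u'_k}^\top u_i)}$$

is pushed toward the empirical neighbor distribution
$\hat p_2(v_j \mid v_i) = w_{ij} / d_i$ by minimizing the degree-weighted
KL divergence, which simplifies to

$$O_2 = -\sum_{(i,j) \in E} w_{ij} \log p_2(v_j \mid v_i).$$

The full softmax is intractable at genome scale, so training uses the
standard stochastic scheme: draw an edge with probability proportional to
its weight (an alias table makes this O(1); both directions of every
undirected edge enter the sampler, which also realizes the node weights
$\lambda_i = d_i$ implicitly), ascend $\sigma({u'_j}^\top u_i)$ for the
positive pair, and descend it for `negatives = 5` noise nodes drawn with
probability proportional to $d^{0.75}$. The learning rate decays linearly
from `rho0 = 0.025` to $10^{-4}$ of that. Initialization is uniform in
$(-0.5/\mathrm{dim}, 0.5/\mathrm{dim})$ for $u$ and zero for $u'$. These
are the conventions of the reference implementation of this family of
embedding models.

Parameters that matter:

* `dim = 8` — eight features are enough to carry genome-wide
  compartmental structure at 100 kb; exposed as a flag.
* `samples` — total edge draws; default `max(100 |E|, 1e6)`, scaled to
  graph size with a floor so small graphs still converge.
* `seed` — the trainer uses its own deterministic RNG (splitmix64-seeded
  xoshiro256\*\*), so a fixed seed gives bit-identical embeddings on any
  platform, independent of R's RNG state. Only the single-threaded trainer
  is provided; an asynchronous trainer would break this guarantee.

Only $u$ is exported as structural features ($u'$ is an auxiliary
quantity). Diagnostic functions expose the exact objective, its analytic
full-softmax gradient (used in finite-difference checks), and the
first-order objective $-\sum w_{ij} \log \sigma(u_j^\top u_i)$ so first-
versus second-order embeddings can be compared on synthetic graphs.

# The annotation model

`annotateDomains()` fits a Gaussian-emission HMM over bins. Functional
tracks are transformed with the inverse hyperbolic sine
$\mathrm{asinh}(x) = \ln(x + \sqrt{x^2 + 1})$ — it is linear near zero and
logarithmic in the tail, taming heavy-tailed coverage signals while
accepting zeros — and then z-scored per track (population convention,
denominator $n$, over unmasked bins). Embedding features are z-scored only;
they are already roughly symmetric. The constants are stored in the model
so decode-time inputs are transformed identically.

Emissions are diagonal-covariance Gaussians with `M = 1` component per
state by default: with 12 + 8 tracks at 100 kb resolution the data per
state are limited, and the mixture generalization (`M > 1`) is a flag for
users with more data. A variance floor of $10^{-3}$ (post-standardization
units) prevents component collapse. Fitting is Baum–Welch EM from a seeded
k-means initialization, stopping at a relative log-likelihood improvement
below $10^{-4}$ or 500 iterations. Each chromosome is an independent
observation sequence, and masked bins *split* a chromosome into separate
sequences rather than being imputed — assembly gaps and filtered bins
should not contribute phantom transitions. One EM run by default for
reproducibility; `restarts` runs seeds `seed, seed+1, ...` and keeps the
best final likelihood, ties resolved by seed order. An emptied state is
re-seeded once from a perturbation of the highest-variance state, then the
fit errors rather than silently returning a degenerate model. Decoding is
the Viterbi path (deterministic); the GMM baseline (`fitGMM`) is the same
emission model without the chain and decodes by maximum posterior.

`K` is a user choice. The evaluation module supports the usual sweep
(variance explained flattens as `K` grows) but the package deliberately
does not automate model selection.

State indices from EM are arbitrary. `relabelByEnrichment()` re-indexes
1..K along an activity scale: by descending fold-change enrichment in the
most-active label of a reference annotation, or by descending state mean of
a ranking track; ties break by larger coverage, then original index.

# Evaluation statistics

**Variance explained (VE).** For annotation $a_{1:n}$ and signal $s_{1:n}$,
each position is predicted by its label mean $\mu_{a_i}$ and
$\mathrm{VE} = 1 - \sum_i d_i^2 / \sum_i (s_i - \bar s)^2$ with
$d_i = s_i - \mu_{a_i}$; bounded in $[0, 1]$. The variance convention
cancels between numerator and denominator, so VE is convention-free.
Fewer than two usable bins, or a constant signal, is an error rather than a
silent 0/0.

**Gene expression VE.** Each gene takes the most frequent label among the
bins its interval overlaps (ties to the lowest label index; genes
overlapping only masked bins are dropped); expression is asinh-transformed
against outliers, and VE is computed *over genes*, not bins.

**Replication timing VE.** Six per-phase tracks at fine resolution are
coarsened to the working resolution by within-bin averaging; each bin's
phase vector is renormalized to sum to one (zero-mass bins excluded); VE is
computed per phase and averaged unweighted. A constant coarsened phase has
undefined VE and is excluded with a warning.

**Loop O/E enrichment.** Loop anchors map to the bin containing their
midpoint — anchors can span bin boundaries, and the midpoint rule is
deterministic and resolution-robust. With label coverage $C$ and unordered
label-pair counts $O$, the expectation under independent anchor placement
is $E_{kk} = \mathrm{totalO}\, C_k^2$ on the diagonal and
$2\,\mathrm{totalO}\, C_k C_l$ for an unordered pair $k < l$, so
$\sum E = \mathrm{totalO}$ exactly. The score is
$\sum_k O_{kk} / \sum_k E_{kk}$: how much more often than chance both loop
ends carry the same domain label. The unordered convention is this
package's choice; it is the one that conserves the total count.

**Overlap.** Fold-change $P(a{=}k_a, b{=}k_b) / (P(a{=}k_a) P(b{=}k_b))$
over jointly annotated bins, plus the adjusted Rand index (via mclust).

**Bootstrap SEs.** Per-bin statistics use a block bootstrap — contiguous
blocks of 10 bins (1 Mb at 100 kb) resampled with replacement to the
original length, respecting the strong spatial autocorrelation of genomic
signals. Gene and loop statistics resample their units i.i.d. The SE is the
standard deviation (denominator $n_{\mathrm{reps}} - 1$) of the replicate
statistics; if the statistic is undefined in more than 20% of replicates
the SE is an error. `bootstrapSE()` is exposed as a generic engine taking
any statistic function of a resampled index vector.

Welch t-tests comparing transformed expression between label pairs are
reported descriptively, without multiple-testing correction.

# The synthetic data generator

The generator exists so every stage — and the end-to-end claim that
combining layers beats either alone — is testable without downloads. Its
central design is a *factorized* truth: a Markov chain (self-transition
`stickiness = 0.9`, expected run 1 Mb at 100 kb) over combined states that
are the cross product of `nFunctional = 3` functional and
`nStructural = 2` structural factors. Functional factors drive the 1D
tracks and gene expression; structural factors drive the Hi-C affinity
matrix and loop co-membership. Each layer is invisible to the other's
assay by construction, which operationalizes "complementary information"
as a testable property: only the combined model can recover the full
cross-product states.

Contacts are Poisson with rate
$\mathrm{depth} \cdot d^{-1} \cdot \mathrm{affinity}[s_i, s_j]$ intra
(within-state affinity 3, between 1) and $0.01 \cdot \mathrm{depth}$ scaled
inter. Signals are per-state Gaussian means (sd `meanSeparation = 2`) plus
unit noise, exponentiated so tracks are non-negative and heavy-tailed like
coverage data. Genes are uniformly placed with lognormal lengths (median
30 kb) and lognormal expression around per-state means; loops draw both
anchors from one structural state's bins with probability
`sameStateFraction = 0.9`. The default scale is 2 chromosomes × 500 bins
(100 Mb): small enough for fast tests, large enough for recovery.

What the generator does **not** emulate: restriction-fragment artifacts,
copy-number effects, translocations, TAD/loop microstructure, or count
overdispersion (Poisson only). Passing tests therefore demonstrate the
machinery is correct under the stated generative assumptions, not that any
particular biological dataset will yield the same margins.

# Numerical choices and caveats

* Softmax and forward–backward computations subtract per-row maxima;
  forward recursions are rescaled per position, so likelihoods are exact in
  log space.
* The gradient of the exact objective is available in closed form and is
  verified against central finite differences on small graphs at relative
  error below $10^{-5}$.
* Degenerate inputs error loudly: isolated nodes at training, empty states
  after one re-seed, constant signals in VE, chromosomes with zero contacts
  (masked with a warning).
* **In-sample VE is biased upward.** An annotation fitted to a set of
  tracks explains part of their variance even when the tracks are pure
  noise — clustering exists to explain variance. Null calibration in the
  test suite therefore scores annotations only against signals they are
  independent of (planted truths against separation-free tracks, fitted
  annotations against fresh noise draws, equal-mean gene expression,
  independent loop anchors); all such VEs are below 0.02 at 10,000 bins and
  loop enrichment stays within 1 ± 0.15.
* Test problem sizes are the package's defaults: 1000-bin factorized
  simulations (5 seeds) for the integration comparison, 200-node planted
  graphs (10 seeds) for embedding recovery, 3000-bin chains for HMM
  parameter recovery, 10,000 bins for null calibration.

# Known limitations

* Input matrices come as cooler-style sparse triplet text; binary cooler
  (HDF5) containers are not read directly — export the triplets first.
* No ICE/KR balancing, significant-interaction calling, TAD or loop
  calling: the O/E graph is built from raw (optionally pre-balanced)
  counts.
* Duration modeling is geometric (plain HMM); semi-Markov duration models
  and hierarchical/multi-scale extensions are out of scope.
* The trainer is single-threaded by design; wall-clock scaling relies on
  the alias-table sampler, which is linear in the number of draws.
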