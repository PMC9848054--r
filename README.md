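# HiCdomains

Integrative annotation of chromatin domain types from Hi-C and 1D functional
genomic signals.

Chromatin organization has two distinguishable megabase-scale layers: a
*functional* layer visible in 1D assays (histone-modification ChIP-seq,
DNase-seq) and a *structural* layer visible in Hi-C as compartments and
subcompartments — groups of bins with similar genome-wide interaction
profiles. The two layers carry complementary information, so HiCdomains
infers *combinatorial* domain types from both at once:

1. **O/E graph.** Binned Hi-C counts become a weighted graph whose edges are
   observed/expected contact enrichments (distance-stratified expectation
   per chromosome intra, a global mean inter; low-coverage bins masked).
2. **Structural embedding.** Each bin is embedded into a low-dimensional
   space (default 8) by minimizing the second-order-proximity objective

   *O*₂ = −Σ₍ᵢ,ⱼ₎∈E *w*ᵢⱼ log *p*₂(*v*ⱼ | *v*ᵢ),  *p*₂(*v*ⱼ | *v*ᵢ) = exp(*u*′ⱼᵀ*u*ᵢ) / Σₖ exp(*u*′ₖᵀ*u*ᵢ),

   trained by weight-proportional edge sampling with negative sampling
   (5 noise nodes ∝ degree^0.75), so bins with similar interaction profiles
   land close together even if they rarely touch.
3. **SAGA HMM.** The embedding features and the binned (asinh + z-scored)
   functional tracks feed one Gaussian-emission hidden Markov model
   (Baum–Welch, Viterbi decoding; GMM baseline included). Functional-only
   and structural-only runs give the single-layer baselines.
4. **Evaluation.** Variance explained (VE) for arbitrary per-bin signals,
   gene expression (majority-label gene assignment, asinh transform) and
   6-phase replication timing; ChIA-PET loop observed/expected enrichment
   (E₍ᵢⱼ₎ = totalO·Cᵢ·Cⱼ); fold-change overlap matrices and adjusted Rand
   index; block/resampling bootstrap standard errors.

A fully synthetic data generator plants factorized functional × structural
domain states and emits every input the pipeline reads (contacts, bedGraph
tracks, genes, loops), so the whole method is testable end to end without
downloads.

## Worked example

```r
library(HiCdomains)

## synthetic genome: 2 chromosomes x 500 bins at 100 kb,
## 3 functional x 2 structural planted states
sim <- simulateDataset(chromLengths = c(chrA = 5e7, chrB = 5e7), seed = 7)

mask  <- filterBins(sim$contacts, sim$genome)
graph <- computeOE(sim$contacts, sim$genome, mask)
graph
#> ContactGraph: 1000 nodes, 88957 edges (O/E weighted) over 1000 bins

emb    <- trainEmbedding(graph, trainConfig(seed = 7))
struct <- exportFeatures(emb, sim$genome)
hm     <- harmonizeMasks(sim$signals, struct)
ann    <- annotateDomains(functional = hm[[1]], structural = hm[[2]],
                          genome = sim$genome, K = 6, seed = 7)
ann
#> DomainAnnotation: 6 domain types over 1000 bins ( 1000 annotated )
#>   coverage: 1:0.175 2:0.217 3:0.174 4:0.129 5:0.164 6:0.141

rep <- evaluateAnnotation(ann, sim$genome, signals = sim$signals,
                          genes = sim$genes, loops = list(ctcf = sim$loops))
rep$geneExpressionVE   # 0.854 : domain labels explain 85% of expression variance
rep$loopOE$ctcf        # 1.943 : same-label loops ~2x over coverage expectation
rep$domainLengths$meanBp  # 1075269 : ~1.1 Mb mean domain length

annotationOverlap(ann, makeAnnotation(sim$truth@combined))$ari
#> 1 : the combined model recovers the planted 6 cross-product states exactly
```

The gene-expression VE says the six labels capture most of the planted
expression differences; the loop OE score near 2 reflects that loops prefer
anchors in the same structural state; the ARI of 1 shows the combined model
resolving states that neither the functional-only nor the structural-only
baseline can fully separate (each sees only its own factor).

A command-line wrapper with `simulate`, `graph`, `embed`, `annotate`,
`evaluate` and `pipeline` subcommands is installed at
`inst/scripts/hicdomains` (see `cliMain()`); stages exchange plain files
(triplet contacts, edge lists, TSV features, BED annotations, JSON reports)
and every run writes its resolved configuration next to its outputs.

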