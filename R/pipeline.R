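#' Run the full annotation workflow
#'
#' Chains the stages: Hi-C bin filtering, O/E graph construction, structural
#' embedding, combined-feature HMM annotation, evaluation. Functional and
#' structural masks are harmonized (intersected) before model fitting so all
#' matrices stay aligned.
#'
#' @param contacts a \linkS4class{RawContacts}
#' @param signals a functional-signal \linkS4class{FeatureMatrix}
#' @param genome the \linkS4class{BinnedGenome}
#' @param K number of domain types (default 8)
#' @param seed master seed for embedding and HMM initialization
#' @param mode "combined" (default), "functional" or "structural"
#' @param embedDim embedding dimension (default 8)
#' @param oeThreshold O/E edge threshold (default 1.0)
#' @param genes,rt,loops optional evaluation inputs passed to
#'   \code{\link{evaluateAnnotation}}
#' @param samples embedding sample count override (NULL = auto)
#' @return list with graph, embedding model, structural features, annotation
#'   and evaluation report
#' @export
runPipeline <- function(contacts, signals, genome, K = 8L, seed = 1L,
                        mode = c("combined", "functional", "structural"),
                        embedDim = 8L, oeThreshold = 1.0,
                        genes = NULL, rt = NULL, loops = NULL,
                        samples = NULL) {
    mode <- match.arg(mode)
    graph <- NULL; model <- NULL; structural <- NULL
    if (mode != "functional") {
        mask <- filterBins(contacts, genome)
        graph <- computeOE(contacts, genome, mask, threshold = oeThreshold)
        model <- trainEmbedding(graph, trainConfig(dim = embedDim, seed = seed,
                                                   samples = samples))
        structural <- exportFeatures(model, genome)
    }
    if (mode == "combined") {
        hm <- harmonizeMasks(signals, structural)
        ann <- annotateDomains(functional = hm[[1]], structural = hm[[2]],
                               genome = genome, K = K, seed = seed)
    } else if (mode == "functional") {
        ann <- annotateDomains(functional = signals, genome = genome, K = K,
                               seed = seed)
    } else {
        ann <- annotateDomains(structural = structural, genome = genome, K = K,
                               seed = seed)
    }
    report <- evaluateAnnotation(ann, genome, signals = signals, genes = genes,
                                 rt = rt, loops = loops)
    list(graph = graph, embedding = model, structural = structural,
         annotation = ann, report = report)
}
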