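#' Preprocess feature tracks for model fitting
#'
#' Per track: optionally the inverse hyperbolic sine \code{ln(x + sqrt(x^2 +
#' 1))} (tames heavy-tailed signal values), then centering and scaling by the
#' mean and population standard deviation (denominator n) computed over
#' unmasked bins. Zero-variance tracks are dropped with a warning. The
#' constants are stored in the result's \code{preproc} record so decode-time
#' inputs can be transformed identically.
#'
#' @param fm a \linkS4class{FeatureMatrix}
#' @param transform "asinh_zscore" (default for functional signal tracks),
#'   "zscore" (default for embedding features) or "none"
#' @return a preprocessed \linkS4class{FeatureMatrix}
#' @export
preprocessFeatures <- function(fm, transform = c("asinh_zscore", "zscore", "none")) {
    transform <- match.arg(transform)
    X <- fm@values
    if (transform == "asinh_zscore") X <- asinh(X)
    if (transform == "none") {
        return(new("FeatureMatrix", values = X, noData = fm@noData, mask = fm@mask,
                   preproc = list(transform = "none",
                                  center = rep(0, ncol(X)), scale = rep(1, ncol(X)),
                                  tracks = colnames(X))))
    }
    sub <- X[fm@mask, , drop = FALSE]
    ctr <- colMeans(sub)
    n <- nrow(sub)
    scl <- sqrt(colMeans(sweep(sub, 2, ctr)^2))
    keep <- scl > 0
    if (!all(keep))
        warning("dropping zero-variance track(s): ",
                paste(colnames(X)[!keep], collapse = ", "))
    X <- sweep(sweep(X[, keep, drop = FALSE], 2, ctr[keep]), 2, scl[keep], "/")
    new("FeatureMatrix", values = X, noData = fm@noData[, keep, drop = FALSE],
        mask = fm@mask,
        preproc = list(transform = transform, center = ctr[keep],
                       scale = scl[keep], tracks = colnames(X)))
}

#' Apply a stored preprocessing record to raw features
#' @param fm a raw \linkS4class{FeatureMatrix}
#' @param preproc a preprocessing record from a fitted model or
#'   \code{\link{preprocessFeatures}} result
#' @return the transformed \linkS4class{FeatureMatrix}
#' @export
applyPreprocess <- function(fm, preproc) {
    X <- fm@values[, preproc$tracks, drop = FALSE]
    if (preproc$transform == "asinh_zscore") X <- asinh(X)
    if (preproc$transform != "none")
        X <- sweep(sweep(X, 2, preproc$center), 2, preproc$scale, "/")
    new("FeatureMatrix", values = X,
        noData = fm@noData[, preproc$tracks, drop = FALSE],
        mask = fm@mask, preproc = preproc)
}

## contiguous unmasked runs within chromosomes = independent HMM sequences
.sequenceRuns <- function(genome, mask) {
    chrom <- as.integer(.binChrom(genome))
    n <- length(mask)
    brk <- c(TRUE, chrom[-1] != chrom[-n])
    seqId <- cumsum(brk | !mask)
    out <- split(seq_len(n)[mask], seqId[mask])
    out[lengths(out) > 0]
}

## log emission densities: list with n x K state log-density matrix and,
## for M > 1, the per-component n x K x M array
.emissionLogDens <- function(X, model) {
    n <- nrow(X); K <- model@K; M <- model@M; D <- ncol(X)
    comp <- array(0, c(n, K, M))
    for (k in seq_len(K)) for (m in seq_len(M)) {
        mu <- model@means[k, m, ]; v <- model@vars[k, m, ]
        q <- sweep(X, 2, mu)
        comp[, k, m] <- -0.5 * sum(log(2 * pi * v)) -
            0.5 * rowSums(sweep(q^2, 2, v, "/")) + log(model@mixWeights[k, m])
    }
    if (M == 1L) {
        list(state = matrix(comp[, , 1L], nrow = n, ncol = K), comp = comp)
    } else {
        mx <- apply(comp, c(1, 2), max)
        state <- mx + log(apply(exp(sweep(comp, c(1, 2), mx)), c(1, 2), sum))
        list(state = state, comp = comp)
    }
}

## scaled forward-backward for one sequence; emission B = n x K density
## matrix in log space. Returns gamma, xi sum, log-likelihood.
.forwardBackward <- function(logB, initProb, transMat) {
    n <- nrow(logB); K <- ncol(logB)
    off <- apply(logB, 1, max)
    B <- exp(logB - off)
    alpha <- matrix(0, n, K); beta <- matrix(0, n, K)
    cvec <- numeric(n)
    a <- initProb * B[1, ]
    cvec[1] <- sum(a); alpha[1, ] <- a / cvec[1]
    if (n > 1) for (t in 2:n) {
        a <- (alpha[t - 1, ] %*% transMat) * B[t, ]
        cvec[t] <- sum(a); alpha[t, ] <- a / cvec[t]
    }
    beta[n, ] <- 1
    if (n > 1) for (t in (n - 1):1)
        beta[t, ] <- (transMat %*% (B[t + 1, ] * beta[t + 1, ])) / cvec[t + 1]
    gamma <- alpha * beta
    gamma <- gamma / rowSums(gamma)
    xi <- matrix(0, K, K)
    if (n > 1) for (t in 1:(n - 1)) {
        x <- transMat * outer(alpha[t, ], B[t + 1, ] * beta[t + 1, ]) / cvec[t + 1]
        xi <- xi + x
    }
    list(gamma = gamma, xi = xi, logLik = sum(log(cvec)) + sum(off))
}

## initialization from k-means labels (shared by GMM and HMM)
.initModel <- function(X, K, M, seed, type, varFloor) {
    set.seed(seed)
    n <- nrow(X); D <- ncol(X)
    km <- kmeans(X, centers = K, nstart = 5, iter.max = 50)
    lab <- km$cluster
    means <- array(0, c(K, M, D)); vars <- array(1, c(K, M, D))
    mixW <- matrix(1 / M, K, M)
    for (k in seq_len(K)) {
        idx <- which(lab == k)
        Xi <- X[idx, , drop = FALSE]
        v <- pmax(colMeans(sweep(Xi, 2, colMeans(Xi))^2), varFloor)
        if (M == 1L) {
            means[k, 1, ] <- colMeans(Xi); vars[k, 1, ] <- v
        } else {
            ## split the cluster again for the mixture components
            km2 <- if (length(idx) >= M * 2) kmeans(Xi, centers = M, nstart = 3)
                   else NULL
            for (m in seq_len(M)) {
                means[k, m, ] <- if (!is.null(km2)) km2$centers[m, ]
                                 else colMeans(Xi) + rnorm(D, sd = 0.1)
                vars[k, m, ] <- v
            }
        }
    }
    initProb <- (tabulate(lab, K) + 1) / (n + K)
    trans <- matrix(1, K, K)
    if (type == "hmm" && n > 1) {
        for (t in 2:n) trans[lab[t - 1], lab[t]] <- trans[lab[t - 1], lab[t]] + 1
    }
    trans <- trans / rowSums(trans)
    new("HmmModel", K = as.integer(K), M = as.integer(M), type = type,
        initProb = initProb, transMat = trans, mixWeights = mixW,
        means = means, vars = vars, preproc = list(), logLik = -Inf,
        seed = as.integer(seed))
}

## shared EM driver; type "gmm" treats bins as independent draws
.fitEM <- function(features, genome, K, seed, type, M, maxIter, tol, varFloor) {
    stopifnot(K >= 1)
    mask <- features@mask
    if (sum(mask) < 10 * K)
        stop("need at least 10 x K unmasked bins to fit ", type)
    Xall <- features@values
    runs <- if (type == "hmm") .sequenceRuns(genome, mask)
            else list(which(mask))
    X <- Xall[mask, , drop = FALSE]
    model <- .initModel(X, K, M, seed, type, varFloor)
    model@preproc <- features@preproc
    history <- numeric(0)
    reseeded <- FALSE
    for (iter in seq_len(maxIter)) {
        gammaAll <- vector("list", length(runs))
        xiSum <- matrix(0, K, K); ll <- 0
        startMass <- numeric(K)
        for (s in seq_along(runs)) {
            idx <- runs[[s]]
            em <- .emissionLogDens(Xall[idx, , drop = FALSE], model)
            if (type == "hmm") {
                fb <- .forwardBackward(em$state, model@initProb, model@transMat)
                gammaAll[[s]] <- fb$gamma
                xiSum <- xiSum + fb$xi
                ll <- ll + fb$logLik
                startMass <- startMass + fb$gamma[1, ]
            } else {
                lp <- sweep(em$state, 2, log(model@initProb), "+")
                mx <- apply(lp, 1, max)
                p <- exp(lp - mx)
                rs <- rowSums(p)
                gammaAll[[s]] <- p / rs
                ll <- ll + sum(log(rs) + mx)
            }
        }
        if (!is.finite(ll))
            stop(type, " EM diverged (non-finite likelihood) at iteration ", iter)
        history <- c(history, ll)
        gamma <- do.call(rbind, gammaAll)
        Xcat <- Xall[unlist(runs), , drop = FALSE]
        colMass <- colSums(gamma)
        empty <- which(colMass < 1e-8)
        if (length(empty)) {
            if (reseeded) stop("empty state persisted after one re-seeding")
            reseeded <- TRUE
            donor <- which.max(apply(model@vars, 1, sum))
            for (k in empty) {
                model@means[k, , ] <- model@means[donor, , ] +
                    rnorm(length(model@means[donor, , ]), sd = 0.5)
                model@vars[k, , ] <- model@vars[donor, , ]
            }
            next
        }
        ## M step (component densities evaluated at the pre-update parameters)
        emAll <- if (M > 1L) .emissionLogDens(Xcat, model) else NULL
        for (k in seq_len(K)) {
            if (M == 1L) {
                g <- gamma[, k]
                mu <- colSums(g * Xcat) / colMass[k]
                v <- colSums(g * sweep(Xcat, 2, mu)^2) / colMass[k]
                model@means[k, 1, ] <- mu
                model@vars[k, 1, ] <- pmax(v, varFloor)
            } else {
                cl <- emAll$comp[, k, ]              # n x M (log, incl weights)
                mxc <- apply(cl, 1, max)
                r <- exp(cl - mxc); r <- r / rowSums(r)
                r <- r * gamma[, k]
                cm <- colSums(r)
                model@mixWeights[k, ] <- cm / sum(cm)
                for (m in seq_len(M)) {
                    mu <- colSums(r[, m] * Xcat) / cm[m]
                    v <- colSums(r[, m] * sweep(Xcat, 2, mu)^2) / cm[m]
                    model@means[k, m, ] <- mu
                    model@vars[k, m, ] <- pmax(v, varFloor)
                }
            }
        }
        if (type == "hmm") {
            model@initProb <- startMass / sum(startMass)
            rs <- rowSums(xiSum)
            ok <- rs > 0
            model@transMat[ok, ] <- xiSum[ok, ] / rs[ok]
        } else {
            model@initProb <- colMass / sum(colMass)
        }
        nh <- length(history)
        if (nh >= 2 &&
            (history[nh] - history[nh - 1]) < tol * abs(history[nh - 1])) break
    }
    model@logLik <- history
    model
}

#' Fit a Gaussian mixture model (GMM) annotation model
#'
#' The simplest segmentation-and-annotation model: bins are independent draws
#' from a K-component diagonal-covariance Gaussian mixture. EM from a seeded
#' k-means initialization; stops when the relative log-likelihood improvement
#' drops below \code{tol} or after \code{maxIter} iterations.
#'
#' @param features a preprocessed \linkS4class{FeatureMatrix}
#' @param genome the \linkS4class{BinnedGenome}
#' @param K number of domain types
#' @param seed initialization seed
#' @param M Gaussian components per state (default 1)
#' @param maxIter,tol,varFloor EM controls
#' @return a fitted \linkS4class{HmmModel} with \code{type = "gmm"}; the
#'   \code{logLik} slot holds the full per-iteration log-likelihood history
#' @export
fitGMM <- function(features, genome, K, seed = 1L, M = 1L, maxIter = 500L,
                   tol = 1e-4, varFloor = 1e-3) {
    .fitEM(features, genome, K, seed, "gmm", M, maxIter, tol, varFloor)
}

#' Fit a Gaussian-emission hidden Markov model
#'
#' Baum-Welch EM with each chromosome (split further at masked bins) treated
#' as an independent observation sequence. Initialization from seeded
#' k-means; diagonal covariances with a variance floor; an empty state is
#' re-seeded once from the highest-variance state.
#'
#' @inheritParams fitGMM
#' @param restarts number of EM runs with seeds \code{seed, seed+1, ...};
#'   the best final log-likelihood wins, ties by seed order
#' @return a fitted \linkS4class{HmmModel} with \code{type = "hmm"}
#' @export
fitHMM <- function(features, genome, K, seed = 1L, M = 1L, maxIter = 500L,
                   tol = 1e-4, varFloor = 1e-3, restarts = 1L) {
    fits <- lapply(seq_len(restarts) - 1L, function(r)
        .fitEM(features, genome, K, seed + r, "hmm", M, maxIter, tol, varFloor))
    finals <- vapply(fits, function(f) tail(f@logLik, 1), numeric(1))
    fits[[which.max(finals)]]
}

#' Decode per-bin domain labels
#'
#' Viterbi path per chromosome sequence for an HMM (deterministic given model
#' and features); maximum-posterior labels for a GMM. Features are brought
#' onto the model's preprocessing scale using its stored constants if they are
#' still raw.
#'
#' @param model a fitted \linkS4class{HmmModel}
#' @param features a \linkS4class{FeatureMatrix} over the same genome
#' @param genome the \linkS4class{BinnedGenome}
#' @return a \linkS4class{DomainAnnotation}
#' @export
decodeAnnotation <- function(model, features, genome) {
    if (!length(features@preproc) && length(model@preproc))
        features <- applyPreprocess(features, model@preproc)
    if (ncol(features@values) != dim(model@means)[3])
        stop("feature dimension mismatch: model expects ", dim(model@means)[3],
             " tracks, got ", ncol(features@values))
    mask <- features@mask
    labels <- rep(NA_integer_, length(mask))
    K <- model@K
    if (model@type == "gmm") {
        idx <- which(mask)
        em <- .emissionLogDens(features@values[idx, , drop = FALSE], model)
        lp <- sweep(em$state, 2, log(model@initProb), "+")
        labels[idx] <- max.col(lp, ties.method = "first")
    } else {
        runs <- .sequenceRuns(genome, mask)
        logA <- log(model@transMat)
        for (idx in runs) {
            em <- .emissionLogDens(features@values[idx, , drop = FALSE], model)
            logB <- em$state
            n <- nrow(logB)
            delta <- matrix(-Inf, n, K); psi <- matrix(0L, n, K)
            delta[1, ] <- log(model@initProb) + logB[1, ]
            if (n > 1) for (t in 2:n) {
                cand <- delta[t - 1, ] + logA       # K x K
                psi[t, ] <- max.col(t(cand), ties.method = "first")
                delta[t, ] <- cand[cbind(psi[t, ], seq_len(K))] + logB[t, ]
            }
            path <- integer(n)
            path[n] <- which.max(delta[n, ])
            if (n > 1) for (t in (n - 1):1) path[t] <- psi[t + 1, path[t + 1]]
            labels[idx] <- path
        }
    }
    new("DomainAnnotation", labels = labels, K = K,
        meta = list(type = model@type, seed = model@seed))
}

## column-bind two feature matrices sharing a mask
.cbindFeatures <- function(a, b) {
    new("FeatureMatrix", values = cbind(a@values, b@values),
        noData = cbind(a@noData, b@noData), mask = a@mask & b@mask,
        preproc = list(transform = "mixed",
                       center = c(a@preproc$center, b@preproc$center),
                       scale = c(a@preproc$scale, b@preproc$scale),
                       tracks = c(a@preproc$tracks, b@preproc$tracks),
                       parts = list(a@preproc, b@preproc)))
}

#' Annotate domains from functional and/or structural features
#'
#' Preprocesses the inputs (functional tracks: asinh + z-score; structural
#' embedding features: z-score), concatenates them when both are given, fits
#' a Gaussian-emission HMM and decodes the Viterbi labels. With only
#' functional input this is the functional-only baseline; with only structural
#' input the structural-only baseline; with both, the combined model.
#'
#' @param functional raw functional-signal \linkS4class{FeatureMatrix}, or NULL
#' @param structural structural-feature \linkS4class{FeatureMatrix}, or NULL
#' @param genome the \linkS4class{BinnedGenome}
#' @param K number of domain types
#' @param seed initialization seed
#' @param M mixture components per state
#' @param restarts EM restarts (best likelihood wins)
#' @return a \linkS4class{DomainAnnotation}; the fitted model and mode are in
#'   its \code{meta} list
#' @export
annotateDomains <- function(functional = NULL, structural = NULL, genome,
                            K, seed = 1L, M = 1L, restarts = 1L) {
    if (is.null(functional) && is.null(structural))
        stop("at least one of functional/structural features is required")
    if (!is.null(functional) && !is.null(structural)) {
        if (!identical(functional@mask, structural@mask))
            stop("mask disagreement between functional and structural features; ",
                 "harmonize masks (e.g. with harmonizeMasks()) first")
        mode <- "combined"
        feat <- .cbindFeatures(preprocessFeatures(functional, "asinh_zscore"),
                               preprocessFeatures(structural, "zscore"))
    } else if (!is.null(functional)) {
        mode <- "functional"
        feat <- preprocessFeatures(functional, "asinh_zscore")
    } else {
        mode <- "structural"
        feat <- preprocessFeatures(structural, "zscore")
    }
    model <- fitHMM(feat, genome, K, seed = seed, M = M, restarts = restarts)
    ann <- decodeAnnotation(model, feat, genome)
    ann@meta <- c(ann@meta, list(mode = mode, model = model))
    ann
}

#' Restrict feature matrices to a common usable-bin mask
#' @param ... FeatureMatrix objects over the same genome
#' @return list of the inputs with their masks intersected
#' @export
harmonizeMasks <- function(...) {
    fms <- list(...)
    common <- Reduce(`&`, lapply(fms, function(f) f@mask))
    lapply(fms, function(f) {
        f@mask <- common
        f
    })
}

#' Re-index domain labels by enrichment
#'
#' Orders states 1..K so that label numbers follow an activity scale: with a
#' reference annotation (whose own label 1 is the most active), states are
#' ranked by descending fold-change enrichment in that most-active reference
#' label; with a numeric ranking track, by descending state mean of the
#' track. Ties break by larger coverage, then original index.
#'
#' @param annotation a \linkS4class{DomainAnnotation}
#' @param reference a \linkS4class{DomainAnnotation} with an ordered label
#'   scale, or a per-bin numeric ranking track
#' @return the relabeled \linkS4class{DomainAnnotation}
#' @export
relabelByEnrichment <- function(annotation, reference) {
    K <- annotation@K
    lab <- annotation@labels
    cov <- labelCoverage(annotation)
    if (is(reference, "DomainAnnotation")) {
        joint <- !is.na(lab) & !is.na(reference@labels)
        if (sum(joint) < 0.5 * sum(!is.na(lab)))
            warning("reference covers less than half of the annotated bins")
        a <- lab[joint]; b <- reference@labels[joint]
        pA <- tabulate(a, K) / length(a)
        pB1 <- mean(b == 1L)
        pJ <- vapply(seq_len(K), function(k) mean(a == k & b == 1L), numeric(1))
        score <- ifelse(pA > 0 & pB1 > 0, pJ / (pA * pB1), 0)
    } else {
        score <- vapply(seq_len(K), function(k)
            mean(reference[!is.na(lab) & lab == k]), numeric(1))
        score[is.nan(score)] <- -Inf
    }
    ord <- order(-score, -cov, seq_len(K))
    remap <- integer(K)
    remap[ord] <- seq_len(K)
    newLab <- ifelse(is.na(lab), NA_integer_, remap[lab])
    new("DomainAnnotation", labels = as.integer(newLab), K = K,
        meta = c(annotation@meta, list(relabelMap = remap)))
}
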