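#' Construct a synthetic benchmark specification
#'
#' Defaults are the benchmark's study conditions: \code{N = 1000} features,
#' \code{N1 = 10} common signal features, \code{M = 10} ordered samples,
#' \code{K = 3} omics slices, 100 ensembles.
#'
#' @param N,N1,M,K tensor dimensions, see [SyntheticSpec-class].
#' @param nEnsembles number of replicate datasets.
#' @param baseSeed ensemble \code{e} is generated with seed
#'   \code{baseSeed + e}.
#' @param amplitude multiplier on the covariate added to signal features
#'   (0 = pure-noise null).
#' @return a [SyntheticSpec-class].
#' @export
SyntheticSpec <- function(N = 1000, N1 = 10, M = 10, K = 3,
                          nEnsembles = 100, baseSeed = 0, amplitude = 1) {
    new("SyntheticSpec", N = as.integer(N), N1 = as.integer(N1),
        M = as.integer(M), K = as.integer(K),
        nEnsembles = as.integer(nEnsembles), baseSeed = as.integer(baseSeed),
        amplitude = as.numeric(amplitude))
}

setMethod("show", "SyntheticSpec", function(object) {
    cat(sprintf(
        "SyntheticSpec: N=%d, N1=%d, M=%d, K=%d, %d ensemble(s), baseSeed=%d, amplitude=%g\n",
        object@N, object@N1, object@M, object@K, object@nEnsembles,
        object@baseSeed, object@amplitude))
})

#' Monotone sample covariate of the synthetic benchmark
#'
#' \code{a_j = 1 + (M - 1) * j / M} for \code{j = 1, ..., M}.
#'
#' @param M number of samples.
#' @return numeric vector of length \code{M}.
#' @export
syntheticCovariate <- function(M) 1 + (M - 1) * seq_len(M) / M

#' Generate one ensemble of the synthetic multi-omics tensor
#'
#' Every entry is i.i.d. Uniform(0, 1) noise; on top of it the monotone
#' covariate \code{a_j} (times \code{amplitude}) is added to feature \code{i}
#' in slice \code{k} when \code{i <= N1} (common signal, present in every
#' slice) or \code{k*N1 < i <= (k+1)*N1} (signal specific to slice \code{k}),
#' so each slice carries exactly \code{2*N1} signal features. The RNG is
#' seeded with \code{baseSeed + ensemble}, making ensembles independent and
#' reproducible.
#'
#' @param spec a [SyntheticSpec-class].
#' @param ensemble ensemble index (1-based).
#' @return list with \code{x} (array \code{N x M x K}), \code{a} (covariate),
#'   \code{commonMask} (logical, the \code{N1} common signal features) and
#'   \code{omicsMasks} (list of per-slice logical masks over the \code{2*N1}
#'   signal features of each slice).
#' @export
generateSynthetic <- function(spec, ensemble = 1L) {
    stopifnot(is(spec, "SyntheticSpec"))
    validObject(spec)
    N <- spec@N; N1 <- spec@N1; M <- spec@M; K <- spec@K
    set.seed(spec@baseSeed + as.integer(ensemble))
    x <- array(stats::runif(N * M * K), dim = c(N, M, K))
    a <- spec@amplitude * syntheticCovariate(M)
    commonMask <- seq_len(N) <= N1
    omicsMasks <- vector("list", K)
    for (k in seq_len(K)) {
        specific <- seq_len(N) > k * N1 & seq_len(N) <= (k + 1L) * N1
        mask <- commonMask | specific
        omicsMasks[[k]] <- mask
        x[mask, , k] <- x[mask, , k] +
            matrix(a, nrow = sum(mask), ncol = M, byrow = TRUE)
    }
    list(x = x, a = syntheticCovariate(M), commonMask = commonMask,
        omicsMasks = omicsMasks)
}

#' Run the full KTD feature-extraction pipeline on a synthetic tensor
#'
#' Linear kernel per slice, stacked to \code{K x M x M}, HOSVD, automatic
#' axis choice (sample mode: largest \code{|r|} with the covariate; omics
#' mode: most constant), shared-feature projection, chi-squared P with one
#' degree of freedom using the pooled root-mean-square sigma, BH adjustment
#' and selection at the threshold.
#'
#' @param x numeric array \code{N x M x K}.
#' @param a numeric covariate of length \code{M}.
#' @param threshold adjusted-P selection threshold.
#' @param pinSample,pinOmics optional pinned \code{l} indices (bypass the
#'   automatic ranking).
#' @return list with \code{scores}, \code{pValue}, \code{adjustedP},
#'   \code{selected} (logical), \code{choice} (the [AxisChoice-class]),
#'   \code{sigma} and \code{hosvd} (the [HOSVDResult-class]).
#' @export
runKTDPipeline <- function(x, a, threshold = 0.01, pinSample = NULL,
                           pinOmics = NULL) {
    d <- dim(x)
    if (length(d) != 3L) stop("x must be a feature x sample x omics array")
    N <- d[1L]; M <- d[2L]; K <- d[3L]
    blks <- lapply(seq_len(K), function(k) {
        MultiOmicsBlock(x[, , k, drop = FALSE][, , 1L],
            omicsId = paste0("k", k))
    })
    kt <- stackKernels(MultiOmicsTensorSet(blks))
    h <- hosvd(kt)
    choice <- chooseAxes(h, hypotheses = list(a),
        pinSample = pinSample, pinOmics = pinOmics)
    scores <- projectFeaturesShared(x, h, choice)
    sigma <- estimateSigma(scores)
    p <- chi2Pvalues(scores, sigma, df = 1)
    q <- bhAdjust(p)
    list(scores = scores, pValue = p, adjustedP = q,
        selected = q <= threshold, choice = choice, sigma = sigma, hosvd = h)
}

# vectorized per-feature OLS of x on a: slope t-test (closed-form normal
# equations; per-feature lm() calls are impractical at N*K fits per ensemble)
.olsSlopeP <- function(xmat, a) {
    M <- length(a)
    if (M < 3L) stop("need M >= 3 for a slope test")
    sa <- a - mean(a)
    saa <- sum(sa^2)
    if (saa == 0) stop("zero-variance regressor")
    xc <- sweep(xmat, 1L, rowMeans(xmat))
    slope <- as.vector(xc %*% sa) / saa
    intercept <- rowMeans(xmat) - slope * mean(a)
    fitted <- outer(slope, a) + intercept
    rss <- rowSums((xmat - fitted)^2)
    se <- sqrt(pmax(rss / (M - 2L), 0) / saa)
    tstat <- ifelse(se > 0, slope / se, ifelse(slope == 0, 0, Inf))
    p <- 2 * stats::pt(abs(tstat), df = M - 2L, lower.tail = FALSE)
    list(slope = slope, intercept = intercept, t = tstat, p = p)
}

#' Per-feature linear-regression baseline
#'
#' Ordinary least squares \code{x[i, j, k] = alpha * a_j + beta} fitted
#' independently for every feature and omics slice; the two-sided slope
#' P-values are BH-adjusted within each slice and features with adjusted
#' \code{P <= threshold} are selected.
#'
#' @param x numeric array \code{N x M x K}.
#' @param a numeric covariate of length \code{M}.
#' @param threshold adjusted-P selection threshold.
#' @return list with one element per slice: data.frame with \code{slope},
#'   \code{pValue}, \code{adjustedP}, \code{selected}.
#' @export
regressionBaseline <- function(x, a, threshold = 0.01) {
    d <- dim(x)
    lapply(seq_len(d[3L]), function(k) {
        fit <- .olsSlopeP(matrix(x[, , k], nrow = d[1L]), a)
        q <- bhAdjust(fit$p)
        data.frame(slope = fit$slope, pValue = fit$p, adjustedP = q,
            selected = q <= threshold)
    })
}

#' Lasso baseline
#'
#' Per omics slice, fits the L1 regularization path of the covariate on the
#' \code{M x N} feature design (geometric grid of \code{nlambda} penalties
#' down to \code{lambdaMinRatio} of the maximal penalty) and returns the
#' support of the path solution with the most nonzero coefficients among
#' solutions whose support does not exceed \code{M}, the largest support a
#' lasso fit on \code{M} samples can attain.
#'
#' @param x numeric array \code{N x M x K}.
#' @param a numeric covariate of length \code{M}.
#' @param nlambda,lambdaMinRatio path grid parameters.
#' @return list with one integer vector of selected feature indices per slice.
#' @export
lassoBaseline <- function(x, a, nlambda = 100L, lambdaMinRatio = 1e-4) {
    d <- dim(x)
    M <- d[2L]
    lapply(seq_len(d[3L]), function(k) {
        fit <- glmnet::glmnet(t(x[, , k]), a, alpha = 1,
            nlambda = nlambda, lambda.min.ratio = lambdaMinRatio)
        ok <- which(fit$df <= M)
        if (!length(ok)) return(integer())
        best <- ok[which.max(fit$df[ok])]
        which(as.vector(fit$beta[, best]) != 0)
    })
}

#' Random-forest baseline
#'
#' Per omics slice, fits a regression forest of the covariate on the
#' \code{M x N} feature design and selects either all features with positive
#' impurity importance (\code{mode = "nonzero"}) or the \code{2*N1} features
#' with the largest absolute importance (\code{mode = "top2N1"}).
#'
#' @param x numeric array \code{N x M x K}.
#' @param a numeric covariate of length \code{M}.
#' @param mode selection rule, see above.
#' @param N1 signal-block size (needed for \code{"top2N1"}).
#' @param numTrees forest size.
#' @param seed RNG seed forwarded to the forest.
#' @return list with one integer vector of selected feature indices per slice.
#' @export
rfBaseline <- function(x, a, mode = c("nonzero", "top2N1"), N1 = 10L,
                       numTrees = 500L, seed = 1L) {
    mode <- match.arg(mode)
    d <- dim(x)
    lapply(seq_len(d[3L]), function(k) {
        X <- t(x[, , k])
        colnames(X) <- paste0("f", seq_len(ncol(X)))
        fit <- ranger::ranger(x = X, y = a, importance = "impurity",
            num.trees = numTrees, seed = seed + k, num.threads = 1L)
        imp <- fit$variable.importance
        if (mode == "nonzero") {
            which(imp > 0)
        } else {
            utils::head(order(abs(imp), decreasing = TRUE), 2L * N1)
        }
    })
}

#' Run a feature-selection method over seeded ensembles
#'
#' Generates each ensemble with [generateSynthetic()], applies the method,
#' computes the confusion matrix against the method's ground truth and
#' averages over ensembles. The KTD method selects on the shared feature
#' index, so its positives are the \code{N1} common signal features (the
#' per-slice-only signal features count as negatives); the baselines select
#' per slice, so their positives are each slice's \code{2*N1} signal
#' features. Ensembles on which a method fails are logged and skipped.
#'
#' @param spec a [SyntheticSpec-class].
#' @param method \code{"ktd"}, \code{"regression"}, \code{"lasso"},
#'   \code{"rf"} (nonzero importance) or \code{"rf_top"} (top \code{2*N1}).
#' @param threshold adjusted-P threshold for the P-value-based methods.
#' @return a [ConfusionSummary-class].
#' @export
runEnsemble <- function(spec, method = c("ktd", "regression", "lasso", "rf", "rf_top"),
                        threshold = 0.01) {
    stopifnot(is(spec, "SyntheticSpec"))
    method <- match.arg(method)
    K <- spec@K
    groups <- if (method == "ktd") "common" else paste0("k=", seq_len(K))
    acc <- matrix(0, nrow = length(groups), ncol = 4L,
        dimnames = list(groups, c("TP", "FN", "FP", "TN")))
    nFailed <- 0L
    universe <- seq_len(spec@N)
    for (e in seq_len(spec@nEnsembles)) {
        dat <- generateSynthetic(spec, e)
        counts <- tryCatch({
            if (method == "ktd") {
                res <- runKTDPipeline(dat$x, dat$a, threshold = threshold)
                rbind(confusionCounts(which(res$selected),
                    which(dat$commonMask), universe))
            } else {
                sel <- switch(method,
                    regression = lapply(regressionBaseline(dat$x, dat$a,
                        threshold), function(tab) which(tab$selected)),
                    lasso = lassoBaseline(dat$x, dat$a),
                    rf = rfBaseline(dat$x, dat$a, mode = "nonzero",
                        N1 = spec@N1, seed = spec@baseSeed + e),
                    rf_top = rfBaseline(dat$x, dat$a, mode = "top2N1",
                        N1 = spec@N1, seed = spec@baseSeed + e))
                do.call(rbind, lapply(seq_len(K), function(k) {
                    confusionCounts(sel[[k]], which(dat$omicsMasks[[k]]),
                        universe)
                }))
            }
        }, error = function(err) {
            message(sprintf("ensemble %d failed for method %s: %s",
                e, method, conditionMessage(err)))
            NULL
        })
        if (is.null(counts)) nFailed <- nFailed + 1L else acc <- acc + counts
    }
    nOk <- spec@nEnsembles - nFailed
    if (nOk < 1L) stop("every ensemble failed")
    counts <- data.frame(group = groups, acc / nOk, row.names = NULL)
    new("ConfusionSummary", method = method, counts = counts,
        nEnsembles = nOk, nFailed = nFailed, spec = spec)
}

setMethod("show", "ConfusionSummary", function(object) {
    cat(sprintf("ConfusionSummary (%s, %d ensemble(s)%s):\n", object@method,
        object@nEnsembles,
        if (object@nFailed) sprintf(", %d failed", object@nFailed) else ""))
    print(object@counts, row.names = FALSE)
})
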