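#' Project the features of one block onto chosen singular vectors
#'
#' Computes, for every feature of the block, the contraction of its sample
#' array with the chosen sample-mode singular vectors:
#' \code{u_i = sum_{j_1...j_m} x[i, j_1, ..., j_m] * prod_s u[l_s, j_s]}.
#' The omics-mode vector never enters: features belong to one block.
#'
#' @param block a [MultiOmicsBlock-class].
#' @param result the [HOSVDResult-class] of the stacked kernel.
#' @param choice an [AxisChoice-class] (or an integer vector of \code{l}
#'   indices, one per sample mode).
#' @return numeric vector of projections, named by feature id.
#' @export
projectFeatures <- function(block, result, choice) {
    stopifnot(is(block, "MultiOmicsBlock"), is(result, "HOSVDResult"))
    ell <- if (is(choice, "AxisChoice")) choice@sampleAxes else as.integer(choice)
    roles <- result@modeRoles
    sampleModes <- if (length(roles)) grep("^sample", roles) else seq_along(result@factors)
    msz <- sampleModeSizes(block)
    if (length(ell) != length(msz)) {
        stop("need one l index per sample mode")
    }
    w <- 1
    for (s in seq_along(msz)) {
        u <- result@factors[[sampleModes[s]]]
        if (nrow(u) != msz[s]) stop("block sample modes do not match factors")
        if (ell[s] < 1L || ell[s] > ncol(u)) {
            stop(sprintf("l index %d out of range for sample mode %d", ell[s], s))
        }
        w <- as.vector(outer(w, u[, ell[s]]))   # column-major kron over modes
    }
    scores <- as.vector(.flattenSamples(block@values) %*% w)
    names(scores) <- block@featureIds
    scores
}

#' Project shared features of a feature x samples x omics tensor
#'
#' For datasets where all omics slices index the same features (as in the
#' synthetic benchmark), the projection also contracts the omics mode:
#' \code{u_i = sum_{j_1...j_m, k} x[i, j..., k] * prod_s u[l_s, j_s] * u[l_o, k]}.
#'
#' @param x numeric array of shape \code{N x M_1 x ... x M_m x K}.
#' @param result the [HOSVDResult-class] of the stacked kernel.
#' @param choice an [AxisChoice-class] (sample axes + omics axis), or a list
#'   \code{list(sample = c(...), omics = l)}.
#' @return numeric vector of length \code{N}.
#' @export
projectFeaturesShared <- function(x, result, choice) {
    stopifnot(is(result, "HOSVDResult"))
    if (is(choice, "AxisChoice")) {
        ell <- choice@sampleAxes
        ellO <- choice@omicsAxis
    } else {
        ell <- as.integer(choice$sample)
        ellO <- as.integer(choice$omics)
    }
    if (is.na(ellO)) stop("shared projection needs an omics-mode index")
    d <- dim(x)
    m <- length(d) - 2L
    if (length(ell) != m) stop("need one l index per sample mode")
    roles <- result@modeRoles
    sampleModes <- grep("^sample", roles)
    omicsMode <- grep("^omics", roles)
    w <- 1
    for (s in seq_len(m)) {
        u <- result@factors[[sampleModes[s]]]
        if (nrow(u) != d[1L + s]) stop("inconsistent sample-mode sizes")
        w <- as.vector(outer(w, u[, ell[s]]))
    }
    uo <- result@factors[[omicsMode]]
    if (nrow(uo) != d[length(d)]) stop("inconsistent omics-mode size")
    if (ellO < 1L || ellO > ncol(uo)) stop("omics l index out of range")
    w <- as.vector(outer(w, uo[, ellO]))
    flat <- x
    dim(flat) <- c(d[1L], prod(d[-1L]))
    as.vector(flat %*% w)
}

#' Null standard deviation of feature projections
#'
#' The Gaussian null for the chi-squared attribution is centred at zero, so
#' sigma is the root mean square of the scores about zero (no centring term),
#' estimated from all features of the group -- signal features are not
#' excluded.
#'
#' @param scores numeric vector of projections (length >= 2).
#' @return single positive number.
#' @examples
#' estimateSigma(c(3, 4))   # sqrt(25/2) = 3.535534
#' @export
estimateSigma <- function(scores) {
    if (length(scores) < 2L) stop("need at least 2 scores")
    s <- sqrt(mean(scores^2))
    if (s == 0) stop("all scores are zero: degenerate null")
    s
}

#' Chi-squared P-values for feature projections
#'
#' Under the null the standardized projections are standard Gaussian, so the
#' sum of their squares over the \code{d} chosen l-combinations follows a
#' chi-squared distribution with \code{d} degrees of freedom; the P-value is
#' its upper tail.
#'
#' @param scores numeric vector (one combination) or matrix with one column
#'   per l-combination.
#' @param sigma positive scalar, or one value per combination.
#' @param df degrees of freedom; defaults to the number of combinations.
#' @return numeric vector of raw P-values in \code{[0, 1]}.
#' @examples
#' chi2Pvalues(0, 1)                      # 1
#' chi2Pvalues(1.959964, 1)               # 0.05
#' @export
chi2Pvalues <- function(scores, sigma, df = NULL) {
    scores <- as.matrix(scores)
    if (is.null(df)) df <- ncol(scores)
    if (df < 1) stop("df must be >= 1")
    if (any(sigma <= 0)) stop("sigma must be positive")
    z2 <- sweep(scores, 2L, sigma, "/")^2
    stats::pchisq(rowSums(z2), df = df, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction (sort ascending, multiply by
#' n/rank, enforce monotonicity from the largest rank down, cap at 1),
#' delegated to \code{stats::p.adjust(method = "BH")} after input validation.
#'
#' @param p numeric vector of raw P-values in \code{[0, 1]}.
#' @return adjusted P-values in the original order.
#' @export
bhAdjust <- function(p) {
    if (any(is.na(p)) || any(p < 0 | p > 1)) {
        stop("P-values must lie in [0, 1]")
    }
    stats::p.adjust(p, method = "BH")
}

#' Score all blocks of a set against chosen axes
#'
#' Runs [projectFeatures()] for every block, estimates sigma per omics block
#' (scales differ with feature counts), attributes chi-squared P-values with
#' one degree of freedom per l-combination, BH-adjusts within each block and
#' flags features with \code{adjustedP <= threshold}.
#'
#' @param set a [MultiOmicsTensorSet-class].
#' @param result the [HOSVDResult-class] of the set's kernel tensor.
#' @param choice an [AxisChoice-class].
#' @param thresholds single threshold or named vector (by omics id) of
#'   per-block adjusted-P thresholds.
#' @return a [FeatureScoreTable-class].
#' @aliases scoreTable selectedFeatures
#' @export
scoreFeatures <- function(set, result, choice, thresholds = 0.01) {
    stopifnot(is(set, "MultiOmicsTensorSet"))
    ids <- omicsIds(set)
    thr <- .resolveThresholds(thresholds, ids)
    rows <- lapply(blocks(set), function(b) {
        sc <- projectFeatures(b, result, choice)
        sg <- estimateSigma(sc)
        p <- chi2Pvalues(sc, sg, df = 1)
        q <- bhAdjust(p)
        data.frame(omicsId = omicsId(b), featureId = featureIds(b),
            score = unname(sc), sigma = sg, pValue = p, adjustedP = q,
            selected = q <= thr[[omicsId(b)]], threshold = thr[[omicsId(b)]],
            row.names = NULL)
    })
    new("FeatureScoreTable", table = do.call(rbind, rows), df = 1,
        axes = choice)
}

.resolveThresholds <- function(thresholds, ids) {
    if (any(thresholds <= 0 | thresholds >= 1)) {
        stop("thresholds must lie in (0, 1)")
    }
    if (is.null(names(thresholds))) {
        if (length(thresholds) == 1L) {
            thresholds <- rep(thresholds, length(ids))
            names(thresholds) <- ids
        } else stop("multiple thresholds must be named by omics id")
    }
    missing <- setdiff(ids, names(thresholds))
    if (length(missing)) {
        stop("missing threshold for block(s): ", paste(missing, collapse = ", "))
    }
    as.list(thresholds[ids])
}

#' Flag selected features of an existing score table
#'
#' Re-applies selection with new per-block thresholds
#' (\code{adjustedP <= threshold}).
#'
#' @param table a [FeatureScoreTable-class].
#' @param thresholds single or named per-block thresholds in (0, 1).
#' @return the updated [FeatureScoreTable-class].
#' @export
selectFeatures <- function(table, thresholds) {
    stopifnot(is(table, "FeatureScoreTable"))
    tab <- table@table
    thr <- .resolveThresholds(thresholds, unique(tab$omicsId))
    tab$threshold <- unlist(thr[tab$omicsId])
    tab$selected <- tab$adjustedP <= tab$threshold
    initialize(table, table = tab)
}

#' @rdname FeatureScoreTable
#' @param x a \code{FeatureScoreTable}.
#' @export
setMethod("scoreTable", "FeatureScoreTable", function(x) x@table)

#' @rdname FeatureScoreTable
#' @param ... for \code{selectedFeatures}, optional \code{omicsId} filter.
#' @export
setMethod("selectedFeatures", "FeatureScoreTable", function(x, ...) {
    args <- list(...)
    tab <- x@table
    if (!is.null(args$omicsId)) tab <- tab[tab$omicsId %in% args$omicsId, ]
    tab$featureId[tab$selected]
})

setMethod("show", "FeatureScoreTable", function(object) {
    tab <- object@table
    cat(sprintf("FeatureScoreTable: %d features, chi-squared df = %g\n",
        nrow(tab), object@df))
    for (id in unique(tab$omicsId)) {
        sub <- tab[tab$omicsId == id, ]
        cat(sprintf("  %s: %d / %d selected (adjusted P <= %g)\n",
            id, sum(sub$selected), nrow(sub), sub$threshold[1L]))
    }
})
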