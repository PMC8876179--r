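#' Rank singular vectors by correlation with a sample covariate
#'
#' For each column \code{l} of a sample-mode factor matrix, computes the
#' Pearson correlation with a numeric covariate (e.g. time, or the monotone
#' covariate of the synthetic benchmark) and the two-sided correlation-test
#' P-value; candidates are returned sorted by \code{|r|} descending. Sign
#' flips of a singular vector do not change the ranking.
#'
#' @param factor numeric matrix whose columns are candidate singular vectors.
#' @param covariate numeric vector of length \code{nrow(factor)}, not constant.
#' @return data.frame with columns \code{ell}, \code{r}, \code{pValue},
#'   sorted by \code{|r|} descending.
#' @examples
#' u <- qr.Q(qr(matrix(rnorm(25), 5)))
#' rankByCovariate(u, u[, 3])[1, "ell"]   # 3
#' @export
rankByCovariate <- function(factor, covariate) {
    factor <- as.matrix(factor)
    if (length(covariate) != nrow(factor)) {
        stop("covariate length must equal the mode size")
    }
    if (nrow(factor) < 3L) stop("need mode size >= 3 for a correlation test")
    if (stats::sd(covariate) == 0) stop("covariate is constant")
    res <- lapply(seq_len(ncol(factor)), function(l) {
        if (stats::sd(factor[, l]) == 0) {
            data.frame(ell = l, r = 0, pValue = 1)
        } else {
            ct <- stats::cor.test(factor[, l], covariate)
            data.frame(ell = l, r = unname(ct$estimate), pValue = ct$p.value)
        }
    })
    out <- do.call(rbind, res)
    out[order(-abs(out$r), out$ell), , drop = FALSE]
}

#' Rank singular vectors by two-class separation
#'
#' Welch (unequal-variance) t statistic of each factor column between two
#' sample classes, with the two-sided P-value; sorted by \code{|t|}
#' descending. Columns that are constant within both classes but differ in
#' mean are reported with \code{t = Inf}, \code{P = 0}; columns constant with
#' equal means get \code{t = 0}, \code{P = 1}.
#'
#' @param factor numeric matrix of candidate singular vectors.
#' @param labels vector with exactly two distinct values; each class needs at
#'   least two members.
#' @return data.frame with columns \code{ell}, \code{t}, \code{pValue},
#'   sorted by \code{|t|} descending.
#' @export
rankByTwoClass <- function(factor, labels) {
    factor <- as.matrix(factor)
    if (length(labels) != nrow(factor)) {
        stop("labels length must equal the mode size")
    }
    cls <- unique(labels)
    if (length(cls) != 2L) stop("labels must contain exactly two classes")
    g1 <- labels == cls[1L]
    if (sum(g1) < 2L || sum(!g1) < 2L) {
        stop("each class needs at least 2 members")
    }
    res <- lapply(seq_len(ncol(factor)), function(l) {
        a <- factor[g1, l]
        b <- factor[!g1, l]
        if (stats::sd(a) == 0 && stats::sd(b) == 0) {
            if (mean(a) == mean(b)) {
                data.frame(ell = l, t = 0, pValue = 1)
            } else {
                data.frame(ell = l, t = Inf, pValue = 0)
            }
        } else {
            tt <- stats::t.test(a, b)
            data.frame(ell = l, t = unname(tt$statistic), pValue = tt$p.value)
        }
    })
    out <- do.call(rbind, res)
    out[order(-abs(out$t), out$ell), , drop = FALSE]
}

#' Rank singular vectors by constancy
#'
#' Scores each factor column by its coefficient of variation,
#' \code{sd / |mean|}; the most constant column (score closest to 0) ranks
#' first. A column with zero mean has an infinite score and ranks last. Used
#' to find the omics-mode vector that weights all omics blocks equally and
#' the sample-mode vectors that are independent of a nuisance mode.
#'
#' @param factor numeric matrix of candidate singular vectors (mode size >= 2).
#' @return data.frame with columns \code{ell}, \code{cv}, sorted ascending
#'   by \code{cv}.
#' @export
constancyScore <- function(factor) {
    factor <- as.matrix(factor)
    if (nrow(factor) < 2L) stop("need mode size >= 2")
    cv <- vapply(seq_len(ncol(factor)), function(l) {
        m <- mean(factor[, l])
        if (m == 0) Inf else stats::sd(factor[, l]) / abs(m)
    }, numeric(1L))
    out <- data.frame(ell = seq_len(ncol(factor)), cv = cv)
    out[order(out$cv, out$ell), , drop = FALSE]
}

#' Choose projection axes from HOSVD factors
#'
#' Semi-automatic axis selection: every sample mode is ranked against the
#' hypothesis supplied for it (numeric covariate: Pearson correlation;
#' two-class labels: Welch t; \code{NULL}: constancy, for modes that should
#' be independent of their index), the omics mode is ranked by constancy,
#' and the top-ranked candidate of each ranking is chosen unless an explicit
#' \code{l} is pinned. All diagnostics are retained.
#'
#' @param result an [HOSVDResult-class] of a [KernelTensor-class]
#'   (mode roles required).
#' @param hypotheses list with one element per sample mode: a numeric
#'   covariate, a two-class label vector, or \code{NULL} for
#'   index-independence.
#' @param pinSample optional integer vector overriding the chosen sample-mode
#'   indices (NA entries keep the automatic choice).
#' @param pinOmics optional integer overriding the omics-mode choice.
#' @return an [AxisChoice-class].
#' @export
chooseAxes <- function(result, hypotheses, pinSample = NULL, pinOmics = NULL) {
    stopifnot(is(result, "HOSVDResult"))
    roles <- result@modeRoles
    if (!length(roles)) stop("result has no mode roles; decompose a KernelTensor")
    sampleModes <- grep("^sample", roles)
    omicsMode <- grep("^omics", roles)
    m <- length(sampleModes)
    if (length(hypotheses) != m) {
        stop(sprintf("need one hypothesis (or NULL) per sample mode (%d)", m))
    }
    diagnostics <- list()
    chosen <- integer(m)
    for (s in seq_len(m)) {
        u <- result@factors[[sampleModes[s]]]
        hyp <- hypotheses[[s]]
        tab <- if (is.null(hyp)) {
            constancyScore(u)
        } else if (is.numeric(hyp) && length(unique(hyp)) > 2L) {
            rankByCovariate(u, hyp)
        } else {
            rankByTwoClass(u, hyp)
        }
        diagnostics[[paste0("sample", s)]] <- tab
        chosen[s] <- tab$ell[1L]
    }
    uo <- result@factors[[omicsMode]]
    if (nrow(uo) >= 2L) {
        tabO <- constancyScore(uo)
        omicsChoice <- tabO$ell[1L]
        diagnostics[["omics"]] <- tabO
    } else {
        omicsChoice <- 1L
        diagnostics[["omics"]] <- data.frame(ell = 1L, cv = 0)
    }
    if (!is.null(pinSample)) {
        stopifnot(length(pinSample) == m)
        keep <- !is.na(pinSample)
        chosen[keep] <- as.integer(pinSample[keep])
    }
    if (!is.null(pinOmics) && !is.na(pinOmics)) {
        omicsChoice <- as.integer(pinOmics)
    }
    sizes <- vapply(sampleModes, function(s) nrow(result@factors[[s]]), integer(1L))
    if (any(chosen < 1L | chosen > sizes)) {
        stop("chosen sample-mode index out of range")
    }
    if (omicsChoice < 1L || omicsChoice > nrow(uo)) {
        stop("chosen omics-mode index out of range")
    }
    new("AxisChoice", sampleAxes = chosen, omicsAxis = as.integer(omicsChoice),
        diagnostics = diagnostics)
}

#' @rdname chooseAxes
#' @param x an [AxisChoice-class].
#' @aliases sampleAxes omicsAxis axisDiagnostics
#' @export
setMethod("sampleAxes", "AxisChoice", function(x) x@sampleAxes)

#' @rdname chooseAxes
#' @export
setMethod("omicsAxis", "AxisChoice", function(x) x@omicsAxis)

#' @rdname chooseAxes
#' @export
setMethod("axisDiagnostics", "AxisChoice", function(x) x@diagnostics)

setMethod("show", "AxisChoice", function(object) {
    cat(sprintf("AxisChoice: sample l = (%s), omics l = %s\n",
        paste(object@sampleAxes, collapse = ", "),
        ifelse(is.na(object@omicsAxis), "-", object@omicsAxis)))
})
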