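#' Confusion matrix of a selection against ground truth
#'
#' @param selected vector of selected elements (subset of \code{universe}).
#' @param truth vector of true-positive elements (subset of \code{universe}).
#' @param universe vector of all candidate elements.
#' @return named numeric vector \code{c(TP, FN, FP, TN)}; the four cells sum
#'   to \code{length(universe)}.
#' @examples
#' confusionCounts(2:5, 1:3, 1:10)   # TP 2, FN 1, FP 2, TN 5
#' @export
confusionCounts <- function(selected, truth, universe) {
    selected <- unique(selected)
    truth <- unique(truth)
    if (length(setdiff(selected, universe)) ||
        length(setdiff(truth, universe))) {
        stop("selected and truth must be subsets of the universe")
    }
    tp <- length(intersect(selected, truth))
    c(TP = tp,
      FN = length(truth) - tp,
      FP = length(selected) - tp,
      TN = length(universe) - length(truth) - length(selected) + tp)
}

#' Exact conditional test for a 2x2 contingency table
#'
#' Fisher's exact test in the conditional-inference convention: the odds
#' ratio is the conditional maximum-likelihood estimate under the noncentral
#' hypergeometric model with fixed margins, and the two-sided P-value sums
#' the probabilities of all tables at least as extreme (probability not
#' larger than the observed table's). Both conventions are those of
#' \code{stats::fisher.test}, which performs the computation. The sample
#' (cross-product) odds ratio is reported alongside for transparency.
#'
#' @param counts 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return list of class \code{"OverlapTestResult"} with \code{counts},
#'   \code{oddsRatio} (conditional MLE), \code{sampleOddsRatio},
#'   \code{pValue} and \code{confInt}.
#' @examples
#' fisherExactConditional(matrix(c(17269, 101, 65, 5), 2, byrow = TRUE))
#' @export
fisherExactConditional <- function(counts) {
    counts <- as.matrix(counts)
    if (!identical(dim(counts), c(2L, 2L))) stop("counts must be 2x2")
    if (any(counts < 0) || any(counts != round(counts))) {
        stop("counts must be non-negative integers")
    }
    if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
        stop("all margins must be positive")
    }
    ft <- stats::fisher.test(counts)
    sor <- if (counts[1L, 2L] * counts[2L, 1L] == 0) {
        if (counts[1L, 1L] * counts[2L, 2L] == 0) NaN else Inf
    } else {
        counts[1L, 1L] * counts[2L, 2L] / (counts[1L, 2L] * counts[2L, 1L])
    }
    structure(list(counts = counts, oddsRatio = unname(ft$estimate),
        sampleOddsRatio = sor, pValue = ft$p.value,
        confInt = unname(ft$conf.int)), class = "OverlapTestResult")
}

#' @export
print.OverlapTestResult <- function(x, ...) {
    cat("Exact conditional 2x2 test\n")
    print(x$counts)
    cat(sprintf("conditional-MLE odds ratio: %.4g (sample OR %.4g)\n",
        x$oddsRatio, x$sampleOddsRatio))
    cat(sprintf("two-sided P = %.4g\n", x$pValue))
    invisible(x)
}

#' Concordance of two feature selections over a common universe
#'
#' Builds the 2x2 table (selected / not selected in A crossed with B) and
#' applies [fisherExactConditional()]. Feature identifiers must already be
#' harmonized between the two selections.
#'
#' @param selA,selB vectors of selected feature identifiers.
#' @param universe vector of all candidate feature identifiers.
#' @return an \code{"OverlapTestResult"} (see [fisherExactConditional()]).
#' @export
overlapSummary <- function(selA, selB, universe) {
    if (!length(universe)) stop("universe must be non-empty")
    selA <- unique(selA)
    selB <- unique(selB)
    if (length(setdiff(selA, universe)) || length(setdiff(selB, universe))) {
        stop("selections must be subsets of the universe")
    }
    inA <- universe %in% selA
    inB <- universe %in% selB
    counts <- matrix(c(
        sum(!inA & !inB), sum(!inA & inB),
        sum(inA & !inB), sum(inA & inB)), nrow = 2L, byrow = TRUE,
        dimnames = list(A = c("notSelected", "selected"),
            B = c("notSelected", "selected")))
    fisherExactConditional(counts)
}
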