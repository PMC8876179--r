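#' @import methods
NULL

#' Single omics block sharing sample modes with its siblings
#'
#' An omics data block is a numeric array whose first mode indexes features
#' (genes, probes, proteins, ...) and whose remaining \code{m} modes index the
#' shared sample structure (e.g. time points x individuals). Missing values may
#' be present as \code{NA} until filled with [fillMissing()]; infinite values
#' are never allowed.
#'
#' @slot omicsId single character label for the block.
#' @slot values numeric array of dimension \code{N_k x M_1 x ... x M_m}.
#' @slot featureIds character vector of length \code{N_k}, unique.
#' @slot sampleModeLabels list of \code{m} character vectors, one per sample
#'   mode, of lengths \code{M_1, ..., M_m}.
#'
#' @seealso [MultiOmicsBlock()] for the user constructor.
#' @exportClass MultiOmicsBlock
setClass("MultiOmicsBlock",
    slots = c(
        omicsId = "character",
        values = "array",
        featureIds = "character",
        sampleModeLabels = "list"
    )
)

setValidity("MultiOmicsBlock", function(object) {
    msg <- character()
    d <- dim(object@values)
    if (length(object@omicsId) != 1L || is.na(object@omicsId)) {
        msg <- c(msg, "omicsId must be a single non-NA string")
    }
    if (!is.numeric(object@values)) {
        msg <- c(msg, "values must be numeric")
    }
    if (length(d) < 2L) {
        msg <- c(msg, "values must have a feature mode and >= 1 sample mode")
    } else {
        if (length(object@featureIds) != d[1L]) {
            msg <- c(msg, sprintf("featureIds length %d != feature-mode size %d",
                length(object@featureIds), d[1L]))
        }
        if (length(object@sampleModeLabels) != length(d) - 1L) {
            msg <- c(msg, "need one label vector per sample mode")
        } else {
            for (s in seq_along(object@sampleModeLabels)) {
                if (length(object@sampleModeLabels[[s]]) != d[s + 1L]) {
                    msg <- c(msg, sprintf(
                        "sample mode %d has %d labels but size %d",
                        s, length(object@sampleModeLabels[[s]]), d[s + 1L]))
                }
            }
        }
    }
    if (anyDuplicated(object@featureIds)) {
        msg <- c(msg, "featureIds must be unique within a block")
    }
    if (any(is.infinite(object@values))) {
        msg <- c(msg, "values must not contain infinite entries")
    }
    if (length(msg)) msg else TRUE
})

#' Collection of omics blocks sharing identical sample modes
#'
#' Holds \code{K >= 1} [MultiOmicsBlock-class] objects whose sample-mode sizes
#' and labels agree exactly; feature counts may differ per block.
#'
#' @slot blocks list of [MultiOmicsBlock-class] objects.
#'
#' @seealso [MultiOmicsTensorSet()], [validateSet()]
#' @exportClass MultiOmicsTensorSet
setClass("MultiOmicsTensorSet", slots = c(blocks = "list"))

setValidity("MultiOmicsTensorSet", function(object) {
    violations <- validateSet(object@blocks)
    if (length(violations)) violations else TRUE
})

#' Kernel choice for sample-similarity computation
#'
#' Only the linear kernel (plain feature-space inner product between sample
#' cells) is implemented; the class exists as the extension point for other
#' kernels, which must produce symmetric positive semi-definite sample
#' matrices.
#'
#' @slot kind kernel family; currently only \code{"linear"}.
#' @exportClass KernelSpec
setClass("KernelSpec", slots = c(kind = "character"))

setValidity("KernelSpec", function(object) {
    if (length(object@kind) != 1L || !object@kind %in% "linear") {
        "kind must be \"linear\""
    } else TRUE
})

#' Stacked sample-kernel tensor
#'
#' Order-(2m+1) tensor of shape \code{K x M_1 x ... x M_m x M_1 x ... x M_m}:
#' the omics mode first, then the m sample modes, then their conjugate copies.
#' Slice \code{k} is the sample Gram tensor of block \code{k}, so its size
#' never depends on any feature count.
#'
#' @slot values numeric array \code{K x M_1...M_m x M_1...M_m}.
#' @slot modeRoles character vector naming each mode role: \code{"omics"},
#'   \code{"sample<s>"}, \code{"conjugate<s>"}.
#' @slot omicsIds block identifiers for the omics mode.
#' @exportClass KernelTensor
setClass("KernelTensor",
    slots = c(values = "array", modeRoles = "character", omicsIds = "character")
)

setValidity("KernelTensor", function(object) {
    msg <- character()
    d <- dim(object@values)
    if (length(d) < 3L || length(d) %% 2L == 0L) {
        msg <- c(msg, "values must have odd order >= 3 (omics + 2m sample modes)")
    } else {
        m <- (length(d) - 1L) %/% 2L
        if (!identical(d[2L:(m + 1L)], d[(m + 2L):(2L * m + 1L)])) {
            msg <- c(msg, "sample modes and conjugate modes must have equal sizes")
        }
    }
    if (length(object@modeRoles) != length(d)) {
        msg <- c(msg, "modeRoles must name every mode")
    }
    if (length(object@omicsIds) != d[1L]) {
        msg <- c(msg, "omicsIds must match the omics-mode size")
    }
    if (length(msg)) msg else TRUE
})

#' Result of a higher-order singular value decomposition
#'
#' Full (untruncated) Tucker-form decomposition: one square orthogonal factor
#' matrix per mode (columns = singular vectors of the mode unfolding, ordered
#' by decreasing singular value, 1-based index \code{l}) and the dense core
#' obtained by projecting the input on all factors.
#'
#' @slot factors list of orthogonal matrices, one per mode.
#' @slot core numeric array with the input's shape.
#' @slot modeRoles mode role labels carried over from the input.
#' @exportClass HOSVDResult
setClass("HOSVDResult",
    slots = c(factors = "list", core = "array", modeRoles = "character")
)

setValidity("HOSVDResult", function(object) {
    msg <- character()
    d <- dim(object@core)
    if (length(object@factors) != length(d)) {
        msg <- c(msg, "need one factor matrix per mode")
    } else {
        for (s in seq_along(object@factors)) {
            f <- object@factors[[s]]
            if (!is.matrix(f) || nrow(f) != d[s] || ncol(f) != d[s]) {
                msg <- c(msg, sprintf("factor %d must be %d x %d", s, d[s], d[s]))
            }
        }
    }
    if (length(object@modeRoles) &&
        length(object@modeRoles) != length(d)) {
        msg <- c(msg, "modeRoles must be empty or name every mode")
    }
    if (length(msg)) msg else TRUE
})

#' Chosen singular-vector indices for feature projection
#'
#' Records which singular vector (1-based \code{l}) is used for each sample
#' mode and, for shared-feature scoring, for the omics mode, together with the
#' ranking diagnostics that justified the choice.
#'
#' @slot sampleAxes integer vector, one chosen \code{l} per sample mode.
#' @slot omicsAxis integer, chosen \code{l} for the omics mode (\code{NA}
#'   when per-block scoring does not use it).
#' @slot diagnostics named list of ranking tables (data.frames) per mode.
#' @exportClass AxisChoice
setClass("AxisChoice",
    slots = c(sampleAxes = "integer", omicsAxis = "integer", diagnostics = "list")
)

setValidity("AxisChoice", function(object) {
    if (length(object@omicsAxis) != 1L) {
        "omicsAxis must have length 1 (possibly NA)"
    } else TRUE
})

#' Per-feature projections, P-values and selection flags
#'
#' One row per feature (per omics block for per-block scoring, or one row per
#' shared feature index). \code{score} is the projection on the chosen
#' singular vectors, \code{sigma} the null standard deviation used, and
#' selection compares BH-adjusted P-values against the block threshold
#' (\code{adjustedP <= threshold}).
#'
#' @slot table data.frame with columns \code{omicsId}, \code{featureId},
#'   \code{score}, \code{sigma}, \code{pValue}, \code{adjustedP},
#'   \code{selected}, \code{threshold}.
#' @slot df chi-squared degrees of freedom (number of l-combinations summed).
#' @slot axes the [AxisChoice-class] used.
#' @exportClass FeatureScoreTable
setClass("FeatureScoreTable",
    slots = c(table = "data.frame", df = "numeric", axes = "AxisChoice")
)

setValidity("FeatureScoreTable", function(object) {
    msg <- character()
    need <- c("omicsId", "featureId", "score", "sigma", "pValue",
        "adjustedP", "selected", "threshold")
    if (!all(need %in% names(object@table))) {
        msg <- c(msg, paste("table must have columns:",
            paste(need, collapse = ", ")))
    } else {
        p <- object@table$pValue
        q <- object@table$adjustedP
        if (any(p < 0 | p > 1, na.rm = TRUE) || any(q < 0 | q > 1, na.rm = TRUE)) {
            msg <- c(msg, "P-values must lie in [0, 1]")
        }
        if (any(q < p - 1e-12, na.rm = TRUE)) {
            msg <- c(msg, "adjusted P must be >= raw P")
        }
        if (any(object@table$sigma <= 0, na.rm = TRUE)) {
            msg <- c(msg, "sigma must be positive")
        }
    }
    if (length(object@df) != 1L || object@df < 1) {
        msg <- c(msg, "df must be a single value >= 1")
    }
    if (length(msg)) msg else TRUE
})

#' Parameters of the synthetic multi-omics benchmark
#'
#' Defines the simulated feature x sample x omics tensor: \code{N} features,
#' \code{M} ordered samples carrying the monotone covariate
#' \code{a_j = 1 + (M-1) j / M}, and \code{K} omics slices. The first
#' \code{N1} features carry the covariate in every slice (the common signal);
#' features \code{k*N1 < i <= (k+1)*N1} carry it only in slice \code{k}.
#' \code{amplitude} scales the added covariate (1 = the study condition;
#' 0 gives a pure-noise null).
#'
#' @slot N,N1,M,K integer dimensions (see above).
#' @slot nEnsembles number of seeded replicate datasets.
#' @slot baseSeed integer; ensemble \code{e} uses seed \code{baseSeed + e}.
#' @slot amplitude numeric multiplier on the covariate signal.
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
    slots = c(N = "integer", N1 = "integer", M = "integer", K = "integer",
        nEnsembles = "integer", baseSeed = "integer", amplitude = "numeric")
)

setValidity("SyntheticSpec", function(object) {
    msg <- character()
    for (nm in c("N", "N1", "M", "K", "nEnsembles", "baseSeed")) {
        if (length(slot(object, nm)) != 1L || is.na(slot(object, nm))) {
            msg <- c(msg, sprintf("%s must be a single non-NA integer", nm))
        }
    }
    if (!length(msg)) {
        if ((object@K + 1L) * object@N1 > object@N) {
            msg <- c(msg, "(K+1)*N1 must not exceed N")
        }
        if (object@M < 3L) msg <- c(msg, "M must be >= 3")
        if (object@N1 < 1L) msg <- c(msg, "N1 must be >= 1")
        if (object@K < 1L) msg <- c(msg, "K must be >= 1")
        if (object@nEnsembles < 1L) msg <- c(msg, "nEnsembles must be >= 1")
        if (object@baseSeed + object@nEnsembles >= 2^31) {
            msg <- c(msg, "baseSeed + nEnsembles must stay below 2^31")
        }
        if (length(object@amplitude) != 1L || object@amplitude < 0) {
            msg <- c(msg, "amplitude must be a single value >= 0")
        }
    }
    if (length(msg)) msg else TRUE
})

#' Averaged confusion matrices over simulation ensembles
#'
#' @slot method one of \code{"ktd"}, \code{"regression"}, \code{"lasso"},
#'   \code{"rf"}, \code{"rf_top"}.
#' @slot counts data.frame with one row per group (\code{"common"} for the
#'   shared-feature truth, or \code{"k=1"}, ... for per-omics truths) and
#'   columns \code{TP}, \code{FN}, \code{FP}, \code{TN} holding ensemble means.
#' @slot nEnsembles number of ensembles averaged.
#' @slot nFailed ensembles skipped because a method failed.
#' @slot spec the [SyntheticSpec-class] used.
#' @exportClass ConfusionSummary
setClass("ConfusionSummary",
    slots = c(method = "character", counts = "data.frame",
        nEnsembles = "integer", nFailed = "integer", spec = "SyntheticSpec")
)

setValidity("ConfusionSummary", function(object) {
    msg <- character()
    need <- c("group", "TP", "FN", "FP", "TN")
    if (!all(need %in% names(object@counts))) {
        msg <- c(msg, paste("counts must have columns:", paste(need, collapse = ", ")))
    } else if (any(unlist(object@counts[c("TP", "FN", "FP", "TN")]) < 0)) {
        msg <- c(msg, "mean counts must be non-negative")
    }
    if (length(msg)) msg else TRUE
})
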