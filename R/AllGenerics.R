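#' @rdname MultiOmicsBlock
#' @export
setGeneric("omicsId", function(x) standardGeneric("omicsId"))

#' @rdname MultiOmicsBlock
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname MultiOmicsBlock
#' @export
setGeneric("blockValues", function(x) standardGeneric("blockValues"))

#' @rdname MultiOmicsBlock
#' @export
setGeneric("nFeatures", function(x) standardGeneric("nFeatures"))

#' Sample-mode sizes of an object
#'
#' @param x a [MultiOmicsBlock-class], [MultiOmicsTensorSet-class] or
#'   [KernelTensor-class] object.
#' @return integer vector \code{M_1, ..., M_m}.
#' @export
setGeneric("sampleModeSizes", function(x) standardGeneric("sampleModeSizes"))

#' @rdname MultiOmicsTensorSet
#' @export
setGeneric("blocks", function(x) standardGeneric("blocks"))

#' @rdname MultiOmicsTensorSet
#' @export
setGeneric("nOmics", function(x) standardGeneric("nOmics"))

#' @rdname MultiOmicsTensorSet
#' @export
setGeneric("omicsIds", function(x) standardGeneric("omicsIds"))

#' Standardize every sample cell of an omics block
#'
#' Rescales the feature vector of each sample cell (each fixed combination of
#' sample-mode indices) to mean 0 and sum of squares \code{N_k}, the
#' convention under which a linear sample kernel has the feature count on its
#' diagonal and off-diagonal entries proportional to sample-sample
#' correlations. No per-feature scaling is applied.
#'
#' @param block a [MultiOmicsBlock-class] with at least two features and no
#'   missing values.
#' @return the standardized [MultiOmicsBlock-class].
#' @examples
#' b <- MultiOmicsBlock(matrix(c(1, 2, 3, 4, 6, 8), nrow = 3), omicsId = "x")
#' colSums(blockValues(standardizeSamples(b)))     # all ~0
#' colSums(blockValues(standardizeSamples(b))^2)   # all = 3
#' @export
setGeneric("standardizeSamples", function(block) standardGeneric("standardizeSamples"))

#' Fill missing values in an omics block
#'
#' @param block a [MultiOmicsBlock-class], possibly containing \code{NA}.
#' @param strategy only \code{"zero"} is supported: missing entries are set
#'   to 0 and everything else is left untouched.
#' @return the imputed [MultiOmicsBlock-class].
#' @export
setGeneric("fillMissing", function(block, strategy = "zero") standardGeneric("fillMissing"))

#' Compute the linear sample kernel of one omics block
#'
#' Entry \code{(j..., j'...)} is the inner product over features of the two
#' sample cells, \code{sum_i x[i, j...] * x[i, j'...]}; the result is a
#' symmetric positive semi-definite tensor of shape
#' \code{M_1 x ... x M_m x M_1 x ... x M_m}.
#'
#' @param block a [MultiOmicsBlock-class] with finite values.
#' @return numeric array of order \code{2m}.
#' @export
setGeneric("linearKernel", function(block) standardGeneric("linearKernel"))

#' @rdname KernelTensor
#' @export
setGeneric("kernelValues", function(x) standardGeneric("kernelValues"))

#' @rdname HOSVDResult
#' @export
setGeneric("factorMatrices", function(x) standardGeneric("factorMatrices"))

#' @rdname HOSVDResult
#' @export
setGeneric("coreTensor", function(x) standardGeneric("coreTensor"))

#' @rdname chooseAxes
#' @export
setGeneric("sampleAxes", function(x) standardGeneric("sampleAxes"))

#' @rdname chooseAxes
#' @export
setGeneric("omicsAxis", function(x) standardGeneric("omicsAxis"))

#' @rdname chooseAxes
#' @export
setGeneric("axisDiagnostics", function(x) standardGeneric("axisDiagnostics"))

#' @rdname FeatureScoreTable
#' @export
setGeneric("scoreTable", function(x) standardGeneric("scoreTable"))

#' @rdname FeatureScoreTable
#' @export
setGeneric("selectedFeatures", function(x, ...) standardGeneric("selectedFeatures"))
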