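#' @rdname KernelSpec
#' @param kind kernel family; only \code{"linear"} is supported.
#' @export
KernelSpec <- function(kind = "linear") new("KernelSpec", kind = kind)

#' @rdname linearKernel
#' @export
setMethod("linearKernel", "MultiOmicsBlock", function(block) {
    v <- block@values
    if (dim(v)[1L] < 1L) stop("block has no features")
    if (anyNA(v)) {
        stop(sprintf("block \"%s\" has missing values; run fillMissing() first",
            block@omicsId))
    }
    flat <- .flattenSamples(v)
    k <- crossprod(flat)                    # (prod M) x (prod M), symmetric PSD
    msz <- dim(v)[-1L]
    dim(k) <- c(msz, msz)
    k
})

#' Stack per-omics sample kernels into a kernel tensor
#'
#' Computes [linearKernel()] for every block of a validated set and stacks
#' the slices along a leading omics mode. The result has shape
#' \code{K x M_1 x ... x M_m x M_1 x ... x M_m}: its storage grows with the
#' sample-mode sizes only, never with any block's feature count, which is
#' what makes integrating many large omics blocks tractable.
#'
#' @param set a [MultiOmicsTensorSet-class].
#' @param spec a [KernelSpec-class]; only the linear kernel is available.
#' @return a [KernelTensor-class].
#' @examples
#' b1 <- MultiOmicsBlock(matrix(rnorm(40), 10, 4), omicsId = "expr")
#' b2 <- MultiOmicsBlock(matrix(rnorm(28), 7, 4), omicsId = "prot")
#' kt <- stackKernels(MultiOmicsTensorSet(b1, b2))
#' dim(kernelValues(kt))  # 2 x 4 x 4
#' @aliases kernelValues
#' @export
stackKernels <- function(set, spec = KernelSpec("linear")) {
    stopifnot(is(set, "MultiOmicsTensorSet"), is(spec, "KernelSpec"))
    validObject(spec)
    violations <- validateSet(set)
    if (length(violations)) {
        stop("invalid set: ", paste(violations, collapse = "; "))
    }
    msz <- unname(sampleModeSizes(set))
    m <- length(msz)
    K <- nOmics(set)
    values <- array(0, dim = c(K, msz, msz))
    flatLen <- prod(msz)^2
    for (k in seq_len(K)) {
        slice <- linearKernel(blocks(set)[[k]])
        # omics mode first: interleave by assigning into the k-th slice
        idx <- seq.int(k, by = K, length.out = flatLen)
        values[idx] <- as.vector(slice)
    }
    roles <- c("omics", paste0("sample", seq_len(m)), paste0("conjugate", seq_len(m)))
    new("KernelTensor", values = values, modeRoles = roles,
        omicsIds = omicsIds(set))
}

#' @rdname KernelTensor
#' @param x a \code{KernelTensor}.
#' @export
setMethod("kernelValues", "KernelTensor", function(x) x@values)

#' @rdname sampleModeSizes
#' @export
setMethod("sampleModeSizes", "KernelTensor", function(x) {
    d <- dim(x@values)
    m <- (length(d) - 1L) %/% 2L
    d[2L:(m + 1L)]
})

setMethod("show", "KernelTensor", function(object) {
    cat(sprintf("KernelTensor: %s (modes: %s)\n",
        paste(dim(object@values), collapse = " x "),
        paste(object@modeRoles, collapse = ", ")))
})
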