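#' Mode-n unfolding of a tensor
#'
#' Rearranges a numeric array into the matrix whose rows are indexed by the
#' chosen mode and whose columns run over all remaining modes in ascending
#' mode order (column-major within that order). [modeFold()] inverts it
#' exactly.
#'
#' @param tensor numeric array.
#' @param mode mode index (1-based).
#' @return matrix of shape \code{dim(tensor)[mode] x prod(dim(tensor)[-mode])}.
#' @examples
#' t3 <- array(1:24, dim = c(2, 3, 4))
#' dim(modeUnfold(t3, 2))              # 3 x 8
#' all(modeFold(modeUnfold(t3, 2), 2, dim(t3)) == t3)
#' @export
modeUnfold <- function(tensor, mode) {
    d <- dim(tensor)
    if (is.null(d)) stop("tensor must be an array")
    if (length(mode) != 1L || mode < 1L || mode > length(d)) {
        stop(sprintf("mode must be in 1..%d", length(d)))
    }
    perm <- c(mode, seq_along(d)[-mode])
    out <- aperm(tensor, perm)
    dim(out) <- c(d[mode], prod(d[-mode]))
    out
}

#' @rdname modeUnfold
#' @param unfolded matrix produced by [modeUnfold()].
#' @param dims original tensor dimensions.
#' @export
modeFold <- function(unfolded, mode, dims) {
    if (length(unfolded) != prod(dims)) stop("shape mismatch in modeFold")
    perm <- c(mode, seq_along(dims)[-mode])
    dim(unfolded) <- dims[perm]
    aperm(unfolded, order(perm))
}

# tensor-times-matrix along one mode: result has dim[mode] = nrow(mat)
.ttm <- function(tensor, mat, mode) {
    d <- dim(tensor)
    out <- mat %*% modeUnfold(tensor, mode)
    d[mode] <- nrow(mat)
    modeFold(out, mode, d)
}

# sign convention: flip each column so its largest-magnitude entry is
# positive; ties broken by lowest row index (which.max on |x|)
.fixSigns <- function(u) {
    for (j in seq_len(ncol(u))) {
        i <- which.max(abs(u[, j]))
        if (u[i, j] < 0) u[, j] <- -u[, j]
    }
    u
}

#' Higher-order singular value decomposition
#'
#' Classical one-pass HOSVD: for each mode, the factor matrix holds the left
#' singular vectors of the mode unfolding (all of them, ordered by decreasing
#' singular value); the core is the input contracted with every factor
#' transpose. Because the factors are square orthogonal matrices the
#' decomposition is exact: [reconstruct()] returns the input to numerical
#' precision, and the core has the input's Frobenius norm. Each factor column
#' is sign-fixed so that its largest-magnitude entry is positive, making the
#' output deterministic.
#'
#' @param x a [KernelTensor-class] or a plain numeric array.
#' @return an [HOSVDResult-class].
#' @examples
#' arr <- array(rnorm(3 * 4 * 5), dim = c(3, 4, 5))
#' h <- hosvd(arr)
#' max(abs(reconstruct(h) - arr))   # ~1e-15
#' @aliases factorMatrices coreTensor
#' @export
hosvd <- function(x) {
    roles <- character()
    if (is(x, "KernelTensor")) {
        roles <- x@modeRoles
        x <- x@values
    }
    if (is.null(dim(x))) stop("input must be an array or KernelTensor")
    if (!all(is.finite(x))) stop("input must be finite")
    if (all(x == 0)) stop("degenerate input: all entries are zero")
    d <- dim(x)
    factors <- vector("list", length(d))
    for (s in seq_along(d)) {
        unf <- modeUnfold(x, s)
        factors[[s]] <- .fixSigns(svd(unf, nu = d[s], nv = 0L)$u)
    }
    core <- x
    for (s in seq_along(d)) core <- .ttm(core, t(factors[[s]]), s)
    new("HOSVDResult", factors = factors, core = core, modeRoles = roles)
}

#' @rdname HOSVDResult
#' @param x an \code{HOSVDResult}.
#' @export
setMethod("factorMatrices", "HOSVDResult", function(x) x@factors)

#' @rdname HOSVDResult
#' @export
setMethod("coreTensor", "HOSVDResult", function(x) x@core)

setMethod("show", "HOSVDResult", function(object) {
    cat(sprintf("HOSVDResult: core %s, %d factor matrices\n",
        paste(dim(object@core), collapse = " x "), length(object@factors)))
    if (length(object@modeRoles)) {
        cat("  modes:", paste(object@modeRoles, collapse = ", "), "\n")
    }
})

#' Rebuild the input tensor from an HOSVD
#'
#' Multiplies the core by every factor matrix; for the full decomposition
#' produced by [hosvd()] this reproduces the original tensor to within
#' floating-point error.
#'
#' @param result an [HOSVDResult-class].
#' @return numeric array with the core's shape.
#' @export
reconstruct <- function(result) {
    stopifnot(is(result, "HOSVDResult"))
    out <- result@core
    for (s in seq_along(result@factors)) {
        out <- .ttm(out, result@factors[[s]], s)
    }
    out
}

#' Check the symmetries a kernel-tensor HOSVD must satisfy
#'
#' A stacked sample-kernel tensor is symmetric under exchanging each sample
#' mode with its conjugate copy, so the factor matrices of a paired mode must
#' agree columnwise up to sign, and the core must be invariant under swapping
#' the paired l indices. Reports the maximum absolute deviation of both.
#'
#' @param result an [HOSVDResult-class] whose \code{modeRoles} identify the
#'   paired modes (as produced by [hosvd()] on a [KernelTensor-class]).
#' @return list with \code{factorDeviation} and \code{coreDeviation}, each the
#'   max absolute deviation over all sample-mode pairs.
#' @export
checkSymmetry <- function(result) {
    stopifnot(is(result, "HOSVDResult"))
    roles <- result@modeRoles
    if (!length(roles)) stop("result has no mode roles; decompose a KernelTensor")
    sampleModes <- grep("^sample", roles)
    conjModes <- grep("^conjugate", roles)
    stopifnot(length(sampleModes) == length(conjModes))
    fdev <- 0
    cdev <- 0
    for (i in seq_along(sampleModes)) {
        us <- result@factors[[sampleModes[i]]]
        uc <- result@factors[[conjModes[i]]]
        # columnwise agreement up to sign
        for (j in seq_len(ncol(us))) {
            fdev <- max(fdev, min(max(abs(us[, j] - uc[, j])),
                max(abs(us[, j] + uc[, j]))))
        }
        perm <- seq_along(roles)
        perm[c(sampleModes[i], conjModes[i])] <- c(conjModes[i], sampleModes[i])
        cdev <- max(cdev, max(abs(result@core - aperm(result@core, perm))))
    }
    list(factorDeviation = fdev, coreDeviation = cdev)
}
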