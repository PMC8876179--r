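#' Construct a multi-omics block
#'
#' @param values numeric matrix (features x samples of a single mode) or
#'   array with the feature mode first.
#' @param omicsId label for the block.
#' @param featureIds optional feature identifiers; defaults to existing
#'   rownames or \code{"f1", "f2", ...}.
#' @param sampleModeLabels optional list of label vectors, one per sample
#'   mode; defaults to existing dimnames or \code{"s<mode>.<index>"}.
#' @return a [MultiOmicsBlock-class] object.
#' @examples
#' b <- MultiOmicsBlock(matrix(rnorm(12), 3, 4), omicsId = "expr")
#' nFeatures(b)
#' sampleModeSizes(b)
#' @aliases omicsId featureIds blockValues nFeatures
#' @export
MultiOmicsBlock <- function(values, omicsId = "omics1", featureIds = NULL,
                            sampleModeLabels = NULL) {
    if (is.null(dim(values))) {
        stop("values must be a matrix or array (feature mode first)")
    }
    values <- as.array(values)
    d <- dim(values)
    if (is.null(featureIds)) {
        featureIds <- if (!is.null(dimnames(values)[[1L]])) {
            dimnames(values)[[1L]]
        } else {
            paste0("f", seq_len(d[1L]))
        }
    }
    if (is.null(sampleModeLabels)) {
        sampleModeLabels <- lapply(seq_along(d)[-1L], function(s) {
            dn <- dimnames(values)[[s]]
            if (!is.null(dn)) dn else paste0("s", s - 1L, ".", seq_len(d[s]))
        })
    }
    dimnames(values) <- NULL
    new("MultiOmicsBlock", omicsId = as.character(omicsId), values = values,
        featureIds = as.character(featureIds),
        sampleModeLabels = lapply(sampleModeLabels, as.character))
}

#' @rdname MultiOmicsBlock
#' @param x a \code{MultiOmicsBlock}.
#' @export
setMethod("omicsId", "MultiOmicsBlock", function(x) x@omicsId)

#' @rdname MultiOmicsBlock
#' @export
setMethod("featureIds", "MultiOmicsBlock", function(x) x@featureIds)

#' @rdname MultiOmicsBlock
#' @export
setMethod("blockValues", "MultiOmicsBlock", function(x) x@values)

#' @rdname MultiOmicsBlock
#' @export
setMethod("nFeatures", "MultiOmicsBlock", function(x) dim(x@values)[1L])

#' @rdname sampleModeSizes
#' @export
setMethod("sampleModeSizes", "MultiOmicsBlock", function(x) dim(x@values)[-1L])

setMethod("show", "MultiOmicsBlock", function(object) {
    d <- dim(object@values)
    cat(sprintf("MultiOmicsBlock \"%s\": %d features x [%s] samples\n",
        object@omicsId, d[1L], paste(d[-1L], collapse = " x ")))
    nmiss <- sum(is.na(object@values))
    if (nmiss) cat(sprintf("  %d missing values (use fillMissing())\n", nmiss))
})

# flatten sample modes: N x (M_1 * ... * M_m)
.flattenSamples <- function(values) {
    d <- dim(values)
    dim(values) <- c(d[1L], prod(d[-1L]))
    values
}

# human-readable label of the flattened sample cell at index idx
.cellLabel <- function(block, idx) {
    d <- sampleModeSizes(block)
    coords <- arrayInd(idx, d)
    paste(mapply(function(s, i) block@sampleModeLabels[[s]][i],
        seq_along(d), coords[1L, ]), collapse = ", ")
}

#' @rdname standardizeSamples
#' @export
setMethod("standardizeSamples", "MultiOmicsBlock", function(block) {
    v <- block@values
    if (anyNA(v)) {
        stop(sprintf("block \"%s\" has missing values; run fillMissing() first",
            block@omicsId))
    }
    n <- dim(v)[1L]
    if (n < 2L) stop("standardization needs at least 2 features")
    flat <- .flattenSamples(v)
    centered <- sweep(flat, 2L, colMeans(flat))
    ss <- colSums(centered^2)
    bad <- which(ss <= 0)
    if (length(bad)) {
        stop(sprintf("zero variance across features in sample cell (%s) of block \"%s\"",
            .cellLabel(block, bad[1L]), block@omicsId))
    }
    out <- sweep(centered, 2L, sqrt(ss / n), "/")
    dim(out) <- dim(v)
    initialize(block, values = out)
})

#' @rdname fillMissing
#' @export
setMethod("fillMissing", "MultiOmicsBlock", function(block, strategy = "zero") {
    strategy <- match.arg(strategy, "zero")
    v <- block@values
    miss <- is.na(v)
    if (!any(miss)) return(block)
    allMissing <- apply(.flattenSamples(miss), 1L, all)
    if (any(allMissing)) {
        warning(sprintf("block \"%s\": %d feature(s) entirely missing, set to zero (e.g. %s)",
            block@omicsId, sum(allMissing),
            block@featureIds[which(allMissing)[1L]]))
    }
    v[miss] <- 0
    initialize(block, values = v)
})

#' Construct a set of omics blocks sharing sample modes
#'
#' @param ... [MultiOmicsBlock-class] objects, or a single list of them.
#' @return a validated [MultiOmicsTensorSet-class].
#' @examples
#' b1 <- MultiOmicsBlock(matrix(rnorm(40), 10, 4), omicsId = "expr")
#' b2 <- MultiOmicsBlock(matrix(rnorm(20), 5, 4), omicsId = "meth")
#' set <- MultiOmicsTensorSet(b1, b2)
#' nOmics(set)
#' @aliases blocks nOmics omicsIds
#' @export
MultiOmicsTensorSet <- function(...) {
    args <- list(...)
    if (length(args) == 1L && is.list(args[[1L]]) &&
        !is(args[[1L]], "MultiOmicsBlock")) {
        args <- args[[1L]]
    }
    new("MultiOmicsTensorSet", blocks = args)
}

#' @rdname MultiOmicsTensorSet
#' @param x a \code{MultiOmicsTensorSet}.
#' @export
setMethod("blocks", "MultiOmicsTensorSet", function(x) x@blocks)

#' @rdname MultiOmicsTensorSet
#' @export
setMethod("nOmics", "MultiOmicsTensorSet", function(x) length(x@blocks))

#' @rdname MultiOmicsTensorSet
#' @export
setMethod("omicsIds", "MultiOmicsTensorSet", function(x) {
    vapply(x@blocks, omicsId, character(1L))
})

#' @rdname sampleModeSizes
#' @export
setMethod("sampleModeSizes", "MultiOmicsTensorSet", function(x) {
    sampleModeSizes(x@blocks[[1L]])
})

setMethod("show", "MultiOmicsTensorSet", function(object) {
    cat(sprintf("MultiOmicsTensorSet: %d block(s), sample modes [%s]\n",
        length(object@blocks),
        paste(sampleModeSizes(object), collapse = " x ")))
    for (b in object@blocks) {
        cat(sprintf("  %s: %d features\n", omicsId(b), nFeatures(b)))
    }
})

#' Report structural violations of a multi-omics set
#'
#' Pure reporting: returns a character vector of violations (sample-mode
#' shape or label mismatches across blocks, duplicated feature or omics
#' identifiers, empty set), empty when the set is consistent. The
#' [MultiOmicsTensorSet()] constructor refuses sets for which this report is
#' non-empty, so this function is mainly useful on raw lists of blocks.
#'
#' @param set a [MultiOmicsTensorSet-class] or a plain list of
#'   [MultiOmicsBlock-class] objects.
#' @return character vector of violation messages (length 0 iff valid).
#' @export
validateSet <- function(set) {
    blks <- if (is(set, "MultiOmicsTensorSet")) set@blocks else set
    out <- character()
    if (length(blks) < 1L) {
        return("set must contain at least one block (K >= 1)")
    }
    for (i in seq_along(blks)) {
        if (!is(blks[[i]], "MultiOmicsBlock")) {
            return(sprintf("element %d is not a MultiOmicsBlock", i))
        }
        v <- validObject(blks[[i]], test = TRUE)
        if (!isTRUE(v)) out <- c(out, sprintf("block %d: %s", i, v))
        if (anyDuplicated(blks[[i]]@featureIds)) {
            out <- c(out, sprintf("block \"%s\": duplicated feature ids",
                omicsId(blks[[i]])))
        }
    }
    ids <- vapply(blks, omicsId, character(1L))
    if (anyDuplicated(ids)) {
        out <- c(out, sprintf("duplicated omics ids: %s",
            paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    }
    ref <- sampleModeSizes(blks[[1L]])
    refLabels <- blks[[1L]]@sampleModeLabels
    for (i in seq_along(blks)[-1L]) {
        sz <- sampleModeSizes(blks[[i]])
        if (!identical(unname(sz), unname(ref))) {
            out <- c(out, sprintf(
                "block \"%s\": sample-mode sizes [%s] differ from [%s]",
                ids[i], paste(sz, collapse = " x "),
                paste(ref, collapse = " x ")))
        } else if (!identical(blks[[i]]@sampleModeLabels, refLabels)) {
            out <- c(out, sprintf(
                "block \"%s\": sample-mode labels differ from block \"%s\"",
                ids[i], ids[1L]))
        }
    }
    unique(out)
}
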