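#' Read an omics block from a delimited matrix file
#'
#' Expects a TSV/CSV file whose first column holds feature identifiers and
#' whose remaining columns are samples, plus a sample map assigning every
#' sample column a coordinate in the shared sample modes. The map is a
#' data.frame (or path to a TSV) with a \code{sample} column naming the file
#' columns and one additional column per sample mode giving that sample's
#' level; mode levels are ordered by first appearance. \code{NA} tokens
#' become missing values for [fillMissing()].
#'
#' @param path matrix file; \code{.csv} is comma-separated, anything else
#'   tab-separated.
#' @param sampleMap data.frame or TSV path as described above.
#' @param omicsId block label; defaults to the file name without extension.
#' @return a [MultiOmicsBlock-class] of shape \code{N x M_1 x ... x M_m}.
#' @seealso [writeBlock()] for the mirrored writer.
#' @export
readBlock <- function(path, sampleMap, omicsId = NULL) {
    if (!file.exists(path)) stop("no such file: ", path)
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    raw <- utils::read.table(path, header = TRUE, sep = sep,
        check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(raw) < 2L) stop("matrix file needs a feature column plus samples")
    ids <- as.character(raw[[1L]])
    if (anyDuplicated(ids)) {
        stop("duplicated feature ids in ", path, ": ",
            paste(utils::head(unique(ids[duplicated(ids)]), 3L), collapse = ", "))
    }
    mat <- as.matrix(raw[, -1L, drop = FALSE])
    storage.mode(mat) <- "double"
    if (is.character(sampleMap)) {
        sampleMap <- utils::read.table(sampleMap, header = TRUE, sep = "\t",
            check.names = FALSE, stringsAsFactors = FALSE)
    }
    if (!"sample" %in% names(sampleMap)) {
        stop("sample map needs a 'sample' column")
    }
    modes <- setdiff(names(sampleMap), "sample")
    if (!length(modes)) stop("sample map needs at least one mode column")
    missingCols <- setdiff(colnames(mat), sampleMap$sample)
    if (length(missingCols)) {
        stop("sample columns missing from map: ",
            paste(missingCols, collapse = ", "))
    }
    unmatched <- setdiff(sampleMap$sample, colnames(mat))
    if (length(unmatched)) {
        stop("mapped samples missing from file: ",
            paste(unmatched, collapse = ", "))
    }
    levelsPerMode <- lapply(modes, function(mo) {
        unique(as.character(sampleMap[[mo]]))
    })
    msz <- vapply(levelsPerMode, length, integer(1L))
    if (prod(msz) != ncol(mat)) {
        stop(sprintf("map defines %s = %d cells but file has %d sample columns",
            paste(msz, collapse = " x "), prod(msz), ncol(mat)))
    }
    values <- array(NA_real_, dim = c(nrow(mat), msz))
    flat <- matrix(NA_real_, nrow(mat), prod(msz))
    for (r in seq_len(nrow(sampleMap))) {
        coords <- mapply(function(mo, lv) match(as.character(sampleMap[[mo]][r]), lv),
            modes, levelsPerMode)
        idx <- 1L + sum((coords - 1L) * cumprod(c(1L, msz))[seq_along(msz)])
        flat[, idx] <- mat[, sampleMap$sample[r]]
    }
    values[] <- flat
    if (is.null(omicsId)) {
        omicsId <- sub("\\.[^.]*$", "", basename(path))
    }
    MultiOmicsBlock(values, omicsId = omicsId, featureIds = ids,
        sampleModeLabels = levelsPerMode)
}

#' Write an omics block (and its sample map) to delimited files
#'
#' Mirrors [readBlock()]: flattens the sample modes to columns (first mode
#' fastest), writes a TSV with the feature-id column first, and optionally a
#' sample-map TSV that [readBlock()] accepts to restore the array shape.
#'
#' @param block a [MultiOmicsBlock-class].
#' @param path output matrix TSV.
#' @param mapPath optional output path for the sample map TSV.
#' @return invisibly, the sample map data.frame.
#' @export
writeBlock <- function(block, path, mapPath = NULL) {
    stopifnot(is(block, "MultiOmicsBlock"))
    msz <- sampleModeSizes(block)
    grid <- expand.grid(block@sampleModeLabels, stringsAsFactors = FALSE)
    names(grid) <- paste0("mode", seq_along(msz))
    sampleNames <- apply(grid, 1L, paste, collapse = "|")
    flat <- .flattenSamples(block@values)
    colnames(flat) <- sampleNames
    out <- data.frame(featureId = block@featureIds, flat,
        check.names = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
        row.names = FALSE)
    map <- data.frame(sample = sampleNames, grid, check.names = FALSE)
    if (!is.null(mapPath)) {
        utils::write.table(map, mapPath, sep = "\t", quote = FALSE,
            row.names = FALSE)
    }
    invisible(map)
}

.asRunConfig <- function(config) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    if (is.null(config$blocks) || !length(config$blocks)) {
        stop("config must declare at least one block")
    }
    config$standardize <- isTRUE(config$standardize)
    if (is.null(config$kernel)) config$kernel <- "linear"
    if (is.null(config$seed)) config$seed <- 1L
    config
}

#' Run the full multi-omics pipeline from a configuration
#'
#' Executes load -> impute -> (optional) standardize -> kernel stack ->
#' HOSVD -> axis selection -> projection -> chi-squared P / BH -> selection,
#' and writes per-block score tables, axis diagnostics and a machine-readable
#' manifest into \code{outputDir}. The same configuration always produces
#' identical outputs.
#'
#' The configuration (YAML file or equivalent list) declares:
#' \describe{
#'   \item{blocks}{list of \code{path}, \code{map}, optional \code{omics_id}
#'     and \code{threshold} (default 0.01) per block.}
#'   \item{standardize}{logical; standardize each sample cell before the
#'     kernel (default \code{FALSE}).}
#'   \item{covariates}{optional list, one entry per sample mode (1-based
#'     declaration order): numeric covariate, two-class labels, or \code{NULL}
#'     for an index-independence (constancy) ranking.}
#'   \item{axes}{optional \code{sample} (integer vector, NA = auto) and
#'     \code{omics} pinned singular-vector indices.}
#'   \item{seed}{RNG seed recorded in the manifest.}
#' }
#'
#' @param config YAML path or list.
#' @param outputDir directory created (if needed) for the outputs.
#' @return invisibly, a list with the [FeatureScoreTable-class], the
#'   [AxisChoice-class] and the manifest list.
#' @export
runPipeline <- function(config, outputDir) {
    config <- .asRunConfig(config)
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    set.seed(as.integer(config$seed))
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e) {
            stop(sprintf("pipeline stage '%s' failed: %s", name,
                conditionMessage(e)), call. = FALSE)
        })
    }
    blks <- stage("load", lapply(config$blocks, function(bc) {
        fillMissing(readBlock(bc$path, bc$map, omicsId = bc$omics_id))
    }))
    if (config$standardize) {
        blks <- stage("standardize", lapply(blks, standardizeSamples))
    }
    set <- stage("validate", MultiOmicsTensorSet(blks))
    m <- length(sampleModeSizes(set))
    kt <- stage("kernel", stackKernels(set, KernelSpec(config$kernel)))
    h <- stage("hosvd", hosvd(kt))
    hyps <- vector("list", m)
    if (!is.null(config$covariates)) {
        for (s in seq_len(min(m, length(config$covariates)))) {
            cv <- config$covariates[[s]]
            if (!is.null(cv)) hyps[[s]] <- unlist(cv)
        }
    }
    pinS <- pinO <- NULL
    if (!is.null(config$axes)) {
        if (!is.null(config$axes$sample)) pinS <- as.integer(unlist(config$axes$sample))
        if (!is.null(config$axes$omics)) pinO <- as.integer(config$axes$omics)
    }
    choice <- stage("axes", chooseAxes(h, hyps, pinSample = pinS, pinOmics = pinO))
    thresholds <- vapply(config$blocks, function(bc) {
        if (is.null(bc$threshold)) 0.01 else as.numeric(bc$threshold)
    }, numeric(1L))
    names(thresholds) <- omicsIds(set)
    fst <- stage("score", scoreFeatures(set, h, choice, thresholds))
    tab <- scoreTable(fst)
    for (id in omicsIds(set)) {
        utils::write.table(tab[tab$omicsId == id, ],
            file.path(outputDir, paste0("scores_", id, ".tsv")),
            sep = "\t", quote = FALSE, row.names = FALSE)
    }
    diag <- do.call(rbind, lapply(names(choice@diagnostics), function(nm) {
        d <- choice@diagnostics[[nm]]
        data.frame(mode = nm, ell = d$ell,
            statistic = d[[setdiff(names(d), "ell")[1L]]],
            pValue = if ("pValue" %in% names(d)) d$pValue else NA_real_)
    }))
    utils::write.table(diag, file.path(outputDir, "axis_diagnostics.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- list(
        package = "ktdFE",
        version = as.character(utils::packageVersion("ktdFE")),
        blocks = lapply(seq_along(config$blocks), function(i) list(
            omicsId = omicsIds(set)[i],
            path = config$blocks[[i]]$path,
            nFeatures = nFeatures(blocks(set)[[i]]),
            threshold = thresholds[[i]],
            nSelected = sum(tab$selected[tab$omicsId == omicsIds(set)[i]]))),
        sampleModeSizes = as.integer(sampleModeSizes(set)),
        standardize = config$standardize,
        kernel = config$kernel,
        sigmaGrouping = "per-block",
        axesPinned = list(sample = pinS, omics = pinO),
        axesChosen = list(sample = choice@sampleAxes, omics = choice@omicsAxis),
        chiSquaredDf = fst@df,
        seed = as.integer(config$seed),
        valid = TRUE)
    jsonlite::write_json(manifest, file.path(outputDir, "manifest.json"),
        auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(list(scores = fst, choice = choice, manifest = manifest))
}

#' Summarize a completed pipeline run
#'
#' Reads the manifest and score tables of a [runPipeline()] output directory
#' and prints selected-feature counts per block, the chosen axes and the
#' thresholds used.
#'
#' @param runDir directory written by [runPipeline()].
#' @return invisibly, the manifest list.
#' @export
reportRun <- function(runDir) {
    manifestPath <- file.path(runDir, "manifest.json")
    if (!file.exists(manifestPath)) {
        stop("no manifest.json in ", runDir, "; not a completed run")
    }
    manifest <- jsonlite::read_json(manifestPath, simplifyVector = TRUE)
    cat(sprintf("ktdFE run (%s), %d block(s), sample modes [%s]\n",
        manifest$version, nrow(manifest$blocks),
        paste(manifest$sampleModeSizes, collapse = " x ")))
    cat(sprintf("kernel: %s; standardized: %s; seed: %d\n", manifest$kernel,
        manifest$standardize, manifest$seed))
    cat(sprintf("chosen axes: sample l = (%s), omics l = %s\n",
        paste(unlist(manifest$axesChosen$sample), collapse = ", "),
        manifest$axesChosen$omics))
    b <- manifest$blocks
    for (i in seq_len(nrow(b))) {
        cat(sprintf("  %s: %d / %d selected (adjusted P <= %g)\n",
            b$omicsId[i], b$nSelected[i], b$nFeatures[i], b$threshold[i]))
    }
    invisible(manifest)
}
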