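#' Compute all contamination and QC metrics for one dataset
#'
#' Full scoring pipeline on an in-memory count matrix: rank barcodes,
#' estimate (or accept) the real-cell number, truncate to a multiple of
#' it, compute the curve-shape metrics, the slope-distribution metric,
#' the ambient-gene metrics, the standard QC metrics, and the overall
#' score.
#'
#' @param x unfiltered count matrix (genes x barcodes sparse matrix or
#'   SingleCellExperiment).
#' @param expectedCells optional user-supplied real-cell number; bypasses
#'   knee estimation.
#' @param multiple truncation multiple (default 4).
#' @param nBins slope-histogram bins (default 100).
#' @param dropoutThreshold ambient-gene dropout cutoff (default 0.02).
#' @param mitoPrefixes mitochondrial gene-symbol prefixes.
#' @param scoreModel a [ScoreModel-class], or NULL to skip the overall
#'   score (it is then NA).
#' @param sampleId optional sample identifier stored in the result.
#' @param verbose log intermediate quantities (estimated cells, retained
#'   barcodes, slope threshold, ambient genes) via `message()`.
#' @return A [MetricSet-class].
#' @examples
#' sim <- simulateDroplets(nCells = 100, nDroplets = 600, bioUMI = 1000,
#'                         nGenes = 300, ambientLevel = 20, seed = 7,
#'                         randomize = FALSE)
#' computeMetrics(sim, verbose = FALSE)
#' @export
computeMetrics <- function(x, expectedCells = NULL, multiple = 4,
                           nBins = 100, dropoutThreshold = 0.02,
                           mitoPrefixes = c("mt-", "MT-"),
                           scoreModel = defaultScoreModel(),
                           sampleId = NA_character_, verbose = TRUE) {
    counts <- .countsMatrix(x)
    curve <- rankedCurve(counts, nCellsEst = expectedCells,
                         multiple = multiple)
    if (verbose)
        message(sprintf(
            "cells: %d%s | retained barcodes: %d (multiple %d)",
            curve@nCellsEst,
            if (is.null(expectedCells)) " (estimated)" else " (supplied)",
            curve@N, curve@multiple))

    prof <- secantProfile(curve)
    dist <- scaledSlopeDistribution(slopeSeries(curve), nBins = nBins)
    trunc <- truncatedCounts(counts, curve)
    amb <- ambientGenes(geneDropout(trunc), threshold = dropoutThreshold)
    pca <- percentCountsAmbient(trunc, amb, curve@nCellsEst)
    symbols <- NULL
    if (is(x, "SummarizedExperiment") &&
        "symbol" %in% colnames(SummarizedExperiment::rowData(x)))
        symbols <- SummarizedExperiment::rowData(x)$symbol[
            match(rownames(trunc), rownames(x))]
    qc <- withCallingHandlers(
        standardQC(trunc, curve@nCellsEst, mitoPrefixes = mitoPrefixes,
                   symbols = symbols),
        warning = function(w) {
            if (grepl("mitochondrial", conditionMessage(w)))
                invokeRestart("muffleWarning")
        })
    if (verbose)
        message(sprintf(
            "slope threshold: %.3g | ambient genes: %d (dropout < %g)",
            dist@threshold, amb@nAmbient, dropoutThreshold))

    ms <- methods::new("MetricSet",
        emptyDropletSlopeSum = emptyDropletSlopeSum(dist),
        invertedMaxSecant = invertedMaxSecant(prof),
        invertedSecantSD = invertedSecantSD(prof),
        invertedAUCPct = invertedAUCPercentage(curve),
        nAmbientGenes = amb@nAmbient,
        avgPctCountsAmbient = pca$avgPct,
        avgAmbientUMIPerCell = pca$avgAmbientUMI,
        nCells = as.integer(curve@nCellsEst),
        avgPctCountsMito = qc$avgPctMito,
        avgGenesPerCell = qc$avgGenes,
        avgUMIPerCell = qc$avgUMI,
        sampleId = sampleId)
    if (!is.null(scoreModel))
        ms@overallScore <- overallScore(ms, scoreModel)
    ms
}

#' Score one sample from disk
#'
#' Reads an unfiltered count matrix (Matrix Market directory/file or
#' 10x-style HDF5, chosen by extension) and runs [computeMetrics()].
#'
#' @param input path to an MTX directory, `.mtx(.gz)` file or `.h5` file.
#' @param sampleId identifier used in reports (default: input basename).
#' @param ... passed to [computeMetrics()].
#' @return A [MetricSet-class].
#' @export
scoreSample <- function(input, sampleId = NULL, ...) {
    if (!file.exists(input)) stop("input not found: ", input)
    x <- if (!dir.exists(input) &&
             grepl("\\.h5(ad)?$", input, ignore.case = TRUE))
        readH5Counts(input) else readMTX(input)
    if (is.null(sampleId))
        sampleId <- sub("\\.[^.]*$", "", basename(input))
    computeMetrics(x, sampleId = sampleId, ...)
}

#' Score a cohort of samples from a manifest
#'
#' The manifest is a TSV (or data.frame) with columns `sample_id`,
#' `path`, optional `expected_cells`, and any further metadata columns,
#' which are carried through to the cohort table. A failing sample is
#' reported in the `errors` attribute and skipped rather than aborting
#' the cohort.
#'
#' @param manifest path to a TSV manifest or a data.frame.
#' @param normalizeRows additionally return min-max row-normalized metric
#'   columns (`<metric>_scaled`), the form used for cohort heatmaps.
#' @param ... passed to [computeMetrics()].
#' @return data.frame with one row per successfully scored sample
#'   (metadata columns, then metrics in canonical order); failed samples
#'   are recorded in `attr(result, "errors")` (sample_id, message).
#' @export
scoreCohort <- function(manifest, normalizeRows = FALSE, ...) {
    if (is.character(manifest))
        manifest <- read.delim(manifest, stringsAsFactors = FALSE)
    if (!all(c("sample_id", "path") %in% colnames(manifest)))
        stop("manifest needs 'sample_id' and 'path' columns")
    results <- list(); errors <- list()
    for (i in seq_len(nrow(manifest))) {
        sid <- as.character(manifest$sample_id[i])
        ms <- tryCatch({
            ec <- NULL
            if ("expected_cells" %in% colnames(manifest) &&
                is.finite(manifest$expected_cells[i]))
                ec <- as.integer(manifest$expected_cells[i])
            scoreSample(as.character(manifest$path[i]), sampleId = sid,
                        expectedCells = ec, ...)
        }, error = function(e) e)
        if (inherits(ms, "error")) {
            errors[[length(errors) + 1L]] <-
                data.frame(sample_id = sid,
                           message = conditionMessage(ms))
        } else results[[sid]] <- ms
    }
    if (!length(results))
        stop("no sample in the manifest could be scored")
    tab <- metricTable(results)
    meta <- manifest[match(tab$sample_id, manifest$sample_id),
                     setdiff(colnames(manifest), c("path")), drop = FALSE]
    tab <- cbind(meta[, setdiff(colnames(meta), "sample_id"),
                      drop = FALSE], tab)
    rownames(tab) <- NULL
    if (normalizeRows) {
        for (nm in .metricOrder) {
            v <- tab[[nm]]
            rng <- range(v, na.rm = TRUE)
            tab[[paste0(nm, "_scaled")]] <-
                if (diff(rng) > 0) (v - rng[1]) / diff(rng) else 0
        }
    }
    attr(tab, "errors") <- if (length(errors)) do.call(rbind, errors)
                           else NULL
    tab
}
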