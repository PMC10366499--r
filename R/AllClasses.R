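#' @import methods
NULL

#' RankedCurve: normalized cumulative transcript-count curve
#'
#' Barcodes ranked by descending total UMI count, truncated to a fixed
#' multiple of the estimated real-cell number, with the normalized rank
#' positions \code{x = i/N} and normalized cumulative totals \code{c}
#' (both in (0, 1]). This curve is the substrate of all curve-shape
#' contamination metrics.
#'
#' @slot totals numeric, per-barcode total UMI of the retained barcodes,
#'   sorted descending (ties broken by input order).
#' @slot x numeric, normalized rank positions i/N.
#' @slot c numeric, normalized cumulative totals; \code{c[N] == 1}.
#' @slot barcodes character, retained barcode identifiers in rank order.
#' @slot nCellsEst integer, estimated (or user-supplied) real-cell number.
#' @slot multiple integer, truncation multiple (default 4).
#' @slot N integer, number of retained barcodes
#'   (\code{min(multiple * nCellsEst, available barcodes)}).
#' @slot lowConfidence logical, TRUE when the knee estimate fell back to
#'   the degenerate-curve default.
#'
#' @seealso [rankedCurve()], [secantProfile()], [slopeSeries()]
#' @export
setClass("RankedCurve", representation(
    totals = "numeric",
    x = "numeric",
    c = "numeric",
    barcodes = "character",
    nCellsEst = "integer",
    multiple = "integer",
    N = "integer",
    lowConfidence = "logical"
))

setValidity("RankedCurve", function(object) {
    msg <- NULL
    N <- object@N
    if (length(object@totals) != N || length(object@x) != N ||
        length(object@c) != N)
        msg <- c(msg, "totals, x and c must all have length N")
    if (is.unsorted(rev(object@totals)))
        msg <- c(msg, "totals must be non-increasing")
    if (N > 0 && abs(object@c[N] - 1) > 1e-8)
        msg <- c(msg, "c[N] must equal 1")
    if (N > 1 && any(diff(object@x) <= 0))
        msg <- c(msg, "x must be strictly increasing")
    if (N > 1 && any(diff(object@c) < -1e-12))
        msg <- c(msg, "c must be non-decreasing")
    if (object@nCellsEst < 1L)
        msg <- c(msg, "nCellsEst must be >= 1")
    if (is.null(msg)) TRUE else msg
})

#' SecantProfile: vertical distances between curve and diagonal
#'
#' For a normalized cumulative-count curve the diagonal joining the origin
#' and the last data point is y = x; the secant distance at rank i is the
#' vertical gap \code{c[i] - x[i]}. A clean dataset bulges far above the
#' diagonal; heavy ambient contamination flattens the curve toward it.
#'
#' @slot d numeric, per-rank distances (clamped at 0), in [0, 1).
#' @slot maxD numeric, maximum distance.
#' @slot sdD numeric, population standard deviation of the distances
#'   (provably < 0.5 for normalized concave curves).
#'
#' @seealso [secantProfile()], [invertedMaxSecant()], [invertedSecantSD()]
#' @export
setClass("SecantProfile", representation(
    d = "numeric", maxD = "numeric", sdD = "numeric"
))

setValidity("SecantProfile", function(object) {
    msg <- NULL
    if (any(object@d < 0)) msg <- c(msg, "distances must be >= 0")
    if (object@maxD >= 1) msg <- c(msg, "maxD must be < 1")
    if (object@sdD < 0) msg <- c(msg, "sdD must be >= 0")
    if (is.null(msg)) TRUE else msg
})

#' SlopeDistribution: scaled slope histogram of the cumulative curve
#'
#' The slope at rank i of the normalized cumulative curve is that barcode's
#' normalized total count. Slopes are binned into 100 equal-width bins; each
#' bin's frequency is multiplied by its midpoint so that high-slope
#' (cell-driven) bins gain mass, and the scaled values are renormalized to
#' sum to one. The cell/empty threshold is median(slopes) + population
#' sd(slopes), computed on the raw (unbinned) slopes.
#'
#' @slot slopes numeric, raw per-barcode normalized slopes (sum to 1).
#' @slot mids numeric, bin midpoints.
#' @slot freqs numeric, bin frequencies (sum to number of barcodes).
#' @slot scaledY numeric, midpoint-weighted frequencies renormalized to
#'   sum to 1.
#' @slot threshold numeric, median + population sd of the raw slopes.
#' @slot emptySum numeric, sum of scaledY over bins with midpoint <=
#'   threshold: the empty-droplet scaled slope sum, rising with
#'   contamination.
#' @slot degenerate logical, TRUE when all slopes are identical (single-bin
#'   fallback; emptySum is 1).
#'
#' @seealso [scaledSlopeDistribution()], [emptyDropletSlopeSum()]
#' @export
setClass("SlopeDistribution", representation(
    slopes = "numeric",
    mids = "numeric",
    freqs = "numeric",
    scaledY = "numeric",
    threshold = "numeric",
    emptySum = "numeric",
    degenerate = "logical"
))

setValidity("SlopeDistribution", function(object) {
    msg <- NULL
    if (abs(sum(object@scaledY) - 1) > 1e-8)
        msg <- c(msg, "scaledY must sum to 1")
    if (!object@degenerate &&
        abs(sum(object@freqs) - length(object@slopes)) > 1e-8)
        msg <- c(msg, "freqs must sum to the number of slopes")
    if (object@emptySum < -1e-12 || object@emptySum > 1 + 1e-12)
        msg <- c(msg, "emptySum must lie in [0, 1]")
    if (object@threshold < median(object@slopes) - 1e-12)
        msg <- c(msg, "threshold must be >= median of slopes")
    if (is.null(msg)) TRUE else msg
})

#' AmbientGeneSet: genes classified as ambient by dropout rate
#'
#' Ambient transcripts contaminate essentially every droplet, so ambient
#' genes are detected in almost all retained barcodes. A gene is called
#' ambient when its dropout rate (fraction of retained barcodes with zero
#' count) is strictly below the threshold (default 2%).
#'
#' @slot dropout named numeric, per-gene dropout rate in [0, 1].
#' @slot ambientIds character, identifiers of the ambient genes.
#' @slot threshold numeric, dropout cutoff (strict inequality).
#' @slot nAmbient integer, number of ambient genes.
#'
#' @seealso [geneDropout()], [ambientGenes()], [percentCountsAmbient()]
#' @export
setClass("AmbientGeneSet", representation(
    dropout = "numeric",
    ambientIds = "character",
    threshold = "numeric",
    nAmbient = "integer"
))

setValidity("AmbientGeneSet", function(object) {
    msg <- NULL
    if (any(object@dropout < 0 | object@dropout > 1))
        msg <- c(msg, "dropout rates must lie in [0, 1]")
    if (!all(object@ambientIds %in% names(object@dropout)))
        msg <- c(msg, "ambientIds must be a subset of the gene identifiers")
    if (object@nAmbient != length(object@ambientIds))
        msg <- c(msg, "nAmbient must equal length(ambientIds)")
    if (is.null(msg)) TRUE else msg
})

#' MetricSet: contamination and standard QC metrics for one dataset
#'
#' Holds the six contamination metrics, the standard per-cell QC metrics
#' computed on the estimated-cell barcode set, and the overall
#' contamination score (0 = perfect signal-to-noise, 1 = all noise).
#'
#' @slot emptyDropletSlopeSum numeric in [0, 1].
#' @slot invertedMaxSecant numeric in [0, 1].
#' @slot invertedSecantSD numeric in [0, 0.5].
#' @slot invertedAUCPct numeric in [0, 1].
#' @slot nAmbientGenes integer count.
#' @slot avgPctCountsAmbient numeric percent in [0, 100].
#' @slot avgAmbientUMIPerCell numeric, mean UMIs in ambient genes per cell.
#' @slot nCells integer, estimated real-cell count.
#' @slot avgPctCountsMito numeric percent in [0, 100].
#' @slot avgGenesPerCell numeric.
#' @slot avgUMIPerCell numeric.
#' @slot overallScore numeric in [0, 1] (NA when no score model applied).
#' @slot sampleId character, optional sample identifier.
#'
#' @seealso [computeMetrics()], [metricValues()], [overallScore()]
#' @export
setClass("MetricSet", representation(
    emptyDropletSlopeSum = "numeric",
    invertedMaxSecant = "numeric",
    invertedSecantSD = "numeric",
    invertedAUCPct = "numeric",
    nAmbientGenes = "integer",
    avgPctCountsAmbient = "numeric",
    avgAmbientUMIPerCell = "numeric",
    nCells = "integer",
    avgPctCountsMito = "numeric",
    avgGenesPerCell = "numeric",
    avgUMIPerCell = "numeric",
    overallScore = "numeric",
    sampleId = "character"
), prototype(overallScore = NA_real_, sampleId = NA_character_))

setValidity("MetricSet", function(object) {
    msg <- NULL
    inRange <- function(v, lo, hi)
        is.na(v) || (v >= lo - 1e-9 && v <= hi + 1e-9)
    if (!inRange(object@emptyDropletSlopeSum, 0, 1))
        msg <- c(msg, "emptyDropletSlopeSum out of [0, 1]")
    if (!inRange(object@invertedMaxSecant, 0, 1))
        msg <- c(msg, "invertedMaxSecant out of [0, 1]")
    if (!inRange(object@invertedSecantSD, 0, 0.5))
        msg <- c(msg, "invertedSecantSD out of [0, 0.5]")
    if (!inRange(object@invertedAUCPct, 0, 1))
        msg <- c(msg, "invertedAUCPct out of [0, 1]")
    if (!inRange(object@avgPctCountsAmbient, 0, 100))
        msg <- c(msg, "avgPctCountsAmbient out of [0, 100]")
    if (!inRange(object@avgPctCountsMito, 0, 100))
        msg <- c(msg, "avgPctCountsMito out of [0, 100]")
    if (!inRange(object@overallScore, 0, 1))
        msg <- c(msg, "overallScore out of [0, 1]")
    if (is.null(msg)) TRUE else msg
})

#' ScoreModel: weights for the overall contamination score
#'
#' The overall score is a weighted linear combination of five
#' contamination features bounded in [0, 1]: empty-droplet scaled slope
#' sum, inverted max secant distance, doubled inverted secant-line sd,
#' inverted AUC percentage, and average percent counts ambient as a
#' fraction. Weights are the absolute first-principal-component loadings
#' of those features in a PCA over a simulated calibration sweep
#' (standardized 6-feature input including the number of ambient genes),
#' renormalized to sum to one.
#'
#' @slot weights named non-negative numeric of length 5, summing to 1.
#' @slot pcaSummary numeric, explained-variance fractions of the PCA.
#' @slot provenance list, simulation parameters and seed used to derive
#'   the weights.
#'
#' @seealso [deriveScoreModel()], [defaultScoreModel()], [overallScore()]
#' @export
setClass("ScoreModel", representation(
    weights = "numeric",
    pcaSummary = "numeric",
    provenance = "list"
))

setValidity("ScoreModel", function(object) {
    msg <- NULL
    if (length(object@weights) != 5L)
        msg <- c(msg, "weights must have length 5")
    if (any(object@weights < 0))
        msg <- c(msg, "weights must be non-negative")
    if (abs(sum(object@weights) - 1) > 1e-8)
        msg <- c(msg, "weights must sum to 1")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "RankedCurve", function(object) {
    cat("RankedCurve with", object@N, "retained barcodes\n")
    cat("  estimated cells:", object@nCellsEst,
        if (object@lowConfidence) "(low confidence)" else "", "\n")
    cat("  truncation multiple:", object@multiple, "\n")
})

setMethod("show", "SecantProfile", function(object) {
    cat("SecantProfile over", length(object@d), "ranks\n")
    cat(sprintf("  max distance: %.4f  population sd: %.4f\n",
                object@maxD, object@sdD))
})

setMethod("show", "SlopeDistribution", function(object) {
    cat("SlopeDistribution:", length(object@slopes), "slopes in",
        length(object@mids), "bins",
        if (object@degenerate) "(degenerate)" else "", "\n")
    cat(sprintf("  threshold (median + sd): %.3g  empty-droplet sum: %.4f\n",
                object@threshold, object@emptySum))
})

setMethod("show", "AmbientGeneSet", function(object) {
    cat("AmbientGeneSet:", object@nAmbient, "of", length(object@dropout),
        "genes with dropout <", object@threshold, "\n")
})

setMethod("show", "MetricSet", function(object) {
    if (!is.na(object@sampleId)) cat("MetricSet for", object@sampleId, "\n")
    else cat("MetricSet\n")
    v <- metricValues(object)
    for (nm in names(v))
        cat(sprintf("  %-28s %s\n", nm, format(v[[nm]], digits = 6)))
})

setMethod("show", "ScoreModel", function(object) {
    cat("ScoreModel (overall contamination score weights)\n")
    for (nm in names(object@weights))
        cat(sprintf("  %-28s %.4f\n", nm, object@weights[[nm]]))
    if (length(object@pcaSummary))
        cat(sprintf("  PC1 explained variance: %.1f%%\n",
                    100 * object@pcaSummary[1]))
})

.metricOrder <- c(
    "emptyDropletSlopeSum", "invertedMaxSecant", "invertedSecantSD",
    "invertedAUCPct", "nAmbientGenes", "avgPctCountsAmbient",
    "avgAmbientUMIPerCell", "nCells", "avgPctCountsMito",
    "avgGenesPerCell", "avgUMIPerCell", "overallScore"
)

#' Extract metric values in canonical report order
#'
#' @param x a [MetricSet-class].
#' @return Named numeric vector: the five contamination metrics, the
#'   ambient-gene metrics, the standard QC metrics, and the overall score.
#' @export
metricValues <- function(x) {
    stopifnot(is(x, "MetricSet"))
    vapply(.metricOrder, function(nm) as.numeric(slot(x, nm)), numeric(1))
}

#' Accessors for RankedCurve and ScoreModel
#'
#' @param x a [RankedCurve-class] or [ScoreModel-class].
#' @return `nCellsEst()` the estimated cell number; `retainedBarcodes()`
#'   retained barcode ids in rank order; `scoreWeights()` the named weight
#'   vector of a score model.
#' @name accessors
NULL

#' @rdname accessors
#' @export
nCellsEst <- function(x) x@nCellsEst

#' @rdname accessors
#' @export
retainedBarcodes <- function(x) x@barcodes

#' @rdname accessors
#' @export
scoreWeights <- function(x) x@weights
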