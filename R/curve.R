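#' Rank barcodes by total UMI count
#'
#' Stable descending sort of per-barcode total counts; ties keep the
#' original barcode order. This is the first step of every downstream
#' metric: in unfiltered data, droplets capturing real cells contribute
#' distinctly larger totals than empty droplets.
#'
#' @param x count matrix (genes x barcodes sparse matrix or
#'   SingleCellExperiment).
#' @return Named numeric vector of totals, sorted descending; names are
#'   barcode ids.
#' @export
rankBarcodes <- function(x) {
    counts <- .countsMatrix(x)
    totals <- Matrix::colSums(counts)
    if (sum(totals) == 0) stop("no counts: all barcode totals are zero")
    ord <- order(-totals)    # radix order is stable: ties by input order
    totals[ord]
}

#' Estimate the real-cell number from the cumulative-count knee
#'
#' Locates the first inflection (knee) of the cumulative total-count
#' curve over barcodes ranked by descending total. The curve of
#' normalized cumulative counts versus normalized rank is concave, so it
#' lies on or above the chord joining its endpoints; the knee is taken
#' as the maximum vertical distance to that chord, which for a concave
#' curve is the unique point where per-barcode totals cross their mean —
#' the boundary between the high-increment (cell) and low-increment
#' (empty droplet) regimes. The distance profile is smoothed with a
#' 5-point moving average to locate the peak region, then the raw argmax
#' within that region gives the rank. When the curve has no distinct knee
#' (near-uniform totals) the estimate falls back to
#' `length(totals) / multiple` with a warning, and the result carries
#' `attr(x, "lowConfidence") = TRUE`.
#'
#' @param totals per-barcode totals sorted descending (as from
#'   [rankBarcodes()]); zero-total barcodes contribute the flat tail of
#'   the curve, and at least 3 positive totals are required.
#' @param multiple truncation multiple used only for the degenerate
#'   fallback (default 4).
#' @return Integer estimate of the number of real cells, in
#'   `[1, length(totals)]`.
#' @export
estimateCellNumber <- function(totals, multiple = 4) {
    n <- length(totals)
    if (sum(totals > 0) < 3)
        stop("need at least 3 barcodes with positive counts")
    u <- seq_len(n) / n
    v <- cumsum(as.numeric(totals))
    v <- v / v[n]
    # vertical distance to the chord; >= 0 for the concave curve
    d <- v - u
    w <- 5L
    sm <- stats::filter(d, rep(1 / w, w), sides = 2)
    sm[is.na(sm)] <- d[is.na(sm)]
    if (max(d) < 1e-3) {
        warning("no distinct knee in the cumulative-count curve; ",
                "falling back to length(totals)/multiple")
        est <- max(1L, as.integer(round(n / multiple)))
        attr(est, "lowConfidence") <- TRUE
        return(est)
    }
    peak <- .firstLocalMax(as.numeric(sm))
    lo <- max(1L, peak - 2L); hi <- min(n, peak + 2L)
    est <- as.integer(lo + which.max(d[lo:hi]) - 1L)
    attr(est, "lowConfidence") <- FALSE
    est
}

# First strict local maximum of a series (plateaus resolved to their first
# index); falls back to the global argmax when the series is monotone.
.firstLocalMax <- function(y) {
    n <- length(y)
    if (n < 3) return(which.max(y))
    for (i in 2:(n - 1)) {
        if (y[i] > y[i - 1] && y[i] >= y[i + 1]) return(i)
    }
    which.max(y)
}

#' Truncate to a multiple of the estimated cell number and normalize
#'
#' Retains the top `N = multiple * nCellsEst` barcodes (all barcodes, with
#' a warning, if fewer are available) and builds the normalized
#' cumulative-count curve: `x = i/N` and `c = cumsum(totals)/sum(totals)`
#' over the retained set, so the curve ends exactly at (1, 1). Scaling
#' the barcode count relative to the expected cell number makes curves
#' comparable between samples with different numbers of encapsulated
#' cells and empty droplets.
#'
#' @param x count matrix or SingleCellExperiment.
#' @param nCellsEst estimated real-cell number; when NULL it is estimated
#'   with [estimateCellNumber()]. A user-supplied expected cell number
#'   bypasses estimation entirely.
#' @param multiple truncation multiple (default 4).
#' @return A [RankedCurve-class].
#' @examples
#' m <- Matrix::rsparsematrix(50, 200, 0.3,
#'                            rand.x = function(n) rpois(n, 5) + 1)
#' curve <- rankedCurve(m, nCellsEst = 40)
#' curve
#' @export
rankedCurve <- function(x, nCellsEst = NULL, multiple = 4) {
    .assertCount(multiple, "multiple")
    totals <- rankBarcodes(x)
    low <- FALSE
    if (is.null(nCellsEst)) {
        nCellsEst <- estimateCellNumber(totals, multiple = multiple)
        low <- isTRUE(attr(nCellsEst, "lowConfidence"))
    }
    .assertCount(nCellsEst, "nCellsEst")
    N <- as.integer(multiple) * as.integer(nCellsEst)
    if (N > length(totals)) {
        warning(sprintf(
            "requested %d barcodes (multiple x nCellsEst) but only %d %s",
            N, length(totals), "available; keeping all"))
        N <- length(totals)
    }
    kept <- totals[seq_len(N)]
    methods::new("RankedCurve",
        totals = as.numeric(kept),
        x = seq_len(N) / N,
        c = cumsum(as.numeric(kept)) / sum(kept),
        barcodes = names(kept),
        nCellsEst = as.integer(nCellsEst),
        multiple = as.integer(multiple),
        N = N,
        lowConfidence = low)
}

#' Subset a count matrix to the retained barcodes of a RankedCurve
#'
#' Returns the matrix restricted to the curve's retained barcodes, with
#' columns in rank order (highest total first); gene-level metrics
#' (dropout, ambient percentages, standard QC) are computed on this
#' truncated matrix.
#'
#' @param x the count matrix the curve was built from.
#' @param curve a [RankedCurve-class].
#' @return genes x retained-barcodes sparse matrix in rank order.
#' @export
truncatedCounts <- function(x, curve) {
    counts <- .countsMatrix(x)
    missing <- setdiff(curve@barcodes, colnames(counts))
    if (length(missing))
        stop("count matrix lacks retained barcodes, e.g. ", missing[1])
    counts[, curve@barcodes, drop = FALSE]
}
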