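#' Per-barcode slopes of the normalized cumulative-count curve
#'
#' The slope at rank i is `c[i] - c[i-1]` (with c[0] = 0), i.e. each
#' retained barcode's total count normalized by the grand total. Slopes
#' are non-negative, non-increasing in rank and sum to 1. Cell-bearing
#' droplets contribute the high-slope mode of the distribution and empty
#' droplets the low-slope mode.
#'
#' @param curve a [RankedCurve-class].
#' @return Numeric vector of slopes.
#' @export
slopeSeries <- function(curve) {
    stopifnot(is(curve, "RankedCurve"))
    # computed directly from the totals: identical to diff(c(0, c)) in
    # exact arithmetic, but free of cumsum round-off, so exactly equal
    # totals give exactly equal slopes
    curve@totals / sum(curve@totals)
}

#' Scaled slope distribution and empty-droplet threshold
#'
#' Bins the slopes into `nBins` equal-width bins (default 100, fixed for
#' comparability across datasets), multiplies each bin's frequency by its
#' midpoint so that the sparse high-slope (cell) bins gain mass against
#' the dominant low-slope (empty droplet) bins, and renormalizes the
#' scaled values to sum to one. The cell/empty threshold is
#' `median(slopes) + population sd(slopes)`, computed on the raw
#' (unbinned) slopes: the empty-droplet mode dominates by construction
#' (the retained set is a multiple of the estimated cell number), so the
#' median estimates its center robustly, and one standard deviation above
#' it excludes ~84% of a Gaussian-shaped empty mode while keeping the
#' high-slope tail.
#'
#' @param slopes numeric slopes from [slopeSeries()] (at least 3).
#' @param nBins number of histogram bins (default 100).
#' @param range `"data"` (default) bins over [min, max] of the slopes;
#'   `"zero"` bins over [0, max].
#' @return A [SlopeDistribution-class]. All-identical slopes yield a
#'   flagged degenerate single-bin distribution with `emptySum = 1` (all
#'   mass at/below the threshold).
#' @export
scaledSlopeDistribution <- function(slopes, nBins = 100,
                                    range = c("data", "zero")) {
    range <- match.arg(range)
    if (length(slopes) < 3) stop("need at least 3 slopes")
    if (any(slopes < -1e-12)) stop("slopes must be non-negative")
    slopes <- pmax(0, slopes)
    thr <- median(slopes) + .popsd(slopes)
    if (diff(range(slopes)) <= 1e-12 * max(slopes)) {
        return(methods::new("SlopeDistribution",
            slopes = slopes, mids = slopes[1], freqs = length(slopes),
            scaledY = 1, threshold = thr, emptySum = 1,
            degenerate = TRUE))
    }
    lo <- if (range == "zero") 0 else min(slopes)
    edges <- seq(lo, max(slopes), length.out = nBins + 1)
    # bin b covers (edges[b], edges[b+1]]; the minimum falls in bin 1
    bin <- findInterval(slopes, edges, rightmost.closed = TRUE,
                        left.open = TRUE)
    bin[bin == 0L] <- 1L
    freqs <- tabulate(bin, nbins = nBins)
    mids <- (edges[-1] + edges[-(nBins + 1)]) / 2
    y <- mids * freqs
    methods::new("SlopeDistribution",
        slopes = slopes, mids = mids, freqs = freqs,
        scaledY = y / sum(y), threshold = thr,
        emptySum = sum((y / sum(y))[mids <= thr]),
        degenerate = FALSE)
}

#' Empty-droplet scaled slope sum
#'
#' The mass of the scaled slope distribution in bins whose midpoint is at
#' or below the median + sd threshold: the scaled slope contribution of
#' barcodes behaving like empty droplets. It rises with the dataset's
#' ambient contamination level; the complementary cell-side sum is
#' `1 - emptyDropletSlopeSum`.
#'
#' @param dist a [SlopeDistribution-class].
#' @return Score in [0, 1].
#' @export
emptyDropletSlopeSum <- function(dist) {
    stopifnot(is(dist, "SlopeDistribution"))
    dist@emptySum
}

#' Coverage of the median + 1 sd threshold under a Gaussian
#'
#' Self-test of the threshold rationale: for Gaussian data the fraction
#' of draws strictly below median + 1 standard deviation converges to
#' Phi(1) ~ 0.8413, i.e. the threshold excludes about 84% of a
#' Gaussian-shaped empty-droplet mode.
#'
#' @param nDraws number of standard-normal draws (>= 1e4).
#' @param seed integer RNG seed.
#' @return Proportion of draws strictly below median + population sd.
#' @export
gaussianThresholdCoverage <- function(nDraws = 1e6, seed = 1L) {
    if (nDraws < 1e4) stop("'nDraws' must be at least 1e4")
    set.seed(as.integer(seed))
    z <- rnorm(nDraws)
    mean(z < median(z) + .popsd(z))
}
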