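#' Secant-line distances between the cumulative curve and its diagonal
#'
#' After normalization the diagonal joining the origin to the last data
#' point is y = x, so the secant distance at rank i is the vertical gap
#' `c[i] - x[i]` (clamped at 0 against numerical noise; it is
#' non-negative for any concave normalized curve). The maximum and the
#' population standard deviation of these distances summarize how far,
#' and how unevenly, the curve bulges above the diagonal: a clean dataset
#' rises steeply within the first 1/multiple of the barcodes and then
#' flattens, while heavy ambient contamination keeps the curve near the
#' diagonal.
#'
#' @param curve a [RankedCurve-class].
#' @return A [SecantProfile-class].
#' @export
secantProfile <- function(curve) {
    stopifnot(is(curve, "RankedCurve"))
    d <- pmax(0, curve@c - curve@x)
    methods::new("SecantProfile", d = d, maxD = max(d), sdD = .popsd(d))
}

#' Inverted maximum secant distance
#'
#' `1 - max(d)`: near 0 for a sharply kneed (clean) curve, 1 for a curve
#' lying on the diagonal (all noise). Higher means more contaminated.
#'
#' @param profile a [SecantProfile-class].
#' @return Score in [0, 1].
#' @export
invertedMaxSecant <- function(profile) {
    stopifnot(is(profile, "SecantProfile"))
    1 - profile@maxD
}

#' Inverted secant-line standard deviation
#'
#' `0.5 - sd(d)` with the population standard deviation. On normalized
#' curves all distances lie in [0, 1) and even the adversarial 3-point
#' extreme (distances approaching 1, 0, 0) keeps the population sd below
#' 0.5, so the inverted value is always positive. Higher means more
#' contaminated.
#'
#' @param profile a [SecantProfile-class].
#' @return Score in [0, 0.5].
#' @export
invertedSecantSD <- function(profile) {
    stopifnot(is(profile, "SecantProfile"))
    0.5 - profile@sdD
}

#' Inverted AUC percentage of the cumulative-count curve
#'
#' The minimal circumscribing rectangle of the curve has area
#' (number of barcodes) x (maximum cumulative count), which is exactly 1
#' after normalization. The AUC percentage is the trapezoidal area under
#' the curve, with the origin (0, 0) prepended so the diagonal anchoring
#' is well defined; the metric is `2 * (1 - AUC percentage)`, i.e. the
#' area above the curve relative to the triangle above the diagonal: 0
#' for a rectangular-hyperbola (clean) curve, 1 for the diagonal
#' (all-noise) curve.
#'
#' @param curve a [RankedCurve-class].
#' @return Score in [0, 1].
#' @export
invertedAUCPercentage <- function(curve) {
    stopifnot(is(curve, "RankedCurve"))
    2 * (1 - aucPercentage(curve))
}

#' Area under the normalized cumulative-count curve
#'
#' Trapezoidal rule on (0,0) followed by the curve points; equals the
#' ratio of the raw area under the curve to the minimal rectangle area.
#'
#' @param curve a [RankedCurve-class].
#' @return AUC percentage in [0.5, 1] for concave curves.
#' @export
aucPercentage <- function(curve) {
    stopifnot(is(curve, "RankedCurve"))
    xs <- c(0, curve@x)
    ys <- c(0, curve@c)
    sum(diff(xs) * (head(ys, -1) + tail(ys, -1)) / 2)
}
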