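# Internal helpers shared across modules.

# Population (not sample) standard deviation. The 0.5 upper bound argued for
# secant distances holds for the population form down to n = 3, so it is used
# everywhere a spread enters a metric.
.popsd <- function(x) {
    n <- length(x)
    if (n == 0L) return(NA_real_)
    sqrt(sum((x - mean(x))^2) / n)
}

# Coerce any accepted input to a genes x barcodes dgCMatrix of counts.
.countsMatrix <- function(x) {
    if (is(x, "SummarizedExperiment")) {
        an <- SummarizedExperiment::assayNames(x)
        nm <- if ("counts" %in% an) "counts" else an[1]
        x <- SummarizedExperiment::assay(x, nm)
    }
    if (is.matrix(x)) x <- methods::as(x, "CsparseMatrix")
    if (!is(x, "CsparseMatrix"))
        x <- methods::as(methods::as(x, "CsparseMatrix"), "generalMatrix")
    if (any(x@x < 0)) stop("count matrix contains negative values")
    if (is.null(rownames(x)))
        rownames(x) <- sprintf("gene%05d", seq_len(nrow(x)))
    if (is.null(colnames(x)))
        colnames(x) <- sprintf("BC%06d", seq_len(ncol(x)))
    x
}

# Deterministic per-dataset seed for sweeps: documented, stable across runs,
# and kept below 2^31 - 1 so it is a valid R integer seed.
.fanoutSeed <- function(baseSeed, levelIdx, repIdx) {
    s <- (as.double(baseSeed) %% 2147483647 +
          as.double(levelIdx) * 1000003 +
          as.double(repIdx)) %% 2147483647
    as.integer(s)
}

# Truncated-normal draw used for dataset sizes and per-cell totals:
# mean `center`, 10% coefficient of variation, floored at 1.
.sizeDraw <- function(n, center, cv = 0.1) {
    pmax(1, round(rnorm(n, mean = center, sd = cv * center)))
}

.assertCount <- function(x, name, minimum = 1) {
    if (length(x) != 1L || !is.finite(x) || x < minimum ||
        x != as.integer(x))
        stop(sprintf("'%s' must be a single integer >= %s", name, minimum))
}
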