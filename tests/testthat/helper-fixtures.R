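# Shared fixtures: all built in code, at sizes small enough for fast tests.

# A tiny simulated dataset; defaults keep one sim under ~0.1 s.
tinySim <- function(ambientLevel = 50, seed = 1, nCells = 100,
                    nDroplets = 600, bioUMI = 2000, nGenes = 300,
                    randomize = FALSE, ...) {
    simulateDroplets(nCells = nCells, nDroplets = nDroplets,
                     bioUMI = bioUMI, nGenes = nGenes,
                     ambientLevel = ambientLevel, randomize = randomize,
                     seed = seed, ...)
}

simCounts <- function(sim) SummarizedExperiment::assay(sim, "counts")

# Build a RankedCurve directly from a vector of descending totals,
# bypassing cell estimation (nCellsEst chosen so nothing is truncated).
curveFromTotals <- function(totals, multiple = 1) {
    m <- Matrix::sparseMatrix(i = rep(1, length(totals)),
                              j = seq_along(totals), x = totals,
                              dims = c(1, length(totals)))
    rownames(m) <- "g1"
    colnames(m) <- paste0("bc", seq_along(totals))
    rankedCurve(m, nCellsEst = length(totals), multiple = multiple)
}

# Dense toy count matrix with named dims.
toyMatrix <- function(values, nGenes, nBarcodes) {
    m <- methods::as(Matrix::Matrix(matrix(values, nGenes, nBarcodes),
                                    sparse = TRUE), "generalMatrix")
    dimnames(m) <- list(sprintf("g%02d", seq_len(nGenes)),
                        sprintf("bc%02d", seq_len(nBarcodes)))
    m
}

# Independent trapezoid oracle used against the package's AUC.
trapzOracle <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

popsdOracle <- function(x) sqrt(mean((x - mean(x))^2))
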