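#' Simulate an unfiltered droplet dataset with controllable ambient RNA
#'
#' Generates a synthetic raw (pre-filtering) droplet-by-gene UMI count
#' matrix. Each droplet either contains a cell or is empty. Cell droplets
#' draw a biological UMI total around `bioUMI` and distribute it
#' multinomially over their cluster's gene-expression profile; clusters
#' share a common sparse baseline but carry distinct high-expression gene
#' sets, so profiles are similar within and distinct between clusters.
#' Every droplet (cell or empty) additionally draws an ambient UMI total
#' from a lognormal distribution with arithmetic mean `ambientLevel`
#' (sdlog = 0.5) and distributes it multinomially over the ambient
#' profile, defined as the expression-weighted average of all simulated
#' cell profiles. An ambient level of 5 against a biological center of
#' 5000 corresponds to a ~0.001 noise-to-signal ratio; 4900 corresponds
#' to ~0.98, a severe quality failure.
#'
#' When `randomize = TRUE` the per-dataset numbers of cells, droplets and
#' the biological UMI center are themselves drawn from truncated normals
#' (10% CV, floored at 1) around the supplied centers, emulating
#' dataset-to-dataset variation in a cohort.
#'
#' @param nCells expected number of real cells (center, default 2000).
#' @param nDroplets total number of droplets (center, default 12000).
#' @param bioUMI biological UMIs per cell (center, default 5000).
#' @param ambientLevel mean ambient UMIs per droplet (>= 0; the calibrated
#'   range is 5 to 4900).
#' @param nClusters number of cell-type clusters (default 5).
#' @param nGenes number of genes (default 2000).
#' @param randomize draw dataset sizes around the centers (default TRUE);
#'   FALSE fixes them exactly.
#' @param seed integer RNG seed; the output is a deterministic function of
#'   the parameters and seed.
#'
#' @return A [SingleCellExperiment::SingleCellExperiment] with a sparse
#'   `counts` assay (genes x droplets), `colData` columns `isCell`,
#'   `cluster` (NA for empty droplets), `bioUMI` and `ambientUMI` (the
#'   per-droplet truth totals; their sum equals the droplet's column sum),
#'   and the simulation parameters in `metadata(x)$params`.
#'
#' @examples
#' sim <- simulateDroplets(nCells = 50, nDroplets = 300, bioUMI = 800,
#'                         nGenes = 200, ambientLevel = 40, seed = 1)
#' table(sim$isCell)
#' @export
simulateDroplets <- function(nCells = 2000, nDroplets = 12000,
                             bioUMI = 5000, ambientLevel = 100,
                             nClusters = 5, nGenes = 2000,
                             randomize = TRUE, seed = 1L) {
    .assertCount(nCells, "nCells")
    .assertCount(nDroplets, "nDroplets")
    .assertCount(bioUMI, "bioUMI")
    .assertCount(nClusters, "nClusters")
    .assertCount(nGenes, "nGenes")
    if (!is.finite(ambientLevel) || ambientLevel < 0)
        stop("'ambientLevel' must be >= 0")
    if (nCells >= nDroplets)
        stop("'nCells' must be smaller than 'nDroplets'")
    params <- list(nCells = nCells, nDroplets = nDroplets, bioUMI = bioUMI,
                   ambientLevel = ambientLevel, nClusters = nClusters,
                   nGenes = nGenes, randomize = randomize, seed = seed)
    set.seed(as.integer(seed))

    if (randomize) {
        nC <- .sizeDraw(1, nCells)
        nD <- .sizeDraw(1, nDroplets)
        bioCenter <- .sizeDraw(1, bioUMI)
        nC <- min(nC, nD - 1)
    } else {
        nC <- nCells; nD <- nDroplets; bioCenter <- bioUMI
    }

    # Cluster profiles: Dirichlet draws over genes with a distinct sparse
    # high-concentration gene block per cluster.
    markersPer <- max(1L, floor(0.05 * nGenes))
    profiles <- matrix(0, nGenes, nClusters)
    markerPool <- sample.int(nGenes)
    for (k in seq_len(nClusters)) {
        alpha <- rep(0.1, nGenes)
        idx <- markerPool[((k - 1) %% floor(nGenes / markersPer)) *
                              markersPer + seq_len(markersPer)]
        alpha[idx] <- 5
        g <- rgamma(nGenes, shape = alpha)
        profiles[, k] <- g / sum(g)
    }

    cellIdx <- sort(sample.int(nD, nC))
    isCell <- logical(nD); isCell[cellIdx] <- TRUE
    cluster <- rep(NA_integer_, nD)
    cluster[cellIdx] <- sample.int(nClusters, nC, replace = TRUE)
    bioTotal <- integer(nD)
    bioTotal[cellIdx] <- as.integer(.sizeDraw(nC, bioCenter))

    # Ambient profile: expression-weighted average of the cell profiles.
    wt <- vapply(seq_len(nClusters), function(k)
        sum(bioTotal[cellIdx][cluster[cellIdx] == k]), numeric(1))
    if (sum(wt) == 0) wt <- rep(1, nClusters)
    ambProfile <- as.numeric(profiles %*% (wt / sum(wt)))

    if (ambientLevel > 0) {
        sdlog <- 0.5
        meanlog <- log(ambientLevel) - sdlog^2 / 2
        ambTotal <- as.integer(round(rlnorm(nD, meanlog, sdlog)))
    } else {
        ambTotal <- integer(nD)
    }

    iList <- vector("list", nD)
    xList <- vector("list", nD)
    for (j in seq_len(nD)) {
        v <- if (ambTotal[j] > 0)
            rmultinom(1, ambTotal[j], ambProfile)[, 1] else numeric(nGenes)
        if (isCell[j])
            v <- v + rmultinom(1, bioTotal[j], profiles[, cluster[j]])[, 1]
        nz <- which(v > 0)
        iList[[j]] <- nz
        xList[[j]] <- v[nz]
    }
    lens <- lengths(iList)
    counts <- Matrix::sparseMatrix(
        i = unlist(iList, use.names = FALSE),
        j = rep.int(seq_len(nD), lens),
        x = unlist(xList, use.names = FALSE),
        dims = c(nGenes, nD),
        dimnames = list(sprintf("gene%05d", seq_len(nGenes)),
                        sprintf("BC%06d", seq_len(nD))))

    SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(
            isCell = isCell, cluster = cluster,
            bioUMI = bioTotal, ambientUMI = ambTotal,
            row.names = colnames(counts)),
        metadata = list(params = params,
                        realized = list(nCells = nC, nDroplets = nD,
                                        bioCenter = bioCenter)))
}

#' Simulate datasets over a sweep of ambient contamination levels
#'
#' One dataset per (level, replicate) pair, with per-dataset seeds derived
#' deterministically from the base seed, the level index and the replicate
#' index (`(seed + levelIndex * 1000003 + replicate) mod (2^31 - 1)`), so
#' a sweep is reproducible and individual datasets can be regenerated in
#' isolation.
#'
#' @param levels numeric vector of ambient UMI levels (non-empty).
#' @param replicates datasets per level (>= 1).
#' @param seed base seed for the fan-out.
#' @param FUN optional function applied to each dataset; when supplied its
#'   value is stored instead of the dataset, which keeps large sweeps in
#'   constant memory.
#' @param ... further arguments passed to [simulateDroplets()]
#'   (`nCells`, `nDroplets`, `bioUMI`, ...).
#'
#' @return A list with one element per (level, replicate), in level-major
#'   order; each element carries attributes `ambientLevel` and `seed` via
#'   the accompanying data.frame `attr(result, "design")`.
#' @export
sweepAmbientLevels <- function(levels, replicates = 1, seed = 1L,
                               FUN = NULL, ...) {
    if (length(levels) < 1) stop("'levels' must be non-empty")
    .assertCount(replicates, "replicates")
    design <- expand.grid(replicate = seq_len(replicates),
                          levelIndex = seq_along(levels))
    design <- design[order(design$levelIndex, design$replicate), ]
    design$ambientLevel <- levels[design$levelIndex]
    design$seed <- mapply(.fanoutSeed, seed, design$levelIndex,
                          design$replicate)
    out <- vector("list", nrow(design))
    for (r in seq_len(nrow(design))) {
        ds <- simulateDroplets(ambientLevel = design$ambientLevel[r],
                               seed = design$seed[r], ...)
        out[[r]] <- if (is.null(FUN)) ds else FUN(ds)
    }
    rownames(design) <- NULL
    attr(out, "design") <- design
    out
}

#' Downsample a count matrix to a fraction of its total UMIs
#'
#' Emulates reduced sequencing depth. The default scheme samples the
#' target number of UMIs without replacement from the individual UMIs of
#' the matrix, so the output total is exactly `round(fraction * total)`
#' and `fraction = 1` is the identity. `replace = TRUE` instead resamples
#' the target total with replacement (a multinomial over entries), the
#' behaviour of common single-cell toolkits.
#'
#' @param x count matrix (genes x barcodes sparse matrix or a
#'   SingleCellExperiment, whose `counts` assay is replaced).
#' @param fraction target fraction of total UMIs, in (0, 1].
#' @param seed integer RNG seed.
#' @param replace use with-replacement resampling (default FALSE).
#' @return Object of the same class as `x` with downsampled counts.
#' @export
downsampleCounts <- function(x, fraction, seed = 1L, replace = FALSE) {
    if (!is.numeric(fraction) || length(fraction) != 1L ||
        fraction <= 0 || fraction > 1)
        stop("'fraction' must lie in (0, 1]")
    counts <- .countsMatrix(x)
    total <- sum(counts@x)
    target <- round(fraction * total)
    set.seed(as.integer(seed))
    if (replace) {
        newx <- rmultinom(1, target, prob = counts@x)[, 1]
    } else if (fraction == 1) {
        newx <- counts@x
    } else {
        umis <- rep.int(seq_along(counts@x), counts@x)
        keep <- umis[sample.int(length(umis), target)]
        newx <- tabulate(keep, nbins = length(counts@x))
    }
    out <- counts
    out@x <- as.double(newx)
    out <- Matrix::drop0(out)
    if (is(x, "SummarizedExperiment")) {
        SummarizedExperiment::assay(x, "counts") <- out
        x
    } else out
}
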