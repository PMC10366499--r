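#' Per-gene dropout rate over retained barcodes
#'
#' The dropout rate of a gene is the fraction of retained barcodes (cells
#' plus empty droplets within the truncation window) in which the gene
#' has zero counts. Ambient transcripts contaminate essentially every
#' droplet, so ambient genes sit at the very bottom of the dropout
#' distribution.
#'
#' @param x truncated count matrix from [truncatedCounts()] (genes x
#'   barcodes), or a SingleCellExperiment.
#' @return Named numeric vector of per-gene dropout rates in [0, 1].
#' @export
geneDropout <- function(x) {
    counts <- .countsMatrix(x)
    1 - Matrix::rowSums(counts > 0) / ncol(counts)
}

#' Classify ambient genes by dropout rate
#'
#' A gene is called ambient when its dropout rate is strictly below
#' `threshold` (default 0.02). Detection of a truly ubiquitous transcript
#' follows binomial sampling, so even a gene present in every droplet
#' shows a few percent dropout at realistic expression; 2% keeps only
#' highly prevalent transcripts and is a user-tunable parameter.
#'
#' @param dropout named per-gene dropout vector from [geneDropout()].
#' @param threshold dropout cutoff in (0, 1] (strict inequality).
#' @return An [AmbientGeneSet-class].
#' @export
ambientGenes <- function(dropout, threshold = 0.02) {
    if (!is.numeric(dropout) || is.null(names(dropout)))
        stop("'dropout' must be a named numeric vector")
    if (threshold <= 0 || threshold > 1)
        stop("'threshold' must lie in (0, 1]")
    ids <- names(dropout)[dropout < threshold]
    methods::new("AmbientGeneSet", dropout = dropout, ambientIds = ids,
                 threshold = threshold, nAmbient = length(ids))
}

#' Percent of per-cell counts falling in ambient genes
#'
#' For each of the top `nCells` retained barcodes (the putative cells),
#' the percentage of its UMIs that fall in ambient genes, together with
#' the mean percentage and the mean ambient UMI count per cell. A cell
#' barcode with zero total counts gets 0% with a warning.
#'
#' @param x truncated count matrix with columns in rank order (as
#'   returned by [truncatedCounts()]).
#' @param ambient an [AmbientGeneSet-class] computed on the same matrix.
#' @param nCells number of top-ranked barcodes treated as cells
#'   (the estimated real-cell number).
#' @return List with `pct` (per-cell percentages), `avgPct` and
#'   `avgAmbientUMI`.
#' @export
percentCountsAmbient <- function(x, ambient, nCells) {
    counts <- .countsMatrix(x)
    stopifnot(is(ambient, "AmbientGeneSet"))
    .assertCount(nCells, "nCells")
    nCells <- min(nCells, ncol(counts))
    cells <- counts[, seq_len(nCells), drop = FALSE]
    tot <- Matrix::colSums(cells)
    amb <- if (ambient@nAmbient > 0)
        Matrix::colSums(cells[ambient@ambientIds, , drop = FALSE])
    else rep(0, nCells)
    pct <- numeric(nCells)
    pos <- tot > 0
    if (any(!pos))
        warning(sum(!pos), " cell barcode(s) with zero total counts; ",
                "their ambient percentage is reported as 0")
    pct[pos] <- 100 * amb[pos] / tot[pos]
    list(pct = pct, avgPct = mean(pct), avgAmbientUMI = mean(amb))
}

#' Standard per-cell quality-control metrics
#'
#' Total transcript counts, detected genes and mitochondrial count
#' percentage, averaged over the top `nCells` retained barcodes (the
#' estimated-cell set). Mitochondrial genes are matched by symbol prefix
#' (gene symbols when available, identifiers otherwise), configurable per
#' species.
#'
#' @param x truncated count matrix with columns in rank order.
#' @param nCells number of top-ranked barcodes treated as cells.
#' @param mitoPrefixes character vector of symbol prefixes
#'   (default `c("mt-", "MT-")`).
#' @param symbols optional per-gene symbols (defaults to
#'   `rowData(x)$symbol` for a SingleCellExperiment, else row names).
#' @return List with `nCells`, `avgPctMito`, `avgGenes`, `avgUMI`.
#' @export
standardQC <- function(x, nCells, mitoPrefixes = c("mt-", "MT-"),
                       symbols = NULL) {
    counts <- .countsMatrix(x)
    .assertCount(nCells, "nCells")
    if (is.null(symbols)) {
        if (is(x, "SummarizedExperiment") &&
            "symbol" %in% colnames(SummarizedExperiment::rowData(x)))
            symbols <- SummarizedExperiment::rowData(x)$symbol
        else symbols <- rownames(counts)
    }
    nCells <- min(nCells, ncol(counts))
    cells <- counts[, seq_len(nCells), drop = FALSE]
    tot <- Matrix::colSums(cells)
    isMito <- Reduce(`|`, lapply(mitoPrefixes, function(p)
        startsWith(symbols, p)), rep(FALSE, nrow(counts)))
    if (!any(isMito)) {
        warning("no gene matched the mitochondrial prefixes (",
                paste(mitoPrefixes, collapse = ", "),
                "); percent mito reported as 0")
        pctMito <- rep(0, nCells)
    } else {
        mito <- Matrix::colSums(cells[isMito, , drop = FALSE])
        pctMito <- ifelse(tot > 0, 100 * mito / tot, 0)
    }
    list(nCells = nCells,
         avgPctMito = mean(pctMito),
         avgGenes = mean(Matrix::colSums(cells > 0)),
         avgUMI = mean(tot))
}
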