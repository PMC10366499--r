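#' Read a Matrix Market count matrix with barcode and feature annotations
#'
#' Reads a triplet-format sparse matrix (`matrix.mtx`, optionally
#' gzipped) together with `barcodes.tsv` and `features.tsv` (or
#' `genes.tsv`) annotation files, as written by CellRanger-style
#' pipelines. The on-disk orientation (genes-as-rows or barcodes-as-rows)
#' is auto-detected from the annotation file lengths; the returned object
#' is always genes x barcodes. Counts are preserved exactly and must be
#' non-negative integers.
#'
#' @param path directory containing the three files, or the path of the
#'   `.mtx` file itself.
#' @param barcodesFile,featuresFile optional explicit annotation paths;
#'   by default located next to the matrix file.
#' @param orientation `"auto"` (default), `"genesRows"` or
#'   `"barcodesRows"`; only needed for square matrices, where length-based
#'   detection is ambiguous.
#'
#' @return A [SingleCellExperiment::SingleCellExperiment] with a sparse
#'   integer `counts` assay, barcode ids as column names, gene ids as row
#'   names and, when the features file has a second column, gene symbols
#'   in `rowData(x)$symbol`.
#' @export
readMTX <- function(path, barcodesFile = NULL, featuresFile = NULL,
                    orientation = c("auto", "genesRows", "barcodesRows")) {
    orientation <- match.arg(orientation)
    locate <- function(dir, names) {
        for (nm in names) {
            for (ext in c("", ".gz")) {
                f <- file.path(dir, paste0(nm, ext))
                if (file.exists(f)) return(f)
            }
        }
        NULL
    }
    if (dir.exists(path)) {
        mtxFile <- locate(path, "matrix.mtx")
        if (is.null(mtxFile))
            stop("no matrix.mtx(.gz) found in ", path)
    } else mtxFile <- path
    dir <- dirname(mtxFile)
    if (is.null(barcodesFile)) barcodesFile <- locate(dir, "barcodes.tsv")
    if (is.null(featuresFile))
        featuresFile <- locate(dir, c("features.tsv", "genes.tsv"))
    if (is.null(barcodesFile) || !file.exists(barcodesFile))
        stop("barcodes.tsv(.gz) not found next to ", mtxFile)
    if (is.null(featuresFile) || !file.exists(featuresFile))
        stop("features.tsv(.gz)/genes.tsv(.gz) not found next to ", mtxFile)

    m <- Matrix::readMM(mtxFile)
    m <- methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
    bc <- read.delim(barcodesFile, header = FALSE,
                     stringsAsFactors = FALSE)
    ft <- read.delim(featuresFile, header = FALSE,
                     stringsAsFactors = FALSE)
    barcodes <- as.character(bc[[1]])
    genes <- as.character(ft[[1]])

    if (orientation == "auto") {
        if (nrow(m) == length(genes) && ncol(m) == length(barcodes)) {
            if (nrow(m) == ncol(m))
                stop("square matrix: orientation is ambiguous, pass ",
                     "'orientation' explicitly")
            orientation <- "genesRows"
        } else if (nrow(m) == length(barcodes) &&
                   ncol(m) == length(genes)) {
            orientation <- "barcodesRows"
        } else {
            stop(sprintf(paste0(
                "matrix is %d x %d but annotations have %d features ",
                "and %d barcodes"), nrow(m), ncol(m), length(genes),
                length(barcodes)))
        }
    }
    if (orientation == "barcodesRows") m <- Matrix::t(m)
    if (nrow(m) != length(genes) || ncol(m) != length(barcodes))
        stop("annotation lengths do not match the declared orientation")
    if (anyDuplicated(barcodes))
        stop("duplicate barcode identifier(s): ",
             paste(unique(barcodes[duplicated(barcodes)]), collapse = ", "))

    bad <- which(m@x != round(m@x))
    if (length(bad)) {
        rowIdx <- m@i[bad[1]] + 1L
        colIdx <- sum(m@p < bad[1])
        stop(sprintf(
            "non-integer count %g at matrix entry (row %d, column %d)",
            m@x[bad[1]], rowIdx, colIdx))
    }
    if (any(m@x < 0)) stop("negative counts are not allowed")
    dimnames(m) <- list(genes, barcodes)
    rd <- S4Vectors::DataFrame(row.names = genes)
    if (ncol(ft) >= 2) rd$symbol <- as.character(ft[[2]])
    SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = m), rowData = rd)
}

#' Write a count matrix (and simulation truth table) as Matrix Market
#'
#' Writes `matrix.mtx` (genes as rows), `barcodes.tsv` and
#' `features.tsv` into `dir`. For a simulated dataset carrying truth
#' labels, a `truth.tsv` with columns barcode, is_cell, cluster and
#' ambient_umi is written alongside.
#'
#' @param x SingleCellExperiment or sparse genes x barcodes matrix.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeMTX <- function(x, dir) {
    counts <- .countsMatrix(x)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    Matrix::writeMM(counts, file.path(dir, "matrix.mtx"))
    writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
    ft <- rownames(counts)
    if (is(x, "SummarizedExperiment")) {
        rd <- SummarizedExperiment::rowData(x)
        if ("symbol" %in% colnames(rd))
            ft <- paste(ft, rd$symbol, sep = "\t")
    }
    writeLines(ft, file.path(dir, "features.tsv"))
    if (is(x, "SummarizedExperiment")) {
        cd <- SummarizedExperiment::colData(x)
        if (all(c("isCell", "cluster", "ambientUMI") %in% colnames(cd))) {
            truth <- data.frame(barcode = colnames(counts),
                                is_cell = cd$isCell,
                                cluster = cd$cluster,
                                ambient_umi = cd$ambientUMI)
            write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                        quote = FALSE, row.names = FALSE)
        }
    }
    invisible(dir)
}

#' Read a 10x-style HDF5 raw count matrix
#'
#' Reads the compressed-sparse layout used by 10x `raw_feature_bc_matrix.h5`
#' containers (datasets `data`, `indices`, `indptr`, `shape`, `barcodes`
#' and `features/id`). Requires the Bioconductor package `rhdf5`; an
#' informative error is raised when it is not installed. The returned
#' object and validation rules are identical to [readMTX()].
#'
#' @param path path to the HDF5 file.
#' @param group group holding the matrix (default: first group in the
#'   file, `"matrix"` in current 10x output).
#' @return A SingleCellExperiment, genes x barcodes.
#' @export
readH5Counts <- function(path, group = NULL) {
    if (!requireNamespace("rhdf5", quietly = TRUE))
        stop("reading HDF5 counts requires the 'rhdf5' package; ",
             "install it or convert the input to Matrix Market ",
             "(matrix.mtx + barcodes.tsv + features.tsv) and use readMTX()")
    if (!file.exists(path)) stop("file not found: ", path)
    ls <- rhdf5::h5ls(path)
    if (is.null(group)) {
        grp <- unique(ls$name[ls$group == "/" & ls$otype == "H5I_GROUP"])
        if (!length(grp)) stop(
            "no group found; expected a 10x-style layout with datasets ",
            "data/indices/indptr/shape/barcodes/features under one group")
        group <- grp[1]
    }
    rd <- function(nm) rhdf5::h5read(path, paste0(group, "/", nm))
    shape <- as.integer(rd("shape"))
    xvals <- as.numeric(rd("data"))
    if (any(xvals != round(xvals)))
        stop("non-integer count value ", xvals[which(xvals != round(xvals))[1]],
             " in HDF5 matrix")
    m <- Matrix::sparseMatrix(i = as.integer(rd("indices")) + 1L,
                              p = as.integer(rd("indptr")),
                              x = xvals, dims = shape)
    barcodes <- as.character(rd("barcodes"))
    genes <- tryCatch(as.character(rd("features/id")),
                      error = function(e) as.character(rd("genes")))
    if (nrow(m) != length(genes) || ncol(m) != length(barcodes))
        stop("HDF5 shape does not match barcode/feature annotation lengths")
    if (anyDuplicated(barcodes))
        stop("duplicate barcode identifier(s): ",
             paste(unique(barcodes[duplicated(barcodes)]), collapse = ", "))
    dimnames(m) <- list(genes, barcodes)
    SingleCellExperiment::SingleCellExperiment(assays = list(counts = m))
}

#' Write a metric report for one or more datasets
#'
#' One row (CSV) or record (JSON) per dataset, fields in the canonical
#' report order (contamination metrics, ambient-gene metrics, standard QC
#' metrics, overall score), serialized at full precision.
#'
#' @param metricSets a [MetricSet-class] or list of them.
#' @param path output file path.
#' @param format `"csv"` or `"json"` (default from the file extension).
#' @return The report data.frame, invisibly.
#' @export
writeReport <- function(metricSets, path, format = NULL) {
    if (is(metricSets, "MetricSet")) metricSets <- list(metricSets)
    if (!length(metricSets)) stop("need at least one MetricSet")
    if (is.null(format))
        format <- if (grepl("\\.json$", path, ignore.case = TRUE))
            "json" else "csv"
    format <- match.arg(format, c("csv", "json"))
    df <- metricTable(metricSets)
    if (format == "csv") {
        utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    } else {
        jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA,
                             dataframe = "rows", na = "null")
    }
    invisible(df)
}

#' Tabulate MetricSets as a data.frame in canonical order
#'
#' @param metricSets a [MetricSet-class] or list of them.
#' @return data.frame with a `sample_id` column followed by the metric
#'   columns in canonical order.
#' @export
metricTable <- function(metricSets) {
    if (is(metricSets, "MetricSet")) metricSets <- list(metricSets)
    rows <- lapply(seq_along(metricSets), function(i) {
        ms <- metricSets[[i]]
        id <- if (!is.na(ms@sampleId)) ms@sampleId else
            if (!is.null(names(metricSets)[i]) &&
                nzchar(names(metricSets)[i])) names(metricSets)[i] else
            paste0("sample", i)
        cbind(data.frame(sample_id = id, stringsAsFactors = FALSE),
              as.data.frame(as.list(metricValues(ms))))
    })
    do.call(rbind, rows)
}
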