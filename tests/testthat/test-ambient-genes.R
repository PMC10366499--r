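test_that("dropout rates follow their definition exactly", {
    m <- toyMatrix(0, 3, 10)
    m[1, ] <- 1           # present everywhere: dropout 0
    m[2, 1:9] <- 1        # present in 9 of 10: dropout 0.1
    d <- geneDropout(m)
    expect_equal(unname(d), c(0, 0.1, 1))
    expect_true(all(d >= 0 & d <= 1))
})

test_that("the ambient-gene threshold is strict", {
    d <- setNames(c(0.00, 0.01, 0.02, 0.50), paste0("g", 1:4))
    amb <- ambientGenes(d, threshold = 0.02)
    expect_equal(amb@nAmbient, 2L)
    expect_identical(amb@ambientIds, c("g1", "g2"))
    expect_error(ambientGenes(unname(d)), "named")
    expect_error(ambientGenes(d, threshold = 0), "threshold")
})

test_that("ambient percentages per cell follow the arithmetic", {
    m <- toyMatrix(0, 4, 1)
    m[, 1] <- c(5, 20, 20, 5)
    amb <- ambientGenes(setNames(c(0, 1, 1, 1), rownames(m)))
    res <- percentCountsAmbient(m, amb, nCells = 1)
    expect_equal(res$pct, 10)        # 5 of 50 UMIs in ambient genes
    expect_equal(res$avgAmbientUMI, 5)
    # no ambient genes -> 0%; all genes ambient -> 100%
    none <- ambientGenes(setNames(rep(1, 4), rownames(m)))
    expect_equal(percentCountsAmbient(m, none, 1)$avgPct, 0)
    all <- ambientGenes(setNames(rep(0, 4), rownames(m)))
    expect_equal(percentCountsAmbient(m, all, 1)$avgPct, 100)
    # zero-total barcode is warned about and reported as 0
    m2 <- toyMatrix(0, 2, 2); m2[1, 1] <- 4
    amb2 <- ambientGenes(setNames(c(0.5, 1), rownames(m2)))
    expect_warning(r2 <- percentCountsAmbient(m2, amb2, 2), "zero total")
    expect_equal(r2$pct[2], 0)
})

test_that("ambient gene counts rise with the simulated ambient level", {
    nAmb <- vapply(c(10, 3000), function(lv) {
        sim <- tinySim(ambientLevel = lv, seed = 17, bioUMI = 5000)
        curve <- suppressWarnings(rankedCurve(sim, nCellsEst = 100))
        amb <- ambientGenes(geneDropout(truncatedCounts(sim, curve)))
        amb@nAmbient
    }, integer(1))
    expect_gt(nAmb[2], nAmb[1])
    # with distinct cluster profiles and no ambient RNA, cluster-specific
    # genes are not called ambient
    sim0 <- tinySim(ambientLevel = 0, seed = 17, bioUMI = 5000)
    curve0 <- suppressWarnings(rankedCurve(sim0, nCellsEst = 100))
    amb0 <- ambientGenes(geneDropout(truncatedCounts(sim0, curve0)))
    expect_equal(amb0@nAmbient, 0L)
})

test_that("ambient gene counts drop under aggressive downsampling", {
    sim <- tinySim(ambientLevel = 2000, seed = 19, bioUMI = 5000,
                   nCells = 150, nDroplets = 900)
    nAmbAt <- function(x) {
        curve <- suppressWarnings(rankedCurve(x, nCellsEst = 150))
        ambientGenes(geneDropout(truncatedCounts(x, curve)))@nAmbient
    }
    full <- nAmbAt(simCounts(sim))
    thin <- nAmbAt(downsampleCounts(simCounts(sim), 0.2, seed = 1))
    expect_lt(thin, full)
})

test_that("standard QC metrics average over the estimated-cell set", {
    m <- toyMatrix(0, 3, 2)
    m[1, ] <- c(90, 280)
    m[2, ] <- c(10, 20)
    rownames(m) <- c("Actb", "mt-Co1", "Gapdh")
    qc <- standardQC(m, nCells = 2)
    expect_equal(qc$avgUMI, 200)
    expect_equal(qc$avgGenes, 2)
    expect_equal(qc$avgPctMito, mean(c(100 * 10 / 100, 100 * 20 / 300)))
    # no mitochondrial match warns and reports 0
    rownames(m) <- c("a", "b", "c")
    expect_warning(qc0 <- standardQC(m, nCells = 2), "mitochondrial")
    expect_equal(qc0$avgPctMito, 0)
})

test_that("simulated per-cell depth matches biological + ambient truth", {
    sim <- tinySim(ambientLevel = 500, seed = 23, bioUMI = 5000,
                   nCells = 150, nDroplets = 900)
    curve <- rankedCurve(sim, nCellsEst = 150)
    qc <- suppressWarnings(standardQC(truncatedCounts(sim, curve), 150))
    expect_equal(qc$avgUMI, 5000 + 500, tolerance = 0.05)
})
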