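test_that("parameter validation rejects impossible settings", {
    expect_error(simulateDroplets(nCells = 0), "nCells")
    expect_error(simulateDroplets(ambientLevel = -1), "ambientLevel")
    expect_error(simulateDroplets(nCells = 600, nDroplets = 600),
                 "smaller")
    expect_error(sweepAmbientLevels(numeric(0)), "non-empty")
    expect_error(downsampleCounts(toyMatrix(1, 2, 2), fraction = 0),
                 "fraction")
    expect_error(downsampleCounts(toyMatrix(1, 2, 2), fraction = 1.2),
                 "fraction")
})

test_that("zero ambient level gives empty droplets no counts at all", {
    sim <- tinySim(ambientLevel = 0)
    tot <- Matrix::colSums(simCounts(sim))
    expect_true(all(tot[!sim$isCell] == 0))
    expect_equal(unname(tot[sim$isCell]),
                 as.numeric(sim$bioUMI[sim$isCell]))
})

test_that("every droplet conserves biological + ambient truth totals", {
    sim <- tinySim(ambientLevel = 80, seed = 4, randomize = TRUE)
    expect_equal(unname(Matrix::colSums(simCounts(sim))),
                 as.numeric(sim$bioUMI + sim$ambientUMI))
    expect_lte(sum(sim$isCell), ncol(sim))
    expect_true(all(is.na(sim$cluster[!sim$isCell])))
})

test_that("identical parameters and seed give identical datasets", {
    a <- tinySim(ambientLevel = 30, seed = 11, randomize = TRUE)
    b <- tinySim(ambientLevel = 30, seed = 11, randomize = TRUE)
    expect_identical(simCounts(a), simCounts(b))
    expect_identical(S4Vectors::as.data.frame(SummarizedExperiment::colData(a)),
                     S4Vectors::as.data.frame(SummarizedExperiment::colData(b)))
})

test_that("realized ambient totals track the requested lognormal mean", {
    sim <- tinySim(ambientLevel = 200, seed = 2, nDroplets = 2000,
                   nCells = 100)
    # lognormal with arithmetic mean 200, sdlog 0.5: the mean over 2000
    # droplets should sit within a few percent of 200
    expect_gt(mean(sim$ambientUMI), 180)
    expect_lt(mean(sim$ambientUMI), 220)
})

test_that("cluster profiles are distinct between clusters", {
    sim <- tinySim(ambientLevel = 0, seed = 5, nCells = 200,
                   nDroplets = 400, bioUMI = 3000)
    counts <- simCounts(sim)
    cl <- sim$cluster[sim$isCell]
    prof <- vapply(sort(unique(cl)), function(k) {
        v <- Matrix::rowSums(counts[, which(sim$isCell)[cl == k],
                                    drop = FALSE])
        v / sum(v)
    }, numeric(nrow(counts)))
    cors <- cor(prof)
    expect_true(all(cors[upper.tri(cors)] < 0.9))
})

test_that("sweep produces one dataset per level x replicate with distinct seeds", {
    sw <- sweepAmbientLevels(c(10, 50), replicates = 3, seed = 7,
                             nCells = 20, nDroplets = 100, bioUMI = 200,
                             nGenes = 50, randomize = FALSE)
    expect_length(sw, 6)
    design <- attr(sw, "design")
    expect_equal(nrow(design), 6)
    expect_equal(anyDuplicated(design$seed), 0L)
    expect_equal(design$ambientLevel, rep(c(10, 50), each = 3))
    # regenerating a single dataset from its fan-out seed reproduces it
    ds <- simulateDroplets(nCells = 20, nDroplets = 100, bioUMI = 200,
                           nGenes = 50, ambientLevel = 50,
                           randomize = FALSE, seed = design$seed[5])
    expect_identical(simCounts(ds), simCounts(sw[[5]]))
})

test_that("empty-droplet scaled slope sum grows with the ambient level", {
    slopeSum <- function(ds) {
        curve <- suppressWarnings(rankedCurve(ds))
        emptyDropletSlopeSum(scaledSlopeDistribution(slopeSeries(curve)))
    }
    lowHigh <- lapply(c(100, 4000), function(lv)
        unlist(sweepAmbientLevels(lv, replicates = 50, seed = 3,
            FUN = slopeSum, nCells = 100, nDroplets = 600, bioUMI = 5000,
            nGenes = 300)))
    expect_gt(mean(lowHigh[[2]]), mean(lowHigh[[1]]))
})

test_that("downsampling without replacement hits the exact target total", {
    m <- simCounts(tinySim(ambientLevel = 40, seed = 9))
    expect_identical(downsampleCounts(m, fraction = 1, seed = 1), m)
    half <- downsampleCounts(m, fraction = 0.5, seed = 1)
    expect_equal(sum(half), round(0.5 * sum(m)))
    expect_true(all((m - half)@x >= 0))   # per-entry counts never grow
    expect_identical(half, downsampleCounts(m, fraction = 0.5, seed = 1))
})

test_that("with-replacement downsampling matches the target in expectation", {
    m <- simCounts(tinySim(ambientLevel = 40, seed = 9))
    ds <- downsampleCounts(m, fraction = 0.4, seed = 2, replace = TRUE)
    expect_equal(sum(ds), round(0.4 * sum(m)))  # multinomial total is exact
    sce <- tinySim(ambientLevel = 40, seed = 9)
    out <- downsampleCounts(sce, fraction = 0.6, seed = 3)
    expect_s4_class(out, "SingleCellExperiment")
    expect_equal(sum(SummarizedExperiment::assay(out)),
                 round(0.6 * sum(m)))
})
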