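mkMetricSet <- function(slope, maxSec, secSD, auc, pctAmb,
                        nAmb = 0L) {
    new("MetricSet", emptyDropletSlopeSum = slope,
        invertedMaxSecant = maxSec, invertedSecantSD = secSD,
        invertedAUCPct = auc, nAmbientGenes = as.integer(nAmb),
        avgPctCountsAmbient = pctAmb, avgAmbientUMIPerCell = 0,
        nCells = 10L, avgPctCountsMito = 0, avgGenesPerCell = 1,
        avgUMIPerCell = 1)
}

test_that("feature transform doubles the secant sd and rescales percent", {
    f <- transformFeatures(mkMetricSet(0.3, 0.4, 0.5, 0.6, 80))
    expect_equal(unname(f),
                 c(0.3, 0.4, 1.0, 0.6, 0.8))
    bad <- mkMetricSet(0.3, 0.4, 0.5, 0.6, 80)
    bad@invertedAUCPct <- 1.5
    expect_error(transformFeatures(bad), "consistency")
})

test_that("overall score hits its closed-form limits", {
    model <- defaultScoreModel()
    expect_equal(sum(scoreWeights(model)), 1)
    expect_true(all(scoreWeights(model) >= 0))
    allNoise <- mkMetricSet(1, 1, 0.5, 1, 100)
    expect_equal(overallScore(allNoise, model), 1)
    perfect <- mkMetricSet(0, 0, 0, 0, 0)
    expect_equal(overallScore(perfect, model), 0)
    # monotone in each feature with the others fixed
    mid <- overallScore(mkMetricSet(0.5, 0.5, 0.25, 0.5, 50), model)
    up <- overallScore(mkMetricSet(0.7, 0.5, 0.25, 0.5, 50), model)
    expect_gte(up, mid)
})

test_that("weight derivation rejects a degenerate single-level sweep", {
    m <- matrix(rep(c(0.4, 0.5, 0.3, 0.45, 12, 20), each = 30), 30)
    colnames(m) <- c("emptyDropletSlopeSum", "invertedMaxSecant",
                     "invertedSecantSD", "invertedAUCPct",
                     "nAmbientGenes", "avgPctCountsAmbient")
    expect_error(scoreModelFromMetrics(m), "degenerate|variance")
})

test_that("PC1 dominates and loadings share a sign on a co-increasing sweep", {
    model <- suppressWarnings(deriveScoreModel(
        levels = c(10, 100, 1000, 4000), replicates = 4, seed = 5,
        nCells = 80, nDroplets = 500, bioUMI = 5000, nGenes = 250))
    expect_gt(model@pcaSummary[1], 0.5)
    expect_equal(sum(scoreWeights(model)), 1)
    # deterministic given the seed
    model2 <- suppressWarnings(deriveScoreModel(
        levels = c(10, 100, 1000, 4000), replicates = 4, seed = 5,
        nCells = 80, nDroplets = 500, bioUMI = 5000, nGenes = 250))
    expect_equal(scoreWeights(model), scoreWeights(model2))
})

test_that("weights are stable when the replicate count doubles", {
    args <- list(levels = c(10, 100, 1000, 4000), seed = 5,
                 nCells = 80, nDroplets = 500, bioUMI = 5000,
                 nGenes = 250)
    m1 <- suppressWarnings(do.call(deriveScoreModel,
                                   c(args, replicates = 6)))
    m2 <- suppressWarnings(do.call(deriveScoreModel,
                                   c(args, replicates = 12)))
    expect_lt(max(abs(scoreWeights(m1) - scoreWeights(m2))), 0.05)
})

test_that("score model JSON round-trips", {
    model <- defaultScoreModel()
    f <- tempfile(fileext = ".json")
    writeScoreModel(model, f)
    back <- readScoreModel(f)
    expect_equal(scoreWeights(back), scoreWeights(model))
    expect_equal(back@pcaSummary, model@pcaSummary)
})

test_that("overall score separates low from high contamination", {
    low <- computeMetrics(tinySim(ambientLevel = 100, seed = 29,
                                  bioUMI = 5000),
                          expectedCells = 100, verbose = FALSE)
    high <- computeMetrics(tinySim(ambientLevel = 4000, seed = 29,
                                   bioUMI = 5000),
                           expectedCells = 100, verbose = FALSE)
    expect_lt(low@overallScore, high@overallScore)
})
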