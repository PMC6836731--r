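# Droplet classification, Poisson occupancy estimation and copy-number
# conversion.

test_that("occupancy estimator matches its closed form", {
    e <- estimateOccupancy(1000, 20000)
    expect_equal(e$lambda, -log(0.95), tolerance = 1e-12)
    expect_equal(e$pHat, 0.05)

    # the assay's ~5%-positive working point
    e2 <- estimateOccupancy(877, 17500)
    expect_equal(e2$pHat, 0.050114, tolerance = 1e-4)
    expect_equal(e2$lambda, 0.051415, tolerance = 1e-4)

    expect_error(estimateOccupancy(100, 100), "saturation")
    expect_error(estimateOccupancy(-1, 100), "0 <= k <= n")

    z <- estimateOccupancy(0, 17500)
    expect_identical(z$lambda, 0)
    expect_identical(z$flags, "zero")
    expect_identical(z$lambdaCi[1], 0)
    expect_gt(z$lambdaCi[2], 0)   # one-sided upper bound survives k = 0

    h <- estimateOccupancy(900, 1000)
    expect_true("high_occupancy" %in% h$flags)
})

test_that("occupancy CI endpoints solve the Wilson score equation", {
    z <- qnorm(0.975)
    for (kn in list(c(50, 17500), c(877, 17500), c(5000, 20000))) {
        e <- estimateOccupancy(kn[1], kn[2])
        pCi <- 1 - exp(-e$lambdaCi)
        for (p in pCi) {
            score <- abs(e$pHat - p) / sqrt(p * (1 - p) / kn[2])
            expect_equal(score, z, tolerance = 1e-8)
        }
    }
})

test_that("volume conversion reproduces the worked arithmetic", {
    est <- estimateOccupancy(1000, 20000)      # lambda = 0.0512933
    ce <- toCopies(est, ReactionContext(cellEquivalents = 5))
    expect_equal(ce@concPerUl, 60.345, tolerance = 1e-4)
    expect_equal(copiesPerReaction(ce), 1206.9, tolerance = 1e-4)

    # counted mode: occupancy times analyzed droplets
    cnt <- list(lambda = 0.051429, lambdaCi = c(0.048, 0.055),
                pHat = 1 - exp(-0.051429), k = 877L, n = 17500L,
                flags = character())
    cc <- toCopies(cnt, ReactionContext(cellEquivalents = 5,
                                        copiesMode = "counted"))
    expect_equal(copiesPerReaction(cc), 900, tolerance = 1e-3)

    # copies per cell equivalent
    expect_equal(2110 / 5, 422)
    est422 <- list(lambda = 1, lambdaCi = c(0.9, 1.1), pHat = 1 - exp(-1),
                   k = 0L, n = 2110L, flags = character())
    cpc <- toCopies(est422, ReactionContext(cellEquivalents = 5,
                                            copiesMode = "counted"))
    expect_equal(copiesPerCell(cpc), 422)

    # lambda = 0 zeroes every copy field
    z <- toCopies(estimateOccupancy(0, 17500),
                  ReactionContext(cellEquivalents = 5))
    expect_identical(copiesPerReaction(z), 0)
    expect_identical(copiesPerCell(z), 0)

    # cell-free context: copies per cell is undefined, not an error
    ctl <- toCopies(est, ReactionContext(cellEquivalents = 0))
    expect_true(is.na(copiesPerCell(ctl)))
})

test_that("expected estimate matches exhaustive enumeration on tiny wells", {
    # all n^m equally likely assignments of m molecules to n droplets
    for (n in 2:4) for (m in 0:4) {
        if (m == 0) {
            expect_equal(expectedPositiveFraction(0, n), 0)
            next
        }
        grids <- expand.grid(rep(list(seq_len(n)), m))
        k <- apply(grids, 1, function(a) length(unique(a)))
        expect_equal(mean(k) / n, expectedPositiveFraction(m, n),
                     tolerance = 1e-12)
    }
})

test_that("copies per reaction is strictly increasing in positives", {
    ctx <- ReactionContext(cellEquivalents = 5)
    cpr <- vapply(c(1, 10, 100, 1000, 5000, 17000),
                  function(k) copiesPerReaction(
                      toCopies(estimateOccupancy(k, 17500), ctx)),
                  numeric(1))
    expect_true(all(diff(cpr) > 0))
})

test_that("classification recovers simulator ground truth when clusters are clean", {
    m <- cleanModel()    # rain 0, misclassification 0, 40-sigma separation
    well <- simulateWell(m, 422, 5, seed = 31)
    cts <- classifyDroplets(well)[[1]]
    expect_identical(nPositive(cts), wellMetadata(well)$positives)
    expect_identical(nTotal(cts), nDroplets(well))
    expect_identical(cts@method, "two_cluster")

    # manual threshold below every amplitude marks all droplets positive
    low <- classifyDroplets(well, method = "manual", manualThreshold = 0)[[1]]
    expect_identical(nPositive(low), nTotal(low))

    # a cell-free control classified against itself finds nothing
    ctl <- simulateWell(m, 422, 0, seed = 32)
    self <- classifyDroplets(ctl, method = "negative_control",
                             negativeControlWell = ctl)[[1]]
    expect_identical(nPositive(self), 0L)
    expect_identical(self@method, "negative_control")

    # degenerate clusters fall back to the control when one is supplied
    fb <- classifyDroplets(ctl, method = "two_cluster",
                           negativeControlWell = ctl)[[1]]
    expect_identical(fb@method, "negative_control")
    expect_warning(classifyDroplets(ctl, method = "two_cluster"),
                   "not separable")

    expect_error(classifyDroplets(well, method = "manual"), "manualThreshold")
    expect_error(classifyDroplets(well, method = "negative_control"),
                 "negativeControlWell")
})

test_that("replicate pooling combines droplets, not estimates", {
    ctx <- ReactionContext(cellEquivalents = 5)
    one <- DropletCounts(900, 17500)
    single <- toCopies(estimateOccupancy(counts = one), ctx)
    merged1 <- mergeReplicates(list(one), ctx)
    expect_equal(copiesPerCell(merged1), copiesPerCell(single))

    # two identical wells: same point estimate, strictly narrower CI
    merged2 <- mergeReplicates(list(one, DropletCounts(900, 17500)), ctx)
    expect_equal(copiesPerCell(merged2), copiesPerCell(single))
    expect_lt(diff(ci95(merged2)), diff(ci95(single)))
    expect_length(merged2@provenance$perWell, 2)

    # pooled vs averaged duplicates agree closely at the working occupancy
    withr::with_seed(5, {
        ks <- simulatePositiveCounts(0.05, 17500, 2)
        cts <- lapply(ks, DropletCounts, nTotal = 17500)
        pooled <- copiesPerCell(mergeReplicates(cts, ctx))
        avg <- mean(vapply(cts, function(ct)
            copiesPerCell(toCopies(estimateOccupancy(counts = ct), ctx)),
            numeric(1)))
        expect_lt(abs(pooled / avg - 1), 0.01)
    })

    expect_error(mergeReplicates(list(one,
        DropletCounts(10, 100, channel = "Ch2 Amplitude")), ctx), "mix")
})

test_that("single-well pipeline composes classification and conversion", {
    m <- cleanModel()
    well <- simulateWell(m, 422, 5, seed = 41)
    est <- quantifyWell(well, ReactionContext(cellEquivalents = 5))
    expect_s4_class(est, "CopyEstimate")
    expect_identical(est@provenance$k, wellMetadata(well)$positives)
    expect_true(is.finite(est@provenance$threshold))
    # the loaded template (thinned to the analyzed volume) is recovered
    truthAnalyzed <- wellMetadata(well)$molecules
    expect_lt(abs(est@lambda * est@provenance$n / truthAnalyzed - 1), 0.02)

    # cell-free control: tiny copies per reaction, undefined per cell
    ctl <- simulateWell(m, 422, 0, seed = 42)
    cest <- quantifyWell(ctl, ReactionContext(cellEquivalents = 0),
                         method = "negative_control",
                         negativeControlWell = ctl)
    expect_true(is.na(copiesPerCell(cest)))
    expect_lt(copiesPerReaction(cest), 50)
})

test_that("estimates are invariant to how many droplets were analyzed", {
    # same emulsion read at 15,000 vs 20,000 droplets: volumetric copies
    # per reaction agree in expectation
    ctx <- ReactionContext(cellEquivalents = 5)
    withr::with_seed(8, {
        mean15 <- mean(vapply(simulatePositiveCounts(0.05, 15000, 400),
            function(k) copiesPerReaction(
                toCopies(estimateOccupancy(k, 15000), ctx)), numeric(1)))
        mean20 <- mean(vapply(simulatePositiveCounts(0.05, 20000, 400),
            function(k) copiesPerReaction(
                toCopies(estimateOccupancy(k, 20000), ctx)), numeric(1)))
    })
    expect_lt(abs(mean15 / mean20 - 1), 0.01)
})

test_that("detection holds down to a hundredth of a cell equivalent", {
    # 0.01 cell equivalents of a 1500-copies/cell sample still yields a
    # nonzero estimate in essentially every well
    nz <- vapply(1:40, function(s) {
        w <- simulateWell(SimModel(copiesPerCellMean = 1500), 1500, 0.01,
                          seed = 5000 + s)
        est <- quantifyWell(w, ReactionContext(cellEquivalents = 0.01))
        copiesPerReaction(est) > 0
    }, logical(1))
    expect_gte(mean(nz), 0.99)
})
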