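# Generative measurement-chain model: partitioning, dilution arithmetic,
# well simulation, qPCR model, cohort time courses.

test_that("partitioning conserves molecules and handles edge cases", {
    occ <- partitionMolecules(900, 17500, seed = 1)
    expect_identical(sum(occ), 900L)
    expect_identical(length(occ), 17500L)

    expect_identical(partitionMolecules(0, 50), integer(50))
    expect_error(partitionMolecules(10, 0), "positive integer")
    expect_error(partitionMolecules(-1, 10), "nonnegative")

    # determinism
    expect_identical(partitionMolecules(500, 2000, seed = 7),
                     partitionMolecules(500, 2000, seed = 7))
})

test_that("two molecules in two droplets land together half the time", {
    # exhaustive enumeration of the 2^2 equally likely assignments gives
    # P(k = 1) = P(k = 2) = 1/2
    k <- vapply(seq_len(2000), function(s)
        sum(partitionMolecules(2, 2, seed = s) > 0L), integer(1))
    expect_true(abs(mean(k == 1) - 0.5) < 0.04)
    expect_true(all(k %in% 1:2))
})

test_that("positive fraction follows the occupancy law", {
    # mean positive fraction over seeds approaches 1 - (1 - 1/n)^m
    p <- vapply(seq_len(400), function(s)
        mean(partitionMolecules(900, 17500, seed = s) > 0L), numeric(1))
    expct <- expectedPositiveFraction(900, 17500)
    expect_true(abs(mean(p) - expct) < 3 * sd(p) / sqrt(length(p)) + 1e-4)
    # Poisson limit is numerically indistinguishable at this n
    expect_equal(expct, expectedPositiveFraction(900, 17500, poissonLimit = TRUE),
                 tolerance = 1e-4)

    # the count-level fast path draws from the same distribution as the
    # explicit Poisson-loading + partition chain
    withr::with_seed(11, {
        kChain <- vapply(seq_len(1000), function(i) {
            m <- rpois(1, 900)
            sum(partitionMolecules(m, 17500) > 0L)
        }, integer(1))
        kFast <- simulatePositiveCounts(900 / 17500, 17500, 1000)
        expect_gt(suppressWarnings(ks.test(kChain, kFast))$p.value, 0.001)
    })
})

test_that("dilution-chain arithmetic is exact for the protocol chains", {
    # bulk: 1e5 cells lysed in 40 uL; 10 uL + 10 uL buffer; 1:250; 1 uL in
    expect_equal(cellEquivalents(bulkChain(), nCells = 1e5), 5)
    # single cell: lysed in 10 uL, + 15 uL water, 7.5 uL into the reaction
    expect_equal(cellEquivalents(singleCellChain(), nCells = 1), 0.3)

    # non-physical chain: taking more than is available
    bad <- DilutionChain(10, data.frame(takeUl = 50, addUl = 10), 1)
    expect_error(cellEquivalents(bad, 1), "available")
})

test_that("lysate-chain simulation matches symbolic expectation", {
    # identity-ish chain: all volume carried through, no dilution
    ident <- DilutionChain(10, data.frame(takeUl = 10, addUl = 0), 10)
    model <- cleanModel(copiesPerCellMean = 500)
    out <- simulateLysateChain(1, model, ident, seed = 1)
    expect_equal(out$expectedMoleculesPerReaction, 500)
    expect_equal(out$cellEquivalentsPerReaction, 1)

    bulk <- simulateLysateChain(1e5, SimModel(copiesPerCellMean = 422),
                                bulkChain(), seed = 2)
    expect_equal(bulk$cellEquivalentsPerReaction, 5)
    expect_equal(bulk$expectedMoleculesPerReaction, 5 * 422)
    # Poisson sampling stays near the expectation
    expect_lt(abs(bulk$sampledMolecules / bulk$expectedMoleculesPerReaction - 1),
              0.2)
})

test_that("simulated wells carry consistent ground truth", {
    well <- simulateWell(SimModel(), 422, 5, seed = 3)
    md <- wellMetadata(well)
    expect_lte(md$molecules, md$moleculesReaction)
    expect_lte(md$positives, md$molecules)
    expect_identical(nDroplets(well), length(amplitudes(well)[[1]]))

    # cell-free control: no template, and without misclassification every
    # amplitude is a negative-cluster draw
    ctl <- simulateWell(cleanModel(), 422, cellEquivalents = 0, seed = 4)
    expect_identical(wellMetadata(ctl)$molecules, 0L)
    expect_lt(max(amplitudes(ctl)[[1]]), 6000)  # below the cluster midpoint

    # determinism: identical seed, bit-identical amplitudes
    w1 <- simulateWell(SimModel(), 422, 5, seed = 5)
    w2 <- simulateWell(SimModel(), 422, 5, seed = 5)
    expect_identical(amplitudes(w1), amplitudes(w2))
    # the model's own seed slot is honoured as a default
    w3 <- simulateWell(SimModel(seed = 5L), 422, 5)
    expect_identical(amplitudes(w1), amplitudes(w3))
})

test_that("well simulation recovers the loaded template on average", {
    est <- vapply(1:60, function(s)
        copiesPerCell(quantifyWell(simulateWell(SimModel(), 422, 5,
                                                seed = 100 + s),
                                   ReactionContext(cellEquivalents = 5))),
        numeric(1))
    expect_lt(abs(mean(est) / 422 - 1), 0.025)
})

test_that("duplex wells split template across channels as specified", {
    m <- cleanModel()
    # f = 1: the MT-ND4 channel is empty
    d1 <- simulateDuplexWell(m, 2000, 1, seed = 1)
    expect_identical(unname(wellMetadata(d1)$molecules["nd4"]), 0L)
    expect_identical(unname(wellMetadata(d1)$positives["nd4"]), 0L)

    # f = 0: both channels see the same expected load
    ks <- vapply(1:40, function(s)
        wellMetadata(simulateDuplexWell(m, 2000, 0, seed = s))$positives,
        numeric(2))
    expect_lt(abs(mean(ks[1, ]) / mean(ks[2, ]) - 1), 0.05)

    expect_error(simulateDuplexWell(m, 2000, 1.2), "deletionFraction")
    expect_error(simulateDuplexWell(m, 0, 0.5), "copiesDloop")
})

test_that("qPCR model has the closed-form standard-curve geometry", {
    det <- QpcrModel(efficiency = 1, ctIntercept = 38, ctSd = 0)
    # tenfold dilution steps Ct by 1/log10(2) = 3.3219 cycles
    expect_equal(simulateQpcrCt(100, det) - simulateQpcrCt(1000, det),
                 1 / log10(2), tolerance = 1e-9)
    e9 <- QpcrModel(efficiency = 0.9, ctSd = 0)
    expect_equal(simulateQpcrCt(100, e9) - simulateQpcrCt(1000, e9),
                 1 / log10(1.9), tolerance = 1e-9)

    # fitting the simulator's own noiseless standard curve recovers E
    copies <- 10^(2:7)
    ct <- simulateQpcrCt(copies, e9)
    slope <- coef(lm(ct ~ log10(copies)))[[2]]
    expect_equal(10^(-1 / slope) - 1, 0.9, tolerance = 1e-6)

    # inversion is exact and noise draws are seed-deterministic
    noisy <- QpcrModel(efficiency = 0.95, ctSd = 0.2)
    expect_equal(qpcrCopiesFromCt(simulateQpcrCt(5000, det), det), 5000,
                 tolerance = 1e-9)
    expect_identical(simulateQpcrCt(5000, noisy, seed = 3),
                     simulateQpcrCt(5000, noisy, seed = 3))
    expect_error(simulateQpcrCt(0, det), "copies")
})

test_that("single-cell panels expose per-cell truth and replicate structure", {
    sc <- simulateSingleCells(5, smallModel(), replicatesPerCell = 2, seed = 9)
    expect_length(sc, 5)
    expect_true(all(vapply(sc, function(x) length(x$wells), integer(1)) == 2L))
    # degenerate heterogeneity: every cell shares the model mean
    expect_true(all(vapply(sc, function(x) x$trueCopiesPerCell,
                           numeric(1)) == 500))
    # enlarging the panel must not perturb earlier cells
    sc2 <- simulateSingleCells(8, smallModel(), replicatesPerCell = 2, seed = 9)
    expect_identical(amplitudes(sc[[1]]$wells[[1]]),
                     amplitudes(sc2[[1]]$wells[[1]]))
})

test_that("cohort simulation honours the peak contract", {
    spec <- list(list(label = "young", nSubjects = 1L, peakMean = 1528,
                      peakSd = 0, ageMean = 33, ageSd = 7, dayGrid = 0:15))
    tc <- simulateCohort(spec, seed = 1)[[1]]
    pk <- extractPeak(tc)
    expect_equal(pk$peak, 1528)
    expect_true(pk$peakDay %in% 3:6)

    # a day-0-only grid collapses to the resting draw
    spec0 <- list(list(label = "x", nSubjects = 1L, peakMean = 1000,
                       peakSd = 0, ageMean = 50, ageSd = 0, dayGrid = 0))
    tc0 <- simulateCohort(spec0, seed = 2)[[1]]
    expect_identical(extractPeak(tc0)$peakDay, 0L)
    expect_equal(extractPeak(tc0)$peak, tc0@values[1])

    # day-1 dip: value at day 1 is the stated fraction of day 0 (series are
    # capped at the subject's peak, which binds only for rare low-peak draws)
    tcs <- simulateCohort(seed = 3)
    dipOk <- vapply(tcs, function(x) {
        isTRUE(all.equal(x@values[2], 0.70 * x@values[1])) ||
            isTRUE(all.equal(x@values[2], max(x@values))) ||
            isTRUE(all.equal(x@values[1], max(x@values)))  # day 0 at cap
    }, logical(1))
    expect_true(all(dipOk))
    exactDip <- vapply(tcs, function(x)
        isTRUE(all.equal(x@values[2] / x@values[1], 0.70)), logical(1))
    expect_gte(mean(exactDip), 0.9)

    # group separation: young vs old peaks separate decisively in
    # essentially every cohort draw
    p <- vapply(1:20, function(s) {
        pk <- cohortPeaks(simulateCohort(seed = 1000 + s))
        raw <- data.frame(group = pk$group, value = pk$peak)
        cg <- compareGroups(raw[raw$group %in% c("young", "old"), ], "welch_t")
        cg$p.value
    }, numeric(1))
    expect_gte(mean(p < 1e-6), 0.95)
})
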