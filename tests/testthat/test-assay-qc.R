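# Assay validation statistics: linearity, CVs, sigma_est, detectable
# differences, measurement-model comparison.

test_that("dilution linearity recovers exact and degenerate series", {
    x <- rep(c(1000, 100, 10, 1), each = 2)
    lin <- suppressWarnings(dilutionLinearity(x, x))  # exact fit
    expect_equal(lin$slope, 1, tolerance = 1e-12)
    expect_equal(lin$r2, 1, tolerance = 1e-12)

    const <- suppressWarnings(dilutionLinearity(c(1000, 100, 10), rep(50, 3)))
    expect_equal(const$slope, 0, tolerance = 1e-12)

    expect_error(dilutionLinearity(c(10, 100), c(10, 100)), "3 distinct")
    expect_warning(
        expect_error(dilutionLinearity(c(1000, 100, 10), c(1000, 100, -1)),
                     "3 distinct"),
        "excluded")
    expect_error(dilutionLinearity(c(-1, 10, 100), c(1, 2, 3)), "> 0")
})

test_that("noise-free simulated dilutions are linear over five decades", {
    # only Poisson loading and partitioning remain; replicate wells are
    # averaged per point
    model <- cleanModel(copiesPerCellMean = 1500,
                        dropletCountRange = c(20000L, 20000L))
    ce <- 10^seq(2, -2)
    expected <- numeric(0)
    measured <- numeric(0)
    for (i in seq_along(ce)) for (r in 1:10) {
        w <- simulateWell(model, 1500, ce[i], seed = 600 + 10 * i + r)
        expected <- c(expected, ce[i])
        measured <- c(measured,
                      copiesPerReaction(quantifyWell(
                          w, ReactionContext(cellEquivalents = ce[i]))))
    }
    lin <- dilutionLinearity(expected, measured)
    expect_gte(lin$slope, 0.98)
    expect_lte(lin$slope, 1.02)
    expect_gte(lin$r2, 0.995)
})

test_that("replicate CVs match hand arithmetic", {
    expect_equal(replicateCv(c(9, 10, 11)), 10)
    expect_equal(replicateCv(c(5, 5, 5, 5)), 0)
    expect_error(replicateCv(c(1, -1)), "mean 0")

    vals <- c(9, 10, 11, 18, 20, 22)
    grp <- rep(c("a", "b"), each = 3)
    cv <- replicateCv(vals, grp)
    expect_equal(unname(cv$intraPerGroup), c(10, 10))
    expect_equal(cv$intraCv, 10)
    expect_equal(cv$interCv, 100 * sd(c(10, 20)) / 15)
    expect_error(replicateCv(c(1, 2, 3), c("a", "a", "b")), "at least 2")
})

test_that("single-well CV at the working point sits on the shot-noise floor", {
    # 900 copies in 17,500 droplets; delta-method floor
    # 100 * sqrt(p / ((1 - p) n)) / lambda ~= 3.38%
    lam <- -log1p(-900 / 17500)
    p <- -expm1(-lam)
    floor <- 100 * sqrt(p / ((1 - p) * 17500)) / lam
    withr::with_seed(12, {
        k <- simulatePositiveCounts(900 / 17500, 17500, 1500)
    })
    est <- -log1p(-k / 17500) * 17500
    expect_lt(abs(100 * sd(est) / mean(est) - floor), 0.5)
})

test_that("sigma_est reproduces the residual arithmetic", {
    expect_equal(sigmaEst(c(10, 20, 30), c(1, 2, 3)), 0, tolerance = 1e-12)

    # residuals (+1, -1, -1, +1) around a flat fit with mean 10:
    # sqrt(4 / 2) / 10 = 14.14%
    measured <- 10 + c(1, -1, -1, 1)
    expect_equal(sigmaEst(measured, 1:4), 100 * sqrt(2) / 10,
                 tolerance = 1e-9)

    expect_error(sigmaEst(c(1, 2, 3), c(5, 5, 5)), "constant")
    expect_error(sigmaEst(c(1, 2), c(1, 2)), "at least 3")
})

test_that("qPCR-model sigma_est matches the delta-method prediction", {
    # ct_sd = 0.2 on target and reference at E = 1:
    # CV(ratio) ~= ln(2) * sqrt(2) * 0.2 = 19.6%
    qm <- QpcrModel(efficiency = 1, ctSd = 0.2)
    withr::with_seed(13, {
        loading <- rep(1 + seq(0, 100, 10) / 100, each = 20)
        tgt <- qpcrCopiesFromCt(simulateQpcrCt(900 * loading, qm), qm)
        ref <- qpcrCopiesFromCt(simulateQpcrCt(rep(900, length(loading)), qm),
                                qm)
    })
    s <- sigmaEst(tgt / ref, loading)
    expect_lt(abs(s - 19.6), 4)
})

test_that("minimal detectable difference handles noise-free and noisy designs", {
    # zero noise at increments 0/10/20: both procedures detect 10%
    v <- rep(c(100, 110, 120), each = 3)
    inc <- rep(c(0, 10, 20), each = 3)
    mdd <- minDetectableDifference(v, inc)
    expect_equal(mdd$minDiffTtest, 10)
    expect_equal(mdd$minDiffAnova, 10)

    expect_error(minDetectableDifference(c(1, 2), c(0, 10)), "replicates")

    # Tukey adjustment is never more permissive than the unadjusted test of
    # the same contrast (same studentized statistic, two-group reference
    # distribution)
    withr::with_seed(14, {
        for (r in 1:20) {
            inc <- rep(c(0, 10, 20, 30), each = 4)
            v <- (1 + inc / 100) * rnorm(16, 100, 8)
            tuk <- compareGroups(data.frame(group = inc, value = v),
                                 "anova_tukey")
            pUnadj <- 2 * pt(-tuk$statistic / sqrt(2), tuk$df)
            expect_true(all(tuk$p.value >= pUnadj - 1e-12))
        }
    })
})

test_that("a 10% increment is detected under 3.77% noise with n = 6", {
    hits <- vapply(1:100, function(s) {
        set.seed(700 + s)
        base <- rnorm(6, 100, 3.77)
        up <- rnorm(6, 110, 3.77 * 1.1)
        raw <- data.frame(group = rep(c("0", "10"), each = 6),
                          value = c(base, up))
        compareGroups(raw, "welch_t")$p.value < 0.05
    }, logical(1))
    expect_gte(mean(hits), 0.90)
})

test_that("measurement models rank as expected in sensitivity", {
    mc <- methodComparison(seed = 15)
    expect_identical(mc$model, c("qpcr", "ddpcr_ratio", "ddmdm"))
    sig <- setNames(mc$sigmaEstPct, mc$model)
    expect_lt(sig["ddmdm"], sig["ddpcr_ratio"])
    expect_lt(sig["ddpcr_ratio"], sig["qpcr"])
    expect_lte(sig[["ddmdm"]], 5)       # near the shot-noise floor
    expect_gte(sig[["qpcr"]], 12)       # compounded exponential read-out
    # detection limits follow the same ordering
    expect_lte(mc$minDiffTtest[mc$model == "ddmdm"],
               mc$minDiffTtest[mc$model == "ddpcr_ratio"])
    expect_lte(mc$minDiffTtest[mc$model == "ddpcr_ratio"],
               mc$minDiffTtest[mc$model == "qpcr"])

    # determinism for a fixed seed
    expect_identical(methodComparison(nReps = 3, seed = 16),
                     methodComparison(nReps = 3, seed = 16))

    # with every noise source off each model measures its loading exactly
    quiet <- suppressWarnings(
        methodComparison(qpcrModel = QpcrModel(ctSd = 0),
                         pipettingCvRatio = 0, pipettingCvDdmdm = 0,
                         shotNoise = FALSE, nReps = 3, seed = 17))
    expect_true(all(abs(quiet$sigmaEstPct) < 1e-9))
    expect_true(all(quiet$minDiffTtest == 10))
})
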