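### Assay validation statistics: dilution-series linearity, replicate CVs,
### standard error of the estimate, minimal detectable difference, and the
### three-way comparison of qPCR, ddPCR-ratio and direct lysate-based
### (per-cell-equivalent) measurement models.

#' Log-log linearity of a dilution series
#'
#' Ordinary least squares of `log10(mean measured)` on `log10(expected)`
#' across the distinct expected inputs of a dilution series.  An accurate
#' absolute assay gives slope 1 (measured copies track input in a 1-to-1
#' ratio) and an R^2 near 1 down to the limit of detection.  Points whose
#' mean measured value is not positive cannot enter a log fit and are
#' excluded with a warning; at least 3 points must remain.
#'
#' @param expected expected input per reaction (cell equivalents or
#'   molecules), one value per measurement.
#' @param measured measured copies per reaction, same length.
#' @return List with `slope`, `intercept`, `r2` and the per-point means
#'   (`points`).
#' @examples
#' exp10 <- rep(c(1000, 100, 10), each = 2)
#' dilutionLinearity(exp10, exp10)   # slope 1, r2 1
#' @export
dilutionLinearity <- function(expected, measured) {
    stopifnot(length(expected) == length(measured))
    if (any(expected <= 0))
        stop("'expected' inputs must be > 0")
    means <- tapply(measured, expected, mean)
    pts <- data.frame(expected = as.numeric(names(means)),
                      meanMeasured = as.numeric(means))
    bad <- pts$meanMeasured <= 0
    if (any(bad)) {
        warning(sum(bad), " dilution point(s) with nonpositive mean excluded ",
                "from the log-log fit", call. = FALSE)
        pts <- pts[!bad, , drop = FALSE]
    }
    if (length(unique(pts$expected)) < 3)
        stop("at least 3 distinct positive dilution points are required")
    fit <- stats::lm(log10(meanMeasured) ~ log10(expected), data = pts)
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r2 = summary(fit)$r.squared,
         points = pts)
}

#' Replicate coefficients of variation
#'
#' `CV = 100 * sd / mean` of replicate measurements.  With a `grouping`
#' factor, the intra-assay CV is computed within each replicate group
#' (reported per group and pooled as their mean) and the inter-assay CV is
#' the CV of the group means.  Without a grouping the single CV of the
#' values is returned.
#'
#' @param values numeric measurements.
#' @param grouping optional factor of replicate-group labels.
#' @return Without grouping: a single CV (percent).  With grouping: a list
#'   with `intraPerGroup`, `intraCv` (pooled) and `interCv`.
#' @examples
#' replicateCv(c(9, 10, 11))   # 10%
#' @export
replicateCv <- function(values, grouping = NULL) {
    cv1 <- function(x) {
        m <- mean(x)
        if (m == 0)
            stop("CV is undefined for mean 0")
        100 * stats::sd(x) / m
    }
    if (is.null(grouping)) {
        if (length(values) < 2)
            stop("at least 2 values are required")
        return(cv1(values))
    }
    stopifnot(length(values) == length(grouping))
    groups <- split(values, grouping)
    if (any(lengths(groups) < 2))
        stop("each replicate group needs at least 2 values for the intra CV")
    intra <- vapply(groups, cv1, numeric(1))
    if (length(groups) < 2)
        stop("at least 2 groups are required for the inter CV")
    means <- vapply(groups, mean, numeric(1))
    list(intraPerGroup = intra, intraCv = mean(intra), interCv = cv1(means))
}

#' Standard error of the estimate, percent of the mean
#'
#' Residual standard deviation about the OLS fit of measured values on the
#' prepared loading, `sqrt(sum(residuals^2) / (N - 2))`, normalized to the
#' mean measured value and expressed in percent.  This is the single-number
#' summary of overall assay variability used when comparing measurement
#' techniques.
#'
#' @param measured measured values.
#' @param expected prepared loading, same length (>= 3), non-constant.
#' @return sigma_est as a percentage of `mean(measured)`.
#' @examples
#' sigmaEst(c(1, 2, 3) * 10, c(1, 2, 3))   # perfectly linear: 0%
#' @export
sigmaEst <- function(measured, expected) {
    stopifnot(length(measured) == length(expected))
    if (length(measured) < 3)
        stop("at least 3 paired values are required")
    if (stats::var(expected) == 0)
        stop("'expected' loading is constant; the regression is degenerate")
    fit <- stats::lm(measured ~ expected)
    sig <- sqrt(sum(stats::residuals(fit)^2) / (length(measured) - 2))
    100 * sig / mean(measured)
}

#' Smallest detectable difference from baseline
#'
#' Given measurements of a baseline sample and of samples prepared at known
#' percent increments above it, finds (a) the smallest increment whose
#' group differs from baseline at two-tailed alpha under an unpaired t-test
#' (Welch by default, pooled-variance optionally), and (b) the smallest
#' pairwise percent difference that is significant under one-way ANOVA with
#' Tukey honest-significant-difference adjustment across all groups.  The
#' Tukey-adjusted criterion is never more permissive than the unadjusted
#' baseline comparison.
#'
#' @param values measurements.
#' @param incrementPct percent increment above baseline for each value; the
#'   baseline group is the minimum increment (normally 0).
#' @param alpha two-tailed significance level.
#' @param ttest `"welch"` (default) or `"pooled"`.
#' @return List with `minDiffTtest`, `minDiffAnova` (percent; `Inf` when no
#'   comparison is significant) and the underlying comparison tables.
#' @export
minDetectableDifference <- function(values, incrementPct, alpha = 0.05,
                                    ttest = c("welch", "pooled")) {
    stopifnot(length(values) == length(incrementPct))
    ttest <- match.arg(ttest)
    groups <- split(values, incrementPct)
    if (length(groups) < 2)
        stop("at least 2 groups (baseline plus one increment) are required")
    if (any(lengths(groups) < 2))
        stop("each group needs at least 2 replicates")
    raw <- data.frame(group = as.character(incrementPct), value = values)
    proc <- if (ttest == "welch") "welch_t" else "pooled_t"
    tt <- compareGroups(raw, procedure = proc)
    tukey <- compareGroups(raw, procedure = "anova_tukey")
    incs <- sort(as.numeric(names(groups)))
    base <- incs[1]
    ## baseline t-tests
    g1 <- as.numeric(tt$group1)
    g2 <- as.numeric(tt$group2)
    isBase <- (g1 == base) | (g2 == base)
    other <- ifelse(g1 == base, g2, g1)
    sigT <- isBase & tt$p.value < alpha
    minT <- if (any(sigT)) min(other[sigT] - base) else Inf
    ## all-pairs Tukey
    dInc <- abs(as.numeric(tukey$group1) - as.numeric(tukey$group2))
    sigA <- tukey$p.value < alpha
    minA <- if (any(sigA)) min(dInc[sigA]) else Inf
    list(minDiffTtest = minT, minDiffAnova = minA,
         ttestTable = tt[isBase, , drop = FALSE], tukeyTable = tukey)
}

#' Compare measurement models for sensitivity
#'
#' Simulates the amplicon-mixing sensitivity experiment under three
#' measurement models and scores each with [sigmaEst()] and
#' [minDetectableDifference()]:
#'
#' * `qpcr`: target and single-copy reference gene measured as noisy Ct
#'   values (cycle SD `ctSd` of `qpcrModel`), converted to copies through
#'   the standard curve; the readout is the target/reference ratio, which
#'   compounds the noise of two exponential read-outs.
#' * `ddpcr_ratio`: target and reference quantified in two independently
#'   pipetted droplet reactions (Poisson shot noise plus per-channel
#'   loading noise `pipettingCvRatio`); the readout is again a ratio.
#' * `ddmdm`: a single droplet channel normalized to the cell equivalents
#'   loaded, with loading noise `pipettingCvDdmdm` — no reference gene, so
#'   no compounded error.
#'
#' Increments are percent additional target above baseline; each model sees
#' the same design.  Under the default noise levels the per-cell-equivalent
#' model is the most sensitive and qPCR the least.
#'
#' @param incrementsPct percent increments including the 0 baseline.
#' @param nReps replicate measurements per increment per model.
#' @param baselineCopies baseline template molecules per droplet reaction.
#' @param nDroplets analyzed droplets per simulated well.
#' @param qpcrModel a [QpcrModel()] used for both qPCR channels.
#' @param pipettingCvRatio per-channel loading CV of the two-reaction
#'   ddPCR-ratio model.
#' @param pipettingCvDdmdm loading CV of the single-channel lysate model.
#' @param alpha significance level for detectable differences.
#' @param shotNoise keep the Poisson loading and partition draws of the
#'   droplet channels (default).  `FALSE` replaces them by their
#'   expectations, leaving only the explicitly parameterised noise — with
#'   all noise parameters at 0 every model then measures its loading
#'   exactly and sigma_est is 0.
#' @param seed optional integer seed; the full metrics table is reproducible
#'   for a fixed seed.
#' @return `data.frame` with one row per model: log-log `slope`,
#'   `intercept`, `r2`, `sigmaEstPct`, `minDiffTtest`, `minDiffAnova`.
#' @examples
#' methodComparison(nReps = 3, seed = 1)
#' @export
methodComparison <- function(incrementsPct = seq(0, 100, by = 10),
                             nReps = 6, baselineCopies = 900,
                             nDroplets = 17500,
                             qpcrModel = QpcrModel(efficiency = 1,
                                                   ctIntercept = 38,
                                                   ctSd = 0.2),
                             pipettingCvRatio = 0.05,
                             pipettingCvDdmdm = 0.01,
                             alpha = 0.05, shotNoise = TRUE, seed = NULL) {
    stopifnot(length(incrementsPct) >= 2, is(qpcrModel, "QpcrModel"))
    .withSeed(seed, {
        design <- expand.grid(rep = seq_len(nReps), inc = incrementsPct)
        loading <- 1 + design$inc / 100
        nObs <- nrow(design)

        ## qPCR: two noisy Ct read-outs, ratio through the standard curve
        ctT <- simulateQpcrCt(baselineCopies * loading, qpcrModel)
        ctR <- simulateQpcrCt(rep(baselineCopies, nObs), qpcrModel)
        qpcr <- qpcrCopiesFromCt(ctT, qpcrModel) /
            qpcrCopiesFromCt(ctR, qpcrModel)

        ## droplet channel: molecules -> partition -> occupancy estimate
        dropletChannel <- function(expectedCopies, cv) {
            vapply(expectedCopies, function(mu) {
                mu <- mu * .noiseFactor(cv)
                if (!shotNoise)
                    return(mu)
                m <- stats::rpois(1, mu)
                occ <- partitionMolecules(m, nDroplets)
                k <- sum(occ > 0L)
                if (k >= nDroplets)
                    k <- nDroplets - 1L
                -log1p(-k / nDroplets) * nDroplets
            }, numeric(1))
        }
        ddT <- dropletChannel(baselineCopies * loading, pipettingCvRatio)
        ddR <- dropletChannel(rep(baselineCopies, nObs), pipettingCvRatio)
        ddpcrRatio <- ddT / ddR
        ddmdm <- dropletChannel(baselineCopies * loading, pipettingCvDdmdm)

        score <- function(measured) {
            lin <- dilutionLinearity(loading, measured)
            mdd <- minDetectableDifference(measured, design$inc, alpha = alpha)
            data.frame(slope = lin$slope, intercept = lin$intercept,
                       r2 = lin$r2,
                       sigmaEstPct = sigmaEst(measured, loading),
                       minDiffTtest = mdd$minDiffTtest,
                       minDiffAnova = mdd$minDiffAnova)
        }
        out <- rbind(qpcr = score(qpcr),
                     ddpcr_ratio = score(ddpcrRatio),
                     ddmdm = score(ddmdm))
        out <- cbind(model = rownames(out), out)
        rownames(out) <- NULL
        out
    })
}
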