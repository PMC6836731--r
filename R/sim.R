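### Generative model of the ddPCR measurement chain: template partitioning,
### lysate dilution, amplitude readout, a matched qPCR model, and cohort
### time-course simulation.  Every simulated object carries its ground truth
### in the well metadata so downstream estimators can be validated.

#' Partition template molecules into droplets
#'
#' Assigns each of `m` template molecules independently and uniformly to one
#' of `nDroplets` droplets (multinomial partitioning, the physical model of
#' emulsion loading).  The returned occupancy vector always sums to `m`;
#' the number of positive droplets is `sum(occupancy > 0)`.
#'
#' @param m nonnegative integer number of template molecules.
#' @param nDroplets number of droplets (>= 1).
#' @param seed optional integer seed; when `NULL` the ambient RNG stream is
#'   used.
#' @return Integer vector of length `nDroplets` with the per-droplet
#'   molecule counts.
#' @seealso [expectedPositiveFraction()] for the closed-form occupancy law.
#' @examples
#' occ <- partitionMolecules(900, 17500, seed = 1)
#' sum(occ)            # exactly 900
#' mean(occ > 0)       # about 1 - exp(-900/17500) = 0.050
#' @export
partitionMolecules <- function(m, nDroplets, seed = NULL) {
    m <- as.integer(m)
    nDroplets <- as.integer(nDroplets)
    if (is.na(nDroplets) || nDroplets < 1L)
        stop("'nDroplets' must be a positive integer")
    if (is.na(m) || m < 0L)
        stop("'m' must be a nonnegative integer")
    .withSeed(seed, {
        if (m == 0L)
            integer(nDroplets)
        else
            tabulate(sample.int(nDroplets, m, replace = TRUE), nbins = nDroplets)
    })
}

#' Expected fraction of positive droplets
#'
#' Closed-form occupancy law for multinomial partitioning: when `m`
#' molecules are spread uniformly over `n` droplets, each droplet is empty
#' with probability `(1 - 1/n)^m`, so the expected positive fraction is
#' `1 - (1 - 1/n)^m`, which converges to the Poisson limit
#' `1 - exp(-m/n)` for large `n`.  At the assay's working point (about 900
#' copies in 17,500 droplets) this is approximately 5% positive droplets.
#'
#' @param m template molecules per reaction.
#' @param n analyzed droplets.
#' @param poissonLimit use the Poisson-limit form `1 - exp(-m/n)` instead of
#'   the exact finite-`n` expression.
#' @return Expected positive-droplet fraction in `[0, 1]`.
#' @export
expectedPositiveFraction <- function(m, n, poissonLimit = FALSE) {
    if (poissonLimit)
        -expm1(-m / n)
    else
        1 - (1 - 1 / n)^m
}

#' Positive-droplet counts under the Poisson loading law
#'
#' Draws positive-droplet counts from the marginal count-level law of the
#' measurement chain: when the number of template molecules is Poisson with
#' mean `lambda * nDroplets` and molecules partition independently, each
#' droplet holds Poisson(`lambda`) molecules, so the positive count is
#' exactly Binomial(`nDroplets`, `1 - exp(-lambda)`).  This is the fast path
#' for estimator calibration studies; its agreement with the explicit
#' [partitionMolecules()] chain is a package invariant.
#'
#' @param lambda mean copies per droplet (>= 0).
#' @param nDroplets droplets per well.
#' @param nWells number of wells to draw.
#' @param seed optional integer seed.
#' @return Integer vector of `nWells` positive-droplet counts.
#' @export
simulatePositiveCounts <- function(lambda, nDroplets, nWells = 1, seed = NULL) {
    if (lambda < 0)
        stop("'lambda' must be >= 0")
    .withSeed(seed, stats::rbinom(nWells, as.integer(nDroplets), -expm1(-lambda)))
}

#' Simulate the lysate dilution chain
#'
#' Propagates a starting cell count through a [DilutionChain()] to the
#' expected number of template molecules per reaction, then samples the
#' realized molecule count: a Poisson draw around the expectation times a
#' multiplicative log-normal pipetting factor (one per call, CV
#' `pipettingCv` from the model).
#'
#' @param nCells starting cell count (>= 1).
#' @param model a [SimModel()]; supplies mean copies per cell and the
#'   pipetting CV.
#' @param chain a [DilutionChain()].
#' @param seed optional integer seed.
#' @return List with `expectedMoleculesPerReaction`, `sampledMolecules` and
#'   `cellEquivalentsPerReaction`.
#' @examples
#' chain <- DilutionChain(40, data.frame(takeUl = c(10, 1), addUl = c(10, 249)), 1)
#' simulateLysateChain(1e5, SimModel(copiesPerCellMean = 422), chain, seed = 1)
#' @export
simulateLysateChain <- function(nCells, model, chain, seed = NULL) {
    stopifnot(is(model, "SimModel"), is(chain, "DilutionChain"))
    if (nCells < 1)
        stop("'nCells' must be >= 1")
    ce <- cellEquivalents(chain, nCells = nCells)
    expected <- ce * model@copiesPerCellMean
    sampled <- .withSeed(.resolveSeed(seed, model), {
        fac <- .noiseFactor(model@pipettingCv)
        stats::rpois(1, expected * fac)
    })
    list(expectedMoleculesPerReaction = expected,
         sampledMolecules = sampled,
         cellEquivalentsPerReaction = ce)
}

## Number of analyzed droplets for one well.
.drawDropletCount <- function(model) {
    rng <- model@dropletCountRange
    if (rng[1] == rng[2]) rng[1] else
        sample.int(rng[2] - rng[1] + 1L, 1L) + rng[1] - 1L
}

## Fraction of the reaction volume covered by the analyzed droplets; each
## reaction molecule is read with this probability.
.analyzedFraction <- function(model, n) {
    min(1, n * model@dropletVolumeNl * 1e-3 / model@reactionVolumeUl)
}

## Amplitude readout for one channel given an occupancy vector.  Rain is
## applied to template-positive droplets first, misclassification after.
.amplitudesFromOccupancy <- function(occ, model) {
    n <- length(occ)
    pos <- occ > 0L
    amp <- stats::rnorm(n, model@amplitudeNeg[1], model@amplitudeNeg[2])
    k <- sum(pos)
    if (k > 0) {
        amp[pos] <- stats::rnorm(k, model@amplitudePos[1], model@amplitudePos[2])
        if (model@rainFraction > 0) {
            rain <- which(pos)[stats::runif(k) < model@rainFraction]
            if (length(rain))
                amp[rain] <- stats::runif(length(rain),
                                          model@amplitudeNeg[1],
                                          model@amplitudePos[1])
        }
    }
    if (model@misclassFp > 0 && k < n) {
        fp <- which(!pos)[stats::runif(n - k) < model@misclassFp]
        if (length(fp))
            amp[fp] <- stats::rnorm(length(fp), model@amplitudePos[1],
                                    model@amplitudePos[2])
    }
    if (model@misclassFn > 0 && k > 0) {
        fn <- which(pos)[stats::runif(k) < model@misclassFn]
        if (length(fn))
            amp[fn] <- stats::rnorm(length(fn), model@amplitudeNeg[1],
                                    model@amplitudeNeg[2])
    }
    amp
}

#' Simulate one ddPCR well
#'
#' Draws a complete single-channel well: the number of analyzed droplets
#' (uniform over the model's `dropletCountRange`), the realized template
#' molecules in the reaction (Poisson around
#' `trueCopiesPerCell * cellEquivalents` times a log-normal pipetting
#' factor), binomial thinning to the analyzed droplets (which cover only
#' `n * dropletVolume` of the reaction volume, so each molecule is read
#' with probability `n * Vd / Vrxn`), their multinomial partition into
#' droplets, and per-droplet fluorescence amplitudes (negative cluster for
#' empty droplets, positive cluster for template-positive droplets, a
#' `rainFraction` of which fall uniformly in the inter-cluster band;
#' amplitude-level misclassification is applied last).  The thinning step
#' is what makes the volumetric concentration estimate unbiased for the
#' reaction content and invariant to how many droplets the reader happens
#' to analyze.  The ground truth — reaction and analyzed molecules,
#' template-positive droplets, loading factor — is stored in the well
#' metadata.
#'
#' @param model a [SimModel()].
#' @param trueCopiesPerCell true mtDNA copies per cell for this sample
#'   (default: the model mean).
#' @param cellEquivalents cell equivalents loaded into the reaction; 0 gives
#'   a cell-free control well.
#' @param seed optional integer seed.
#' @param wellId,sampleRef labels stored on the well.
#' @param channel amplitude channel name.
#' @return A [DropletWell()] with ground truth in `wellMetadata()`.
#' @examples
#' model <- SimModel(seed = 7L)
#' well <- simulateWell(model, trueCopiesPerCell = 422, cellEquivalents = 5)
#' wellMetadata(well)$positives
#' @export
simulateWell <- function(model, trueCopiesPerCell = model@copiesPerCellMean,
                         cellEquivalents = 5, seed = NULL,
                         wellId = "sim", sampleRef = wellId,
                         channel = "Ch1 Amplitude") {
    stopifnot(is(model, "SimModel"))
    if (trueCopiesPerCell < 0 || cellEquivalents < 0)
        stop("'trueCopiesPerCell' and 'cellEquivalents' must be >= 0")
    .withSeed(.resolveSeed(seed, model), {
        n <- .drawDropletCount(model)
        fac <- .noiseFactor(model@pipettingCv)
        expected <- trueCopiesPerCell * cellEquivalents * fac
        mReaction <- stats::rpois(1, expected)
        mAnalyzed <- stats::rbinom(1, mReaction, .analyzedFraction(model, n))
        occ <- partitionMolecules(mAnalyzed, n)
        amp <- .amplitudesFromOccupancy(occ, model)
        DropletWell(
            amplitudes = stats::setNames(list(amp), channel),
            wellId = wellId, sampleRef = sampleRef,
            metadata = list(
                trueCopiesPerCell = trueCopiesPerCell,
                cellEquivalents = cellEquivalents,
                loadingFactor = fac,
                expectedMolecules = trueCopiesPerCell * cellEquivalents,
                moleculesReaction = mReaction,
                molecules = mAnalyzed,
                positives = sum(occ > 0L)))
    })
}

#' Simulate a duplexed two-channel well
#'
#' Simulates the common-deletion duplex: channel 1 carries the D-Loop
#' target (all replication-competent mtDNA, expected `copiesDloop`
#' molecules per reaction), channel 2 the MT-ND4 target, lost with the
#' 4977-bp deletion, at `copiesDloop * (1 - deletionFraction)`.  Both
#' channels share the same droplet set and the same loading factor (one
#' well, one pipetting event) but their templates partition independently;
#' co-occupancy of a droplet by both targets is permitted.  As in
#' [simulateWell()], reaction molecules are binomially thinned to the
#' analyzed-droplet fraction of the reaction volume.
#'
#' @param model a [SimModel()].
#' @param copiesDloop expected D-Loop molecules per reaction (> 0).
#' @param deletionFraction true deletion fraction `f` in `[0, 1]`.
#' @param seed optional integer seed.
#' @param wellId,sampleRef labels.
#' @return A two-channel [DropletWell()] (`Ch1 Amplitude` = D-Loop,
#'   `Ch2 Amplitude` = MT-ND4) with per-channel ground truth in metadata.
#' @seealso [estimateDeletion()]
#' @export
simulateDuplexWell <- function(model, copiesDloop, deletionFraction,
                               seed = NULL, wellId = "duplex",
                               sampleRef = wellId) {
    stopifnot(is(model, "SimModel"))
    if (deletionFraction < 0 || deletionFraction > 1)
        stop("'deletionFraction' must be in [0, 1]")
    if (copiesDloop <= 0)
        stop("'copiesDloop' must be > 0")
    .withSeed(.resolveSeed(seed, model), {
        n <- .drawDropletCount(model)
        frac <- .analyzedFraction(model, n)
        fac <- .noiseFactor(model@pipettingCv)
        m1 <- stats::rbinom(1, stats::rpois(1, copiesDloop * fac), frac)
        m2 <- stats::rbinom(1, stats::rpois(1, copiesDloop *
                                               (1 - deletionFraction) * fac),
                            frac)
        occ1 <- partitionMolecules(m1, n)
        occ2 <- partitionMolecules(m2, n)
        DropletWell(
            amplitudes = list(
                "Ch1 Amplitude" = .amplitudesFromOccupancy(occ1, model),
                "Ch2 Amplitude" = .amplitudesFromOccupancy(occ2, model)),
            wellId = wellId, sampleRef = sampleRef,
            metadata = list(
                deletionFraction = deletionFraction,
                copiesDloop = copiesDloop,
                loadingFactor = fac,
                molecules = c(dloop = m1, nd4 = m2),
                positives = c(dloop = sum(occ1 > 0L), nd4 = sum(occ2 > 0L))))
    })
}

#' Simulate a qPCR quantification cycle
#'
#' Draws a Ct value under the standard-curve model of a [QpcrModel()]:
#' `Ct = ctIntercept - log(copies)/log(1 + E) + N(0, ctSd)`.  Deterministic
#' when `ctSd = 0`; vectorized over `copies`.
#'
#' @param copies input copies (> 0), scalar or vector.
#' @param model a [QpcrModel()].
#' @param seed optional integer seed.
#' @return Numeric Ct value(s).
#' @examples
#' m <- QpcrModel(efficiency = 1, ctSd = 0)
#' diff(simulateQpcrCt(c(1000, 100), m))   # +3.32 cycles per tenfold dilution
#' @export
simulateQpcrCt <- function(copies, model, seed = NULL) {
    stopifnot(is(model, "QpcrModel"))
    if (any(copies <= 0))
        stop("'copies' must be > 0")
    .withSeed(seed,
        model@ctIntercept - log(copies) / log1p(model@efficiency) +
            stats::rnorm(length(copies), 0, model@ctSd))
}

#' Invert a qPCR standard curve
#'
#' Converts Ct back to input copies under the same model used by
#' [simulateQpcrCt()]: `copies = exp((ctIntercept - Ct) * log(1 + E))`.
#'
#' @param ct Ct value(s).
#' @param model a [QpcrModel()].
#' @return Estimated input copies.
#' @export
qpcrCopiesFromCt <- function(ct, model) {
    stopifnot(is(model, "QpcrModel"))
    exp((model@ctIntercept - ct) * log1p(model@efficiency))
}

#' Simulate a single-cell quantitation panel
#'
#' Draws `nCells` cells whose true copy numbers follow the model's
#' log-normal heterogeneity (mean `copiesPerCellMean`, CV
#' `copiesPerCellCv`; a CV of 0 gives a degenerate clone with identical
#' copies in every cell), then simulates `replicatesPerCell` replicate wells
#' per cell, each loading `cellEquivalents` of that cell's lysate (default
#' 0.3, the share of one cell's lysate a single-cell reaction receives).
#' Per-cell replicate wells use sub-stream seeds drawn once up front, so
#' increasing `nCells` never changes the wells of earlier cells.
#'
#' @param nCells number of cells (>= 1).
#' @param model a [SimModel()].
#' @param replicatesPerCell technical replicates per cell (>= 1).
#' @param cellEquivalents cell equivalents loaded per replicate reaction.
#' @param seed optional integer seed.
#' @return List with one element per cell: `cellId`, `trueCopiesPerCell`
#'   and `wells` (list of [DropletWell()]).
#' @export
simulateSingleCells <- function(nCells, model, replicatesPerCell = 3,
                                cellEquivalents = 0.3, seed = NULL) {
    stopifnot(is(model, "SimModel"))
    if (nCells < 1 || replicatesPerCell < 1)
        stop("'nCells' and 'replicatesPerCell' must be >= 1")
    .withSeed(.resolveSeed(seed, model), {
        truths <- if (model@copiesPerCellCv <= 0)
            rep(model@copiesPerCellMean, nCells)
        else {
            p <- .lnormPars(model@copiesPerCellMean, model@copiesPerCellCv)
            stats::rlnorm(nCells, p$meanlog, p$sdlog)
        }
        cellSeeds <- .childSeeds(nCells * replicatesPerCell)
        lapply(seq_len(nCells), function(i) {
            wells <- lapply(seq_len(replicatesPerCell), function(r) {
                s <- cellSeeds[(i - 1L) * replicatesPerCell + r]
                simulateWell(model, trueCopiesPerCell = truths[i],
                             cellEquivalents = cellEquivalents, seed = s,
                             wellId = sprintf("cell%03d_rep%d", i, r),
                             sampleRef = sprintf("cell%03d", i))
            })
            list(cellId = sprintf("cell%03d", i),
                 trueCopiesPerCell = truths[i], wells = wells)
        })
    })
}

#' Simulate a dilution series of wells
#'
#' Convenience wrapper for limit-of-detection style designs: one set of
#' replicate wells per cell-equivalent input, all at the same true copies
#' per cell.
#'
#' @param model a [SimModel()].
#' @param cellEquivalents vector of cell-equivalent inputs per reaction.
#' @param wellsPerPoint replicate wells per input.
#' @param trueCopiesPerCell true copies per cell for the diluted sample.
#' @param seed optional integer seed.
#' @return List with one element per input: `cellEquivalents` and `wells`.
#' @export
simulateDilutionSeries <- function(model,
                                   cellEquivalents = c(5, 0.5, 0.05, 0.01),
                                   wellsPerPoint = 6,
                                   trueCopiesPerCell = 1500,
                                   seed = NULL) {
    stopifnot(is(model, "SimModel"))
    .withSeed(.resolveSeed(seed, model), {
        seeds <- .childSeeds(length(cellEquivalents) * wellsPerPoint)
        lapply(seq_along(cellEquivalents), function(i) {
            wells <- lapply(seq_len(wellsPerPoint), function(r) {
                s <- seeds[(i - 1L) * wellsPerPoint + r]
                simulateWell(model, trueCopiesPerCell = trueCopiesPerCell,
                             cellEquivalents = cellEquivalents[i], seed = s,
                             wellId = sprintf("dil%02d_rep%d", i, r),
                             sampleRef = sprintf("dil%02d", i))
            })
            list(cellEquivalents = cellEquivalents[i], wells = wells)
        })
    })
}

#' Default cohort group specifications
#'
#' The four study groups of the stimulation cohort with their sizes, ages
#' and peak-mtDNA distributions (copies per cell equivalent): young (n = 22,
#' age 33 +/- 7, peak 1528 +/- 272, 15-day grid), old (n = 22, age 73 +/- 6,
#' peak 809 +/- 332, 10-day grid), healthy centenarians (n = 7, age
#' 104 +/- 4, peak 1198 +/- 261) and frail centenarians (n = 10, age
#' 104 +/- 3; no published peak summary — a peak below the old group,
#' 650 +/- 300, is used as a synthetic default).
#'
#' @return List of group specification lists accepted by [simulateCohort()].
#' @export
cohortGroupDefaults <- function() {
    list(
        list(label = "young", nSubjects = 22L, peakMean = 1528, peakSd = 272,
             ageMean = 33, ageSd = 7, dayGrid = 0:15),
        list(label = "old", nSubjects = 22L, peakMean = 809, peakSd = 332,
             ageMean = 73, ageSd = 6, dayGrid = 0:10),
        list(label = "healthy_centenarian", nSubjects = 7L, peakMean = 1198,
             peakSd = 261, ageMean = 104, ageSd = 4, dayGrid = 0:10),
        list(label = "frail_centenarian", nSubjects = 10L, peakMean = 650,
             peakSd = 300, ageMean = 104, ageSd = 3, dayGrid = 0:10))
}

## Truncated-at-zero normal draw (rejection; means here are far from 0).
.truncNorm <- function(n, mean, sd) {
    if (sd <= 0)
        return(rep(mean, n))
    x <- stats::rnorm(n, mean, sd)
    while (any(bad <- x <= 0))
        x[bad] <- stats::rnorm(sum(bad), mean, sd)
    x
}

#' Simulate a stimulation cohort
#'
#' Generates per-subject mtDNA time courses after T-cell stimulation.  Each
#' subject receives: a resting day-0 value (truncated normal,
#' `restingMean`/`restingSd`), a transient day-1 dip (`day1Factor` times day
#' 0, reflecting activation-induced cell death), a unimodal rise to a peak
#' drawn from the group's truncated Normal(`peakMean`, `peakSd`) on a peak
#' day drawn uniformly from `peakDays` (stimulated T cells generally peak
#' 3--6 days after stimulation), and a slow exponential decline afterwards.
#' The series maximum equals the drawn peak whenever the peak day is on the
#' subject's day grid.  Subjects are generated from per-subject sub-stream
#' seeds, so enlarging a group never changes earlier subjects.
#'
#' @param groupSpecs list of group specifications, each a list with
#'   `label`, `nSubjects`, `peakMean`, `peakSd`, `ageMean`, `ageSd`,
#'   `dayGrid`; see [cohortGroupDefaults()].
#' @param seed optional integer seed.
#' @param restingMean,restingSd day-0 resting distribution (copies/cell).
#' @param day1Factor multiplicative day-1 dip relative to day 0.
#' @param declineRate exponential decline rate per day after the peak.
#' @param peakDays candidate peak days.
#' @return List of [SubjectTimecourse()] objects.
#' @examples
#' tcs <- simulateCohort(cohortGroupDefaults(), seed = 1)
#' extractPeak(tcs[[1]])
#' @export
simulateCohort <- function(groupSpecs = cohortGroupDefaults(), seed = NULL,
                           restingMean = 422, restingSd = 44,
                           day1Factor = 0.70, declineRate = 0.05,
                           peakDays = 3:6) {
    stopifnot(length(groupSpecs) >= 1)
    .withSeed(seed, {
        out <- list()
        for (spec in groupSpecs) {
            stopifnot(!is.null(spec$label), !is.null(spec$nSubjects))
            if (spec$peakSd < 0)
                stop("'peakSd' must be >= 0")
            days <- sort(unique(as.integer(spec$dayGrid)))
            if (!length(days))
                stop("'dayGrid' must be nonempty")
            subjSeeds <- .childSeeds(spec$nSubjects)
            for (i in seq_len(spec$nSubjects)) {
                tc <- .withSeed(subjSeeds[i], {
                    age <- .truncNorm(1, spec$ageMean, spec$ageSd)
                    peak <- .truncNorm(1, spec$peakMean, spec$peakSd)
                    pd <- if (length(peakDays) == 1L) peakDays else
                        sample(peakDays, 1L)
                    d0 <- .truncNorm(1, restingMean, restingSd)
                    d1 <- day1Factor * d0
                    vals <- vapply(days, function(d) {
                        if (d == 0L) d0
                        else if (d == 1L) d1
                        else if (d <= pd)
                            d1 * (peak / d1)^((d - 1) / (pd - 1))
                        else peak * exp(-declineRate * (d - pd))
                    }, numeric(1))
                    vals <- pmin(vals, peak)
                    SubjectTimecourse(
                        subjectId = sprintf("%s_%02d", spec$label, i),
                        group = spec$label, age = age,
                        days = days, values = vals)
                })
                out[[length(out) + 1L]] <- tc
            }
        }
        out
    })
}
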