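### S4 class definitions, validity and constructors for the core containers.

## ---------------------------------------------------------------------------
## Simulator parameterisation
## ---------------------------------------------------------------------------

#' Measurement-chain simulation model
#'
#' `SimModel` collects every parameter of the generative model of a ddPCR
#' mtDNA measurement: the biological signal (mean copies per cell and
#' cell-to-cell heterogeneity), the handling noise (a multiplicative
#' log-normal pipetting factor per well), the droplet readout (number of
#' analyzed droplets, droplet volume, the negative and positive fluorescence
#' clusters, the fraction of intermediate-amplitude "rain" droplets) and
#' amplitude-level misclassification probabilities.
#'
#' Defaults emulate a typical lysate-based mtDNA assay: 15,000--20,000
#' analyzed droplets of 0.85 nL in a 20 uL reaction, well-separated
#' fluorescence clusters, 2% rain and very rare misclassification.
#'
#' @param copiesPerCellMean mean true mtDNA copies per cell (> 0).
#' @param copiesPerCellCv cell-to-cell coefficient of variation of true
#'   copies per cell; heterogeneity is log-normal (>= 0).
#' @param pipettingCv coefficient of variation of the multiplicative
#'   log-normal loading-noise factor applied per well (>= 0).
#' @param dropletCountRange integer interval `c(low, high)`; the number of
#'   analyzed droplets per well is drawn uniformly from it.
#' @param dropletVolumeNl droplet volume in nanolitres (> 0).
#' @param reactionVolumeUl pre-emulsion reaction volume in microlitres (> 0).
#' @param amplitudeNeg,amplitudePos `c(mean, sd)` of the negative and
#'   positive fluorescence clusters (arbitrary units);
#'   `amplitudePos[1] > amplitudeNeg[1]` is required.
#' @param rainFraction fraction of template-positive droplets whose
#'   amplitude is drawn uniformly from the band between the cluster means.
#' @param misclassFp,misclassFn probability that an empty droplet receives a
#'   positive-cluster amplitude (false positive) and vice versa.
#' @param seed optional integer; used as the default seed by simulation
#'   calls when they are not given one explicitly.
#'
#' @return A `SimModel` object.
#' @seealso [simulateWell()], [simulateDuplexWell()], [simulateSingleCells()]
#' @examples
#' model <- SimModel(copiesPerCellMean = 422)
#' model
#' @export
SimModel <- function(copiesPerCellMean = 500,
                     copiesPerCellCv = 0.5,
                     pipettingCv = 0.05,
                     dropletCountRange = c(15000L, 20000L),
                     dropletVolumeNl = 0.85,
                     reactionVolumeUl = 20,
                     amplitudeNeg = c(mean = 2000, sd = 200),
                     amplitudePos = c(mean = 10000, sd = 400),
                     rainFraction = 0.02,
                     misclassFp = 1e-4,
                     misclassFn = 1e-4,
                     seed = NA_integer_) {
    new("SimModel",
        copiesPerCellMean = as.numeric(copiesPerCellMean),
        copiesPerCellCv = as.numeric(copiesPerCellCv),
        pipettingCv = as.numeric(pipettingCv),
        dropletCountRange = as.integer(dropletCountRange),
        dropletVolumeNl = as.numeric(dropletVolumeNl),
        reactionVolumeUl = as.numeric(reactionVolumeUl),
        amplitudeNeg = unname(as.numeric(amplitudeNeg)),
        amplitudePos = unname(as.numeric(amplitudePos)),
        rainFraction = as.numeric(rainFraction),
        misclassFp = as.numeric(misclassFp),
        misclassFn = as.numeric(misclassFn),
        seed = as.integer(seed))
}

setClass("SimModel",
    slots = c(
        copiesPerCellMean = "numeric",
        copiesPerCellCv = "numeric",
        pipettingCv = "numeric",
        dropletCountRange = "integer",
        dropletVolumeNl = "numeric",
        reactionVolumeUl = "numeric",
        amplitudeNeg = "numeric",
        amplitudePos = "numeric",
        rainFraction = "numeric",
        misclassFp = "numeric",
        misclassFn = "numeric",
        seed = "integer"),
    validity = function(object) {
        msg <- character()
        if (object@copiesPerCellMean <= 0)
            msg <- c(msg, "'copiesPerCellMean' must be > 0")
        if (object@copiesPerCellCv < 0)
            msg <- c(msg, "'copiesPerCellCv' must be >= 0")
        if (object@pipettingCv < 0)
            msg <- c(msg, "'pipettingCv' must be >= 0")
        rng <- object@dropletCountRange
        if (length(rng) != 2L || any(is.na(rng)) || rng[1] < 1L ||
            rng[1] > rng[2])
            msg <- c(msg,
                "'dropletCountRange' must be c(low, high) with 1 <= low <= high")
        if (object@dropletVolumeNl <= 0)
            msg <- c(msg, "'dropletVolumeNl' must be > 0")
        if (object@reactionVolumeUl <= 0)
            msg <- c(msg, "'reactionVolumeUl' must be > 0")
        if (length(object@amplitudeNeg) != 2L || length(object@amplitudePos) != 2L)
            msg <- c(msg, "amplitude clusters must be c(mean, sd)")
        else {
            if (object@amplitudePos[1] <= object@amplitudeNeg[1])
                msg <- c(msg, "positive cluster mean must exceed negative cluster mean")
            if (object@amplitudeNeg[2] < 0 || object@amplitudePos[2] < 0)
                msg <- c(msg, "cluster sds must be >= 0")
        }
        if (object@rainFraction < 0 || object@rainFraction > 1)
            msg <- c(msg, "'rainFraction' must be in [0, 1]")
        if (object@misclassFp < 0 || object@misclassFp > 1 ||
            object@misclassFn < 0 || object@misclassFn > 1)
            msg <- c(msg, "misclassification probabilities must be in [0, 1]")
        if (length(msg)) msg else TRUE
    })

#' Serial dilution chain
#'
#' Describes how a cell lysate is carried from the lysed pellet to the PCR
#' reaction: a starting volume, an ordered list of take/add dilution steps,
#' and the aliquot finally pipetted into the reaction.  The derived quantity
#' of interest is the number of cell equivalents delivered per reaction,
#' computed symbolically (no sampling) by [cellEquivalents()].
#'
#' @param startVolumeUl volume (uL) in which the starting cells are lysed.
#' @param steps `data.frame` with columns `takeUl` and `addUl`: each step
#'   takes `takeUl` of the current dilution and adds `addUl` of diluent.
#' @param aliquotVolumeUl volume (uL) of the final dilution pipetted into
#'   the PCR reaction.
#'
#' @return A `DilutionChain` object.
#' @examples
#' ## bulk protocol: 1e5 cells lysed in 40 uL; 10 uL lysate + 10 uL buffer;
#' ## 1:250 dilution; 1 uL into the 20 uL reaction -> 5 cell equivalents
#' chain <- DilutionChain(40, data.frame(takeUl = c(10, 1), addUl = c(10, 249)), 1)
#' cellEquivalents(chain, nCells = 1e5)
#' @export
DilutionChain <- function(startVolumeUl,
                          steps = data.frame(takeUl = numeric(), addUl = numeric()),
                          aliquotVolumeUl) {
    steps <- as.data.frame(steps)
    new("DilutionChain",
        startVolumeUl = as.numeric(startVolumeUl),
        steps = steps,
        aliquotVolumeUl = as.numeric(aliquotVolumeUl))
}

setClass("DilutionChain",
    slots = c(
        startVolumeUl = "numeric",
        steps = "data.frame",
        aliquotVolumeUl = "numeric"),
    validity = function(object) {
        msg <- character()
        if (object@startVolumeUl <= 0)
            msg <- c(msg, "'startVolumeUl' must be > 0")
        st <- object@steps
        if (!all(c("takeUl", "addUl") %in% names(st)))
            msg <- c(msg, "'steps' needs columns 'takeUl' and 'addUl'")
        else if (nrow(st) && (any(st$takeUl <= 0) || any(st$addUl < 0)))
            msg <- c(msg, "step volumes must be positive")
        if (object@aliquotVolumeUl <= 0)
            msg <- c(msg, "'aliquotVolumeUl' must be > 0")
        if (length(msg)) msg else TRUE
    })

#' qPCR cycle-threshold model
#'
#' Log-linear standard-curve model of quantitative PCR: for amplification
#' efficiency `E` (1 = perfect doubling) the quantification cycle of `x`
#' input copies is `Ct = ctIntercept - log(x) / log(1 + E)`, plus Gaussian
#' cycle noise with standard deviation `ctSd`.  With `ctSd = 0` the model is
#' deterministic and `Ct` is strictly decreasing in input copies; the slope
#' per decade of input is `-1 / log10(1 + E)` (the textbook -3.32
#' cycles/decade at E = 1).
#'
#' @param efficiency amplification efficiency `E`, `0 < E <= 1`.
#' @param ctIntercept cycles at one input copy.
#' @param ctSd standard deviation of cycle noise (>= 0).
#' @return A `QpcrModel` object.
#' @seealso [simulateQpcrCt()]
#' @export
QpcrModel <- function(efficiency = 1, ctIntercept = 38, ctSd = 0.2) {
    new("QpcrModel",
        efficiency = as.numeric(efficiency),
        ctIntercept = as.numeric(ctIntercept),
        ctSd = as.numeric(ctSd))
}

setClass("QpcrModel",
    slots = c(efficiency = "numeric", ctIntercept = "numeric", ctSd = "numeric"),
    validity = function(object) {
        msg <- character()
        if (object@efficiency <= 0 || object@efficiency > 1)
            msg <- c(msg, "'efficiency' must be in (0, 1]")
        if (object@ctSd < 0)
            msg <- c(msg, "'ctSd' must be >= 0")
        if (length(msg)) msg else TRUE
    })

## ---------------------------------------------------------------------------
## Measurement containers
## ---------------------------------------------------------------------------

#' Raw per-droplet amplitudes for one well
#'
#' One ddPCR well after droplet reading: a list of per-channel fluorescence
#' amplitude vectors (one value per analyzed droplet, equal length across
#' channels), plus identifying labels.  Extra per-droplet columns from an
#' instrument export (e.g. a `Cluster` call) are preserved untouched in
#' `extra`; simulation provenance (true molecule and positive-droplet
#' counts) lives in `metadata`.
#'
#' @param amplitudes named list of numeric vectors, one per channel, e.g.
#'   `list("Ch1 Amplitude" = x)`; all the same length (>= 1).
#' @param wellId,sampleRef labels.
#' @param extra optional `data.frame` of additional per-droplet columns.
#' @param metadata list of provenance fields.
#' @return A `DropletWell` object.
#' @seealso [classifyDroplets()], [readAmplitudeCsv()]
#' @export
DropletWell <- function(amplitudes, wellId = "well", sampleRef = wellId,
                        extra = data.frame(), metadata = list()) {
    if (!is.list(amplitudes))
        amplitudes <- list("Ch1 Amplitude" = amplitudes)
    if (is.null(names(amplitudes)) || any(!nzchar(names(amplitudes))))
        names(amplitudes) <- paste0("Ch", seq_along(amplitudes), " Amplitude")
    amplitudes <- lapply(amplitudes, as.numeric)
    new("DropletWell", wellId = as.character(wellId),
        sampleRef = as.character(sampleRef), amplitudes = amplitudes,
        extra = as.data.frame(extra), metadata = metadata)
}

setClass("DropletWell",
    slots = c(
        wellId = "character",
        sampleRef = "character",
        amplitudes = "list",
        extra = "data.frame",
        metadata = "list"),
    validity = function(object) {
        msg <- character()
        lens <- lengths(object@amplitudes)
        if (length(lens) == 0L)
            msg <- c(msg, "at least one amplitude channel is required")
        else {
            if (any(lens < 1L))
                msg <- c(msg, "each channel needs >= 1 droplet")
            if (length(unique(lens)) > 1L)
                msg <- c(msg, "all channels must have the same number of droplets")
            if (!all(vapply(object@amplitudes, is.numeric, logical(1))))
                msg <- c(msg, "amplitudes must be numeric")
        }
        if (nrow(object@extra) && length(lens) && nrow(object@extra) != lens[1])
            msg <- c(msg, "'extra' must have one row per droplet")
        if (length(msg)) msg else TRUE
    })

#' Classified droplet counts for one channel
#'
#' The result of thresholding one channel of a well: total droplets,
#' positive droplets, the amplitude threshold used and how it was chosen
#' (`manual`, `two_cluster` or `negative_control`).
#'
#' @param nPositive,nTotal droplet counts, `0 <= nPositive <= nTotal`.
#' @param threshold amplitude threshold; positives are strictly above it.
#' @param method thresholding method label.
#' @param channel channel label.
#' @return A `DropletCounts` object.
#' @seealso [estimateOccupancy()], [classifyDroplets()]
#' @export
DropletCounts <- function(nPositive, nTotal, threshold = NA_real_,
                          method = "manual", channel = "Ch1 Amplitude") {
    new("DropletCounts", channel = as.character(channel),
        nTotal = as.integer(nTotal), nPositive = as.integer(nPositive),
        threshold = as.numeric(threshold), method = as.character(method))
}

setClass("DropletCounts",
    slots = c(
        channel = "character",
        nTotal = "integer",
        nPositive = "integer",
        threshold = "numeric",
        method = "character"),
    validity = function(object) {
        msg <- character()
        if (object@nTotal < 1L)
            msg <- c(msg, "'nTotal' must be >= 1")
        if (object@nPositive < 0L || object@nPositive > object@nTotal)
            msg <- c(msg, "'nPositive' must satisfy 0 <= nPositive <= nTotal")
        if (!object@method %in% c("manual", "two_cluster", "negative_control"))
            msg <- c(msg, "'method' must be manual, two_cluster or negative_control")
        if (length(msg)) msg else TRUE
    })

#' Reaction context for copy-number conversion
#'
#' The volumetric and loading facts needed to turn a Poisson occupancy into
#' absolute copies: reaction volume, droplet volume, cell equivalents loaded
#' per reaction, the target label, and the conversion convention.
#'
#' `copiesMode = "volumetric"` converts occupancy to a concentration through
#' the droplet volume and multiplies by the pre-emulsion reaction volume
#' (the instrument-software convention); `"counted"` multiplies occupancy by
#' the number of analyzed droplets, i.e. counts only the emulsified
#' template.  The two differ by the fraction of the reaction actually read
#' as droplets.
#'
#' @param cellEquivalents cell equivalents loaded per reaction (>= 0).
#' @param reactionVolumeUl reaction volume in uL (default 20).
#' @param dropletVolumeNl droplet volume in nL (default 0.85).
#' @param target target label (e.g. `"D-Loop"`, `"MT-ND4"`, `"NCOA3"`).
#' @param copiesMode `"volumetric"` or `"counted"`.
#' @return A `ReactionContext` object.
#' @seealso [toCopies()]
#' @export
ReactionContext <- function(cellEquivalents = 5, reactionVolumeUl = 20,
                            dropletVolumeNl = 0.85, target = "D-Loop",
                            copiesMode = c("volumetric", "counted")) {
    copiesMode <- match.arg(copiesMode)
    new("ReactionContext",
        reactionVolumeUl = as.numeric(reactionVolumeUl),
        dropletVolumeNl = as.numeric(dropletVolumeNl),
        cellEquivalents = as.numeric(cellEquivalents),
        target = as.character(target), copiesMode = copiesMode)
}

setClass("ReactionContext",
    slots = c(
        reactionVolumeUl = "numeric",
        dropletVolumeNl = "numeric",
        cellEquivalents = "numeric",
        target = "character",
        copiesMode = "character"),
    validity = function(object) {
        msg <- character()
        if (object@reactionVolumeUl <= 0 || object@dropletVolumeNl <= 0)
            msg <- c(msg, "volumes must be > 0")
        if (object@cellEquivalents < 0)
            msg <- c(msg, "'cellEquivalents' must be >= 0")
        if (!object@copiesMode %in% c("volumetric", "counted"))
            msg <- c(msg, "'copiesMode' must be 'volumetric' or 'counted'")
        if (length(msg)) msg else TRUE
    })

#' Absolute copy-number estimate
#'
#' Result container of the occupancy-to-copies pipeline: the Poisson
#' occupancy `lambda = -ln(1 - k/n)`, the positive fraction, concentration
#' per uL, copies per reaction and per cell equivalent, a 95% confidence
#' interval on copies per cell equivalent, QC flags (`zero`, `saturated`,
#' `high_occupancy`, `degenerate_clusters`) and classification provenance.
#'
#' Built by [toCopies()], [quantifyWell()] and [mergeReplicates()]; users
#' rarely construct it directly.
#'
#' @param lambda,pHat occupancy and positive fraction.
#' @param lambdaCi numeric(2), 95% CI on `lambda`.
#' @param concPerUl,copiesPerReaction,copiesPerCell converted copy numbers
#'   (`copiesPerCell` may be `NA` when cell equivalents are 0).
#' @param ci95 numeric(2), 95% CI on `copiesPerCell` (on `copiesPerReaction`
#'   when cell equivalents are 0).
#' @param flags character vector of QC flags.
#' @param provenance list: `k`, `n`, `threshold`, `method`, per-well
#'   estimates for merged replicates, etc.
#' @return A `CopyEstimate` object.
#' @export
CopyEstimate <- function(lambda, pHat, lambdaCi, concPerUl, copiesPerReaction,
                         copiesPerCell, ci95, flags = character(),
                         provenance = list()) {
    new("CopyEstimate", lambda = as.numeric(lambda), pHat = as.numeric(pHat),
        lambdaCi = as.numeric(lambdaCi), concPerUl = as.numeric(concPerUl),
        copiesPerReaction = as.numeric(copiesPerReaction),
        copiesPerCell = as.numeric(copiesPerCell), ci95 = as.numeric(ci95),
        flags = as.character(flags), provenance = provenance)
}

setClass("CopyEstimate",
    slots = c(
        lambda = "numeric",
        pHat = "numeric",
        lambdaCi = "numeric",
        concPerUl = "numeric",
        copiesPerReaction = "numeric",
        copiesPerCell = "numeric",
        ci95 = "numeric",
        flags = "character",
        provenance = "list"),
    validity = function(object) {
        msg <- character()
        if (object@lambda < 0)
            msg <- c(msg, "'lambda' must be >= 0")
        if (length(object@lambdaCi) != 2L || length(object@ci95) != 2L)
            msg <- c(msg, "confidence intervals must be numeric(2)")
        else {
            if (!any(is.na(object@lambdaCi)) &&
                (object@lambdaCi[1] > object@lambda + 1e-12 ||
                 object@lambdaCi[2] < object@lambda - 1e-12))
                msg <- c(msg, "'lambdaCi' must bracket 'lambda'")
        }
        if (!is.na(object@copiesPerReaction) && object@copiesPerReaction < 0)
            msg <- c(msg, "copy numbers must be nonnegative")
        bad <- setdiff(object@flags,
                       c("zero", "saturated", "high_occupancy",
                         "degenerate_clusters"))
        if (length(bad))
            msg <- c(msg, paste("unknown flag(s):", paste(bad, collapse = ", ")))
        if (length(msg)) msg else TRUE
    })

#' Duplex common-deletion estimate
#'
#' Result of the duplexed deletion assay: per-channel occupancies for the
#' D-Loop (all replication-competent mtDNA) and MT-ND4 (lost with the
#' 4977-bp common deletion) targets, the deletion fraction
#' `f = 1 - lambda_ND4 / lambda_DLoop`, and a bootstrap 95% CI.  Sampling
#' noise can push `f` slightly below 0; such values are reported as-is with
#' `flagNegative` set, never clamped.
#'
#' @param lambdaDloop,lambdaNd4 channel occupancies.
#' @param fDeletion deletion fraction point estimate.
#' @param ci95 numeric(2) bootstrap CI on `fDeletion`.
#' @param flagNegative logical, `fDeletion < 0`.
#' @param provenance list of counts and bootstrap settings.
#' @return A `DuplexEstimate` object.
#' @seealso [estimateDeletion()]
#' @export
DuplexEstimate <- function(lambdaDloop, lambdaNd4, fDeletion, ci95,
                           flagNegative = fDeletion < 0, provenance = list()) {
    new("DuplexEstimate", lambdaDloop = as.numeric(lambdaDloop),
        lambdaNd4 = as.numeric(lambdaNd4), fDeletion = as.numeric(fDeletion),
        ci95 = as.numeric(ci95), flagNegative = as.logical(flagNegative),
        provenance = provenance)
}

setClass("DuplexEstimate",
    slots = c(
        lambdaDloop = "numeric",
        lambdaNd4 = "numeric",
        fDeletion = "numeric",
        ci95 = "numeric",
        flagNegative = "logical",
        provenance = "list"),
    validity = function(object) {
        msg <- character()
        if (object@lambdaDloop <= 0)
            msg <- c(msg, "'lambdaDloop' must be > 0")
        if (object@lambdaNd4 < 0)
            msg <- c(msg, "'lambdaNd4' must be >= 0")
        if (length(object@ci95) != 2L)
            msg <- c(msg, "'ci95' must be numeric(2)")
        else if (!any(is.na(object@ci95)) &&
                 (object@ci95[1] > object@fDeletion + 1e-9 ||
                  object@ci95[2] < object@fDeletion - 1e-9))
            msg <- c(msg, "'ci95' must bracket 'fDeletion'")
        if (length(msg)) msg else TRUE
    })

#' One participant's stimulation time course
#'
#' Day-indexed mtDNA copies per cell equivalent for one subject after
#' T-cell stimulation, with group label and age.  Days are sorted at
#' construction so peak extraction ([extractPeak()]) is invariant to input
#' ordering; ties in the maximum are broken by the earliest day.
#'
#' @param subjectId subject label.
#' @param group group label, one of `young`, `old`, `healthy_centenarian`,
#'   `frail_centenarian` (other labels are accepted for general use).
#' @param age age in years.
#' @param days nonnegative integer measurement days.
#' @param values copies per cell equivalent, same length as `days`.
#' @return A `SubjectTimecourse` object.
#' @export
SubjectTimecourse <- function(subjectId, group, age, days, values) {
    o <- order(days)
    new("SubjectTimecourse", subjectId = as.character(subjectId),
        group = as.character(group), age = as.numeric(age),
        days = as.integer(days)[o], values = as.numeric(values)[o])
}

setClass("SubjectTimecourse",
    slots = c(
        subjectId = "character",
        group = "character",
        age = "numeric",
        days = "integer",
        values = "numeric"),
    validity = function(object) {
        msg <- character()
        if (length(object@days) == 0L)
            msg <- c(msg, "series must be nonempty")
        if (length(object@days) != length(object@values))
            msg <- c(msg, "'days' and 'values' must have the same length")
        if (any(object@days < 0L))
            msg <- c(msg, "days must be nonnegative")
        if (anyDuplicated(object@days))
            msg <- c(msg, "days must be unique")
        if (is.unsorted(object@days))
            msg <- c(msg, "days must be sorted")
        if (length(msg)) msg else TRUE
    })
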