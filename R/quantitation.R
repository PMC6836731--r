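### Core quantitation: droplet classification, Poisson occupancy estimation
### with Wilson-score confidence intervals, and conversion to absolute
### copies per reaction and per cell equivalent.

#' Classify droplets as positive or negative
#'
#' Thresholds each channel of a well.  Three methods are available:
#'
#' * `two_cluster` (default): 1-D two-means clustering of the amplitudes,
#'   initialized at the amplitude extremes; the threshold is the midpoint of
#'   the two cluster centres.  If the centres are closer than three pooled
#'   within-cluster standard deviations the clusters are considered
#'   degenerate (e.g. a template-free well) and the method falls back to
#'   `negative_control` when a control well is supplied, otherwise it keeps
#'   the midpoint and emits a warning.
#' * `negative_control`: threshold at the control well's mean amplitude plus
#'   five control standard deviations.
#' * `manual`: an explicit amplitude threshold.
#'
#' Droplets strictly above the threshold are positive (ties count as
#' negative, the conservative choice).
#'
#' @param well a [DropletWell()].
#' @param method `"two_cluster"`, `"manual"` or `"negative_control"`.
#' @param manualThreshold amplitude threshold(s) for `method = "manual"`;
#'   recycled across channels.
#' @param negativeControlWell a [DropletWell()] of a cell-free control, used
#'   by `negative_control` and as the `two_cluster` fallback.
#' @return Named list of [DropletCounts()], one per channel.
#' @examples
#' model <- SimModel(rainFraction = 0, misclassFp = 0, misclassFn = 0)
#' well <- simulateWell(model, 422, 5, seed = 1)
#' counts <- classifyDroplets(well)
#' nPositive(counts[[1]]) == wellMetadata(well)$positives
#' @export
classifyDroplets <- function(well,
                             method = c("two_cluster", "manual",
                                        "negative_control"),
                             manualThreshold = NULL,
                             negativeControlWell = NULL) {
    stopifnot(is(well, "DropletWell"))
    method <- match.arg(method)
    chans <- channelNames(well)
    if (method == "manual") {
        if (is.null(manualThreshold))
            stop("method 'manual' requires 'manualThreshold'")
        manualThreshold <- rep_len(manualThreshold, length(chans))
    }
    if (method == "negative_control" && is.null(negativeControlWell))
        stop("method 'negative_control' requires 'negativeControlWell'")
    out <- lapply(seq_along(chans), function(i) {
        ch <- chans[i]
        x <- amplitudes(well, ch)
        if (!length(x))
            stop("empty amplitude list in channel '", ch, "'")
        usedMethod <- method
        thr <- switch(method,
            manual = manualThreshold[i],
            negative_control = .controlThreshold(negativeControlWell, ch),
            two_cluster = {
                tc <- .twoClusterThreshold(x)
                if (tc$degenerate) {
                    if (!is.null(negativeControlWell)) {
                        usedMethod <- "negative_control"
                        .controlThreshold(negativeControlWell, ch)
                    } else {
                        warning("channel '", ch, "' of well '", wellId(well),
                                "': amplitude clusters are not separable; ",
                                "keeping the midpoint threshold -- supply a ",
                                "negative control well", call. = FALSE)
                        tc$threshold
                    }
                } else tc$threshold
            })
        DropletCounts(nPositive = sum(x > thr), nTotal = length(x),
                      threshold = thr, method = usedMethod, channel = ch)
    })
    stats::setNames(out, chans)
}

## Threshold from a cell-free control: mean + 5 sd of the control channel.
.controlThreshold <- function(control, channel) {
    stopifnot(is(control, "DropletWell"))
    ch <- if (channel %in% channelNames(control)) channel
          else channelNames(control)[1]
    x <- amplitudes(control, ch)
    mean(x) + 5 * stats::sd(x)
}

## 1-D two-means clustering, deterministically initialized at the extremes.
## Returns the midpoint threshold and a degeneracy flag: centres closer than
## three pooled within-cluster sds.  Three, not two, because two-means run on
## a single Gaussian cluster (a template-free well) splits it at the mean
## and reports centres ~2.7 pooled sds apart; genuinely bimodal wells sit
## tens of sds apart.
.twoClusterThreshold <- function(x) {
    if (min(x) == max(x))
        return(list(threshold = max(x), degenerate = TRUE))
    km <- stats::kmeans(x, centers = matrix(c(min(x), max(x)), ncol = 1))
    centres <- sort(as.vector(km$centers))
    sizes <- km$size[order(as.vector(km$centers))]
    wss <- km$withinss[order(as.vector(km$centers))]
    df <- sum(pmax(sizes - 1, 0))
    pooledSd <- if (df > 0) sqrt(sum(wss) / df) else 0
    list(threshold = mean(centres),
         degenerate = diff(centres) < 3 * pooledSd)
}

#' Estimate Poisson occupancy from droplet counts
#'
#' The digital-PCR estimator: with `k` of `n` droplets positive, the mean
#' copies per droplet is `lambda = -ln(1 - k/n)`, the Poisson correction
#' for multiply occupied droplets.  The 95% confidence interval is a Wilson
#' score interval on the positive fraction `p = k/n`, transformed through
#' `-ln(1 - p)` (monotone, so the interval maps directly).
#'
#' `k = 0` returns `lambda = 0` with a one-sided upper bound and the `zero`
#' flag; `k/n > 0.85` adds the `high_occupancy` flag (precision degrades
#' near saturation; the assay targets about 5% positives).  `k = n` is an
#' error: occupancy is undefined at saturation and the sample must be
#' diluted.
#'
#' @param k positive droplets.
#' @param n total droplets (>= 1).
#' @param counts alternatively, a [DropletCounts()] supplying `k` and `n`.
#' @return List with `lambda`, `lambdaCi` (numeric(2)), `pHat`, `k`, `n`
#'   and `flags`.
#' @examples
#' estimateOccupancy(1000, 20000)$lambda   # -log(0.95) = 0.0512933
#' @export
estimateOccupancy <- function(k, n, counts = NULL) {
    if (!is.null(counts)) {
        stopifnot(is(counts, "DropletCounts"))
        k <- nPositive(counts)
        n <- nTotal(counts)
    }
    if (n < 1)
        stop("'n' must be >= 1")
    if (k < 0 || k > n)
        stop("'k' must satisfy 0 <= k <= n")
    if (k == n)
        stop("all ", n, " droplets are positive: occupancy is undefined at ",
             "saturation; dilute the sample and rerun")
    p <- k / n
    ciP <- .wilson(k, n)
    flags <- character()
    if (k == 0) {
        flags <- "zero"
        ciP[1] <- 0
    }
    if (p > 0.85)
        flags <- c(flags, "high_occupancy")
    lambda <- -log1p(-p)
    lambdaCi <- -log1p(-pmin(ciP, 1 - 1e-12))
    list(lambda = lambda, lambdaCi = lambdaCi, pHat = p, k = as.integer(k),
         n = as.integer(n), flags = flags)
}

#' Convert an occupancy estimate to absolute copies
#'
#' Applies the volume arithmetic of a [ReactionContext()] to an occupancy
#' estimate from [estimateOccupancy()]:
#' concentration = `lambda / dropletVolume` (copies/uL);
#' copies per reaction = concentration x reaction volume (`volumetric`
#' mode, the instrument-software convention) or `lambda x n` droplets
#' (`counted` mode, which counts only the emulsified template);
#' copies per cell equivalent = copies per reaction / cell equivalents.
#' The confidence interval is propagated through the same monotone scaling.
#' With 0 cell equivalents (a cell-free control) `copiesPerCell` is `NA`
#' and the interval is reported on copies per reaction.
#'
#' @param est list from [estimateOccupancy()].
#' @param ctx a [ReactionContext()].
#' @return A [CopyEstimate()].
#' @examples
#' est <- estimateOccupancy(1000, 20000)
#' toCopies(est, ReactionContext(cellEquivalents = 5))
#' @export
toCopies <- function(est, ctx) {
    stopifnot(is.list(est), is(ctx, "ReactionContext"))
    dropletVolUl <- ctx@dropletVolumeNl * 1e-3
    conc <- est$lambda / dropletVolUl
    scale <- if (ctx@copiesMode == "volumetric")
        ctx@reactionVolumeUl / dropletVolUl
    else
        est$n
    cpr <- est$lambda * scale
    cprCi <- est$lambdaCi * scale
    ce <- ctx@cellEquivalents
    if (ce > 0) {
        cpc <- cpr / ce
        ci <- cprCi / ce
    } else {
        cpc <- NA_real_
        ci <- cprCi
    }
    CopyEstimate(lambda = est$lambda, pHat = est$pHat,
                 lambdaCi = est$lambdaCi, concPerUl = conc,
                 copiesPerReaction = cpr, copiesPerCell = cpc, ci95 = ci,
                 flags = est$flags,
                 provenance = list(k = est$k, n = est$n,
                                   target = ctx@target,
                                   copiesMode = ctx@copiesMode,
                                   cellEquivalents = ce))
}

#' Pool replicate wells of one sample
#'
#' Merges the classified counts of replicate wells by droplet pooling: the
#' pooled estimate uses the summed positives and summed totals, which
#' weights wells by their droplet counts and tightens the confidence
#' interval.  Per-well estimates are retained in the provenance for CV
#' computation.
#'
#' @param countsList list of [DropletCounts()] for the same target.
#' @param ctx a [ReactionContext()].
#' @return A [CopyEstimate()] with `provenance$perWell` holding the
#'   individual well estimates.
#' @export
mergeReplicates <- function(countsList, ctx) {
    stopifnot(length(countsList) >= 1,
              all(vapply(countsList, is, logical(1), "DropletCounts")))
    chans <- vapply(countsList, function(x) x@channel, character(1))
    if (length(unique(chans)) > 1L)
        stop("replicate wells mix channels/targets: ",
             paste(unique(chans), collapse = ", "))
    k <- sum(vapply(countsList, nPositive, integer(1)))
    n <- sum(vapply(countsList, nTotal, integer(1)))
    pooled <- toCopies(estimateOccupancy(k, n), ctx)
    perWell <- lapply(countsList, function(cts)
        toCopies(estimateOccupancy(counts = cts), ctx))
    pooled@provenance$perWell <- perWell
    pooled
}

#' Quantify one well end to end
#'
#' The full single-well pipeline: classify droplets, estimate Poisson
#' occupancy, convert to copies per reaction and per cell equivalent.
#' Classification provenance (threshold, method, counts) is carried in the
#' result.
#'
#' @param well a [DropletWell()].
#' @param ctx a [ReactionContext()].
#' @param channel channel to quantify (default: first channel).
#' @inheritParams classifyDroplets
#' @return A [CopyEstimate()].
#' @examples
#' model <- SimModel(seed = 11L)
#' well <- simulateWell(model, trueCopiesPerCell = 422, cellEquivalents = 5)
#' quantifyWell(well, ReactionContext(cellEquivalents = 5))
#' @export
quantifyWell <- function(well, ctx, channel = channelNames(well)[1],
                         method = c("two_cluster", "manual",
                                    "negative_control"),
                         manualThreshold = NULL, negativeControlWell = NULL) {
    stopifnot(is(well, "DropletWell"), is(ctx, "ReactionContext"))
    method <- match.arg(method)
    counts <- classifyDroplets(well, method = method,
                               manualThreshold = manualThreshold,
                               negativeControlWell = negativeControlWell)
    if (!channel %in% names(counts))
        stop("channel '", channel, "' not present in well '", wellId(well), "'")
    cts <- counts[[channel]]
    res <- toCopies(estimateOccupancy(counts = cts), ctx)
    res@provenance$wellId <- wellId(well)
    res@provenance$sampleRef <- sampleRef(well)
    res@provenance$channel <- cts@channel
    res@provenance$threshold <- threshold(cts)
    res@provenance$method <- cts@method
    res
}
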