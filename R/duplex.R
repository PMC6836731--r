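### Duplexed common-deletion estimation: the fraction of mtDNA molecules
### carrying the 4977-bp common deletion, from a two-channel well that
### multiplexes MT-ND4 (inside the deletion) with the D-Loop (present in
### every replication-competent molecule).

#' Estimate the common-deletion fraction from a duplex well
#'
#' Computes `f = 1 - lambda_ND4 / lambda_DLoop` on the per-channel Poisson
#' occupancies — not on raw positive counts, which are biased downwards at
#' high occupancy by droplet co-occupancy.  The 95% confidence interval is
#' a parametric bootstrap: per channel, positives are resampled as
#' Binomial(`n`, `k/n`), occupancies recomputed, and the percentile
#' interval of the resampled `f` taken.  Sampling noise can produce `f`
#' slightly below 0 (e.g. in young donors with little deletion burden);
#' such values are reported unclamped with `flagNegative` set, because
#' clamping at 0 would bias group means upward.
#'
#' @param countsDloop,countsNd4 [DropletCounts()] for the D-Loop and MT-ND4
#'   channels of the same well.
#' @param nBoot bootstrap draws for the confidence interval.
#' @param seed optional integer seed for the bootstrap.
#' @return A [DuplexEstimate()].
#' @examples
#' model <- SimModel(seed = 3L)
#' dup <- simulateDuplexWell(model, copiesDloop = 2000, deletionFraction = 0.3)
#' cts <- classifyDroplets(dup)
#' estimateDeletion(cts[["Ch1 Amplitude"]], cts[["Ch2 Amplitude"]], seed = 1)
#' @export
estimateDeletion <- function(countsDloop, countsNd4, nBoot = 2000,
                             seed = NULL) {
    stopifnot(is(countsDloop, "DropletCounts"), is(countsNd4, "DropletCounts"))
    ed <- estimateOccupancy(counts = countsDloop)
    en <- estimateOccupancy(counts = countsNd4)
    if (ed$lambda <= 0)
        stop("D-Loop occupancy is zero: the deletion fraction is undefined ",
             "without detectable reference template")
    f <- 1 - en$lambda / ed$lambda
    ci <- .withSeed(seed, {
        kd <- stats::rbinom(nBoot, ed$n, ed$pHat)
        kn <- stats::rbinom(nBoot, en$n, en$pHat)
        ## saturation cannot occur at assay occupancies; cap defensively so
        ## the occupancy transform stays finite
        kd <- pmin(kd, ed$n - 1L)
        kn <- pmin(kn, en$n - 1L)
        ld <- -log1p(-kd / ed$n)
        ln <- -log1p(-kn / en$n)
        ok <- ld > 0
        stats::quantile(1 - ln[ok] / ld[ok], c(0.025, 0.975), names = FALSE)
    })
    ## the percentile interval can narrowly miss the point estimate on very
    ## sparse channels; widen to bracket it
    ci[1] <- min(ci[1], f)
    ci[2] <- max(ci[2], f)
    DuplexEstimate(lambdaDloop = ed$lambda, lambdaNd4 = en$lambda,
                   fDeletion = f, ci95 = ci, flagNegative = f < 0,
                   provenance = list(kDloop = ed$k, nDloop = ed$n,
                                     kNd4 = en$k, nNd4 = en$n,
                                     nBoot = nBoot))
}

#' Percent intact and percent deleted mtDNA
#'
#' Expresses a deletion estimate as the labelled percentage pair used for
#' plotting and age regression: `100 * (1 - f)` percent intact (unmutated)
#' mtDNA and `100 * f` percent carrying the deletion.
#'
#' @param est a [DuplexEstimate()] or a numeric deletion fraction.
#' @return Named numeric vector with `intact` and `deleted` percentages.
#' @examples
#' percentIntact(0.25)   # 75% intact, 25% deleted
#' @export
percentIntact <- function(est) {
    f <- if (is(est, "DuplexEstimate")) deletionFraction(est) else as.numeric(est)
    c(intact = 100 * (1 - f), deleted = 100 * f)
}
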