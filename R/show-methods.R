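### show() methods and a small diagnostic plot.

setMethod("show", "SimModel", function(object) {
    cat("SimModel\n")
    cat(sprintf("  copies/cell: mean %.4g, cv %.3g; pipetting cv %.3g\n",
                object@copiesPerCellMean, object@copiesPerCellCv,
                object@pipettingCv))
    cat(sprintf("  droplets: %d-%d of %.3g nL; reaction %.3g uL\n",
                object@dropletCountRange[1], object@dropletCountRange[2],
                object@dropletVolumeNl, object@reactionVolumeUl))
    cat(sprintf("  clusters: neg %.4g (sd %.3g), pos %.4g (sd %.3g); rain %.3g\n",
                object@amplitudeNeg[1], object@amplitudeNeg[2],
                object@amplitudePos[1], object@amplitudePos[2],
                object@rainFraction))
    cat(sprintf("  misclass: fp %.2g, fn %.2g\n",
                object@misclassFp, object@misclassFn))
})

setMethod("show", "DropletWell", function(object) {
    cat(sprintf("DropletWell '%s' (sample '%s'): %d droplets, %d channel(s): %s\n",
                object@wellId, object@sampleRef, nDroplets(object),
                length(object@amplitudes),
                paste(channelNames(object), collapse = ", ")))
    if (length(object@metadata))
        cat("  simulation ground truth attached\n")
})

setMethod("show", "DropletCounts", function(object) {
    cat(sprintf("DropletCounts [%s]: %d/%d positive (%.3g%%), threshold %.4g (%s)\n",
                object@channel, object@nPositive, object@nTotal,
                100 * object@nPositive / object@nTotal, object@threshold,
                object@method))
})

setMethod("show", "ReactionContext", function(object) {
    cat(sprintf("ReactionContext: %s, %.3g uL reaction, %.3g nL droplets, %.3g cell eq., mode '%s'\n",
                object@target, object@reactionVolumeUl,
                object@dropletVolumeNl, object@cellEquivalents,
                object@copiesMode))
})

setMethod("show", "CopyEstimate", function(object) {
    cat("CopyEstimate\n")
    cat(sprintf("  occupancy lambda = %.5g (p = %.5g)\n",
                object@lambda, object@pHat))
    cat(sprintf("  %.5g copies/uL; %.5g copies/reaction\n",
                object@concPerUl, object@copiesPerReaction))
    if (is.na(object@copiesPerCell))
        cat(sprintf("  copies/cell: NA (no cell equivalents); CI on copies/reaction [%.5g, %.5g]\n",
                    object@ci95[1], object@ci95[2]))
    else
        cat(sprintf("  %.5g copies/cell equivalent, 95%% CI [%.5g, %.5g]\n",
                    object@copiesPerCell, object@ci95[1], object@ci95[2]))
    if (length(object@flags))
        cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "DuplexEstimate", function(object) {
    cat("DuplexEstimate\n")
    cat(sprintf("  lambda D-Loop = %.5g, lambda MT-ND4 = %.5g\n",
                object@lambdaDloop, object@lambdaNd4))
    cat(sprintf("  deletion fraction f = %.4g, 95%% CI [%.4g, %.4g]%s\n",
                object@fDeletion, object@ci95[1], object@ci95[2],
                if (object@flagNegative) " [negative: sampling noise]" else ""))
})

setMethod("show", "SubjectTimecourse", function(object) {
    pk <- extractPeak(object)
    cat(sprintf("SubjectTimecourse '%s' (%s, age %.3g): %d days, peak %.4g copies/cell on day %d\n",
                object@subjectId, object@group, object@age,
                length(object@days), pk$peak, pk$peakDay))
})

#' Plot per-droplet amplitudes of a well
#'
#' Diagnostic dot plot of a well's droplet amplitudes in reading order,
#' with an optional classification threshold line.
#'
#' @param well a [DropletWell()].
#' @param channel channel to plot (default: first).
#' @param threshold optional amplitude threshold drawn as a dashed line.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `NULL`.
#' @export
plotAmplitudes <- function(well, channel = channelNames(well)[1],
                           threshold = NULL, ...) {
    x <- amplitudes(well, channel)
    graphics::plot(seq_along(x), x, pch = ".", cex = 2,
                   col = if (!is.null(threshold))
                       ifelse(x > threshold, "dodgerblue3", "grey40")
                   else "grey40",
                   xlab = "droplet", ylab = channel,
                   main = wellId(well), ...)
    if (!is.null(threshold))
        graphics::abline(h = threshold, lty = 2, col = "red3")
    invisible(NULL)
}
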