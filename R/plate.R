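### Plate-level pipelines binding I/O, classification and estimation:
### one row per sample/well in, a results table out.

## Build the ReactionContext for one plate-config well row.
.ctxFromRow <- function(row, defaults, copiesMode = NULL) {
    ReactionContext(
        cellEquivalents = row$cell_equivalents,
        reactionVolumeUl = defaults$reaction_volume_ul,
        dropletVolumeNl = defaults$droplet_volume_nl,
        target = row$target,
        copiesMode = copiesMode %||% defaults$copies_mode)
}

## Read every amplitude file referenced by a plate config.
.readPlateWells <- function(amplitudeDir, config) {
    wells <- config$wells
    out <- lapply(seq_len(nrow(wells)), function(i) {
        readAmplitudeCsv(file.path(amplitudeDir, wells$amplitude_file[i]),
                         wellId = wells$well_id[i],
                         sampleRef = wells$sample_ref[i])
    })
    stats::setNames(out, wells$well_id)
}

#' Quantify every well of a plate
#'
#' Runs the classify / estimate-occupancy / convert pipeline over all wells
#' referenced by a plate configuration.  Wells with a `control_ref` are
#' thresholded against that cell-free control; all others use two-cluster
#' thresholding.  Negative-control wells themselves are quantified with
#' their own threshold (they report copies per reaction; copies per cell is
#' `NA` at 0 cell equivalents).
#'
#' @param amplitudeDir directory containing the per-well amplitude CSVs.
#' @param config a `PlateConfig` from [readPlateConfig()], or a path to one.
#' @param copiesMode optional override of the config's copies mode.
#' @return `data.frame` with one row per well: identifiers, `k`, `n`,
#'   `threshold`, `method`, `lambda`, `conc_per_ul`, `copies_per_reaction`,
#'   `copies_per_cell`, `ci_low`, `ci_high`, `flags`.
#' @seealso [writeResults()]
#' @export
quantifyPlate <- function(amplitudeDir, config, copiesMode = NULL) {
    if (is.character(config))
        config <- readPlateConfig(config)
    stopifnot(inherits(config, "PlateConfig"))
    wells <- .readPlateWells(amplitudeDir, config)
    cfg <- config$wells
    rows <- lapply(seq_len(nrow(cfg)), function(i) {
        row <- cfg[i, ]
        ctx <- .ctxFromRow(row, config$defaults, copiesMode)
        ctl <- if (!is.na(row$control_ref)) wells[[row$control_ref]]
        method <- if (!is.null(ctl)) "negative_control" else "two_cluster"
        est <- quantifyWell(wells[[row$well_id]], ctx,
                            channel = row$channel, method = method,
                            negativeControlWell = ctl)
        data.frame(
            sample = row$sample_ref, well = row$well_id,
            target = row$target, channel = row$channel,
            cell_equivalents = row$cell_equivalents,
            k = est@provenance$k, n = est@provenance$n,
            threshold = est@provenance$threshold,
            method = est@provenance$method,
            lambda = occupancy(est), conc_per_ul = est@concPerUl,
            copies_per_reaction = copiesPerReaction(est),
            copies_per_cell = copiesPerCell(est),
            ci_low = ci95(est)[1], ci_high = ci95(est)[2],
            flags = paste(qcFlags(est), collapse = ";"),
            stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

#' Estimate deletion fractions across a plate
#'
#' Runs [estimateDeletion()] on every two-channel well of a plate: channel
#' 1 is taken as the D-Loop reference, channel 2 as MT-ND4.
#'
#' @param amplitudeDir directory with per-well amplitude CSVs.
#' @param config a `PlateConfig` or path to one.
#' @param nBoot bootstrap draws per well.
#' @param seed optional integer seed for the bootstrap intervals.
#' @return `data.frame` with one row per well: identifiers, channel
#'   occupancies, `f_deletion`, `ci_low`, `ci_high`, `pct_intact`,
#'   `flag_negative`.
#' @export
deletionPlate <- function(amplitudeDir, config, nBoot = 2000, seed = NULL) {
    if (is.character(config))
        config <- readPlateConfig(config)
    stopifnot(inherits(config, "PlateConfig"))
    wells <- .readPlateWells(amplitudeDir, config)
    seeds <- .withSeed(seed, .childSeeds(length(wells)))
    rows <- lapply(seq_along(wells), function(i) {
        w <- wells[[i]]
        chans <- channelNames(w)
        if (length(chans) < 2) {
            warning("well '", wellId(w), "' has a single channel; skipped",
                    call. = FALSE)
            return(NULL)
        }
        cts <- classifyDroplets(w)
        est <- estimateDeletion(cts[[chans[1]]], cts[[chans[2]]],
                                nBoot = nBoot, seed = seeds[i])
        data.frame(
            sample = sampleRef(w), well = wellId(w),
            lambda_dloop = est@lambdaDloop, lambda_nd4 = est@lambdaNd4,
            f_deletion = deletionFraction(est),
            ci_low = ci95(est)[1], ci_high = ci95(est)[2],
            pct_intact = unname(percentIntact(est)["intact"]),
            flag_negative = est@flagNegative,
            stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
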