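### Generics and simple accessor methods.

#' Accessors for ddmdm containers
#'
#' Slot access for the S4 containers goes through these accessors.
#' `nDroplets()` and `channelNames()` describe a [DropletWell()];
#' `amplitudes()` returns one channel's amplitude vector (or the full named
#' list); `nPositive()`, `nTotal()` and `threshold()` read a
#' [DropletCounts()]; `occupancy()`, `copiesPerCell()`,
#' `copiesPerReaction()`, `ci95()` and `qcFlags()` read a [CopyEstimate()];
#' `deletionFraction()` reads a [DuplexEstimate()]; `cellEquivalents()`
#' computes the cell equivalents a [DilutionChain()] delivers per reaction
#' (or reads the slot of a [ReactionContext()]).
#'
#' @param x,object an object of the documented class.
#' @param channel optional channel name for `amplitudes()`.
#' @param nCells starting cell count for `cellEquivalents()` on a
#'   `DilutionChain`.
#' @param ... further arguments for methods.
#' @return The accessed value; see the class documentation.
#' @name ddmdm-accessors
#' @aliases nDroplets channelNames amplitudes wellId sampleRef wellMetadata
#'   nPositive nTotal threshold occupancy copiesPerCell copiesPerReaction
#'   ci95 qcFlags deletionFraction cellEquivalents
NULL

#' @rdname ddmdm-accessors
#' @export
setGeneric("nDroplets", function(x) standardGeneric("nDroplets"))

#' @rdname ddmdm-accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname ddmdm-accessors
#' @export
setGeneric("amplitudes", function(x, channel = NULL) standardGeneric("amplitudes"))

#' @rdname ddmdm-accessors
#' @export
setGeneric("wellId", function(x) standardGeneric("wellId"))

#' @rdname ddmdm-accessors
#' @export
setGeneric("sampleRef", function(x) standardGeneric("sampleRef"))

#' @rdname ddmdm-accessors
#' @export
setGeneric("wellMetadata", function(x) standardGeneric("wellMetadata"))

#' @rdname ddmdm-accessors
#' @export
setGeneric("nPositive", function(x) standardGeneric("nPositive"))

#' @rdname ddmdm-accessors
#' @export
setGeneric("nTotal", function(x) standardGeneric("nTotal"))

#' @rdname ddmdm-accessors
#' @export
setGeneric("threshold", function(x) standardGeneric("threshold"))

#' @rdname ddmdm-accessors
#' @export
setGeneric("occupancy", function(x) standardGeneric("occupancy"))

#' @rdname ddmdm-accessors
#' @export
setGeneric("copiesPerCell", function(x) standardGeneric("copiesPerCell"))

#' @rdname ddmdm-accessors
#' @export
setGeneric("copiesPerReaction", function(x) standardGeneric("copiesPerReaction"))

#' @rdname ddmdm-accessors
#' @export
setGeneric("ci95", function(x) standardGeneric("ci95"))

#' @rdname ddmdm-accessors
#' @export
setGeneric("qcFlags", function(x) standardGeneric("qcFlags"))

#' @rdname ddmdm-accessors
#' @export
setGeneric("deletionFraction", function(x) standardGeneric("deletionFraction"))

#' @rdname ddmdm-accessors
#' @export
setGeneric("cellEquivalents", function(x, ...) standardGeneric("cellEquivalents"))

#' @rdname extractPeak
#' @export
setGeneric("extractPeak", function(x, ...) standardGeneric("extractPeak"))

## ---------------------------------------------------------------------------
## DropletWell accessors
## ---------------------------------------------------------------------------

#' @rdname ddmdm-accessors
setMethod("nDroplets", "DropletWell", function(x) lengths(x@amplitudes)[[1]])

#' @rdname ddmdm-accessors
setMethod("channelNames", "DropletWell", function(x) names(x@amplitudes))

#' @rdname ddmdm-accessors
setMethod("amplitudes", "DropletWell", function(x, channel = NULL) {
    if (is.null(channel))
        return(x@amplitudes)
    if (!channel %in% names(x@amplitudes))
        stop("unknown channel '", channel, "' in well '", x@wellId, "'")
    x@amplitudes[[channel]]
})

#' @rdname ddmdm-accessors
setMethod("wellId", "DropletWell", function(x) x@wellId)

#' @rdname ddmdm-accessors
setMethod("sampleRef", "DropletWell", function(x) x@sampleRef)

#' @rdname ddmdm-accessors
setMethod("wellMetadata", "DropletWell", function(x) x@metadata)

## ---------------------------------------------------------------------------
## DropletCounts accessors
## ---------------------------------------------------------------------------

#' @rdname ddmdm-accessors
setMethod("nPositive", "DropletCounts", function(x) x@nPositive)

#' @rdname ddmdm-accessors
setMethod("nTotal", "DropletCounts", function(x) x@nTotal)

#' @rdname ddmdm-accessors
setMethod("threshold", "DropletCounts", function(x) x@threshold)

## ---------------------------------------------------------------------------
## CopyEstimate / DuplexEstimate accessors
## ---------------------------------------------------------------------------

#' @rdname ddmdm-accessors
setMethod("occupancy", "CopyEstimate", function(x) x@lambda)

#' @rdname ddmdm-accessors
setMethod("copiesPerCell", "CopyEstimate", function(x) x@copiesPerCell)

#' @rdname ddmdm-accessors
setMethod("copiesPerReaction", "CopyEstimate", function(x) x@copiesPerReaction)

#' @rdname ddmdm-accessors
setMethod("ci95", "CopyEstimate", function(x) x@ci95)

#' @rdname ddmdm-accessors
setMethod("qcFlags", "CopyEstimate", function(x) x@flags)

#' @rdname ddmdm-accessors
setMethod("deletionFraction", "DuplexEstimate", function(x) x@fDeletion)

#' @rdname ddmdm-accessors
setMethod("ci95", "DuplexEstimate", function(x) x@ci95)

## ---------------------------------------------------------------------------
## Dilution-chain arithmetic
## ---------------------------------------------------------------------------

#' @rdname ddmdm-accessors
setMethod("cellEquivalents", "ReactionContext", function(x, ...) x@cellEquivalents)

#' @rdname ddmdm-accessors
setMethod("cellEquivalents", "DilutionChain", function(x, nCells = 1, ...) {
    ## concentration bookkeeping: each take/add step multiplies the cell
    ## concentration by takeUl / (takeUl + addUl); the aliquot then carries
    ## conc * aliquotVolumeUl cell equivalents into the reaction.
    conc <- nCells / x@startVolumeUl
    vol <- x@startVolumeUl
    if (nrow(x@steps))
        for (i in seq_len(nrow(x@steps))) {
            take <- x@steps$takeUl[i]
            add <- x@steps$addUl[i]
            if (take > vol)
                stop("dilution step ", i, " takes ", take,
                     " uL but only ", vol, " uL are available")
            conc <- conc * take / (take + add)
            vol <- take + add
        }
    if (x@aliquotVolumeUl > vol)
        stop("aliquot of ", x@aliquotVolumeUl, " uL exceeds the ", vol,
             " uL available after the last step")
    conc * x@aliquotVolumeUl
})
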