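# Shared fixtures: a noiseless model for exact-recovery checks and a small
# fast model for tests where droplet count does not matter.

cleanModel <- function(...) {
    SimModel(rainFraction = 0, misclassFp = 0, misclassFn = 0,
             pipettingCv = 0, copiesPerCellCv = 0, ...)
}

smallModel <- function(...) {
    cleanModel(dropletCountRange = c(4000L, 4000L), ...)
}

# The protocol dilution chains used throughout: bulk lysate (5 cell
# equivalents per reaction from 1e5 cells) and single cell (0.3 cell
# equivalents).
bulkChain <- function() {
    DilutionChain(40, data.frame(takeUl = c(10, 1), addUl = c(10, 249)), 1)
}

singleCellChain <- function() {
    DilutionChain(10, data.frame(takeUl = 10, addUl = 15), 7.5)
}
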