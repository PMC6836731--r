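### File interchange: per-droplet amplitude CSVs (instrument-export
### dialect), plate configuration (YAML), and results tables with a
### commented metadata header.

#' Read a per-droplet amplitude CSV
#'
#' Parses an instrument-style per-droplet export: a header row, one
#' amplitude column per channel named `"Ch1 Amplitude"`, `"Ch2 Amplitude"`,
#' ..., one row per droplet.  Any other columns (e.g. a `Cluster` call) are
#' preserved untouched in the well's `extra` slot but ignored for
#' classification.  Malformed amplitude values are rejected with
#' row-indexed errors; nothing is silently coerced.
#'
#' @param path CSV file path.
#' @param wellId well label; defaults to the file name without extension.
#' @param sampleRef sample label; defaults to `wellId`.
#' @return A [DropletWell()].
#' @seealso [writeAmplitudeCsv()]
#' @export
readAmplitudeCsv <- function(path, wellId = NULL, sampleRef = NULL) {
    if (!file.exists(path))
        stop("amplitude file not found: ", path)
    if (file.size(path) == 0)
        stop("amplitude file is empty: ", path)
    df <- tryCatch(
        utils::read.csv(path, check.names = FALSE, colClasses = "character"),
        error = function(e) stop("cannot parse '", path, "': ",
                                 conditionMessage(e), call. = FALSE))
    ampCols <- grep("Amplitude", names(df), value = TRUE)
    if (!length(ampCols))
        stop("'", path, "' has no amplitude column; expected a header like ",
             "'Ch1 Amplitude'")
    if (!nrow(df))
        stop("'", path, "' contains a header but no droplets")
    amps <- lapply(ampCols, function(cn) {
        x <- suppressWarnings(as.numeric(df[[cn]]))
        bad <- which(is.na(x) & !is.na(df[[cn]]) & nzchar(df[[cn]]))
        bad <- union(bad, which(is.na(df[[cn]]) | !nzchar(df[[cn]])))
        if (length(bad))
            stop("'", path, "', column '", cn, "': non-numeric amplitude in ",
                 "row(s) ", paste(utils::head(sort(bad), 5), collapse = ", "),
                 if (length(bad) > 5) " ..." else "")
        x
    })
    names(amps) <- ampCols
    extra <- df[setdiff(names(df), ampCols)]
    if (ncol(extra))
        extra <- utils::type.convert(extra, as.is = TRUE)
    if (is.null(wellId))
        wellId <- sub("\\.[^.]*$", "", basename(path))
    DropletWell(amplitudes = amps, wellId = wellId,
                sampleRef = if (is.null(sampleRef)) wellId else sampleRef,
                extra = extra)
}

#' Write a well as a per-droplet amplitude CSV
#'
#' Writes the same dialect [readAmplitudeCsv()] reads.  Amplitudes are
#' written with 17 significant digits so a write/read round trip reproduces
#' them exactly; extra per-droplet columns are carried through.
#'
#' @param well a [DropletWell()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeAmplitudeCsv <- function(well, path) {
    stopifnot(is(well, "DropletWell"))
    cols <- lapply(amplitudes(well), function(x) sprintf("%.17g", x))
    df <- as.data.frame(cols, check.names = FALSE, optional = TRUE)
    names(df) <- channelNames(well)
    if (nrow(well@extra))
        df <- cbind(df, well@extra)
    utils::write.table(df, path, sep = ",", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' Read and validate a plate configuration
#'
#' Loads a YAML plate description: a `defaults` block (reaction volume,
#' droplet volume, copies mode, optional seed) and a `wells` list, each
#' entry giving `well_id`, `sample_ref`, `target`, `cell_equivalents`, and
#' optionally `amplitude_file`, `replicate_group`, `channel`,
#' `negative_control` (flag) and `control_ref` (the `well_id` of the
#' cell-free control to threshold against).  Validation errors name the
#' offending key and well.
#'
#' @param path YAML file path.
#' @return A `PlateConfig`: list with `defaults` (list) and `wells`
#'   (`data.frame`, one row per well).
#' @export
readPlateConfig <- function(path) {
    if (!file.exists(path))
        stop("plate config not found: ", path)
    cfg <- yaml::read_yaml(path)
    defaults <- list(reaction_volume_ul = 20, droplet_volume_nl = 0.85,
                     copies_mode = "volumetric", seed = NA_integer_)
    if (!is.null(cfg$defaults)) {
        unknown <- setdiff(names(cfg$defaults), names(defaults))
        if (length(unknown))
            stop("unknown key(s) in 'defaults': ",
                 paste(unknown, collapse = ", "))
        defaults[names(cfg$defaults)] <- cfg$defaults
    }
    if (!defaults$copies_mode %in% c("volumetric", "counted"))
        stop("'defaults$copies_mode' must be 'volumetric' or 'counted', got '",
             defaults$copies_mode, "'")
    if (is.null(cfg$wells) || !length(cfg$wells))
        stop("plate config has no 'wells' entries")
    wells <- lapply(seq_along(cfg$wells), function(i) {
        w <- cfg$wells[[i]]
        if (is.null(w$well_id))
            stop("wells[", i, "]: missing required key 'well_id'")
        if (is.null(w$cell_equivalents))
            stop("well '", w$well_id, "': missing required key ",
                 "'cell_equivalents'")
        if (w$cell_equivalents < 0)
            stop("well '", w$well_id, "': 'cell_equivalents' must be >= 0")
        data.frame(
            well_id = as.character(w$well_id),
            sample_ref = as.character(w$sample_ref %||% w$well_id),
            target = as.character(w$target %||% "D-Loop"),
            cell_equivalents = as.numeric(w$cell_equivalents),
            amplitude_file = as.character(w$amplitude_file %||%
                                          paste0(w$well_id, ".csv")),
            replicate_group = as.character(w$replicate_group %||%
                                           w$sample_ref %||% w$well_id),
            channel = as.character(w$channel %||% "Ch1 Amplitude"),
            negative_control = isTRUE(w$negative_control),
            control_ref = as.character(w$control_ref %||% NA_character_),
            stringsAsFactors = FALSE)
    })
    wells <- do.call(rbind, wells)
    dup <- wells$well_id[duplicated(wells$well_id)]
    if (length(dup))
        stop("duplicate well_id in plate config: ",
             paste(unique(dup), collapse = ", "))
    missingCtl <- setdiff(stats::na.omit(wells$control_ref), wells$well_id)
    if (length(missingCtl))
        stop("control_ref refers to unknown well(s): ",
             paste(missingCtl, collapse = ", "))
    structure(list(defaults = defaults, wells = wells),
              class = "PlateConfig")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a results table with a metadata header
#'
#' Writes a `data.frame` as CSV preceded by `#`-prefixed metadata lines
#' (tool version, seed, free-form parameters).  Numeric columns are written
#' with 17 significant digits so [readResults()] recovers them at full
#' double precision.
#'
#' @param df results `data.frame`.
#' @param path output path.
#' @param metadata named list written as `# key: value` lines; the package
#'   version is always included.
#' @return `path`, invisibly.
#' @export
writeResults <- function(df, path, metadata = list()) {
    stopifnot(is.data.frame(df))
    meta <- c(list(tool = paste0("ddmdm ",
                                 as.character(utils::packageVersion("ddmdm")))),
              metadata)
    hdr <- vapply(names(meta), function(k)
        sprintf("# %s: %s", k, paste(format(meta[[k]]), collapse = " ")),
        character(1))
    out <- df
    for (cn in names(out))
        if (is.numeric(out[[cn]]))
            out[[cn]] <- sprintf("%.17g", out[[cn]])
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    utils::write.table(out, con, sep = ",", quote = TRUE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' Read a results table written by [writeResults()]
#'
#' @param path CSV path.
#' @return `data.frame` (metadata header lines are skipped).
#' @export
readResults <- function(path) {
    utils::read.csv(path, comment.char = "#", check.names = FALSE)
}
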