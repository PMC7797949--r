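# File formats: 16-bit grayscale TIFF fields in, CSV/JSON tables out,
# YAML/JSON run configuration.

tableSchemaVersion <- "EVcoloc-tables-v1"

#' Write a single-channel field image as 16-bit grayscale TIFF
#'
#' Counts are rounded and clamped to the 16-bit range; reading the file
#' back with [readFieldTiff()] recovers the integer counts exactly.
#'
#' @param image numeric matrix of camera counts.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeFieldTiff <- function(image, path) {
    img <- pmin(pmax(round(image), 0), 65535)
    tiff::writeTIFF(img / 65535, path, bits.per.sample = 16L)
    invisible(path)
}

#' Read a single-plane grayscale TIFF as a counts matrix
#'
#' @param path TIFF file path.
#' @return numeric matrix of integer counts.
#' @export
readFieldTiff <- function(path) {
    img <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(img)) != 2L)
        stop(sprintf("%s is not a single-plane grayscale image", path))
    storage.mode(img) <- "double"
    img
}

# Filename for one field/channel image: <sample>_f<field>_<channel>.tif
fieldFileName <- function(sample, field, channel)
    sprintf("%s_f%d_%s.tif", sample, field, channel)

#' Write a simulated sample to disk
#'
#' Writes one 16-bit TIFF per field and channel (pattern
#' `<sample>_f<field>_<channel>.tif`) plus the ground truth as
#' `<sample>_truth.csv` (vesicle id, field, position in nm, class, and the
#' per-channel emission flags).
#'
#' @param fields list as returned by [simulateSample()].
#' @param outDir output directory (created if needed).
#' @param sample sample name used in filenames.
#' @return character vector of written image paths, invisibly.
#' @export
writeSample <- function(fields, outDir, sample) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    paths <- character()
    truths <- list()
    for (f in seq_along(fields)) {
        for (ch in names(fields[[f]]$images)) {
            p <- file.path(outDir, fieldFileName(sample, f, ch))
            writeFieldTiff(fields[[f]]$images[[ch]], p)
            paths <- c(paths, p)
        }
        tr <- fields[[f]]$truth
        tr$field <- f
        truths[[f]] <- tr
    }
    truth <- do.call(rbind, truths)
    utils::write.csv(truth, file.path(outDir, paste0(sample, "_truth.csv")),
                     row.names = FALSE)
    invisible(paths)
}

#' Read grouped field images from a directory
#'
#' Discovers files matching `<sample>_f<field>_<channel>.tif` and groups
#' them by field. Fields missing any requested channel are skipped with a
#' warning.
#'
#' @param dir directory containing the images.
#' @param channels channel names expected per field.
#' @param sample sample name; when NULL, the single sample present is used.
#' @return named list field -> named list channel -> counts matrix.
#' @export
readFieldImages <- function(dir, channels, sample = NULL) {
    files <- list.files(dir, pattern = "_f[0-9]+_.*\\.tif$")
    meta <- regmatches(files, regexec("^(.*)_f([0-9]+)_(.*)\\.tif$", files))
    info <- do.call(rbind, lapply(meta, function(m)
        data.frame(file = m[1], sample = m[2],
                   field = as.integer(m[3]), channel = m[4])))
    if (is.null(info) || nrow(info) == 0L)
        stop(sprintf("no field images found in %s", dir))
    if (is.null(sample)) {
        samples <- unique(info$sample)
        if (length(samples) > 1L)
            stop("multiple samples present; specify `sample`")
        sample <- samples
    }
    info <- info[info$sample == sample & info$channel %in% channels, ,
                 drop = FALSE]
    out <- list()
    for (f in sort(unique(info$field))) {
        sub <- info[info$field == f, , drop = FALSE]
        if (!all(channels %in% sub$channel)) {
            warning(sprintf(
                "field %d skipped: missing channel(s) %s", f,
                paste(setdiff(channels, sub$channel), collapse = ", ")))
            next
        }
        imgs <- stats::setNames(lapply(channels, function(ch)
            readFieldTiff(file.path(dir,
                                    sub$file[sub$channel == ch][1]))),
            channels)
        out[[paste0("f", f)]] <- imgs
    }
    out
}

# Write a CSV with a one-line schema header comment.
writeTableCsv <- function(df, path, what) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# %s %s", tableSchemaVersion, what), con)
    utils::write.csv(df, con, row.names = FALSE)
    invisible(path)
}

readTableCsv <- function(path) {
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write analysis tables
#'
#' Writes the spot table (one row per detected spot, reference-frame pixel
#' coordinates plus nm columns), the vesicle-record table (record id,
#' class, centroid, member count), a JSON profile summary and, optionally,
#' a JSON comparison summary. Empty inputs give header-only files.
#'
#' @param spots spot data.frame (any number of fields/channels; a `field`
#'   column is preserved when present).
#' @param vesicles a [VesicleSet-class], a list of them (one per field), or
#'   NULL.
#' @param profile a [PopulationProfile-class] or NULL.
#' @param outDir output directory.
#' @param comparison a [ProfileComparison-class] or NULL.
#' @param pixelSize nm per pixel for the nm coordinate columns.
#' @return named list of written paths, invisibly.
#' @export
writeTables <- function(spots, vesicles = NULL, profile = NULL, outDir,
                        comparison = NULL, pixelSize = 100) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    paths <- list()
    sp <- if (is.null(spots) || nrow(spots) == 0L) emptySpots() else spots
    sp$x_nm <- sp$x * pixelSize
    sp$y_nm <- sp$y * pixelSize
    paths$spots <- writeTableCsv(sp, file.path(outDir, "spots.csv"), "spots")
    if (!is.null(vesicles)) {
        vl <- if (is(vesicles, "VesicleSet")) list(vesicles) else vesicles
        recs <- do.call(rbind, lapply(seq_along(vl), function(i) {
            r <- records(vl[[i]])
            if (nrow(r)) r$field <- names(vl)[i] %||% i
            r
        }))
        if (is.null(recs)) recs <- matchChannels(list(a = emptySpots()))@records
        if (nrow(recs)) {
            recs$centroid_x_nm <- recs$centroid_x * pixelSize
            recs$centroid_y_nm <- recs$centroid_y * pixelSize
        }
        paths$records <- writeTableCsv(recs, file.path(outDir, "records.csv"),
                                       "vesicle records")
    }
    if (!is.null(profile)) {
        pj <- list(schema = tableSchemaVersion,
                   sample_id = profile@sampleId,
                   channels = profile@channels,
                   total_records = profile@totalRecords,
                   class_fractions = as.list(profile@classFractions),
                   class_fraction_sd = as.list(profile@classFractionSd),
                   per_field_counts = apply(profile@perFieldCounts, 1,
                                            as.list, simplify = FALSE))
        paths$profile <- file.path(outDir, "profile.json")
        jsonlite::write_json(pj, paths$profile, auto_unbox = TRUE,
                             digits = NA, pretty = TRUE)
    }
    if (!is.null(comparison)) {
        cj <- list(schema = tableSchemaVersion,
                   sample_ids = comparison@sampleIds,
                   distance_matrix = comparison@distanceMatrix,
                   embedding = comparison@embedding,
                   perplexity = comparison@perplexity)
        paths$comparison <- file.path(outDir, "comparison.json")
        jsonlite::write_json(cj, paths$comparison, auto_unbox = TRUE,
                             digits = NA, pretty = TRUE)
    }
    invisible(paths)
}

#' Read a spot table written by [writeTables()]
#'
#' @param path path to spots.csv.
#' @return spot data.frame.
#' @export
readSpotTable <- function(path) readTableCsv(path)

#' Read and validate a run configuration
#'
#' YAML (.yml/.yaml) or JSON configuration mirroring the parameter classes:
#' top-level keys `channels`, `paths` (images, bead_images, out_dir),
#' `acquisition`, `detection`, `colocalization`, `analysis`, `seed`,
#' `sample`. Missing parameter blocks fall back to package defaults.
#'
#' @param path configuration file.
#' @return validated config list with parameter objects attached
#'   (elements acquisitionParams, detectionParams, colocalizationParams).
#' @export
readRunConfig <- function(path) {
    cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
           else jsonlite::read_json(path, simplifyVector = TRUE)
    buildRunConfig(cfg)
}

#' Build a validated run configuration from a list
#'
#' @param cfg configuration list (see [readRunConfig()]).
#' @return the config with instantiated parameter objects.
#' @export
buildRunConfig <- function(cfg) {
    if (is.null(cfg$channels) || length(cfg$channels) < 1L)
        stop("config must declare at least one channel")
    cfg$channels <- as.character(cfg$channels)
    acqArgs <- cfg$acquisition %||% list()
    # channel transforms may be given in config as translations {dx, dy}
    if (!is.null(acqArgs$channelTransforms) &&
        !all(vapply(acqArgs$channelTransforms, is, logical(1),
                    "ChannelTransform")))
        acqArgs$channelTransforms <- lapply(acqArgs$channelTransforms,
            function(t) translationTransform(t$dx %||% 0, t$dy %||% 0))
    acq <- do.call(acquisitionParams, acqArgs)
    det <- do.call(detectionParams, cfg$detection %||% list())
    col <- do.call(colocalizationParams, cfg$colocalization %||% list())
    cfg$acquisitionParams <- acq
    cfg$detectionParams <- det
    cfg$colocalizationParams <- col
    cfg$seed <- cfg$seed %||% 1
    cfg$sample <- cfg$sample %||% "sample"
    cfg$analysis <- cfg$analysis %||% list()
    cfg
}

# Polynomial rolling hash of a character string, as hex (run-log config
# hashes; stability matters, cryptographic strength does not).
configHash <- function(txt) {
    bytes <- utf8ToInt(txt)
    h <- 0
    for (b in bytes) h <- (h * 131 + b) %% 2147483647
    sprintf("%08x", as.integer(h))
}
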