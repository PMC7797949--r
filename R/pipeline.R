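# End-to-end pipeline driver: registration (when bead images exist) ->
# localization -> co-localization -> profile, with tables and a run log.

pkgVersion <- function() {
    as.character(utils::packageVersion("EVcoloc"))
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes, for one sample: channel calibration from fiducial-bead images
#' (identity transforms with a warning when none are given), per-channel
#' spot localization on every field, coordinate correction into the
#' reference frame, distance-threshold co-localization, and population
#' profiling. Writes the spot/record tables, the profile JSON, and a run
#' log (plain text and JSON lines) recording the tool version, config
#' hash, seed and per-stage counts. Deterministic for a fixed config and
#' seed.
#'
#' @param config configuration list from [readRunConfig()] /
#'   [buildRunConfig()]. Uses `channels`, `paths$images`,
#'   `paths$bead_images` (optional), `paths$out_dir`, `sample`, `seed`,
#'   and the parameter blocks.
#' @return invisibly, a list with elements transforms, spots,
#'   vesiclesByField, profile, counts and paths.
#' @export
runPipeline <- function(config) {
    cfg <- if (is.null(config$acquisitionParams)) buildRunConfig(config)
           else config
    channels <- cfg$channels
    outDir <- cfg$paths$out_dir %||% "."
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    logLines <- character()
    logJson <- character()
    note <- function(stage, ...) {
        entry <- list(stage = stage, ...)
        msgTxt <- paste(names(entry)[-1], unlist(entry[-1]),
                        sep = "=", collapse = " ")
        logLines <<- c(logLines, sprintf("[%s] %s", stage, msgTxt))
        logJson <<- c(logJson, jsonlite::toJSON(entry, auto_unbox = TRUE))
    }
    note("run", version = pkgVersion(),
         config_hash = configHash(jsonlite::toJSON(
             cfg[setdiff(names(cfg), c("acquisitionParams", "detectionParams",
                                       "colocalizationParams"))],
             auto_unbox = TRUE, force = TRUE)),
         seed = cfg$seed, sample = cfg$sample)

    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
    }

    # --- registration -----------------------------------------------------
    transforms <- stage("register", {
        if (!is.null(cfg$paths$bead_images)) {
            beadFields <- readFieldImages(cfg$paths$bead_images, channels)
            if (!length(beadFields)) stop("no complete bead fields found")
            calibrateChannels(beadFields[[1]], cfg$detectionParams,
                              model = cfg$analysis$transform_model %||% "affine")
        } else {
            warning("no bead images configured; assuming identity transforms")
            note("register", assumed = "identity")
            stats::setNames(rep(list(identityTransform()), length(channels)),
                            channels)
        }
    })
    for (ch in channels)
        note("register", channel = ch,
             rms_residual = transforms[[ch]]@rmsResidual,
             n_control_points = transforms[[ch]]@nControlPoints)

    # --- localization + correction ---------------------------------------
    fields <- stage("localize", {
        f <- readFieldImages(cfg$paths$images, channels, sample = cfg$sample)
        if (!length(f)) stop("no complete fields found")
        f
    })
    spotsByField <- list()
    for (fn in names(fields)) {
        perCh <- stats::setNames(lapply(channels, function(ch) {
            sp <- localizeSpots(fields[[fn]][[ch]], cfg$detectionParams, ch)
            applyTransform(sp, transforms[[ch]])
        }), channels)
        for (ch in channels)
            note("localize", field = fn, channel = ch,
                 n_spots = nrow(perCh[[ch]]))
        spotsByField[[fn]] <- perCh
    }

    # --- co-localization ---------------------------------------------------
    vesiclesByField <- stage("colocalize", {
        out <- lapply(spotsByField, matchChannels,
                      params = cfg$colocalizationParams)
        for (fn in names(out)) {
            tab <- table(records(out[[fn]])$class)
            note("colocalize", field = fn,
                 n_records = nrow(records(out[[fn]])),
                 classes = paste(names(tab), as.integer(tab),
                                 sep = ":", collapse = ","))
        }
        out
    })

    # --- profile -----------------------------------------------------------
    profile <- stage("profile",
                     buildProfile(vesiclesByField, cfg$sample, channels))
    note("profile", total_records = profile@totalRecords,
         n_fields = nrow(profile@perFieldCounts))

    allSpots <- do.call(rbind, lapply(names(spotsByField), function(fn) {
        sp <- do.call(rbind, spotsByField[[fn]])
        if (nrow(sp)) sp$field <- fn
        sp
    }))
    paths <- writeTables(allSpots, vesiclesByField, profile, outDir,
                         pixelSize = cfg$acquisitionParams@pixelSize)
    writeLines(logLines, file.path(outDir, "run_log.txt"))
    writeLines(logJson, file.path(outDir, "run_log.jsonl"))
    invisible(list(transforms = transforms, spots = allSpots,
                   vesiclesByField = vesiclesByField, profile = profile,
                   paths = paths))
}

#' Simulate a dataset and write it to disk
#'
#' Convenience driver for the simulator: draws the configured population
#' for each field, renders every channel, writes the TIFFs and ground
#' truth, and (optionally) writes bead calibration fields.
#'
#' @param config configuration list; uses `channels`, `sample`, `seed`,
#'   `paths$out_dir`, `acquisition`, and a `population` block
#'   (class_fractions, n_vesicles, labeling_efficiency, mean_brightness,
#'   brightness_sdlog) plus `n_fields` and `n_beads`.
#' @return invisibly, the list of simulated fields.
#' @export
simulateDataset <- function(config) {
    cfg <- if (is.null(config$acquisitionParams)) buildRunConfig(config)
           else config
    pop <- cfg$population %||% stop("config must have a population block")
    fr <- unlist(pop$class_fractions)
    spec <- populationSpec(cfg$channels, fr,
                           nVesicles = pop$n_vesicles %||% 300,
                           labelingEfficiency = pop$labeling_efficiency %||% 1,
                           meanBrightness = pop$mean_brightness %||% 1,
                           brightnessSdLog = pop$brightness_sdlog %||% 0)
    params <- cfg$acquisitionParams
    outDir <- cfg$paths$out_dir %||% "."
    fields <- simulateSample(spec, params, cfg$n_fields %||% 5,
                             seed = cfg$seed)
    writeSample(fields, outDir, cfg$sample)
    nBeads <- cfg$n_beads %||% 0
    if (nBeads > 0) {
        beads <- renderBeadFields(nBeads, params, cfg$channels,
                                  seed = deriveSeed(cfg$seed, "beads"))
        beadDir <- file.path(outDir, "beads")
        dir.create(beadDir, recursive = TRUE, showWarnings = FALSE)
        for (ch in cfg$channels)
            writeFieldTiff(beads$images[[ch]],
                           file.path(beadDir,
                                     fieldFileName("beads", 1, ch)))
        utils::write.csv(beads$positions,
                         file.path(beadDir, "beads_truth.csv"),
                         row.names = FALSE)
    }
    invisible(fields)
}
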