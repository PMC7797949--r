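# Accessor generics and show methods.

#' Accessors for EVcoloc objects
#'
#' `records()` and `spotTable()` return the vesicle-record and member-spot
#' tables of a [VesicleSet-class]; `channelNames()` the ordered channel set
#' of a VesicleSet or [PopulationProfile-class]; `classFractions()` /
#' `classFractionSd()` / `perFieldCounts()` / `sampleId()` the profile
#' summaries.
#'
#' @param object an EVcoloc S4 object.
#' @return the corresponding table or vector.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("records", function(object) standardGeneric("records"))
#' @rdname accessors
#' @export
setMethod("records", "VesicleSet", function(object) object@records)

#' @rdname accessors
#' @export
setGeneric("spotTable", function(object) standardGeneric("spotTable"))
#' @rdname accessors
#' @export
setMethod("spotTable", "VesicleSet", function(object) object@spots)

#' @rdname accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setMethod("channelNames", "VesicleSet", function(object) object@channels)
#' @rdname accessors
#' @export
setMethod("channelNames", "PopulationProfile", function(object) object@channels)
#' @rdname accessors
#' @export
setMethod("channelNames", "PopulationSpec", function(object) object@channels)

#' @rdname accessors
#' @export
setGeneric("classFractions", function(object) standardGeneric("classFractions"))
#' @rdname accessors
#' @export
setMethod("classFractions", "PopulationProfile",
          function(object) object@classFractions)
#' @rdname accessors
#' @export
setMethod("classFractions", "PopulationSpec",
          function(object) object@classFractions)

#' @rdname accessors
#' @export
setGeneric("classFractionSd",
           function(object) standardGeneric("classFractionSd"))
#' @rdname accessors
#' @export
setMethod("classFractionSd", "PopulationProfile",
          function(object) object@classFractionSd)

#' @rdname accessors
#' @export
setGeneric("perFieldCounts", function(object) standardGeneric("perFieldCounts"))
#' @rdname accessors
#' @export
setMethod("perFieldCounts", "PopulationProfile",
          function(object) object@perFieldCounts)

#' @rdname accessors
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setMethod("sampleId", "PopulationProfile", function(object) object@sampleId)

setMethod("show", "ChannelTransform", function(object) {
    cat(sprintf("ChannelTransform (%s)\n", object@model))
    cat(sprintf("  A = [% .6f % .6f; % .6f % .6f]  b = (% .4f, % .4f)\n",
                object@A[1, 1], object@A[1, 2], object@A[2, 1], object@A[2, 2],
                object@b[1], object@b[2]))
    if (object@nControlPoints > 0L)
        cat(sprintf("  fitted on %d control points, RMS residual %.4g px\n",
                    object@nControlPoints, object@rmsResidual))
})

setMethod("show", "AcquisitionParams", function(object) {
    cat("AcquisitionParams\n")
    cat(sprintf("  %d x %d px at %.0f nm/px (%.0f um^2), PSF sigma %.0f nm\n",
                object@fieldShape[1], object@fieldShape[2], object@pixelSize,
                fieldAreaUm2(object), object@psfSigma))
    cat(sprintf("  background %.0f counts, read noise %.1f, photon scale %.0f\n",
                object@backgroundLevel, object@readNoiseSd, object@photonScale))
    if (length(object@channelTransforms))
        cat(sprintf("  channel transforms: %s\n",
                    paste(names(object@channelTransforms), collapse = ", ")))
})

setMethod("show", "PopulationSpec", function(object) {
    cat(sprintf("PopulationSpec: %d vesicles, channels %s\n",
                object@nVesicles, paste(object@channels, collapse = ", ")))
    fr <- object@classFractions
    cat(paste(sprintf("  %-16s %5.1f%%", names(fr), 100 * fr),
              collapse = "\n"), "\n")
})

setMethod("show", "VesicleSet", function(object) {
    recs <- object@records
    cat(sprintf("VesicleSet: %d records from %d spots in %d channels (%s)\n",
                nrow(recs), nrow(object@spots), length(object@channels),
                paste(object@channels, collapse = ", ")))
    if (nrow(recs)) {
        tab <- table(recs$class)
        cat(paste(sprintf("  %-16s %d", names(tab), as.integer(tab)),
                  collapse = "\n"), "\n")
    }
})

setMethod("show", "PopulationProfile", function(object) {
    cat(sprintf("PopulationProfile '%s': %d records over %d fields\n",
                object@sampleId, object@totalRecords,
                nrow(object@perFieldCounts)))
    fr <- object@classFractions
    sd <- object@classFractionSd
    cat(paste(sprintf("  %-16s %5.1f%% +/- %4.1f%%",
                      names(fr), 100 * fr, 100 * sd), collapse = "\n"), "\n")
})

setMethod("show", "ProfileComparison", function(object) {
    cat(sprintf("ProfileComparison of %d observations\n",
                length(object@sampleIds)))
    if (!is.null(object@linkage))
        cat("  hierarchical clustering: complete tree available\n")
    if (nrow(object@embedding))
        cat(sprintf("  t-SNE embedding at perplexity %.0f\n",
                    object@perplexity))
})
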