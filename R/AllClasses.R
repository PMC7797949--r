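#' @import methods
NULL

#' Acquisition parameters for simulated (and real) imaging fields
#'
#' Describes the imaging geometry and camera model shared by the simulator
#' and the analysis: physical pixel size, field dimensions, the point spread
#' function width, the background and noise model of an EMCCD-style camera,
#' and the per-channel true coordinate transforms applied at render time.
#'
#' Coordinate convention used throughout the package: continuous image
#' coordinates with the origin at the image corner; the pixel stored at
#' matrix row r, column c spans x in [c-1, c] and y in [r-1, r], so its
#' centre is (c - 0.5, r - 0.5). x runs along columns, y along rows.
#'
#' @slot pixelSize physical size of one pixel in nm (default 100, so that
#'   the 3-pixel co-localization radius corresponds to ~300 nm).
#' @slot fieldShape integer vector (rows, cols) of the image in pixels.
#' @slot psfSigma PSF standard deviation in nm.
#' @slot backgroundLevel mean background in camera counts.
#' @slot readNoiseSd standard deviation of additive Gaussian read noise.
#' @slot photonScale camera counts per unit emitter brightness (integrated).
#' @slot channelTransforms named list of [ChannelTransform-class] objects,
#'   the true reference-frame -> raw-channel-frame mapping per channel.
#' @slot fieldArea standard analysis area per field in um^2 to which signal
#'   counts are normalized (default 2000).
#' @export
setClass("AcquisitionParams", representation(
    pixelSize = "numeric",
    fieldShape = "integer",
    psfSigma = "numeric",
    backgroundLevel = "numeric",
    readNoiseSd = "numeric",
    photonScale = "numeric",
    channelTransforms = "list",
    fieldArea = "numeric"
))

setValidity("AcquisitionParams", function(object) {
    msg <- character()
    if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
        object@pixelSize <= 0) msg <- c(msg, "pixelSize must be a positive number")
    if (length(object@fieldShape) != 2L || any(object@fieldShape < 16L))
        msg <- c(msg, "fieldShape must be two integers >= 16")
    if (length(object@psfSigma) != 1L || object@psfSigma <= 0)
        msg <- c(msg, "psfSigma must be positive")
    if (object@backgroundLevel < 0) msg <- c(msg, "backgroundLevel must be >= 0")
    if (object@readNoiseSd < 0) msg <- c(msg, "readNoiseSd must be >= 0")
    if (object@photonScale <= 0) msg <- c(msg, "photonScale must be positive")
    if (object@fieldArea <= 0) msg <- c(msg, "fieldArea must be positive")
    nm <- names(object@channelTransforms)
    if (length(object@channelTransforms)) {
        if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
            msg <- c(msg, "channelTransforms must be uniquely named")
        if (!all(vapply(object@channelTransforms, is, logical(1), "ChannelTransform")))
            msg <- c(msg, "channelTransforms entries must be ChannelTransform objects")
    }
    if (length(msg)) msg else TRUE
})

#' Mapping between a channel's coordinates and the reference frame
#'
#' A 2D linear map p' = A p + b, restricted to translation, similarity
#' (rotation + isotropic scale + shift) or full affine. Used in two roles:
#' the simulator's ground-truth chromatic distortion (reference -> raw) and
#' the estimated correction (raw -> reference) from fiducial beads.
#'
#' @slot model one of "translation", "similarity", "affine".
#' @slot A 2x2 linear part.
#' @slot b length-2 offset (pixels).
#' @slot rmsResidual root-mean-square residual of the fit in pixels (0 for
#'   constructed transforms).
#' @slot nControlPoints number of bead pairs used in the fit.
#' @export
setClass("ChannelTransform", representation(
    model = "character",
    A = "matrix",
    b = "numeric",
    rmsResidual = "numeric",
    nControlPoints = "integer"
))

setValidity("ChannelTransform", function(object) {
    msg <- character()
    if (!object@model %in% c("translation", "similarity", "affine"))
        msg <- c(msg, "model must be translation, similarity or affine")
    if (!all(dim(object@A) == c(2L, 2L))) msg <- c(msg, "A must be 2x2")
    if (length(object@b) != 2L) msg <- c(msg, "b must have length 2")
    if (abs(det(object@A)) < 1e-12) msg <- c(msg, "transform is not invertible")
    if (length(object@rmsResidual) != 1L || object@rmsResidual < 0)
        msg <- c(msg, "rmsResidual must be a single non-negative number")
    if (length(msg)) msg else TRUE
})

#' Vesicle population specification for the simulator
#'
#' Defines the latent marker-combination composition of a simulated sample:
#' the fraction of vesicles in each subpopulation class (a non-empty subset
#' of the declared channels), the number of vesicles, the per-channel
#' probability that a present marker actually emits (imperfect antibody
#' labeling), and the emitter brightness distribution (log-normal).
#'
#' @slot channels ordered channel (marker) names, e.g. c("CD9","CD63","CD81").
#' @slot classFractions named numeric; names are canonical class labels
#'   (channel names joined by the U+2219 dot in channel order), values sum to 1.
#' @slot nVesicles number of vesicles to draw.
#' @slot labelingEfficiency named per-channel probability in [0,1] that a
#'   present marker emits; default 1 for all channels.
#' @slot meanBrightness mean emitter brightness (arbitrary units; counts are
#'   brightness * photonScale).
#' @slot brightnessSdLog log-normal sdlog of brightness (0 = fixed).
#' @export
setClass("PopulationSpec", representation(
    channels = "character",
    classFractions = "numeric",
    nVesicles = "integer",
    labelingEfficiency = "numeric",
    meanBrightness = "numeric",
    brightnessSdLog = "numeric"
))

setValidity("PopulationSpec", function(object) {
    msg <- character()
    if (length(object@channels) < 1L || anyDuplicated(object@channels))
        msg <- c(msg, "channels must be non-empty and unique")
    fr <- object@classFractions
    if (is.null(names(fr)) || any(names(fr) == ""))
        msg <- c(msg, "classFractions must be named by class label")
    if (any(fr < 0)) msg <- c(msg, "classFractions must be >= 0")
    if (abs(sum(fr) - 1) > 1e-9)
        msg <- c(msg, "classFractions must sum to 1 (tolerance 1e-9)")
    for (cl in names(fr)) {
        members <- strsplit(cl, "\u2219", fixed = TRUE)[[1]]
        if (length(members) == 0L || !all(members %in% object@channels))
            msg <- c(msg, sprintf(
                "class '%s' is not a non-empty subset of the declared channels", cl))
    }
    le <- object@labelingEfficiency
    if (!all(object@channels %in% names(le)))
        msg <- c(msg, "labelingEfficiency must name every channel")
    if (any(le < 0 | le > 1)) msg <- c(msg, "labelingEfficiency must be in [0,1]")
    if (length(object@nVesicles) != 1L || object@nVesicles < 0L)
        msg <- c(msg, "nVesicles must be a single non-negative integer")
    if (object@meanBrightness <= 0) msg <- c(msg, "meanBrightness must be positive")
    if (object@brightnessSdLog < 0) msg <- c(msg, "brightnessSdLog must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Spot detection and fitting parameters
#'
#' @slot smoothingSigma Gaussian smoothing sigma (px) for candidate detection.
#' @slot thresholdK detection threshold in robust background SDs above the
#'   background median of the smoothed image.
#' @slot fitWindow half-width of the square fit window (px).
#' @slot minSnr minimum fitted-amplitude / background-SD ratio to keep a spot.
#' @slot sigmaBounds (min, max) admissible fitted PSF sigma in px.
#' @slot edgeMargin candidates closer than this to the border are discarded (px).
#' @slot mergeRadius candidates closer than this are merged to the brighter (px).
#' @export
setClass("DetectionParams", representation(
    smoothingSigma = "numeric",
    thresholdK = "numeric",
    fitWindow = "integer",
    minSnr = "numeric",
    sigmaBounds = "numeric",
    edgeMargin = "numeric",
    mergeRadius = "numeric"
))

setValidity("DetectionParams", function(object) {
    msg <- character()
    if (object@fitWindow < 2L) msg <- c(msg, "fitWindow must be >= 2")
    if (length(object@sigmaBounds) != 2L ||
        object@sigmaBounds[1] >= object@sigmaBounds[2] || object@sigmaBounds[1] <= 0)
        msg <- c(msg, "sigmaBounds must be (min, max) with 0 < min < max")
    if (object@smoothingSigma <= 0) msg <- c(msg, "smoothingSigma must be positive")
    if (object@mergeRadius < 0) msg <- c(msg, "mergeRadius must be >= 0")
    if (object@edgeMargin < 0) msg <- c(msg, "edgeMargin must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Co-localization parameters
#'
#' @slot thresholdPx co-localization radius in reference-frame pixels;
#'   default 3 px (~300 nm at 100 nm/px).
#' @slot matching "greedy" (mutual, ascending-distance greedy linking;
#'   default) or "optimal" (exact minimum total linked distance, small
#'   instances only).
#' @slot semantics "component" (default; linked components merge into one
#'   record, so chains can span up to twice the radius) or "clique" (all
#'   pairwise member distances must be within the radius).
#' @export
setClass("ColocalizationParams", representation(
    thresholdPx = "numeric",
    matching = "character",
    semantics = "character"
))

setValidity("ColocalizationParams", function(object) {
    msg <- character()
    if (length(object@thresholdPx) != 1L || object@thresholdPx <= 0)
        msg <- c(msg, "thresholdPx must be positive")
    if (!object@matching %in% c("greedy", "optimal"))
        msg <- c(msg, "matching must be 'greedy' or 'optimal'")
    if (!object@semantics %in% c("component", "clique"))
        msg <- c(msg, "semantics must be 'component' or 'clique'")
    if (length(msg)) msg else TRUE
})

#' A set of vesicle records from one field
#'
#' The result of cross-channel co-localization: every input spot belongs to
#' exactly one record; a record's labels are the channels contributing at
#' least one member spot.
#'
#' @slot records data.frame with one row per vesicle record: record_id,
#'   class (canonical label), n_labels, n_spots, centroid_x, centroid_y,
#'   max_pair_distance.
#' @slot spots data.frame of all member spots with their record_id.
#' @slot channels ordered channel names defining the class space.
#' @slot params the [ColocalizationParams-class] used.
#' @export
setClass("VesicleSet", representation(
    records = "data.frame",
    spots = "data.frame",
    channels = "character",
    params = "ColocalizationParams"
))

setValidity("VesicleSet", function(object) {
    msg <- character()
    need <- c("record_id", "class", "n_labels", "n_spots",
              "centroid_x", "centroid_y", "max_pair_distance")
    if (!all(need %in% names(object@records)))
        msg <- c(msg, "records is missing required columns")
    if (nrow(object@spots) &&
        !all(c("record_id", "channel", "x", "y") %in% names(object@spots)))
        msg <- c(msg, "spots is missing required columns")
    if (nrow(object@spots) &&
        !all(object@spots$record_id %in% object@records$record_id))
        msg <- c(msg, "every spot must belong to a record")
    if (length(msg)) msg else TRUE
})

#' Per-sample population profile
#'
#' Subpopulation fractions with per-field replicate structure: per-field
#' class counts, the mean fraction of each class across fields and its SD.
#'
#' @slot sampleId sample identifier.
#' @slot channels ordered channel names (K channels give 2^K - 1 classes).
#' @slot perFieldCounts integer matrix, fields x classes.
#' @slot classFractions named mean fraction per class (sums to 1).
#' @slot classFractionSd named SD of the per-field fractions.
#' @slot totalRecords total number of vesicle records across fields.
#' @export
setClass("PopulationProfile", representation(
    sampleId = "character",
    channels = "character",
    perFieldCounts = "matrix",
    classFractions = "numeric",
    classFractionSd = "numeric",
    totalRecords = "integer"
))

setValidity("PopulationProfile", function(object) {
    msg <- character()
    k <- length(object@channels)
    nclass <- 2L^k - 1L
    if (ncol(object@perFieldCounts) != nclass)
        msg <- c(msg, "perFieldCounts must have 2^K - 1 class columns")
    if (length(object@classFractions) != nclass ||
        length(object@classFractionSd) != nclass)
        msg <- c(msg, "fraction vectors must cover all 2^K - 1 classes")
    if (object@totalRecords > 0L &&
        abs(sum(object@classFractions) - 1) > 1e-9)
        msg <- c(msg, "classFractions must sum to 1 (tolerance 1e-9)")
    if (any(object@classFractionSd < 0)) msg <- c(msg, "SDs must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Result of comparing several population profiles
#'
#' @slot sampleIds identifiers of the compared observations.
#' @slot distanceMatrix symmetric Euclidean distance matrix between
#'   fraction vectors.
#' @slot linkage the agglomerative clustering tree (an hclust object), or
#'   NULL when only an embedding was computed.
#' @slot embedding n x 2 t-SNE coordinates (0-row matrix when absent).
#' @slot perplexity t-SNE perplexity used (NA when absent).
#' @export
setClass("ProfileComparison", representation(
    sampleIds = "character",
    distanceMatrix = "matrix",
    linkage = "ANY",
    embedding = "matrix",
    perplexity = "numeric"
))

setValidity("ProfileComparison", function(object) {
    msg <- character()
    d <- object@distanceMatrix
    if (nrow(d) != ncol(d)) msg <- c(msg, "distanceMatrix must be square")
    else {
        if (max(abs(d - t(d))) > 1e-9) msg <- c(msg, "distanceMatrix must be symmetric")
        if (any(abs(diag(d)) > 1e-9)) msg <- c(msg, "distanceMatrix diagonal must be 0")
        if (any(d < -1e-12)) msg <- c(msg, "distances must be non-negative")
    }
    if (length(msg)) msg else TRUE
})
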