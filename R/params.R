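# User-facing constructors for the parameter classes.

#' Construct acquisition parameters
#'
#' Defaults describe the imaging conditions assumed throughout: 100 nm
#' pixels (so the 3-pixel co-localization radius is ~300 nm), a 150 nm PSF
#' sigma (1.5 px; a ~100 nm vesicle imaged near the diffraction limit),
#' and an EMCCD-style noise model of Poisson shot noise on top of a flat
#' background plus Gaussian read noise.
#'
#' @param pixelSize nm per pixel.
#' @param fieldShape image shape in pixels, (rows, cols).
#' @param psfSigma PSF standard deviation in nm.
#' @param backgroundLevel mean background in counts.
#' @param readNoiseSd Gaussian read noise SD in counts.
#' @param photonScale counts per unit emitter brightness (integrated over
#'   the PSF).
#' @param channelTransforms named list of [ChannelTransform-class]; the true
#'   reference -> raw mapping per channel used by the simulator. Channels
#'   absent from the list get the identity.
#' @param fieldArea standard normalization area in um^2.
#' @return an [AcquisitionParams-class] object.
#' @export
#' @examples
#' p <- acquisitionParams(fieldShape = c(256L, 256L))
#' fieldAreaUm2(p)
acquisitionParams <- function(pixelSize = 100,
                              fieldShape = c(450L, 450L),
                              psfSigma = 150,
                              backgroundLevel = 100,
                              readNoiseSd = 10,
                              photonScale = 2000,
                              channelTransforms = list(),
                              fieldArea = 2000) {
    new("AcquisitionParams", pixelSize = pixelSize,
        fieldShape = as.integer(fieldShape), psfSigma = psfSigma,
        backgroundLevel = backgroundLevel, readNoiseSd = readNoiseSd,
        photonScale = photonScale, channelTransforms = channelTransforms,
        fieldArea = fieldArea)
}

#' Actual analysis area of a field in square micrometres
#'
#' @param params an [AcquisitionParams-class] object.
#' @return area in um^2 implied by fieldShape and pixelSize.
#' @export
fieldAreaUm2 <- function(params) {
    stopifnot(is(params, "AcquisitionParams"))
    prod(params@fieldShape) * (params@pixelSize / 1000)^2
}

# PSF sigma in pixel units.
psfSigmaPx <- function(params) params@psfSigma / params@pixelSize

#' Construct a vesicle population specification
#'
#' @param channels ordered channel (marker) names.
#' @param classFractions named fractions per subpopulation class; names use
#'   canonical labels (see [canonicalClass()]); must sum to 1.
#' @param nVesicles number of vesicles per field.
#' @param labelingEfficiency per-channel emission probability for a present
#'   marker; a single number is recycled to all channels.
#' @param meanBrightness mean emitter brightness.
#' @param brightnessSdLog log-normal sdlog of brightness around the mean.
#' @return a [PopulationSpec-class] object.
#' @export
#' @examples
#' populationSpec(c("CD9", "CD63", "CD81"),
#'                c("CD9∙CD63∙CD81" = 1), nVesicles = 50)
populationSpec <- function(channels, classFractions, nVesicles,
                           labelingEfficiency = 1,
                           meanBrightness = 1, brightnessSdLog = 0) {
    if (length(labelingEfficiency) == 1L && is.null(names(labelingEfficiency)))
        labelingEfficiency <- stats::setNames(
            rep(labelingEfficiency, length(channels)), channels)
    new("PopulationSpec", channels = channels,
        classFractions = classFractions, nVesicles = as.integer(nVesicles),
        labelingEfficiency = labelingEfficiency,
        meanBrightness = meanBrightness, brightnessSdLog = brightnessSdLog)
}

#' The HEK293 ultracentrifugation-EV tetraspanin profile
#'
#' Convenience population spec mirroring a typical HEK293 EV tetraspanin
#' composition: ~34% CD63 single-positive, ~34% CD9∙CD81 double-positive,
#' ~11% triple-positive, minor CD9 and CD81 singles, and negligible
#' CD9∙CD63 / CD63∙CD81 doubles.
#'
#' @param nVesicles vesicles per field.
#' @param ... passed to [populationSpec()].
#' @return a [PopulationSpec-class].
#' @export
hek293Spec <- function(nVesicles = 300, ...) {
    ch <- c("CD9", "CD63", "CD81")
    s <- classSep()
    fr <- c(0.09, 0.34, 0.08, 0.02, 0.34, 0.02, 0.11)
    names(fr) <- c("CD9", "CD63", "CD81",
                   paste("CD9", "CD63", sep = s),
                   paste("CD9", "CD81", sep = s),
                   paste("CD63", "CD81", sep = s),
                   paste("CD9", "CD63", "CD81", sep = s))
    populationSpec(ch, fr, nVesicles, ...)
}

#' Construct spot detection parameters
#'
#' Defaults follow common single-molecule practice: detect local maxima of
#' the lightly smoothed image exceeding the background median by 5 robust
#' SDs, fit in a 9x9 window, and keep fits with amplitude SNR >= 3 and a
#' plausible PSF width.
#'
#' @param smoothingSigma Gaussian pre-smoothing sigma in px.
#' @param thresholdK detection threshold in robust background SDs.
#' @param fitWindow half-width of the square fit window in px.
#' @param minSnr minimum amplitude / background-SD for a kept spot.
#' @param sigmaBounds admissible fitted sigma range (px).
#' @param edgeMargin border exclusion in px.
#' @param mergeRadius candidate merge radius in px.
#' @return a [DetectionParams-class] object.
#' @export
detectionParams <- function(smoothingSigma = 1, thresholdK = 5,
                            fitWindow = 4L, minSnr = 3,
                            sigmaBounds = c(0.5, 3), edgeMargin = 5,
                            mergeRadius = 2) {
    new("DetectionParams", smoothingSigma = smoothingSigma,
        thresholdK = thresholdK, fitWindow = as.integer(fitWindow),
        minSnr = minSnr, sigmaBounds = sigmaBounds,
        edgeMargin = edgeMargin, mergeRadius = mergeRadius)
}

#' Construct co-localization parameters
#'
#' @param thresholdPx co-localization radius in reference-frame pixels;
#'   the default 3 px corresponds to ~300 nm at 100 nm/px.
#' @param matching "greedy" (default) or "optimal".
#' @param semantics "component" (default) or "clique".
#' @return a [ColocalizationParams-class] object.
#' @export
colocalizationParams <- function(thresholdPx = 3, matching = "greedy",
                                 semantics = "component") {
    new("ColocalizationParams", thresholdPx = thresholdPx,
        matching = matching, semantics = semantics)
}
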