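# Synthetic single-vesicle field generator. The forward model: vesicles are
# point emitters (sub-resolution, so finite vesicle size is folded into the
# PSF sigma); each emitting label contributes a pixel-integrated isotropic
# 2D Gaussian at the channel-transformed true position; the camera adds a
# flat background, Poisson shot noise and Gaussian read noise.

#' Draw a ground-truth vesicle population
#'
#' Samples vesicle subpopulation classes multinomially from the spec's
#' class fractions, positions uniformly over the field interior (a 5-px
#' edge margin is excluded so fits are never truncated), per-vesicle
#' brightness log-normally, and per-channel emission flags from the
#' labeling efficiency. The RNG draw order (classes, x, y, brightness,
#' per-channel emission in channel order) is fixed, so results are
#' reproducible for a given seed.
#'
#' @param spec a [PopulationSpec-class].
#' @param params an [AcquisitionParams-class] (field bounds).
#' @param seed integer seed.
#' @return data.frame with one row per vesicle: id, class, x_nm, y_nm
#'   (reference frame), brightness, and one logical emit_<channel> column
#'   per declared channel. Channel order is stored in attribute "channels".
#' @export
generatePopulation <- function(spec, params, seed) {
    stopifnot(is(spec, "PopulationSpec"), is(params, "AcquisitionParams"))
    validObject(spec)
    chans <- spec@channels
    n <- spec@nVesicles
    margin <- 5                       # px, matches the localize edge filter
    lo <- margin * params@pixelSize
    hiX <- (params@fieldShape[2] - margin) * params@pixelSize
    hiY <- (params@fieldShape[1] - margin) * params@pixelSize
    if (hiX <= lo || hiY <= lo) stop("field too small for the edge margin")
    truth <- withSeed(seed, {
        cls <- if (n > 0L)
            sample(names(spec@classFractions), n, replace = TRUE,
                   prob = spec@classFractions)
        else character()
        x <- stats::runif(n, lo, hiX)
        y <- stats::runif(n, lo, hiY)
        br <- if (spec@brightnessSdLog > 0)
            stats::rlnorm(n,
                          log(spec@meanBrightness) - spec@brightnessSdLog^2 / 2,
                          spec@brightnessSdLog)
        else rep(spec@meanBrightness, n)
        df <- data.frame(id = seq_len(n), class = cls, x_nm = x, y_nm = y,
                         brightness = br, stringsAsFactors = FALSE)
        for (ch in chans) {
            present <- vapply(cls, function(cl)
                ch %in% classMembers(cl, chans), logical(1), USE.NAMES = FALSE)
            eff <- spec@labelingEfficiency[[ch]]
            emits <- present & (stats::runif(n) < eff)
            df[[paste0("emit_", ch)]] <- if (n > 0L) emits else logical()
        }
        df
    })
    attr(truth, "channels") <- chans
    truth
}

# Add flux of one pixel-integrated Gaussian to an image, in place.
# x0, y0 in continuous px coordinates, flux in counts.
addGaussianSpot <- function(img, x0, y0, sigma, flux) {
    nr <- nrow(img); nc <- ncol(img)
    w <- ceiling(6 * sigma)
    c0 <- max(1L, floor(x0) - w); c1 <- min(nc, ceiling(x0) + w)
    r0 <- max(1L, floor(y0) - w); r1 <- min(nr, ceiling(y0) + w)
    if (c0 > c1 || r0 > r1) return(img)
    cols <- c0:c1; rows <- r0:r1
    gx <- stats::pnorm(cols, x0, sigma) - stats::pnorm(cols - 1, x0, sigma)
    gy <- stats::pnorm(rows, y0, sigma) - stats::pnorm(rows - 1, y0, sigma)
    img[rows, cols] <- img[rows, cols] + flux * (gy %o% gx)
    img
}

#' Render one channel image of a vesicle field
#'
#' Every vesicle whose `emit_<channel>` flag is set contributes an
#' integrated flux of brightness * photonScale at its channel-transformed
#' position. With `noise = TRUE`, the noiseless expectation (spots +
#' background) is Poisson-sampled and Gaussian read noise is added.
#'
#' @param truth ground-truth table from [generatePopulation()].
#' @param params an [AcquisitionParams-class]; `channelTransforms[[channel]]`
#'   (identity when absent) maps reference px coordinates to this channel's
#'   raw frame.
#' @param channel channel name to render.
#' @param seed integer seed (noise only; ignored when `noise = FALSE`).
#' @param noise logical; disable for analytically exact images.
#' @return numeric matrix (rows = fieldShape[1]); attribute "rendered" is a
#'   logical vector flagging, per vesicle, whether it was emitting and its
#'   transformed centre fell inside the image (off-field emitters are
#'   clipped and flagged FALSE).
#' @export
renderField <- function(truth, params, channel, seed = 1, noise = TRUE) {
    stopifnot(is(params, "AcquisitionParams"))
    chans <- attr(truth, "channels")
    emitCol <- paste0("emit_", channel)
    if (!emitCol %in% names(truth))
        stop(sprintf("channel '%s' not present in ground truth", channel))
    tf <- params@channelTransforms[[channel]] %||% identityTransform()
    nr <- params@fieldShape[1]; nc <- params@fieldShape[2]
    img <- matrix(0, nr, nc)
    n <- nrow(truth)
    rendered <- logical(n)
    if (n > 0L) {
        pxy <- cbind(x = truth$x_nm / params@pixelSize,
                     y = truth$y_nm / params@pixelSize)
        txy <- transformPoints(tf, pxy)
        sig <- psfSigmaPx(params)
        for (i in seq_len(n)) {
            if (!truth[[emitCol]][i]) next
            x0 <- txy[i, 1]; y0 <- txy[i, 2]
            if (x0 < 0 || x0 > nc || y0 < 0 || y0 > nr) next   # clipped
            img <- addGaussianSpot(img, x0, y0, sig,
                                   truth$brightness[i] * params@photonScale)
            rendered[i] <- TRUE
        }
    }
    img <- img + params@backgroundLevel
    if (noise) {
        img <- withSeed(seed, {
            shot <- matrix(stats::rpois(length(img), lambda = img), nr, nc)
            shot + matrix(stats::rnorm(length(img), 0, params@readNoiseSd),
                          nr, nc)
        })
    }
    attr(img, "rendered") <- rendered
    img
}

#' Render all channels of a vesicle field
#'
#' @param truth ground-truth table from [generatePopulation()].
#' @param params an [AcquisitionParams-class].
#' @param channels channel names; default the truth's channel set.
#' @param seed integer master seed; each channel uses a derived sub-seed.
#' @param noise logical.
#' @return named list of images (see [renderField()]).
#' @export
renderFieldImages <- function(truth, params, channels = attr(truth, "channels"),
                              seed = 1, noise = TRUE) {
    out <- stats::setNames(vector("list", length(channels)), channels)
    for (ch in channels)
        out[[ch]] <- renderField(truth, params, ch,
                                 seed = deriveSeed(seed, paste0("render_", ch)),
                                 noise = noise)
    out
}

#' Render fiducial-bead calibration fields
#'
#' Beads are "full-range" fluorophores: every bead appears in every channel
#' at the same true reference position, rendered through that channel's
#' true transform at registration-grade brightness.
#'
#' @param nBeads number of beads (>= 3, the minimum for an affine fit).
#' @param params an [AcquisitionParams-class].
#' @param channels channel names to render.
#' @param seed integer seed (positions and noise).
#' @param brightness per-bead brightness (default 20: with the default
#'   photonScale, ~20x a typical vesicle signal).
#' @param noise logical.
#' @return list with elements `images` (named list of matrices) and
#'   `positions` (data.frame id, x, y in reference px coordinates).
#' @export
renderBeadFields <- function(nBeads, params, channels, seed = 1,
                             brightness = 20, noise = TRUE) {
    stopifnot(is(params, "AcquisitionParams"))
    if (nBeads < 3L)
        stop("nBeads must be >= 3 for downstream transform estimation")
    margin <- 10
    nr <- params@fieldShape[1]; nc <- params@fieldShape[2]
    pos <- withSeed(deriveSeed(seed, "bead_positions"), {
        data.frame(id = seq_len(nBeads),
                   x = stats::runif(nBeads, margin, nc - margin),
                   y = stats::runif(nBeads, margin, nr - margin))
    })
    sig <- psfSigmaPx(params)
    images <- stats::setNames(vector("list", length(channels)), channels)
    for (ch in channels) {
        tf <- params@channelTransforms[[ch]] %||% identityTransform()
        txy <- transformPoints(tf, pos)
        img <- matrix(0, nr, nc)
        for (i in seq_len(nBeads))
            img <- addGaussianSpot(img, txy[i, 1], txy[i, 2], sig,
                                   brightness * params@photonScale)
        img <- img + params@backgroundLevel
        if (noise) {
            img <- withSeed(deriveSeed(seed, paste0("bead_noise_", ch)), {
                matrix(stats::rpois(length(img), img), nr, nc) +
                    matrix(stats::rnorm(length(img), 0, params@readNoiseSd),
                           nr, nc)
            })
        }
        images[[ch]] <- img
    }
    list(images = images, positions = pos)
}

#' Simulate a complete multi-field sample
#'
#' Convenience wrapper: draws an independent ground-truth population per
#' field and renders every channel.
#'
#' @param spec a [PopulationSpec-class].
#' @param params an [AcquisitionParams-class].
#' @param nFields number of fields.
#' @param seed master seed; fields use derived sub-seeds.
#' @param noise logical.
#' @return list of fields, each a list with `truth` and `images`.
#' @export
simulateSample <- function(spec, params, nFields, seed = 1, noise = TRUE) {
    lapply(seq_len(nFields), function(f) {
        s <- deriveSeed(seed, paste0("field_", f))
        truth <- generatePopulation(spec, params, seed = s)
        images <- renderFieldImages(truth, params, seed = s, noise = noise)
        list(truth = truth, images = images)
    })
}
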