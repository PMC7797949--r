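# Fiducial-bead channel registration: construct, estimate, apply and invert
# inter-channel coordinate transforms so all channels share one frame.

#' Transform constructors
#'
#' Build [ChannelTransform-class] objects directly. `identityTransform()`
#' gives the no-op mapping; `translationTransform()` a pure pixel shift;
#' `similarityTransform()` rotation (degrees) + isotropic scale + shift;
#' `affineTransform()` an arbitrary invertible 2x2 linear part plus offset.
#'
#' @param dx,dy translation in pixels.
#' @param rotationDeg rotation angle in degrees (counter-clockwise).
#' @param scale isotropic scale factor.
#' @param A 2x2 linear part.
#' @param b length-2 offset.
#' @return a [ChannelTransform-class].
#' @export
identityTransform <- function() {
    new("ChannelTransform", model = "translation", A = diag(2), b = c(0, 0),
        rmsResidual = 0, nControlPoints = 0L)
}

#' @rdname identityTransform
#' @export
translationTransform <- function(dx, dy) {
    new("ChannelTransform", model = "translation", A = diag(2), b = c(dx, dy),
        rmsResidual = 0, nControlPoints = 0L)
}

#' @rdname identityTransform
#' @export
similarityTransform <- function(rotationDeg = 0, scale = 1, dx = 0, dy = 0) {
    th <- rotationDeg * pi / 180
    A <- scale * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    new("ChannelTransform", model = "similarity", A = A, b = c(dx, dy),
        rmsResidual = 0, nControlPoints = 0L)
}

#' @rdname identityTransform
#' @export
affineTransform <- function(A, b) {
    new("ChannelTransform", model = "affine", A = A, b = as.numeric(b),
        rmsResidual = 0, nControlPoints = 0L)
}

#' Apply a transform to raw coordinates
#'
#' @param transform a [ChannelTransform-class].
#' @param xy matrix or data.frame with columns x, y (pixels).
#' @return a two-column matrix of mapped coordinates.
#' @export
transformPoints <- function(transform, xy) {
    stopifnot(is(transform, "ChannelTransform"))
    p <- asXY(xy)
    out <- p %*% t(transform@A)
    out[, 1] <- out[, 1] + transform@b[1]
    out[, 2] <- out[, 2] + transform@b[2]
    colnames(out) <- c("x", "y")
    out
}

#' Invert a transform
#'
#' @param transform a [ChannelTransform-class].
#' @return the inverse [ChannelTransform-class].
#' @export
invertTransform <- function(transform) {
    Ai <- solve(transform@A)
    new("ChannelTransform", model = transform@model, A = Ai,
        b = as.numeric(-Ai %*% transform@b),
        rmsResidual = transform@rmsResidual,
        nControlPoints = transform@nControlPoints)
}

#' Match fiducial beads between two channels
#'
#' Pairs spots by mutual nearest neighbour within a radius: a pair (i, j)
#' is kept when j is the closest moving spot to reference spot i, i is the
#' closest reference spot to j, and their distance is at most `radius`.
#' Each spot is used at most once.
#'
#' @param refSpots,movingSpots spot data.frames (columns x, y) from the
#'   reference and moving channel bead images.
#' @param radius maximum pairing distance in px.
#' @return data.frame with columns ref (row index in refSpots), moving
#'   (row index in movingSpots) and dist.
#' @export
matchBeads <- function(refSpots, movingSpots, radius = 5) {
    pairs <- crossPairsWithin(refSpots, movingSpots, radius)
    if (nrow(pairs) == 0L)
        return(data.frame(ref = integer(), moving = integer(),
                          dist = numeric()))
    # nearest moving per ref and nearest ref per moving, within radius
    bestFor <- function(key, other, d) {
        o <- order(d)
        keep <- o[!duplicated(key[o])]
        stats::setNames(other[keep], key[keep])
    }
    nnOfRef <- bestFor(pairs$i, pairs$j, pairs$d)
    nnOfMov <- bestFor(pairs$j, pairs$i, pairs$d)
    mutual <- pairs[nnOfRef[as.character(pairs$i)] == pairs$j &
                    nnOfMov[as.character(pairs$j)] == pairs$i, , drop = FALSE]
    mutual <- mutual[order(mutual$i), , drop = FALSE]
    data.frame(ref = mutual$i, moving = mutual$j, dist = mutual$d)
}

#' Estimate a channel transform from matched control points
#'
#' Least-squares fit of the mapping moving -> reference. `translation` is
#' the mean displacement; `similarity` the closed-form Procrustes solution
#' (rotation + isotropic scale + shift); `affine` (default) an ordinary
#' linear least-squares solve of all 6 coefficients.
#'
#' @param refXY,movingXY matched coordinates (matrix or data.frame with
#'   columns x, y), row i of one corresponding to row i of the other.
#' @param model "translation", "similarity" or "affine".
#' @return a fitted [ChannelTransform-class] with `rmsResidual` and
#'   `nControlPoints` set.
#' @export
estimateTransform <- function(refXY, movingXY,
                              model = c("affine", "similarity", "translation")) {
    model <- match.arg(model)
    R <- asXY(refXY)
    M <- asXY(movingXY)
    n <- nrow(R)
    if (n != nrow(M)) stop("control point sets differ in length")
    minPts <- switch(model, translation = 1L, similarity = 2L, affine = 3L)
    if (n < minPts)
        stop(sprintf("registration error: %s needs >= %d control points",
                     model, minPts))
    if (model == "affine") {
        X <- cbind(M, 1)
        if (qr(X)$rank < 3L)
            stop("registration error: control points are collinear")
        beta <- qr.solve(X, R)        # 3x2: rows = (a_x, a_y, offset)
        A <- t(beta[1:2, , drop = FALSE])
        b <- as.numeric(beta[3, ])
    } else if (model == "similarity") {
        mR <- colMeans(R); mM <- colMeans(M)
        Rc <- sweep(R, 2, mR); Mc <- sweep(M, 2, mM)
        S <- t(Rc) %*% Mc             # cross-covariance (ref x moving)
        sv <- svd(S)
        D <- diag(c(1, sign(det(sv$u %*% t(sv$v)))))
        rot <- sv$u %*% D %*% t(sv$v)
        denom <- sum(Mc^2)
        if (denom < 1e-12) stop("registration error: degenerate geometry")
        s <- sum(diag(D) * sv$d) / denom
        A <- s * rot
        b <- as.numeric(mR - A %*% mM)
    } else {
        A <- diag(2)
        b <- colMeans(R) - colMeans(M)
    }
    A <- unname(A); b <- unname(b)
    dimnames(A) <- NULL
    pred <- M %*% t(A) + matrix(b, n, 2, byrow = TRUE)
    rms <- sqrt(mean(rowSums((R - pred)^2)))
    new("ChannelTransform", model = model, A = A, b = b,
        rmsResidual = rms, nControlPoints = as.integer(n))
}

#' Map a spot table into the reference frame
#'
#' Replaces each spot's centre with its transformed coordinates; all other
#' columns are unchanged.
#'
#' @param spots spot data.frame with columns x, y.
#' @param transform a [ChannelTransform-class] mapping these coordinates
#'   into the reference frame.
#' @return the spot data.frame with corrected x, y.
#' @export
applyTransform <- function(spots, transform) {
    stopifnot(is(transform, "ChannelTransform"))
    if (nrow(spots) == 0L) return(spots)
    xy <- transformPoints(transform, spots)
    spots$x <- xy[, "x"]
    spots$y <- xy[, "y"]
    spots
}

#' Estimate per-channel corrections from fiducial-bead images
#'
#' Localizes beads in every channel image, matches each non-reference
#' channel's beads to the reference channel by mutual nearest neighbour,
#' and fits the raw -> reference transform. The first channel is the
#' reference and gets the identity.
#'
#' @param beadImages named list of bead-field images (one per channel).
#' @param detection [DetectionParams-class] for bead localization; beads are
#'   bright, so defaults are fine.
#' @param model transform model (default "affine").
#' @param matchRadius mutual-NN pairing radius in px (generous: raw
#'   chromatic offsets are a few px).
#' @return named list of [ChannelTransform-class], one per channel.
#' @export
calibrateChannels <- function(beadImages, detection = detectionParams(),
                              model = "affine", matchRadius = 8) {
    chans <- names(beadImages)
    if (is.null(chans) || length(chans) < 1L)
        stop("beadImages must be a named list of images")
    ref <- chans[1]
    refSpots <- localizeSpots(beadImages[[ref]], detection, channel = ref)
    out <- stats::setNames(vector("list", length(chans)), chans)
    out[[ref]] <- identityTransform()
    for (ch in chans[-1]) {
        sp <- localizeSpots(beadImages[[ch]], detection, channel = ch)
        m <- matchBeads(refSpots, sp, radius = matchRadius)
        if (nrow(m) < 3L)
            stop(sprintf(
                "registration error: only %d bead pairs matched for channel %s",
                nrow(m), ch))
        out[[ch]] <- estimateTransform(refSpots[m$ref, c("x", "y")],
                                       sp[m$moving, c("x", "y")],
                                       model = model)
    }
    out
}
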