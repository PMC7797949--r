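# Spot detection and sub-pixel localization: local-maximum candidate
# detection on a smoothed image, then least-squares fitting of a
# pixel-integrated isotropic 2D Gaussian per candidate.

# Robust background statistics (median and MAD-based SD) of an image.
robustBackground <- function(image) {
    med <- stats::median(image)
    list(median = med, sd = stats::mad(image, center = med))
}

#' Detect spot candidates in a single-channel image
#'
#' Smooths the image with a Gaussian kernel, estimates background
#' statistics robustly (median, MAD), and keeps local maxima of the
#' smoothed image exceeding median + thresholdK * SD. Maxima within
#' `edgeMargin` of the border are discarded; maxima closer than
#' `mergeRadius` are merged to the brighter one.
#'
#' @param image 2D numeric matrix of camera counts.
#' @param params a [DetectionParams-class].
#' @return data.frame with columns col, row (1-based pixel indices), x, y
#'   (continuous pixel-centre coordinates) and value (smoothed intensity),
#'   ordered by descending value.
#' @export
detectCandidates <- function(image, params = detectionParams()) {
    if (!is.matrix(image) || !is.numeric(image))
        stop("image must be a 2D numeric matrix")
    if (!all(is.finite(image))) stop("image must contain finite values")
    sm <- EBImage::gblur(image, sigma = params@smoothingSigma)
    bg <- robustBackground(sm)
    # floor the robust SD so numerically flat (noise-free) backgrounds do
    # not promote FFT-filtering ripples to candidates
    sdFloor <- 1e-9 * diff(range(image)) + .Machine$double.eps
    thr <- bg$median + params@thresholdK * max(bg$sd, sdFloor)
    mx <- EBImage::dilate(sm, EBImage::makeBrush(3L, shape = "box"))
    isMax <- (sm >= mx) & (sm > thr)
    idx <- which(isMax, arr.ind = TRUE)
    if (nrow(idx) == 0L)
        return(data.frame(col = integer(), row = integer(),
                          x = numeric(), y = numeric(), value = numeric()))
    cand <- data.frame(col = unname(idx[, 2]), row = unname(idx[, 1]))
    cand$x <- cand$col - 0.5
    cand$y <- cand$row - 0.5
    cand$value <- sm[idx]
    m <- params@edgeMargin
    nr <- nrow(image); nc <- ncol(image)
    cand <- cand[cand$x >= m & cand$x <= nc - m &
                 cand$y >= m & cand$y <= nr - m, , drop = FALSE]
    cand <- cand[order(-cand$value, cand$x, cand$y), , drop = FALSE]
    # merge near-duplicates: keep the brighter of any pair within mergeRadius
    if (nrow(cand) > 1L && params@mergeRadius > 0) {
        keep <- rep(TRUE, nrow(cand))
        r2 <- params@mergeRadius^2
        for (i in seq_len(nrow(cand) - 1L)) {
            if (!keep[i]) next
            later <- (i + 1L):nrow(cand)
            d2 <- (cand$x[later] - cand$x[i])^2 + (cand$y[later] - cand$y[i])^2
            keep[later[d2 <= r2]] <- FALSE
        }
        cand <- cand[keep, , drop = FALSE]
    }
    rownames(cand) <- NULL
    cand
}

# One invalid-spot row (kept so downstream filters can drop it).
invalidSpot <- function(background = NA_real_) {
    data.frame(channel = NA_character_, x = NA_real_, y = NA_real_,
               intensity = NA_real_, amplitude = NA_real_, sigma = NA_real_,
               background = background, fit_rss = NA_real_, snr = 0,
               valid = FALSE)
}

#' Fit an integrated 2D Gaussian to one candidate spot
#'
#' Nonlinear least squares (Levenberg-Marquardt, [minpack.lm::nlsLM()]) of
#' the model background + flux * gx(x0, sigma) * gy(y0, sigma), where gx
#' and gy are the Gaussian integrals over each pixel, on a square window of
#' half-width `fitWindow` around the candidate. The integrated-Gaussian
#' model matches the pixelated image of a point emitter exactly, so
#' noiseless fits recover the true centre to machine precision. The fit is
#' initialized at moment-based estimates from the window.
#'
#' A fit is flagged invalid when it does not converge or the centre
#' migrates more than fitWindow/2 from the candidate pixel.
#'
#' @param image 2D numeric matrix.
#' @param candidate one-row data.frame (or list) with elements col, row
#'   (1-based pixel indices, as returned by [detectCandidates()]).
#' @param params a [DetectionParams-class].
#' @param backgroundSd robust background SD used for the spot's SNR
#'   (fitted peak amplitude / backgroundSd); estimated from the window
#'   border when NULL.
#' @return one-row spot data.frame: channel (NA at this stage), x, y
#'   (sub-pixel centre), intensity (integrated counts above background),
#'   amplitude (peak counts above background), sigma (px), background,
#'   fit_rss, snr, valid.
#' @export
fitSpot <- function(image, candidate, params = detectionParams(),
                    backgroundSd = NULL) {
    w <- params@fitWindow
    ccol <- candidate$col[1]; crow <- candidate$row[1]
    nr <- nrow(image); nc <- ncol(image)
    if (ccol - w < 1L || ccol + w > nc || crow - w < 1L || crow + w > nr)
        stop("fit window extends outside the image")
    cols <- (ccol - w):(ccol + w)
    rows <- (crow - w):(crow + w)
    win <- image[rows, cols]
    xc <- cols - 0.5; yc <- rows - 0.5           # pixel-centre coordinates
    border <- c(win[1, ], win[nrow(win), ], win[-c(1, nrow(win)), 1],
                win[-c(1, nrow(win)), ncol(win)])
    b0 <- stats::median(border)
    if (is.null(backgroundSd)) backgroundSd <- stats::mad(border)
    backgroundSd <- max(backgroundSd, .Machine$double.eps)
    pos <- pmax(win - b0, 0)
    tot <- sum(pos)
    if (tot <= 0) return(invalidSpot(b0))
    colMass <- colSums(pos); rowMass <- rowSums(pos)
    x0 <- sum(colMass * xc) / tot
    y0 <- sum(rowMass * yc) / tot
    varx <- sum(colMass * (xc - x0)^2) / tot
    vary <- sum(rowMass * (yc - y0)^2) / tot
    s0 <- sqrt(max((varx + vary) / 2, 0.04))
    s0 <- min(max(s0, params@sigmaBounds[1]), params@sigmaBounds[2])
    df <- data.frame(z = as.vector(win),
                     X = rep(xc, each = length(yc)),
                     Y = rep(yc, times = length(xc)))
    fit <- tryCatch(
        minpack.lm::nlsLM(
            z ~ b + flux *
                (pnorm(X + 0.5, x0, s) - pnorm(X - 0.5, x0, s)) *
                (pnorm(Y + 0.5, y0, s) - pnorm(Y - 0.5, y0, s)),
            data = df,
            start = list(b = b0, flux = tot, x0 = x0, y0 = y0, s = s0),
            lower = c(b = -Inf, flux = 0,
                      x0 = min(xc) - 1, y0 = min(yc) - 1, s = 0.05),
            upper = c(b = Inf, flux = Inf,
                      x0 = max(xc) + 1, y0 = max(yc) + 1, s = 4 * w),
            control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
    if (is.null(fit)) return(invalidSpot(b0))
    p <- as.list(stats::coef(fit))
    amp <- p$flux / (2 * pi * p$s^2)
    migration <- sqrt((p$x0 - (ccol - 0.5))^2 + (p$y0 - (crow - 0.5))^2)
    valid <- is.finite(p$x0) && is.finite(p$y0) && p$s > 0 &&
        migration <= w / 2 &&
        p$x0 >= 0 && p$x0 < nc && p$y0 >= 0 && p$y0 < nr
    data.frame(channel = NA_character_, x = p$x0, y = p$y0,
               intensity = p$flux, amplitude = amp, sigma = p$s,
               background = p$b,
               fit_rss = sum(stats::resid(fit)^2),
               snr = amp / backgroundSd, valid = valid)
}

#' Filter fitted spots on quality criteria
#'
#' Keeps spots that are valid fits with snr >= minSnr and sigma within
#' sigmaBounds, and returns them in a deterministic order (descending
#' intensity, ties broken by x then y).
#'
#' @param spots spot data.frame as produced by [fitSpot()].
#' @param params a [DetectionParams-class].
#' @return the filtered, re-ordered spot data.frame.
#' @export
filterSpots <- function(spots, params = detectionParams()) {
    if (nrow(spots) == 0L) return(spots)
    keep <- spots$valid &
        spots$snr >= params@minSnr &
        spots$sigma >= params@sigmaBounds[1] &
        spots$sigma <= params@sigmaBounds[2]
    keep[is.na(keep)] <- FALSE
    out <- spots[keep, , drop = FALSE]
    out <- out[order(-out$intensity, out$x, out$y), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Detect, fit and filter all spots in one image
#'
#' @param image 2D numeric matrix.
#' @param params a [DetectionParams-class].
#' @param channel channel name recorded on each spot.
#' @return filtered spot data.frame.
#' @export
localizeSpots <- function(image, params = detectionParams(),
                          channel = NA_character_) {
    cand <- detectCandidates(image, params)
    if (nrow(cand) == 0L) {
        out <- emptySpots()
        return(out)
    }
    bgSd <- robustBackground(image)$sd
    fits <- do.call(rbind, lapply(seq_len(nrow(cand)), function(i) {
        w <- params@fitWindow
        if (cand$col[i] - w < 1L || cand$col[i] + w > ncol(image) ||
            cand$row[i] - w < 1L || cand$row[i] + w > nrow(image))
            return(invalidSpot())
        fitSpot(image, cand[i, ], params, backgroundSd = bgSd)
    }))
    fits$channel <- channel
    filterSpots(fits, params)
}

#' Signal counts per field, normalized to the standard analysis area
#'
#' @param spots spot data.frame from one field (any number of channels).
#' @param params an [AcquisitionParams-class]; `fieldArea` is the standard
#'   area (um^2) to which counts are rescaled, the actual area follows from
#'   fieldShape and pixelSize.
#' @param channels channel names to report; defaults to those present.
#' @return data.frame with columns channel, n (raw count) and
#'   nPerStdArea (count rescaled to `fieldArea`).
#' @export
countPerField <- function(spots, params, channels = NULL) {
    stopifnot(is(params, "AcquisitionParams"))
    if (is.null(channels))
        channels <- unique(stats::na.omit(spots$channel))
    if (length(channels) == 0L) channels <- NA_character_
    actual <- fieldAreaUm2(params)
    n <- vapply(channels, function(ch)
        sum(!is.na(spots$channel) & spots$channel == ch), numeric(1))
    data.frame(channel = channels, n = as.numeric(n),
               nPerStdArea = as.numeric(n) * params@fieldArea / actual,
               row.names = NULL)
}
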