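# Shared fixtures: small acquisition geometries and population specs used
# across the suite. All data are generated in code at test time.

DOT <- "\u2219"
CH3 <- c("CD9", "CD63", "CD81")

tripleClass <- function(channels = CH3) paste(channels, collapse = DOT)

# Small field for fast unit tests (256 px = 25.6 um at 100 nm/px).
smallParams <- function(..., fieldShape = c(256L, 256L),
                        channelTransforms = list()) {
    acquisitionParams(fieldShape = fieldShape,
                      channelTransforms = channelTransforms, ...)
}

# A spec in which every vesicle carries all three markers (calibration
# particle analogue). brightness 1 with the default photonScale 2000 and
# background 100 / read noise 10 gives peak SNR ~ 10.
tripleSpec <- function(n, brightness = 1, channels = CH3) {
    populationSpec(channels,
                   stats::setNames(1, tripleClass(channels)),
                   nVesicles = n, meanBrightness = brightness)
}

# Typical HEK293-like tetraspanin composition (34% CD63, 34% CD9-CD81,
# 11% triple, remainder split over the minor classes).
hekFractions <- function() {
    classFractions(hek293Spec(1))
}

# Per-spot peak amplitude over background-noise SD for given brightness.
peakSnr <- function(params, brightness) {
    amp <- brightness * params@photonScale /
        (2 * pi * (params@psfSigma / params@pixelSize)^2)
    amp / sqrt(params@backgroundLevel + params@readNoiseSd^2)
}

# Minimal spot data.frame at given coordinates (handles length zero).
spotsAt <- function(x, y) {
    n <- length(x)
    data.frame(channel = rep(NA_character_, n), x = x, y = y,
               intensity = rep(1000, n), amplitude = rep(100, n),
               sigma = rep(1.5, n), background = rep(100, n),
               fit_rss = rep(0, n), snr = rep(10, n),
               valid = rep(TRUE, n))
}

# Match detected spots to true positions within a radius; returns the
# number of true positions recovered (for recall/precision checks).
matchToTruth <- function(spots, trueXY, radius = 1) {
    if (nrow(spots) == 0L || nrow(trueXY) == 0L) return(0L)
    used <- rep(FALSE, nrow(spots))
    hits <- 0L
    for (i in seq_len(nrow(trueXY))) {
        d <- sqrt((spots$x - trueXY$x[i])^2 + (spots$y - trueXY$y[i])^2)
        d[used] <- Inf
        j <- which.min(d)
        if (d[j] <= radius) {
            hits <- hits + 1L
            used[j] <- TRUE
        }
    }
    hits
}
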