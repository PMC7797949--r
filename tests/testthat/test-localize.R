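# Spot detection and sub-pixel Gaussian localization.

test_that("flat or invalid images yield no candidates", {
    expect_equal(nrow(detectCandidates(matrix(100, 64, 64))), 0)
    expect_error(detectCandidates(array(1, c(4, 4, 2))), "2D")
    expect_error(detectCandidates(matrix(c(1, NA, 1, 1), 2, 2)), "finite")
})

test_that("well-separated spots are detected within a pixel of truth", {
    params <- acquisitionParams(fieldShape = c(400L, 400L))   # 1600 um^2
    spec <- tripleSpec(100)                                   # 0.0625 /um^2
    truth <- generatePopulation(spec, params, seed = 21)
    img <- renderField(truth, params, "CD9", seed = 21)
    cand <- detectCandidates(img, detectionParams())
    expect_gte(nrow(cand), 95)
    expect_lte(nrow(cand), 100 + 2)
    trueXY <- data.frame(x = truth$x_nm / 100, y = truth$y_nm / 100)
    hits <- matchToTruth(cand, trueXY, radius = 1)
    expect_gte(hits, 95)
})

test_that("candidates closer than the merge radius collapse to one", {
    img <- matrix(100, 64, 64)
    img <- img + 150 * exp(-((col(img) - 30.2)^2 + (row(img) - 30)^2) / 4.5)
    img <- img + 140 * exp(-((col(img) - 31.2)^2 + (row(img) - 30)^2) / 4.5)
    cand <- detectCandidates(img, detectionParams(mergeRadius = 2))
    expect_equal(nrow(cand), 1)
})

test_that("noiseless fits recover the true sub-pixel centre", {
    params <- smallParams()
    spec <- tripleSpec(1)
    truth <- generatePopulation(spec, params, seed = 1)
    truth$x_nm <- 10.30 * 100; truth$y_nm <- 12.70 * 100
    img <- renderField(truth, params, "CD9", noise = FALSE)
    cand <- detectCandidates(img, detectionParams())
    fit <- fitSpot(img, cand[1, ], detectionParams())
    expect_true(fit$valid)
    expect_lt(abs(fit$x - 10.30), 0.02)
    expect_lt(abs(fit$y - 12.70), 0.02)
    # cross-check against a model-free centre-of-mass refinement
    com <- centroidLocalize(img)
    expect_lt(abs(fit$x - com["x"]), 0.05)
    expect_lt(abs(fit$y - com["y"]), 0.05)
    # integrated intensity and width match the generative model
    expect_equal(fit$intensity, params@photonScale, tolerance = 0.01)
    expect_equal(fit$sigma, 1.5, tolerance = 0.01)

    # symmetric spot at an exact pixel centre: recovered to numerical noise
    truth$x_nm <- 2050; truth$y_nm <- 3050          # centre of pixel (21, 31)
    img2 <- renderField(truth, params, "CD9", noise = FALSE)
    fit2 <- fitSpot(img2, data.frame(col = 21, row = 31), detectionParams())
    expect_lt(abs(fit2$x - 20.5), 1e-6)
    expect_lt(abs(fit2$y - 30.5), 1e-6)
})

test_that("localization error is bounded and shrinks with SNR", {
    params <- smallParams(fieldShape = c(32L, 32L))
    rmsAt <- function(brightness, n) {
        spec <- tripleSpec(1, brightness = brightness)
        errs <- vapply(seq_len(n), function(k) {
            truth <- generatePopulation(spec, params, seed = 1000 + k)
            img <- renderField(truth, params, "CD9", seed = 1000 + k)
            cand <- detectCandidates(img, detectionParams(edgeMargin = 4))
            if (nrow(cand) == 0L) return(NA_real_)
            fit <- fitSpot(img, cand[1, ], detectionParams())
            if (!fit$valid) return(NA_real_)
            (fit$x - truth$x_nm / 100)^2 + (fit$y - truth$y_nm / 100)^2
        }, numeric(1))
        sqrt(mean(errs, na.rm = TRUE))
    }
    rms10 <- rmsAt(1.0, 300)          # peak SNR ~10
    expect_lt(rms10, 0.15)
    rms5 <- rmsAt(0.5, 200)
    rms20 <- rmsAt(2.0, 200)
    expect_lt(rms20, rms5)
})

test_that("integer-pixel image shifts move fitted centres exactly", {
    params <- smallParams(fieldShape = c(48L, 48L))
    spec <- tripleSpec(1)
    truth <- generatePopulation(spec, params, seed = 5)
    truth$x_nm <- 2030; truth$y_nm <- 2270
    img <- renderField(truth, params, "CD9", noise = FALSE)
    fit <- fitSpot(img, data.frame(col = 21, row = 23), detectionParams())
    shifted <- matrix(params@backgroundLevel, 48, 48)
    shifted[(1 + 3):48, (1 + 2):48] <- img[1:(48 - 3), 1:(48 - 2)]
    fitS <- fitSpot(shifted, data.frame(col = 23, row = 26),
                    detectionParams())
    expect_equal(fitS$x - fit$x, 2, tolerance = 1e-9)
    expect_equal(fitS$y - fit$y, 3, tolerance = 1e-9)
})

test_that("quality filtering drops bad fits and dim spots", {
    sp <- rbind(spotsAt(10, 10), spotsAt(20, 20), spotsAt(30, 30))
    sp$sigma[2] <- 10                      # outside sigmaBounds (0.5, 3)
    sp$snr[3] <- 1                         # below minSnr
    out <- filterSpots(sp, detectionParams(minSnr = 3))
    expect_equal(nrow(out), 1)
    expect_equal(out$x, 10)

    # simulated two-brightness-class field: the dim class is excluded by a
    # high SNR cut, within binomial error of the bright-class count
    params <- acquisitionParams(fieldShape = c(400L, 400L))
    bright <- generatePopulation(tripleSpec(80, brightness = 1.2),
                                 params, seed = 31)
    dim <- generatePopulation(tripleSpec(20, brightness = 0.35),
                              params, seed = 32)
    dim$id <- dim$id + 80
    both <- rbind(bright, dim)
    attr(both, "channels") <- CH3
    img <- renderField(both, params, "CD9", seed = 33)
    kept <- localizeSpots(img, detectionParams(minSnr = 8), "CD9")
    expect_gte(nrow(kept), 80 - 3 * sqrt(80 * 0.05))
    expect_lte(nrow(kept), 86)
})

test_that("field counts rescale linearly to the standard area", {
    # 250 x 400 px at 100 nm/px = 1000 um^2, half the standard 2000 um^2
    params <- acquisitionParams(fieldShape = c(250L, 400L))
    expect_equal(fieldAreaUm2(params), 1000)
    sp <- spotsAt(runif(100, 0, 250), runif(100, 0, 250))
    sp$channel <- "CD9"
    cnt <- countPerField(sp, params)
    expect_equal(cnt$n, 100)
    expect_equal(cnt$nPerStdArea, 200)
    empty <- countPerField(emptySpots <- sp[0, ], params, channels = CH3)
    expect_true(all(empty$n == 0))
})
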