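# Ground-truth generator and forward imaging model.

test_that("population draw respects degenerate and empty specs", {
    params <- smallParams()
    spec <- tripleSpec(50)
    truth <- generatePopulation(spec, params, seed = 1)
    expect_equal(nrow(truth), 50)
    expect_true(all(truth$class == tripleClass()))
    expect_true(all(truth$emit_CD9 & truth$emit_CD63 & truth$emit_CD81))
    # positions respect the edge margin (5 px) in nm units
    expect_true(all(truth$x_nm >= 500 & truth$x_nm <= (256 - 5) * 100))

    empty <- generatePopulation(tripleSpec(0), params, seed = 1)
    expect_equal(nrow(empty), 0)
})

test_that("invalid population specs are rejected", {
    bad <- stats::setNames(c(0.5, 0.4), c("CD9", "CD63"))   # sums to 0.9
    expect_error(populationSpec(CH3, bad, 10), "sum to 1")
    unknown <- stats::setNames(1, "CD7")
    expect_error(populationSpec(CH3, unknown, 10), "subset")
    expect_error(populationSpec(CH3, stats::setNames(1, "CD9"), 10,
                                labelingEfficiency = 1.2), "0,1")
})

test_that("class frequencies follow the multinomial model", {
    params <- smallParams()
    spec <- hek293Spec(10000)
    truth <- generatePopulation(spec, params, seed = 42)
    fr <- classFractions(spec)
    counts <- table(factor(truth$class, levels = names(fr)))
    # every class within 3 multinomial SDs of its expectation
    expected <- 10000 * fr
    sds <- sqrt(10000 * fr * (1 - fr))
    expect_true(all(abs(counts - expected) <= 3 * sds))
    # goodness of fit at larger n: chi-square not rejected at alpha = 0.01
    big <- generatePopulation(hek293Spec(100000), params, seed = 7)
    tab <- table(factor(big$class, levels = names(fr)))
    gof <- suppressWarnings(stats::chisq.test(tab, p = fr))
    expect_gt(gof$p.value, 0.01)
})

test_that("rendering conserves photons and is deterministic", {
    params <- smallParams()
    spec <- tripleSpec(40)
    truth <- generatePopulation(spec, params, seed = 3)

    # empty field, noise off: constant background
    img0 <- renderField(truth[0, ], params, "CD9", noise = FALSE)
    expect_true(all(img0 == params@backgroundLevel))

    img <- renderField(truth, params, "CD9", noise = FALSE)
    rendered <- attr(img, "rendered")
    expected <- sum(truth$brightness[rendered]) * params@photonScale +
        params@backgroundLevel * length(img)
    expect_equal(sum(img), expected, tolerance = 1e-6)

    # same seed -> bit-identical noisy images; different seed differs
    a <- renderField(truth, params, "CD9", seed = 11)
    b <- renderField(truth, params, "CD9", seed = 11)
    c <- renderField(truth, params, "CD9", seed = 12)
    expect_identical(a, b)
    expect_false(identical(a, c))
})

test_that("a single emitter lands on the correct pixel with the right flux", {
    params <- smallParams()
    spec <- tripleSpec(1)
    truth <- generatePopulation(spec, params, seed = 1)
    truth$x_nm <- 1050; truth$y_nm <- 1050        # centre of pixel (11, 11)
    img <- renderField(truth, params, "CD9", noise = FALSE)
    peak <- which(img == max(img), arr.ind = TRUE)
    expect_equal(unname(peak[1, ]), c(11, 11))
    flux <- sum(img - params@backgroundLevel)
    expect_equal(flux, truth$brightness[1] * params@photonScale,
                 tolerance = 0.01)
})

test_that("bead fields share true positions across channels", {
    # identity transforms, noise off: argmax sets coincide pixel-for-pixel
    params <- smallParams()
    beads <- renderBeadFields(5, params, CH3, seed = 2, noise = FALSE)
    peaks <- lapply(beads$images, function(im)
        which(im > params@backgroundLevel + 1))
    expect_identical(peaks$CD9, peaks$CD63)
    expect_identical(peaks$CD9, peaks$CD81)

    # a pure translation on one channel is visible in the bead centroids
    shift <- translationTransform(2.5, -1.25)
    params2 <- smallParams(channelTransforms = list(CD63 = shift))
    b2 <- renderBeadFields(8, params2, c("CD9", "CD63"), seed = 4)
    s1 <- localizeSpots(b2$images$CD9, detectionParams(), "CD9")
    s2 <- localizeSpots(b2$images$CD63, detectionParams(), "CD63")
    m <- matchBeads(s1, s2, radius = 5)
    expect_equal(nrow(m), 8)
    dx <- mean(s2$x[m$moving] - s1$x[m$ref])
    dy <- mean(s2$y[m$moving] - s1$y[m$ref])
    expect_equal(dx, 2.5, tolerance = 0.05)
    expect_equal(dy, -1.25, tolerance = 0.05)

    expect_error(renderBeadFields(2, params, CH3), ">= 3")
})

test_that("three noiseless beads identify an affine distortion exactly", {
    tf <- similarityTransform(rotationDeg = 0.5, scale = 1.002,
                              dx = 1.0, dy = -0.7)
    params <- smallParams(channelTransforms = list(CD63 = tf))
    beads <- renderBeadFields(3, params, c("CD9", "CD63"), seed = 9,
                              noise = FALSE)
    s1 <- localizeSpots(beads$images$CD9, detectionParams(), "CD9")
    s2 <- localizeSpots(beads$images$CD63, detectionParams(), "CD63")
    m <- matchBeads(s1, s2, radius = 8)
    expect_equal(nrow(m), 3)
    est <- estimateTransform(s2[m$moving, c("x", "y")],
                             s1[m$ref, c("x", "y")], model = "affine")
    expect_equal(est@A, tf@A, tolerance = 1e-5)
    expect_equal(est@b, tf@b, tolerance = 1e-3)
    expect_lt(est@rmsResidual, 1e-5)
})
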