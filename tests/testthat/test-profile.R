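# Population profiles, overlap summaries and comparative statistics.

recordsOf <- function(classes) data.frame(class = classes)

test_that("profile fractions and replicate SDs follow the field counts", {
    f1 <- recordsOf(c("CD63", "CD63", tripleClass()))
    prof <- buildProfile(list(f1), "s1", channels = CH3)
    fr <- classFractions(prof)
    expect_equal(sum(fr), 1, tolerance = 1e-9)
    expect_equal(unname(fr["CD63"]), 2 / 3)
    expect_equal(unname(fr[tripleClass()]), 1 / 3)
    expect_equal(unname(fr["CD9"]), 0)
    expect_length(fr, 7)

    prof2 <- buildProfile(list(f1, f1), "s1", channels = CH3)
    expect_true(all(classFractionSd(prof2) == 0))

    expect_warning(
        prof3 <- buildProfile(list(f1, recordsOf(character())), "s1",
                              channels = CH3),
        "zero records")
    expect_equal(nrow(perFieldCounts(prof3)), 1)
})

test_that("venn overlap counts add up class-by-class", {
    cls <- c(rep(paste0("CD9", DOT, "CD81"), 34), rep("CD63", 34),
             rep(tripleClass(), 11), rep("CD9", 9), rep("CD81", 8),
             rep(paste0("CD9", DOT, "CD63"), 2),
             rep(paste0("CD63", DOT, "CD81"), 2))
    prof <- buildProfile(list(recordsOf(cls)), "hek", channels = CH3)
    v <- vennCounts(prof)
    expect_equal(unname(v$markerTotals["CD9"]), 56)
    expect_equal(unname(v$markerTotals["CD81"]), 55)
    expect_equal(unname(v$markerTotals["CD63"]), 49)
    expect_equal(unname(v$overlaps[paste0("CD9", DOT, "CD81")]), 45)

    # a single-class profile has the full total on one marker, no overlaps
    solo <- buildProfile(list(recordsOf(rep("CD9", 12))), "s", channels = CH3)
    vs <- vennCounts(solo)
    expect_equal(unname(vs$markerTotals), c(12, 0, 0))
    expect_true(all(vs$overlaps == 0))
})

test_that("nested marker hierarchies produce nested venn overlaps", {
    # AV-positive implies DiI-positive implies CTB-positive
    chans <- c("AV", "DiI", "CTB")
    s <- DOT
    cls <- c(rep(paste("AV", "DiI", "CTB", sep = s), 10),
             rep(paste("DiI", "CTB", sep = s), 20),
             rep("CTB", 30))
    prof <- buildProfile(list(data.frame(class = cls)), "lipid",
                         channels = chans)
    v <- vennCounts(prof)
    expect_equal(unname(v$overlaps[paste("AV", "DiI", sep = s)]),
                 unname(v$markerTotals["AV"]))
    expect_equal(unname(v$overlaps[paste("DiI", "CTB", sep = s)]),
                 unname(v$markerTotals["DiI"]))
})

test_that("the two-sample t-test matches the closed form", {
    same <- compareGroups(c(0.2, 0.2, 0.2), c(0.2, 0.2, 0.2))
    expect_equal(same$statistic, 0)
    expect_equal(same$p, 1)
    expect_equal(same$stars, "")

    set.seed(101)
    sep <- compareGroups(c(0.1, 0.1, 0.1) + rnorm(3, 0, 1e-4),
                         c(0.9, 0.9, 0.9) + rnorm(3, 0, 1e-4))
    expect_lt(sep$p, 0.01)
    expect_equal(sep$stars, "**")

    # worked example vs the textbook pooled-variance formula
    a <- c(1.1, 2.0, 2.9, 1.8)
    b <- c(3.0, 4.1, 4.9, 3.6, 4.4)
    sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
        (length(a) + length(b) - 2)
    tHand <- (mean(a) - mean(b)) /
        sqrt(sp2 * (1 / length(a) + 1 / length(b)))
    pHand <- 2 * pt(-abs(tHand), df = length(a) + length(b) - 2)
    got <- compareGroups(a, b)
    expect_equal(round(got$statistic, 4), round(tHand, 4))
    expect_equal(round(got$p, 4), round(pHand, 4))
    expect_equal(got$df, 7)
})

test_that("linear correlation reports slope, R2 and slope test", {
    x <- c(1, 2, 3, 4, 5)
    # an exactly collinear input makes summary.lm warn; that is expected here
    perfect <- suppressWarnings(linearCorrelation(x, 2 * x))
    expect_equal(perfect$slope, 2)
    expect_equal(perfect$r.squared, 1)
    expect_error(linearCorrelation(rep(1, 5), x), "zero variance")
    expect_error(linearCorrelation(1:2, 1:2), "3 points")

    set.seed(102)
    y <- x + rnorm(5, 0, 0.1)
    got <- linearCorrelation(x, y)
    expect_equal(got$r.squared, cor(x, y)^2, tolerance = 1e-12)
})

test_that("profiles cluster by Euclidean distance deterministically", {
    mk <- function(id, fracs) {
        classes <- allClasses(CH3)
        cls <- unlist(mapply(rep, classes, fracs, SIMPLIFY = FALSE))
        buildProfile(list(data.frame(class = cls)), id, channels = CH3)
    }
    p1 <- mk("a", c(100, 0, 0, 0, 0, 0, 0))
    p2 <- mk("b", c(0, 100, 0, 0, 0, 0, 0))
    p3 <- mk("c", c(100, 0, 0, 0, 0, 0, 0))
    cmp <- distanceCluster(list(p1, p2, p3))
    d <- cmp@distanceMatrix
    expect_equal(d["a", "c"], 0)
    expect_equal(d["a", "b"], sqrt(2))
    # identical profiles merge first
    expect_equal(sort(cmp@linkage$merge[1, ]), c(-3, -1))
    # input order does not change the distance set
    cmp2 <- distanceCluster(list(p2, p3, p1))
    expect_equal(sort(as.vector(cmp2@distanceMatrix)),
                 sort(as.vector(d)))
    expect_error(distanceCluster(list(p1)), "at least 2")
})

test_that("t-SNE embeddings are deterministic and separate distinct specs", {
    set.seed(103)
    grpA <- matrix(rep(c(0.8, 0.1, 0.1, 0, 0, 0, 0), each = 9), 9) +
        matrix(runif(63, 0, 0.02), 9)
    grpB <- matrix(rep(c(0, 0, 0.1, 0.1, 0.8, 0, 0), each = 9), 9) +
        matrix(runif(63, 0, 0.02), 9)
    obs <- rbind(grpA, grpB)
    e1 <- embedTsne(obs, perplexity = 4, seed = 11)
    e2 <- embedTsne(obs, perplexity = 4, seed = 11)
    expect_identical(e1, e2)
    labels <- rep(c(1, 2), each = 9)
    intra <- mean(dist(e1[labels == 1, ])) + mean(dist(e1[labels == 2, ]))
    inter <- mean(as.matrix(dist(e1))[labels == 1, labels == 2])
    expect_gt(inter, intra / 2)

    ident <- matrix(0.5, 8, 7)
    deg <- embedTsne(ident, perplexity = 2)
    expect_true(attr(deg, "degenerate"))
    expect_error(embedTsne(obs, perplexity = 20), "perplexity")

    sweep <- perplexitySweep(obs, c(2, 4), seed = 3)
    expect_equal(nrow(sweep), 2)
    expect_true(all(is.finite(sweep$kl)))
})
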