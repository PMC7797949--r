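# Population profiling: per-sample subpopulation fractions with per-field
# replicate structure, marker overlap summaries, group statistics,
# correlation, Euclidean-distance clustering and t-SNE embedding.

#' Build a population profile from per-field vesicle records
#'
#' Computes, for every field, the fraction of vesicle records in each of
#' the 2^K - 1 subpopulation classes, then summarises mean and SD across
#' fields. Fields with zero records are excluded with a warning.
#'
#' @param recordsByField list (one element per field) of
#'   [VesicleSet-class] objects or record data.frames with a `class` column.
#' @param sampleId sample identifier.
#' @param channels ordered channel names; taken from the first VesicleSet
#'   when NULL.
#' @return a [PopulationProfile-class].
#' @export
buildProfile <- function(recordsByField, sampleId, channels = NULL) {
    if (length(recordsByField) < 1L) stop("at least one field is required")
    recs <- lapply(recordsByField, function(f)
        if (is(f, "VesicleSet")) records(f) else f)
    if (is.null(channels)) {
        vs <- Filter(function(f) is(f, "VesicleSet"), recordsByField)
        if (!length(vs))
            stop("channels must be given when fields are plain data.frames")
        channels <- channelNames(vs[[1]])
    }
    classes <- allClasses(channels)
    nrec <- vapply(recs, nrow, integer(1))
    if (any(nrec == 0L)) {
        warning(sprintf("%d field(s) with zero records excluded",
                        sum(nrec == 0L)))
        recs <- recs[nrec > 0L]
    }
    if (!length(recs)) stop("no fields with records")
    counts <- t(vapply(recs, function(r) {
        bad <- setdiff(unique(r$class), classes)
        if (length(bad))
            stop(sprintf("unknown class label(s): %s",
                         paste(bad, collapse = ", ")))
        tab <- table(factor(r$class, levels = classes))
        as.integer(tab)
    }, integer(length(classes))))
    colnames(counts) <- classes
    rownames(counts) <- names(recs) %||% paste0("field", seq_len(nrow(counts)))
    fr <- counts / rowSums(counts)
    means <- colMeans(fr)
    sds <- if (nrow(fr) > 1L) apply(fr, 2, stats::sd) else
        stats::setNames(rep(0, length(classes)), classes)
    new("PopulationProfile", sampleId = as.character(sampleId),
        channels = channels, perFieldCounts = counts,
        classFractions = means, classFractionSd = sds,
        totalRecords = sum(counts))
}

#' Marker overlap (Venn) counts of a profile
#'
#' Aggregates class counts into per-marker totals and overlap counts:
#' for each marker the number of records positive for it, and for every
#' marker pair (and higher combination) the number of records positive for
#' all of them, i.e. the Venn-diagram region totals.
#'
#' @param profile a [PopulationProfile-class] (or a named numeric vector of
#'   class counts with a `channels` attribute).
#' @return list with `markerTotals` (named numeric, one per channel) and
#'   `overlaps` (named numeric over combinations of >= 2 markers, named by
#'   canonical class label).
#' @export
vennCounts <- function(profile) {
    if (is(profile, "PopulationProfile")) {
        channels <- profile@channels
        counts <- colSums(profile@perFieldCounts)
    } else {
        channels <- attr(profile, "channels")
        counts <- profile
        if (is.null(channels)) stop("counts need a 'channels' attribute")
    }
    classes <- names(counts)
    containing <- function(markers) {
        has <- vapply(classes, function(cl)
            all(markers %in% classMembers(cl, channels)), logical(1))
        sum(counts[has])
    }
    totals <- vapply(channels, function(ch) containing(ch), numeric(1))
    combos <- allClasses(channels)
    combos <- combos[vapply(combos, function(cl)
        length(classMembers(cl, channels)) >= 2L, logical(1))]
    overlaps <- vapply(combos, function(cl)
        containing(classMembers(cl, channels)), numeric(1))
    list(markerTotals = totals, overlaps = overlaps)
}

#' Two-sample comparison of per-field fractions
#'
#' Classical two-tailed unpaired Student's t-test (equal variances), with
#' significance flags at 0.05 (*) and 0.01 (**). When both groups have zero
#' variance and equal means the test is degenerate and p = 1 by convention.
#'
#' @param a,b numeric vectors of per-field (replicate) values, >= 2 each.
#' @return list with statistic, df, p, significant05, significant01, stars.
#' @export
compareGroups <- function(a, b) {
    if (length(a) < 2L || length(b) < 2L)
        stop("both groups need at least 2 values")
    if (stats::var(a) == 0 && stats::var(b) == 0) {
        if (mean(a) == mean(b)) {
            t <- 0; p <- 1
        } else {
            t <- sign(mean(a) - mean(b)) * Inf; p <- 0
        }
        df <- length(a) + length(b) - 2L
    } else {
        tt <- stats::t.test(a, b, var.equal = TRUE,
                            alternative = "two.sided")
        t <- unname(tt$statistic); p <- tt$p.value
        df <- unname(tt$parameter)
    }
    list(statistic = t, df = df, p = p,
         significant05 = p < 0.05, significant01 = p < 0.01,
         stars = if (p < 0.01) "**" else if (p < 0.05) "*" else "")
}

#' Ordinary least-squares correlation between two sample-level quantities
#'
#' @param x,y numeric vectors (>= 3 points); x must vary.
#' @return list with slope, intercept, r.squared, p (two-tailed test of the
#'   slope).
#' @export
linearCorrelation <- function(x, y) {
    if (length(x) != length(y)) stop("x and y must have equal length")
    if (length(x) < 3L) stop("at least 3 points are required")
    if (stats::var(x) == 0) stop("x has zero variance")
    fit <- stats::lm(y ~ x)
    sm <- summary(fit)
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r.squared = sm$r.squared,
         p = unname(sm$coefficients[2, 4]))
}

# Mean-fraction matrix (samples x classes) from a list of profiles, with a
# shared class space.
profileFractionMatrix <- function(profiles) {
    stopifnot(length(profiles) >= 1L)
    classes <- names(profiles[[1]]@classFractions)
    for (p in profiles)
        if (!identical(names(p@classFractions), classes))
            stop("profiles have mismatched class spaces")
    m <- t(vapply(profiles, function(p) p@classFractions,
                  numeric(length(classes))))
    rownames(m) <- vapply(profiles, function(p) p@sampleId, character(1))
    m
}

#' Euclidean-distance hierarchical clustering of population profiles
#'
#' Pairwise Euclidean distances between the samples' mean class-fraction
#' vectors, clustered agglomeratively (complete linkage by default, as in
#' standard clustered-heatmap displays).
#'
#' @param profiles list of [PopulationProfile-class] objects (>= 2) sharing
#'   one class space.
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @return a [ProfileComparison-class] with the distance matrix and tree.
#' @export
distanceCluster <- function(profiles, linkage = "complete") {
    if (length(profiles) < 2L) stop("at least 2 profiles are required")
    m <- profileFractionMatrix(profiles)
    d <- stats::dist(m, method = "euclidean")
    hc <- stats::hclust(d, method = linkage)
    new("ProfileComparison", sampleIds = rownames(m),
        distanceMatrix = as.matrix(d), linkage = hc,
        embedding = matrix(numeric(), 0, 2), perplexity = NA_real_)
}

#' t-SNE embedding of population observations
#'
#' Embeds per-field (or per-replicate) class-fraction vectors in 2D with
#' exact t-SNE (theta = 0), on the raw fractions without standardization.
#' Default perplexity 16. Degenerate input (all observations identical) is
#' flagged via the "degenerate" attribute rather than raising an error.
#'
#' @param observations numeric matrix, observations x classes.
#' @param perplexity t-SNE perplexity; must satisfy
#'   perplexity < n_observations, and 3 * perplexity < n - 1 for the
#'   underlying implementation.
#' @param seed integer seed; the same input and seed give identical
#'   coordinates.
#' @param max_iter gradient-descent iterations.
#' @return n x 2 coordinate matrix with attributes "kl" (final KL
#'   divergence) and "degenerate".
#' @export
embedTsne <- function(observations, perplexity = 16, seed = 1,
                      max_iter = 1000) {
    m <- as.matrix(observations)
    n <- nrow(m)
    if (perplexity >= n)
        stop("perplexity must be smaller than the number of observations")
    if (3 * perplexity >= n - 1)
        stop("perplexity too large: need 3 * perplexity < n - 1")
    if (max(stats::dist(m)) < 1e-12) {
        out <- matrix(0, n, 2)
        attr(out, "kl") <- 0
        attr(out, "degenerate") <- TRUE
        return(out)
    }
    res <- withSeed(seed, Rtsne::Rtsne(m, dims = 2, perplexity = perplexity,
                                       theta = 0, pca = FALSE,
                                       check_duplicates = FALSE,
                                       max_iter = max_iter))
    out <- res$Y
    attr(out, "kl") <- utils::tail(res$itercosts, 1)
    attr(out, "degenerate") <- FALSE
    out
}

#' Sweep t-SNE perplexities
#'
#' Runs [embedTsne()] at several perplexities and reports the final KL
#' divergence per value, so the embedding that best separates the clusters
#' at low error can be chosen.
#'
#' @param observations numeric matrix, observations x classes.
#' @param perplexities numeric vector of perplexity values.
#' @param seed integer seed shared by all runs.
#' @return data.frame with columns perplexity and kl; the embeddings are
#'   attached as the "embeddings" attribute (a named list).
#' @export
perplexitySweep <- function(observations, perplexities, seed = 1) {
    embeds <- lapply(perplexities, function(p)
        embedTsne(observations, perplexity = p, seed = seed))
    kl <- vapply(embeds, function(e) as.numeric(attr(e, "kl")), numeric(1))
    out <- data.frame(perplexity = perplexities, kl = kl)
    attr(out, "embeddings") <- stats::setNames(embeds,
                                               as.character(perplexities))
    out
}
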