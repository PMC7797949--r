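# Cross-channel co-localization: link registered spots whose centres lie
# within the co-localization radius (default 3 px ~ 300 nm), merge linked
# spots into vesicle records, and classify each record by its marker set.

# Minimal union-find.
ufFind <- function(parent, i) {
    while (parent[i] != i) {
        parent[i] <- parent[parent[i]]
        i <- parent[i]
    }
    i
}

# Candidate cross-channel pairs within the radius, deterministically ordered
# by ascending distance (ties: channel pair, then spot indices).
candidatePairs <- function(combined, channels, threshold) {
    pairs <- list()
    for (ai in seq_along(channels)) {
        for (bi in seq_along(channels)) {
            if (bi <= ai) next
            a <- combined[combined$chIdx == ai, , drop = FALSE]
            b <- combined[combined$chIdx == bi, , drop = FALSE]
            if (nrow(a) == 0L || nrow(b) == 0L) next
            p <- crossPairsWithin(a, b, threshold)
            if (nrow(p) == 0L) next
            pairs[[length(pairs) + 1L]] <- data.frame(
                s1 = a$gid[p$i], s2 = b$gid[p$j], d = p$d,
                chPair = ai * 1000L + bi)
        }
    }
    if (!length(pairs))
        return(data.frame(s1 = integer(), s2 = integer(), d = numeric(),
                          chPair = integer()))
    out <- do.call(rbind, pairs)
    out[order(out$d, out$chPair, out$s1, out$s2), , drop = FALSE]
}

# Greedy link selection: accept pairs in ascending distance, each spot
# linkable to at most one spot per other channel.
selectLinksGreedy <- function(pairs, chIdx, nChannels, nSpots) {
    taken <- matrix(FALSE, nSpots, nChannels)
    acc <- logical(nrow(pairs))
    for (k in seq_len(nrow(pairs))) {
        s1 <- pairs$s1[k]; s2 <- pairs$s2[k]
        c1 <- chIdx[s1]; c2 <- chIdx[s2]
        if (!taken[s1, c2] && !taken[s2, c1]) {
            acc[k] <- TRUE
            taken[s1, c2] <- TRUE
            taken[s2, c1] <- TRUE
        }
    }
    acc
}

# Exact link selection: maximum number of links, minimum total distance
# among maximum-cardinality selections. Exhaustive DFS over candidate
# pairs; small instances only.
selectLinksOptimal <- function(pairs, chIdx, nChannels, nSpots) {
    np <- nrow(pairs)
    if (np == 0L) return(logical(0))
    if (np > 25L)
        stop("optimal matching is exhaustive; instance too large (> 25 candidate pairs)")
    best <- list(card = -1L, dist = Inf, sel = logical(np))
    taken <- matrix(FALSE, nSpots, nChannels)
    sel <- logical(np)
    dfs <- function(k, card, dist) {
        remaining <- np - k + 1L
        if (card + remaining < best$card) return()
        if (k > np) {
            if (card > best$card ||
                (card == best$card && dist < best$dist - 1e-12))
                best <<- list(card = card, dist = dist, sel = sel)
            return()
        }
        s1 <- pairs$s1[k]; s2 <- pairs$s2[k]
        c1 <- chIdx[s1]; c2 <- chIdx[s2]
        if (!taken[s1, c2] && !taken[s2, c1]) {
            taken[s1, c2] <<- TRUE; taken[s2, c1] <<- TRUE; sel[k] <<- TRUE
            dfs(k + 1L, card + 1L, dist + pairs$d[k])
            taken[s1, c2] <<- FALSE; taken[s2, c1] <<- FALSE; sel[k] <<- FALSE
        }
        dfs(k + 1L, card, dist)
    }
    dfs(1L, 0L, 0)
    best$sel
}

# Split components violating the clique rule (all pairwise member distances
# within the threshold) by dropping the longest accepted link until every
# component satisfies it.
enforceClique <- function(links, combined, threshold) {
    repeat {
        comp <- componentsFromLinks(links, nrow(combined))
        bad <- FALSE
        for (cid in unique(comp)) {
            members <- which(comp == cid)
            if (length(members) < 3L) next
            xy <- combined[members, c("x", "y")]
            dm <- as.matrix(stats::dist(xy))
            if (max(dm) <= threshold + 1e-12) next
            inComp <- links$s1 %in% combined$gid[members]
            drop <- which(inComp)[which.max(links$d[inComp])]
            links <- links[-drop, , drop = FALSE]
            bad <- TRUE
            break
        }
        if (!bad) return(links)
    }
}

componentsFromLinks <- function(links, n) {
    parent <- seq_len(n)
    for (k in seq_len(nrow(links))) {
        r1 <- ufFind(parent, links$s1[k])
        r2 <- ufFind(parent, links$s2[k])
        if (r1 != r2) parent[r2] <- r1
    }
    vapply(seq_len(n), function(i) ufFind(parent, i), integer(1))
}

#' Merge registered per-channel spot lists into vesicle records
#'
#' Creates cross-channel links between spots whose distance in the
#' reference frame is at most `thresholdPx`, using greedy ascending-distance
#' matching (default) or exact minimum-distance matching; each spot links to
#' at most one spot per other channel. Linked components become one vesicle
#' record; unlinked spots become single-positive records. With
#' `semantics = "clique"` chained components whose members span more than
#' the radius are split.
#'
#' @param spotsByChannel named list, channel -> registered spot data.frame
#'   (columns x, y at minimum). List order declares the channel order used
#'   for class naming.
#' @param params a [ColocalizationParams-class].
#' @return a [VesicleSet-class].
#' @export
matchChannels <- function(spotsByChannel, params = colocalizationParams()) {
    stopifnot(is(params, "ColocalizationParams"))
    channels <- names(spotsByChannel)
    if (is.null(channels) || any(channels == "") || anyDuplicated(channels))
        stop("spotsByChannel must have unique non-empty channel names")
    tabs <- lapply(seq_along(channels), function(i) {
        sp <- spotsByChannel[[i]]
        if (nrow(sp) == 0L)
            return(data.frame(channel = character(), x = numeric(),
                              y = numeric(), chIdx = integer()))
        sp$channel <- channels[i]
        sp$chIdx <- i
        sp
    })
    common <- Reduce(intersect, lapply(tabs, names))
    combined <- do.call(rbind, lapply(tabs, function(t) t[common]))
    n <- nrow(combined)
    if (n == 0L)
        return(new("VesicleSet",
                   records = data.frame(record_id = integer(),
                                        class = character(),
                                        n_labels = integer(),
                                        n_spots = integer(),
                                        centroid_x = numeric(),
                                        centroid_y = numeric(),
                                        max_pair_distance = numeric()),
                   spots = cbind(combined[0, , drop = FALSE],
                                 record_id = integer()),
                   channels = channels, params = params))
    combined$gid <- seq_len(n)
    rownames(combined) <- NULL
    pairs <- candidatePairs(combined, channels, params@thresholdPx)
    selector <- switch(params@matching,
                       greedy = selectLinksGreedy,
                       optimal = selectLinksOptimal)
    acc <- selector(pairs, combined$chIdx, length(channels), n)
    links <- pairs[acc, , drop = FALSE]
    if (params@semantics == "clique")
        links <- enforceClique(links, combined, params@thresholdPx)
    comp <- componentsFromLinks(links, n)
    recIds <- match(comp, unique(comp))          # first-appearance order
    combined$record_id <- recIds
    recs <- lapply(sort(unique(recIds)), function(rid) {
        members <- combined[combined$record_id == rid, , drop = FALSE]
        labels <- unique(members$channel)
        mpd <- if (nrow(members) > 1L)
            max(stats::dist(members[, c("x", "y")])) else 0
        data.frame(record_id = rid,
                   class = canonicalClass(labels, channels),
                   n_labels = length(labels),
                   n_spots = nrow(members),
                   centroid_x = mean(members$x),
                   centroid_y = mean(members$y),
                   max_pair_distance = mpd)
    })
    records <- do.call(rbind, recs)
    combined$chIdx <- NULL
    combined$gid <- NULL
    new("VesicleSet", records = records, spots = combined,
        channels = channels, params = params)
}

#' Co-localized fractions of a vesicle set
#'
#' Two denominators are reported: the fraction of vesicle records carrying
#' at least two markers, and the signal-weighted variant, the fraction of
#' underlying detected spots that belong to multi-marker records.
#'
#' @param vesicles a [VesicleSet-class].
#' @return list with elements `recordFraction` and `signalFraction`.
#' @export
colocalizationFraction <- function(vesicles) {
    stopifnot(is(vesicles, "VesicleSet"))
    recs <- records(vesicles)
    if (nrow(recs) == 0L)
        stop("co-localized fraction is undefined for an empty vesicle set")
    multi <- recs$n_labels >= 2L
    list(recordFraction = mean(multi),
         signalFraction = sum(recs$n_spots[multi]) / sum(recs$n_spots))
}
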