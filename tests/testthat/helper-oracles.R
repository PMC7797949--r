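# Independent brute-force oracles. These deliberately re-derive results
# with naive algorithms (plain loops, exhaustive enumeration) so they can
# check the package's optimised code paths.

# Mutual nearest-neighbour pairs by direct O(n*m) search.
bruteMutualNN <- function(a, b, radius) {
    n <- nrow(a); m <- nrow(b)
    out <- data.frame(ref = integer(), moving = integer(), dist = numeric())
    if (n == 0L || m == 0L) return(out)
    D <- outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2
    for (i in seq_len(n)) {
        j <- which.min(D[i, ])
        if (which.min(D[, j]) == i && sqrt(D[i, j]) <= radius)
            out <- rbind(out, data.frame(ref = i, moving = j,
                                         dist = sqrt(D[i, j])))
    }
    out
}

# Exhaustive co-localization oracle: enumerate every feasible set of
# cross-channel links (distance <= r, each spot at most one partner per
# other channel), keep the maximum-cardinality sets, and among those the
# minimum total distance; return the component partition as a canonical
# string. spots: data.frame(x, y, ch [integer]).
bruteMatchPartition <- function(spots, r) {
    n <- nrow(spots)
    pairs <- list()
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (j <= i || spots$ch[i] == spots$ch[j]) next
        d <- sqrt((spots$x[i] - spots$x[j])^2 + (spots$y[i] - spots$y[j])^2)
        if (d <= r) pairs[[length(pairs) + 1L]] <- c(i, j, d)
    }
    np <- length(pairs)
    best <- list(card = -1L, dist = Inf, links = list())
    explore <- function(k, chosen, card, dist) {
        if (k > np) {
            if (card > best$card ||
                (card == best$card && dist < best$dist - 1e-12))
                best <<- list(card = card, dist = dist, links = chosen)
            return()
        }
        p <- pairs[[k]]
        ok <- TRUE
        for (c in chosen) {
            # conflict: shares a spot with an existing link to the same channel
            if ((p[1] == c[1] && spots$ch[p[2]] == spots$ch[c[2]]) ||
                (p[1] == c[2] && spots$ch[p[2]] == spots$ch[c[1]]) ||
                (p[2] == c[1] && spots$ch[p[1]] == spots$ch[c[2]]) ||
                (p[2] == c[2] && spots$ch[p[1]] == spots$ch[c[1]])) {
                ok <- FALSE
                break
            }
        }
        if (ok) explore(k + 1L, c(chosen, list(p)), card + 1L, dist + p[3])
        explore(k + 1L, chosen, card, dist)
    }
    explore(1L, list(), 0L, 0)
    # components by repeated merging
    comp <- seq_len(n)
    repeat {
        changed <- FALSE
        for (p in best$links) {
            if (comp[p[1]] != comp[p[2]]) {
                comp[comp == comp[p[2]]] <- comp[p[1]]
                changed <- TRUE
            }
        }
        if (!changed) break
    }
    list(partition = partitionKey(comp),
         totalDist = best$dist, card = best$card)
}

# Canonical string for a partition given per-element group ids.
partitionKey <- function(groups) {
    sets <- split(seq_along(groups), groups)
    sets <- vapply(sets, function(s) paste(sort(s), collapse = ","),
                   character(1))
    paste(sort(sets), collapse = "|")
}

# Partition key of a VesicleSet in terms of the input order of its spots
# (spots must carry a unique `uid` column surviving the match).
vesicleSetPartition <- function(vs) {
    sp <- spotTable(vs)
    partitionKey(stats::setNames(sp$record_id, NULL)[order(sp$uid)])
}

# Centre-of-mass refinement around the brightest pixel: an independent
# (model-free) sub-pixel localizer used to cross-check Gaussian fits.
centroidLocalize <- function(image, half = 5) {
    idx <- which(image == max(image), arr.ind = TRUE)[1, ]
    rows <- max(1, idx[1] - half):min(nrow(image), idx[1] + half)
    cols <- max(1, idx[2] - half):min(ncol(image), idx[2] + half)
    win <- image[rows, cols]
    win <- pmax(win - median(image), 0)
    xc <- cols - 0.5; yc <- rows - 0.5
    c(x = sum(colSums(win) * xc) / sum(win),
      y = sum(rowSums(win) * yc) / sum(win))
}
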