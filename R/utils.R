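# Shared internal helpers: class-label algebra, neighbour search, RNG scoping.

# Separator used in canonical subpopulation class labels ("CD9∙CD81").
classSep <- function() "\u2219"

#' Canonical subpopulation class label for a set of markers
#'
#' Class names list the member channels in the declared channel order,
#' joined by the "∙" dot, e.g. \code{"CD9∙CD81"}.
#'
#' @param labels character vector of channel names present on the vesicle.
#' @param channels ordered channel names declaring the class space.
#' @return a single class label string.
#' @export
#' @examples
#' canonicalClass(c("CD81", "CD9"), c("CD9", "CD63", "CD81"))
canonicalClass <- function(labels, channels) {
    labels <- unique(labels)
    if (length(labels) == 0L) stop("empty label set cannot be classified")
    if (!all(labels %in% channels))
        stop("labels contain channels not in the declared channel set")
    paste(channels[channels %in% labels], collapse = classSep())
}

#' All subpopulation class labels for a channel set
#'
#' Enumerates the 2^K - 1 non-empty marker combinations for K channels,
#' ordered by combination size, then by channel order (singles first,
#' ending with the all-positive class).
#'
#' @param channels ordered channel names.
#' @return character vector of length 2^K - 1.
#' @export
#' @examples
#' allClasses(c("CD9", "CD63", "CD81"))
allClasses <- function(channels) {
    k <- length(channels)
    stopifnot(k >= 1L)
    out <- character()
    for (size in seq_len(k)) {
        idx <- utils::combn(k, size, simplify = FALSE)
        out <- c(out, vapply(idx, function(i)
            paste(channels[i], collapse = classSep()), character(1)))
    }
    out
}

# Split a canonical class label back into channel names.
classMembers <- function(class, channels = NULL) {
    members <- strsplit(class, classSep(), fixed = TRUE)[[1]]
    if (!is.null(channels) && !all(members %in% channels))
        stop(sprintf("class '%s' has channels outside the declared set", class))
    members
}

# Run code with a locally seeded RNG, restoring the caller's RNG state.
withSeed <- function(seed, code) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(seed)
    force(code)
}

# Derive a per-stage child seed from a master seed (keeps values < 2^31).
deriveSeed <- function(seed, stage) {
    h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
    (as.double(seed) * 48271 + h) %% 2147483629
}

# All pairs (i from a, j from b) with Euclidean distance <= r, via grid
# binning so dense point sets avoid the full n*m distance matrix.
# a, b: matrices/data.frames with columns x, y. Returns data.frame(i, j, d).
crossPairsWithin <- function(a, b, r) {
    ax <- a[["x"]]; ay <- a[["y"]]
    bx <- b[["x"]]; by <- b[["y"]]
    n <- length(ax); m <- length(bx)
    empty <- data.frame(i = integer(), j = integer(), d = numeric())
    if (n == 0L || m == 0L) return(empty)
    if (as.double(n) * m <= 250000) {
        d2 <- outer(ax, bx, "-")^2 + outer(ay, by, "-")^2
        hit <- which(d2 <= r * r, arr.ind = TRUE)
        if (nrow(hit) == 0L) return(empty)
        return(data.frame(i = hit[, 1], j = hit[, 2],
                          d = sqrt(d2[hit])))
    }
    cell <- r
    key <- function(x, y) paste(floor(x / cell), floor(y / cell))
    bIndex <- split(seq_len(m), key(bx, by))
    res_i <- vector("list", n); res_j <- vector("list", n); res_d <- vector("list", n)
    cxa <- floor(ax / cell); cya <- floor(ay / cell)
    for (i in seq_len(n)) {
        cand <- integer()
        for (dx in -1:1) for (dy in -1:1) {
            k <- paste(cxa[i] + dx, cya[i] + dy)
            cand <- c(cand, bIndex[[k]])
        }
        if (!length(cand)) next
        d <- sqrt((bx[cand] - ax[i])^2 + (by[cand] - ay[i])^2)
        keep <- d <= r
        if (any(keep)) {
            res_i[[i]] <- rep.int(i, sum(keep))
            res_j[[i]] <- cand[keep]
            res_d[[i]] <- d[keep]
        }
    }
    data.frame(i = unlist(res_i, use.names = FALSE) %||% integer(),
               j = unlist(res_j, use.names = FALSE) %||% integer(),
               d = unlist(res_d, use.names = FALSE) %||% numeric())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Coerce a data.frame (columns x, y) or two-column matrix to an n x 2 matrix.
asXY <- function(obj) {
    if (is.data.frame(obj)) cbind(x = as.numeric(obj$x), y = as.numeric(obj$y))
    else cbind(x = as.numeric(obj[, 1]), y = as.numeric(obj[, 2]))
}

# Empty spot table with the canonical column set.
emptySpots <- function() {
    data.frame(channel = character(), x = numeric(), y = numeric(),
               intensity = numeric(), amplitude = numeric(),
               sigma = numeric(), background = numeric(),
               fit_rss = numeric(), snr = numeric(), valid = logical())
}
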