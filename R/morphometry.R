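#' Measure normalized spine-head size in arbitrary units (AU)
#'
#' Implements the two-dimensional integrated-fluorescence measure of
#' spine-head size.  The frame `z*` maximizing the summed head-mask intensity
#' is selected (ties broken toward the lower z index); the head intensities at
#' `z*` are summed after subtracting the mean of the adjacent background mask;
#' and the result is normalized by the mean of the brightest 10% of the
#' adjacent shaft-mask pixels at `z*`.  The ratio is dimensionless ("AU") and
#' invariant to a global intensity scale, which removes biases from uneven
#' excitation and indicator expression.  Spine sizes in real data of this kind
#' span roughly 0.15--70 AU.
#'
#' The stack is expected to be median-filtered first (see
#' [medianFilterFrames()]); the function does not filter.
#'
#' @param stack an [ImageStack-class] or 3-D array `[z, y, x]`.
#' @param ann a [SpineAnnotation-class].
#' @param topFraction fraction of brightest shaft pixels averaged for the
#'   normalizer (default 0.1); the pixel count is `ceiling(topFraction * n)`,
#'   at least 1.
#' @param saturationLevel intensity at or above which head pixels are flagged
#'   as saturated (default `Inf`, i.e. never).
#' @return A one-row data.frame: `spine_id`, `dendrite_id`, `size_au`,
#'   `frame`, `flag_negative` (background-subtracted integral was negative;
#'   the value is kept, not clipped), `flag_saturated`.
#' @seealso [measureSpineHeadSizes()] for a list of annotations.
#' @examples
#' a <- array(10, c(1, 20, 20))
#' a[1, 5:9, 5:14] <- 20                      # head: 50 px summing to 1000
#' a[1, 15, 1:20] <- 50                       # shaft
#' ann <- SpineAnnotation("s1",
#'   head = cbind(1, rep(5:9, 10), rep(5:14, each = 5)),
#'   background = cbind(1, 12, 1:10),
#'   shaft = cbind(1, 15, 1:20))
#' measureSpineHeadSize(a, ann)$size_au  # (1000 - 10*50)/50 = 10 AU
#' @export
measureSpineHeadSize <- function(stack, ann, topFraction = 0.1,
                                 saturationLevel = Inf) {
    arr <- if (is(stack, "ImageStack")) intensity(stack) else stack
    stopifnot(length(dim(arr)) == 3L)
    validObject(ann)
    d <- dim(arr)
    for (w in c("head", "background", "shaft")) {
        m <- slot(ann, w)
        if (nrow(m) > 0 && (any(m[, "z"] > d[1]) || any(m[, "y"] > d[2]) ||
                            any(m[, "x"] > d[3])))
            stop(sprintf("'%s' mask indexes outside the stack", w))
    }
    head <- ann@head
    frames <- sort(unique(head[, "z"]))
    sums <- vapply(frames, function(z) {
        hz <- head[head[, "z"] == z, , drop = FALSE]
        sum(arr[hz])
    }, numeric(1))
    zStar <- frames[which.max(sums)]  # which.max: first max, i.e. lowest z

    headZ <- head[head[, "z"] == zStar, , drop = FALSE]
    bgZ <- ann@background[ann@background[, "z"] == zStar, , drop = FALSE]
    shZ <- ann@shaft[ann@shaft[, "z"] == zStar, , drop = FALSE]
    if (nrow(bgZ) == 0L)
        stop(sprintf("spine '%s': empty background mask at frame %d",
                     ann@spineId, zStar))
    if (nrow(shZ) == 0L)
        stop(sprintf("spine '%s': empty shaft mask at frame %d",
                     ann@spineId, zStar))

    headVals <- arr[headZ]
    integrated <- sum(headVals) - mean(arr[bgZ]) * nrow(headZ)
    shVals <- sort(arr[shZ], decreasing = TRUE)
    nTop <- max(1L, ceiling(topFraction * length(shVals)))
    shaftNorm <- mean(shVals[seq_len(nTop)])
    if (shaftNorm <= 0)
        stop(sprintf("spine '%s': shaft normalizer is not positive",
                     ann@spineId))
    data.frame(spine_id = ann@spineId, dendrite_id = ann@dendriteId,
               size_au = integrated / shaftNorm, frame = as.integer(zStar),
               flag_negative = integrated < 0,
               flag_saturated = any(headVals >= saturationLevel),
               stringsAsFactors = FALSE)
}

#' Measure many spines at once
#'
#' @param stack an [ImageStack-class] or 3-D array.
#' @param annotations list of [SpineAnnotation-class] objects.
#' @param ... passed to [measureSpineHeadSize()].
#' @return data.frame with one row per spine.
#' @export
measureSpineHeadSizes <- function(stack, annotations, ...) {
    do.call(rbind, lapply(annotations, function(a)
        measureSpineHeadSize(stack, a, ...)))
}

#' Spine density along a dendrite
#'
#' Density is the number of spine heads divided by the dendrite arc length in
#' micrometres.  Every head of a multi-headed protrusion counts as one spine,
#' regardless of neck origin.
#'
#' @param trace a [DendriteTrace-class], or a plain length in um.
#' @param spineCount number of spine heads on the dendrite.
#' @return list with `dendrite_id` (if available), `length_um`, `n_spines`,
#'   `density_per_um` and `density_per_10um`.
#' @examples
#' spineDensity(50, 20)$density_per_um  # 0.4
#' @export
spineDensity <- function(trace, spineCount) {
    if (length(spineCount) != 1L || !is.finite(spineCount) ||
        spineCount < 0 || spineCount != round(spineCount))
        stop("'spineCount' must be a single non-negative integer")
    if (is(trace, "DendriteTrace")) {
        len <- traceLength(trace)
        id <- trace@dendriteId
    } else {
        len <- as.numeric(trace)
        id <- NA_character_
    }
    if (!is.finite(len) || len <= 0)
        stop("dendrite length must be positive")
    list(dendrite_id = id, length_um = len, n_spines = as.integer(spineCount),
         density_per_um = spineCount / len,
         density_per_10um = 10 * spineCount / len)
}

#' Binned spine-size distribution
#'
#' Relative frequencies of spine sizes in fixed-width AU bins
#' (`[0, 10)`, `[10, 20)`, ...), the representation used for two-sample KS
#' comparisons and per-bin t-tests of size distributions.
#'
#' @param sizes numeric vector of spine sizes, AU.
#' @param binWidth bin width in AU (default 10).
#' @return data.frame with `bin_start`, `bin_end`, `count`, `freq`
#'   (frequencies sum to 1); bins are left-closed, right-open.
#' @examples
#' sizeDistributionSummary(c(5, 15, 55))$freq
#' @export
sizeDistributionSummary <- function(sizes, binWidth = 10) {
    if (length(sizes) == 0L)
        stop("'sizes' must be non-empty")
    if (!all(is.finite(sizes)))
        stop("'sizes' must be finite")
    if (!is.finite(binWidth) || binWidth <= 0)
        stop("'binWidth' must be positive")
    lo <- binWidth * floor(min(c(sizes, 0)) / binWidth)
    hi <- binWidth * (floor(max(sizes) / binWidth) + 1)
    breaks <- seq(lo, hi, by = binWidth)
    counts <- as.integer(table(cut(sizes, breaks, right = FALSE,
                                   include.lowest = FALSE)))
    data.frame(bin_start = breaks[-length(breaks)], bin_end = breaks[-1],
               count = counts, freq = counts / length(sizes))
}
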