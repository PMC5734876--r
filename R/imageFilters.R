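#' Per-frame 2-D median filter
#'
#' Filters every z-frame of a stack independently with a square median
#' filter (default 3 x 3 px), the standard denoising step applied before
#' spine-head size measurement.  At the frame borders the window is clipped
#' to the frame, so the median is taken over the available pixels only.
#'
#' @param stack an [ImageStack-class] (or a bare 3-D array `[z, y, x]`).
#' @param size odd window side length in pixels (default 3).
#' @return An object of the same type as `stack`, same dimensions.
#' @examples
#' a <- array(10, c(1, 8, 8)); a[1, 4, 4] <- 500  # hot pixel
#' f <- medianFilterFrames(a)
#' f[1, 4, 4]  # back to background
#' @export
medianFilterFrames <- function(stack, size = 3L) {
    if (length(size) != 1L || !is.finite(size) || size < 1 ||
        size %% 2 == 0)
        stop("'size' must be a single odd integer >= 1")
    arr <- if (is(stack, "ImageStack")) intensity(stack) else stack
    if (length(dim(arr)) != 3L)
        stop("'stack' must be a 3-D array [z, y, x]")
    k <- (size - 1L) / 2L
    out <- arr
    for (z in seq_len(dim(arr)[1])) {
        out[z, , ] <- .medianFilter2D(arr[z, , ], k)
    }
    if (is(stack, "ImageStack"))
        ImageStack(out, pixelSizeXY(stack), zStep(stack))
    else out
}

## windows clipped at borders; stacked shifted copies, median over non-NA
.medianFilter2D <- function(m, k) {
    ny <- nrow(m); nx <- ncol(m)
    offs <- expand.grid(dy = -k:k, dx = -k:k)
    sheets <- array(NA_real_, c(ny, nx, nrow(offs)))
    for (i in seq_len(nrow(offs))) {
        dy <- offs$dy[i]; dx <- offs$dx[i]
        ys <- seq_len(ny) + dy; xs <- seq_len(nx) + dx
        okY <- ys >= 1 & ys <= ny; okX <- xs >= 1 & xs <= nx
        sheets[which(okY), which(okX), i] <- m[ys[okY], xs[okX]]
    }
    apply(sheets, c(1, 2), stats::median, na.rm = TRUE)
}

#' Per-frame Gaussian blur
#'
#' Separable Gaussian smoothing of every z-frame, the filtering applied to
#' time-lapse stacks before spine dynamics are scored.  The truncated kernel
#' is renormalized at the borders.
#'
#' @param stack an [ImageStack-class] or 3-D array `[z, y, x]`.
#' @param sigma Gaussian standard deviation in pixels (default 1).
#' @return Same type as `stack`.
#' @export
gaussianBlurFrames <- function(stack, sigma = 1) {
    if (!is.finite(sigma) || sigma <= 0)
        stop("'sigma' must be positive")
    arr <- if (is(stack, "ImageStack")) intensity(stack) else stack
    if (length(dim(arr)) != 3L)
        stop("'stack' must be a 3-D array [z, y, x]")
    r <- max(1L, ceiling(3 * sigma))
    kern <- exp(-((-r:r)^2) / (2 * sigma^2))
    kern <- kern / sum(kern)
    out <- arr
    for (z in seq_len(dim(arr)[1])) {
        m <- arr[z, , ]
        m <- .convolveRows(m, kern)
        m <- t(.convolveRows(t(m), kern))
        out[z, , ] <- m
    }
    if (is(stack, "ImageStack"))
        ImageStack(out, pixelSizeXY(stack), zStep(stack))
    else out
}

## 1-D convolution along columns of each row, border-renormalized
.convolveRows <- function(m, kern) {
    r <- (length(kern) - 1L) / 2L
    nx <- ncol(m)
    acc <- matrix(0, nrow(m), nx)
    wsum <- numeric(nx)
    for (i in seq_along(kern)) {
        dx <- i - r - 1L
        xs <- seq_len(nx) + dx
        ok <- xs >= 1 & xs <= nx
        acc[, which(ok)] <- acc[, which(ok)] + kern[i] * m[, xs[ok]]
        wsum[which(ok)] <- wsum[which(ok)] + kern[i]
    }
    sweep(acc, 2, wsum, "/")
}

#' Read / write image stacks as multi-page TIFF
#'
#' `writeImageStack()` stores the frames of a stack as a multi-page 32-bit
#' float TIFF; intensities are scaled into `[0, 1]` by the stack maximum
#' (spine-head sizes in AU are ratios and unaffected by a global scale).
#' `readImageStack()` reads the pages back into an [ImageStack-class]; the
#' physical voxel sizes are supplied by the caller because baseline TIFF
#' carries no calibrated size fields.
#'
#' @param stack an [ImageStack-class].
#' @param path file path.
#' @param pixelSizeXY,zStep voxel sizes in um attached on read.
#' @return `readImageStack()` an `ImageStack`; `writeImageStack()` the path,
#'   invisibly.
#' @export
writeImageStack <- function(stack, path) {
    arr <- intensity(stack)
    mx <- max(arr, 1e-12)
    pages <- lapply(seq_len(dim(arr)[1]), function(z) arr[z, , ] / mx)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    invisible(path)
}

#' @rdname writeImageStack
#' @export
readImageStack <- function(path, pixelSizeXY = 0.2, zStep = 0.5) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    d <- dim(pages[[1]])
    arr <- array(0, c(length(pages), d[1], d[2]))
    for (z in seq_along(pages)) arr[z, , ] <- pages[[z]]
    ImageStack(arr, pixelSizeXY = pixelSizeXY, zStep = zStep)
}
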