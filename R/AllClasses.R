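#' @import methods
NULL

.checkVoxelMatrix <- function(m, what) {
    if (!is.matrix(m) || ncol(m) != 3L)
        return(sprintf("'%s' must be a matrix with columns z, y, x", what))
    if (nrow(m) > 0 && (anyNA(m) || any(m < 1) || any(m != round(m))))
        return(sprintf("'%s' must contain positive integer voxel indices", what))
    if (!identical(colnames(m), c("z", "y", "x")))
        return(sprintf("'%s' must have column names z, y, x", what))
    NULL
}

#' ImageStack: a 3-D fluorescence stack with physical voxel sizes
#'
#' Container for a single-channel confocal or two-photon image stack.  The
#' intensity array is indexed `[z, y, x]` (frame, row, column) and carries the
#' lateral pixel size and the axial step so that downstream measurements
#' (dendrite lengths, contact densities) can be expressed in micrometres.
#'
#' @slot intensity numeric 3-D array `[z, y, x]`, finite and non-negative.
#' @slot pixelSizeXY lateral pixel size in micrometres (default 0.2, within
#'   the 0.165--0.2 um/px range typical of high-NA confocal imaging).
#' @slot zStep axial step in micrometres (default 0.5).
#' @export
setClass("ImageStack",
    representation(intensity = "array", pixelSizeXY = "numeric",
                   zStep = "numeric"))

setValidity("ImageStack", function(object) {
    d <- dim(object@intensity)
    if (length(d) != 3L)
        return("'intensity' must be a 3-D array [z, y, x]")
    if (!all(is.finite(object@intensity)))
        return("'intensity' must be finite")
    if (any(object@intensity < 0))
        return("'intensity' must be non-negative")
    if (length(object@pixelSizeXY) != 1L || !is.finite(object@pixelSizeXY) ||
        object@pixelSizeXY <= 0)
        return("'pixelSizeXY' must be a single positive number")
    if (length(object@zStep) != 1L || !is.finite(object@zStep) ||
        object@zStep <= 0)
        return("'zStep' must be a single positive number")
    TRUE
})

#' Construct an ImageStack
#'
#' @param intensity numeric 3-D array `[z, y, x]`.
#' @param pixelSizeXY lateral pixel size, um.
#' @param zStep axial step, um.
#' @return An [ImageStack-class] object.
#' @examples
#' s <- ImageStack(array(0, c(3, 8, 8)))
#' dim(s)
#' @export
ImageStack <- function(intensity, pixelSizeXY = 0.2, zStep = 0.5) {
    new("ImageStack", intensity = intensity, pixelSizeXY = pixelSizeXY,
        zStep = zStep)
}

#' @describeIn ImageStack dimensions of the intensity array (z, y, x).
#' @param x an `ImageStack`.
#' @export
setMethod("dim", "ImageStack", function(x) dim(x@intensity))

setMethod("show", "ImageStack", function(object) {
    d <- dim(object@intensity)
    cat(sprintf(
        "ImageStack: %d frames of %d x %d px (%.3g um/px xy, %.3g um z-step)\n",
        d[1], d[2], d[3], object@pixelSizeXY, object@zStep))
    cat(sprintf("  intensity range [%.4g, %.4g]\n",
                min(object@intensity), max(object@intensity)))
})

#' @rdname intensity
#' @export
setGeneric("intensity", function(x) standardGeneric("intensity"))

#' Accessors for ImageStack slots
#'
#' @param x an [ImageStack-class].
#' @return `intensity()` the 3-D array; `pixelSizeXY()` and `zStep()` the
#'   voxel sizes in micrometres.
#' @name intensity
#' @export
setMethod("intensity", "ImageStack", function(x) x@intensity)

#' @rdname intensity
#' @export
setGeneric("pixelSizeXY", function(x) standardGeneric("pixelSizeXY"))

#' @rdname intensity
#' @export
setMethod("pixelSizeXY", "ImageStack", function(x) x@pixelSizeXY)

#' @rdname intensity
#' @export
setGeneric("zStep", function(x) standardGeneric("zStep"))

#' @rdname intensity
#' @export
setMethod("zStep", "ImageStack", function(x) x@zStep)

#' SpineAnnotation: head / background / shaft regions of one spine
#'
#' Manual (or synthetic ground-truth) annotation of a single dendritic spine:
#' the set of voxels forming the spine head, an adjacent empty background
#' region, and a stretch of the parent dendritic shaft.  The three regions are
#' the inputs of the normalized head-size measurement and must be pairwise
#' disjoint.  Voxel coordinates are 1-based `[z, y, x]` indices into the
#' parent stack.
#'
#' @slot spineId character, unique spine identifier.
#' @slot head integer voxel matrix (columns z, y, x) of the head region.
#' @slot background voxel matrix of the adjacent background region.
#' @slot shaft voxel matrix of the adjacent dendritic shaft region.
#' @slot dendriteId character, parent dendrite identifier.
#' @slot positionUm arc-length position of the spine along its dendrite, um.
#' @export
setClass("SpineAnnotation",
    representation(spineId = "character", head = "matrix",
                   background = "matrix", shaft = "matrix",
                   dendriteId = "character", positionUm = "numeric"))

setValidity("SpineAnnotation", function(object) {
    for (w in c("head", "background", "shaft")) {
        msg <- .checkVoxelMatrix(slot(object, w), w)
        if (!is.null(msg)) return(msg)
    }
    if (nrow(object@head) == 0L)
        return("head mask must be non-empty")
    key <- function(m) paste(m[, 1], m[, 2], m[, 3])
    kh <- key(object@head); kb <- key(object@background)
    ks <- key(object@shaft)
    if (length(intersect(kh, kb)) || length(intersect(kh, ks)) ||
        length(intersect(kb, ks)))
        return("head, background and shaft masks must be pairwise disjoint")
    if (length(object@positionUm) != 1L || !is.finite(object@positionUm) ||
        object@positionUm < 0)
        return("'positionUm' must be a single non-negative number")
    TRUE
})

#' Construct a SpineAnnotation
#'
#' @param spineId spine identifier.
#' @param head,background,shaft voxel matrices with columns `z`, `y`, `x`
#'   (1-based indices into the stack).
#' @param dendriteId parent dendrite identifier.
#' @param positionUm arc-length position along the dendrite, um.
#' @return A [SpineAnnotation-class] object.
#' @export
SpineAnnotation <- function(spineId, head, background, shaft,
                            dendriteId = "d1", positionUm = 0) {
    fix <- function(m) {
        m <- as.matrix(m)
        storage.mode(m) <- "integer"
        colnames(m) <- c("z", "y", "x")
        m
    }
    new("SpineAnnotation", spineId = as.character(spineId), head = fix(head),
        background = fix(background), shaft = fix(shaft),
        dendriteId = as.character(dendriteId), positionUm = positionUm)
}

setMethod("show", "SpineAnnotation", function(object) {
    cat(sprintf(
        "SpineAnnotation '%s' on dendrite '%s' at %.2f um (head %d px, bg %d px, shaft %d px)\n",
        object@spineId, object@dendriteId, object@positionUm,
        nrow(object@head), nrow(object@background), nrow(object@shaft)))
})

#' DendriteTrace: a polyline trace of one dendritic segment
#'
#' An ordered list of voxel coordinates tracing a dendrite through the stack.
#' Arc length is computed from the polyline scaled anisotropically by the
#' lateral pixel size (y, x) and axial step (z); it is the denominator of
#' spine density and shaft-contact density.
#'
#' @slot dendriteId character identifier.
#' @slot points numeric matrix with columns z, y, x (0-based distances are
#'   never used; these are voxel indices, possibly fractional).
#' @slot pixelSizeXY lateral pixel size, um.
#' @slot zStep axial step, um.
#' @slot spineIds character vector of spine ids attached to this dendrite.
#' @export
setClass("DendriteTrace",
    representation(dendriteId = "character", points = "matrix",
                   pixelSizeXY = "numeric", zStep = "numeric",
                   spineIds = "character"))

setValidity("DendriteTrace", function(object) {
    p <- object@points
    if (!is.numeric(p) || ncol(p) != 3L || nrow(p) < 2L)
        return("'points' must be a numeric matrix [>=2, 3] of z, y, x")
    if (anyNA(p) || any(!is.finite(p)))
        return("'points' must be finite")
    if (object@pixelSizeXY <= 0 || object@zStep <= 0)
        return("voxel sizes must be positive")
    if (traceLength(object) <= 0)
        return("trace must have positive arc length")
    TRUE
})

#' Construct a DendriteTrace
#'
#' @param dendriteId identifier.
#' @param points numeric matrix with columns `z`, `y`, `x`.
#' @param pixelSizeXY,zStep voxel sizes, um.
#' @param spineIds ids of spines attached to this dendrite.
#' @return A [DendriteTrace-class] object.
#' @examples
#' tr <- DendriteTrace("d1", cbind(z = c(1, 1), y = c(10, 10), x = c(1, 251)),
#'                     pixelSizeXY = 0.2)
#' traceLength(tr)  # 50 um
#' @export
DendriteTrace <- function(dendriteId, points, pixelSizeXY = 0.2, zStep = 0.5,
                          spineIds = character()) {
    points <- as.matrix(points)
    colnames(points) <- c("z", "y", "x")
    new("DendriteTrace", dendriteId = as.character(dendriteId),
        points = points, pixelSizeXY = pixelSizeXY, zStep = zStep,
        spineIds = as.character(spineIds))
}

#' @rdname traceLength
#' @export
setGeneric("traceLength", function(x) standardGeneric("traceLength"))

#' Arc length of a dendrite trace in micrometres
#'
#' Polyline arc length with z differences scaled by the axial step and y/x
#' differences by the lateral pixel size.
#'
#' @param x a [DendriteTrace-class].
#' @return length in um.
#' @name traceLength
#' @export
setMethod("traceLength", "DendriteTrace", function(x) {
    p <- x@points
    d <- diff(p)
    sum(sqrt((d[, 1] * x@zStep)^2 + (d[, 2] * x@pixelSizeXY)^2 +
             (d[, 3] * x@pixelSizeXY)^2))
})

setMethod("show", "DendriteTrace", function(object) {
    cat(sprintf("DendriteTrace '%s': %d points, %.2f um, %d spines attached\n",
                object@dendriteId, nrow(object@points), traceLength(object),
                length(object@spineIds)))
})

#' TrialSet: trial-structured calcium traces with a blank channel
#'
#' Raw fluorescence traces organized as a 4-D array
#' `[cell, odor, trial, sample]` on a common time grid, together with the
#' acquisition timing needed by the response classifier: sampling rate,
#' stimulus-onset sample, stimulus duration, and the identity of the blank
#' (no-odor) channel that serves as the null reference.
#'
#' @slot traces numeric 4-D array `[cell, odor, trial, sample]` with dimnames
#'   on the cell and odor dimensions.
#' @slot samplingRate acquisition rate, Hz.
#' @slot stimOnsetSample 1-based sample index of stimulus onset.
#' @slot stimDurationSec stimulus duration, seconds.
#' @slot blankOdor name of the blank channel among the odor dimnames.
#' @export
setClass("TrialSet",
    representation(traces = "array", samplingRate = "numeric",
                   stimOnsetSample = "numeric", stimDurationSec = "numeric",
                   blankOdor = "character"))

setValidity("TrialSet", function(object) {
    d <- dim(object@traces)
    if (length(d) != 4L)
        return("'traces' must be a 4-D array [cell, odor, trial, sample]")
    dn <- dimnames(object@traces)
    if (is.null(dn) || is.null(dn[[1]]) || is.null(dn[[2]]))
        return("'traces' must carry cell and odor dimnames")
    if (!(object@blankOdor %in% dn[[2]]))
        return("blank odor must be present among the odor dimnames")
    if (object@samplingRate <= 0)
        return("'samplingRate' must be positive")
    if (object@stimOnsetSample < 2 || object@stimOnsetSample > d[4])
        return("'stimOnsetSample' must lie inside the trial")
    if (object@stimDurationSec <= 0)
        return("'stimDurationSec' must be positive")
    TRUE
})

#' Construct a TrialSet
#'
#' @param traces numeric 4-D array `[cell, odor, trial, sample]` with cell and
#'   odor dimnames; the odor dimension includes the blank channel.
#' @param samplingRate Hz.
#' @param stimOnsetSample 1-based onset sample index.
#' @param stimDurationSec stimulus duration, s.
#' @param blankOdor name of the blank channel.
#' @return A [TrialSet-class] object.
#' @export
TrialSet <- function(traces, samplingRate = 7, stimOnsetSample = 70,
                     stimDurationSec = 2, blankOdor = "blank") {
    new("TrialSet", traces = traces, samplingRate = samplingRate,
        stimOnsetSample = stimOnsetSample, stimDurationSec = stimDurationSec,
        blankOdor = blankOdor)
}

setMethod("show", "TrialSet", function(object) {
    d <- dim(object@traces)
    cat(sprintf(
        "TrialSet: %d cells x %d odors (blank: '%s') x %d trials x %d samples @ %g Hz\n",
        d[1], d[2], object@blankOdor, d[3], d[4], object@samplingRate))
    cat(sprintf("  stimulus: onset sample %d, duration %g s\n",
                as.integer(object@stimOnsetSample), object@stimDurationSec))
})

#' @rdname odorNames
#' @export
setGeneric("odorNames", function(x) standardGeneric("odorNames"))

#' Odor and cell names of a TrialSet
#'
#' @param x a [TrialSet-class].
#' @return character vector of odor names (including the blank) or cell ids.
#' @name odorNames
#' @export
setMethod("odorNames", "TrialSet", function(x) dimnames(x@traces)[[2]])

#' @rdname odorNames
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' @rdname odorNames
#' @export
setMethod("cellIds", "TrialSet", function(x) dimnames(x@traces)[[1]])

#' @rdname odorNames
#' @export
setGeneric("blankOdor", function(x) standardGeneric("blankOdor"))

#' @rdname odorNames
#' @export
setMethod("blankOdor", "TrialSet", function(x) x@blankOdor)
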