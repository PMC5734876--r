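#' Detect putative microglia contacts on dendritic shafts and spines
#'
#' A putative contact is spatial overlap ("double staining") between the
#' microglial-process mask and a target mask (a dendritic shaft or a spine
#' head) within a focal plane.  Per z-plane, every 8-connected 2-D component
#' of the overlap is one contact; components on the same target that share at
#' least one (y, x) voxel column between consecutive planes are merged into a
#' single event, so a blob spanning several focal planes counts once.
#'
#' @param microgliaMask logical 3-D array `[z, y, x]`.
#' @param shaftMasks named list of logical arrays, one per dendritic shaft
#'   (a single array is accepted for one shaft).
#' @param spineMasks named list of logical arrays, one per spine head.
#' @return data.frame with one row per contact event: `event_id`,
#'   `target_type` (`"shaft"`/`"spine"`), `target_id`, `n_voxels`, `z_min`,
#'   `z_max`.
#' @export
detectContacts <- function(microgliaMask, shaftMasks = list(),
                           spineMasks = list()) {
    if (length(dim(microgliaMask)) != 3L)
        stop("'microgliaMask' must be a 3-D array")
    asList <- function(x, prefix) {
        if (is.array(x)) x <- stats::setNames(list(x), prefix)
        if (length(x) > 0 && is.null(names(x)))
            names(x) <- paste0(prefix, seq_along(x))
        x
    }
    shaftMasks <- asList(shaftMasks, "shaft1")
    spineMasks <- asList(spineMasks, "spine")
    rows <- list()
    eid <- 0L
    scan <- function(masks, type) {
        for (nm in names(masks)) {
            tm <- masks[[nm]]
            if (!identical(dim(tm), dim(microgliaMask)))
                stop(sprintf("mask '%s' does not match the microglia grid", nm))
            ov <- microgliaMask & tm
            comps <- .overlapComponents(ov)
            for (cp in comps) {
                eid <<- eid + 1L
                rows[[eid]] <<- data.frame(
                    event_id = eid, target_type = type, target_id = nm,
                    n_voxels = nrow(cp), z_min = min(cp[, 1]),
                    z_max = max(cp[, 1]), stringsAsFactors = FALSE)
            }
        }
    }
    scan(shaftMasks, "shaft")
    scan(spineMasks, "spine")
    if (eid == 0L)
        return(data.frame(event_id = integer(), target_type = character(),
                          target_id = character(), n_voxels = integer(),
                          z_min = integer(), z_max = integer(),
                          stringsAsFactors = FALSE))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

## components of a logical 3-D overlap array under 8-connectivity in-plane
## plus same-column adjacency across consecutive planes; returns a list of
## voxel coordinate matrices
.overlapComponents <- function(ov) {
    vox <- which(ov, arr.ind = TRUE)
    if (nrow(vox) == 0L) return(list())
    colnames(vox) <- c("z", "y", "x")
    key <- function(z, y, x) paste(z, y, x, sep = ",")
    ids <- key(vox[, 1], vox[, 2], vox[, 3])
    offs <- rbind(c(0, 0, 1), c(0, 1, -1), c(0, 1, 0), c(0, 1, 1),
                  c(1, 0, 0))
    edges <- NULL
    for (i in seq_len(nrow(offs))) {
        nb <- key(vox[, 1] + offs[i, 1], vox[, 2] + offs[i, 2],
                  vox[, 3] + offs[i, 3])
        hit <- nb %in% ids
        if (any(hit))
            edges <- rbind(edges, cbind(ids[hit], nb[hit]))
    }
    g <- igraph::graph_from_data_frame(
        if (is.null(edges)) data.frame(from = character(), to = character())
        else data.frame(from = edges[, 1], to = edges[, 2]),
        directed = FALSE, vertices = data.frame(name = ids))
    memb <- igraph::components(g)$membership[ids]
    lapply(split(seq_len(nrow(vox)), memb),
           function(ii) vox[ii, , drop = FALSE])
}

#' Shaft-contact density per millimetre
#'
#' Number of shaft-contact events normalized by the dendritic shaft length,
#' expressed as contacts per mm of shaft.
#'
#' @param events contact-event data.frame from [detectContacts()].
#' @param shaftLengthUm shaft length in micrometres.
#' @return contacts per mm (numeric).
#' @examples
#' ev <- data.frame(target_type = rep("shaft", 4))
#' shaftContactDensity(ev, 200)  # 20 per mm
#' @export
shaftContactDensity <- function(events, shaftLengthUm) {
    if (!is.finite(shaftLengthUm) || shaftLengthUm <= 0)
        stop("'shaftLengthUm' must be positive")
    n <- if (nrow(events) == 0L) 0L else sum(events$target_type == "shaft")
    1000 * n / shaftLengthUm
}

#' Fraction of spines contacted by microglia
#'
#' Percentage of distinct spines with at least one contact event out of the
#' total spine count; multiple events on one spine count once.
#'
#' @param events contact-event data.frame from [detectContacts()].
#' @param nSpines total number of spines.
#' @return percentage in `[0, 100]`.
#' @export
spineContactFraction <- function(events, nSpines) {
    if (!is.finite(nSpines) || nSpines <= 0)
        stop("'nSpines' must be positive")
    contacted <- if (nrow(events) == 0L) character() else
        unique(events$target_id[events$target_type == "spine"])
    100 * length(contacted) / nSpines
}

#' Areal cell density from point annotations
#'
#' Counts annotated cells inside a region polygon whose depth lies within the
#' first `zDepthUm` micrometres of the slice (boundary inclusive), divided by
#' the region area in mm^2.  This reproduces manual counting of
#' immunolabeled cells (e.g. Iba-1 microglia or DCX neuroblasts) restricted
#' to the first 8 um of each 40 um section; for proliferation birthdating,
#' only cells co-labeled by both markers (e.g. BrdU and NeuN along the
#' z-axis) are counted, via `requireColabel`.
#'
#' @param points data.frame with columns `x_um`, `y_um`, `z_um` and
#'   optionally logical `colabeled`.
#' @param polygon optional matrix/data.frame of region vertices (`x_um`,
#'   `y_um`); points outside are excluded.
#' @param areaMm2 region area in mm^2; computed from `polygon` (shoelace
#'   formula) when missing.
#' @param zDepthUm inclusion depth, um (default 8, inclusive).
#' @param requireColabel count only points with `colabeled == TRUE`.
#' @return list with `count`, `areaMm2`, `densityPerMm2`.
#' @export
cellDensity <- function(points, polygon = NULL, areaMm2 = NULL, zDepthUm = 8,
                        requireColabel = FALSE) {
    if (is.null(areaMm2)) {
        if (is.null(polygon))
            stop("give either 'areaMm2' or a 'polygon'")
        p <- as.matrix(polygon)
        n <- nrow(p)
        j <- c(2:n, 1)
        areaUm2 <- abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
        areaMm2 <- areaUm2 / 1e6
    }
    if (!is.finite(areaMm2) || areaMm2 <= 0)
        stop("region area must be positive")
    keep <- rep(TRUE, nrow(points))
    if (nrow(points) > 0) {
        keep <- points$z_um <= zDepthUm
        if (requireColabel) {
            if (is.null(points$colabeled))
                stop("'colabeled' column required when requireColabel = TRUE")
            keep <- keep & points$colabeled
        }
        if (!is.null(polygon) && any(keep)) {
            inside <- mgcv::in.out(as.matrix(polygon)[, 1:2, drop = FALSE],
                                   as.matrix(points[, c("x_um", "y_um")]))
            keep <- keep & inside
        }
    }
    count <- sum(keep)
    list(count = as.integer(count), areaMm2 = areaMm2,
         densityPerMm2 = count / areaMm2)
}
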