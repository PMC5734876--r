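#' Simulate paired-session spine cohorts with known fates
#'
#' Generates two-session spine records for a set of dendritic segments with
#' known ground-truth fates, emulating 24-h time-lapse imaging of dendritic
#' spines.  Each first-session spine survives to the second session
#' independently with probability `survivalProb`; the number of gained spines
#' per segment is Poisson with mean `gainRate` times the realized stable
#' count (a maximum-entropy count model that keeps the expected turnover rate
#' analytically computable).  Every record carries an arc-length position so
#' that positional matching can be run downstream.  Gained spines appear at
#' genuinely new sites: candidate positions closer than `minSeparationUm` to
#' any first-session spine are rejected, because a new spine within the
#' resolution limit of a pre-existing site cannot be told apart from that
#' site's spine and would be scored as stable rather than as a loss-plus-gain.
#' Gained spines impose no exclusion on one another.
#'
#' @param nSegments number of dendritic segments.
#' @param spinesPerSegment first-session spines per segment.
#' @param survivalProb per-spine survival probability in `[0, 1]`.
#' @param gainRate expected gained spines per realized stable spine (>= 0).
#' @param segmentLengthUm segment length in um; default gives a spine
#'   density of 0.5 per um.
#' @param minSeparationUm exclusion radius around first-session sites for
#'   new-spine placement (default 1 um, the default matching radius).
#' @param seed optional integer; when given, output is reproducible.
#' @return list with `records` (data.frame `segment_id`, `session`,
#'   `spine_id`, `position_um`) and `truth` (data.frame `segment_id`,
#'   `spine_id_s1`, `spine_id_s2`, `fate`).
#' @examples
#' sim <- simulateSpineSessions(3, 10, 0.7, 0.5, seed = 1)
#' table(sim$truth$fate)
#' @export
simulateSpineSessions <- function(nSegments, spinesPerSegment, survivalProb,
                                  gainRate,
                                  segmentLengthUm = spinesPerSegment / 0.5,
                                  minSeparationUm = 1, seed = NULL) {
    if (!is.finite(nSegments) || nSegments < 1)
        stop("'nSegments' must be a positive integer")
    if (!is.finite(spinesPerSegment) || spinesPerSegment < 0)
        stop("'spinesPerSegment' must be a non-negative integer")
    if (!is.finite(survivalProb) || survivalProb < 0 || survivalProb > 1)
        stop("'survivalProb' must lie in [0, 1]")
    if (!is.finite(gainRate) || gainRate < 0)
        stop("'gainRate' must be non-negative")
    if (!is.finite(segmentLengthUm) || segmentLengthUm <= 0)
        stop("'segmentLengthUm' must be positive")
    if (!is.null(seed)) set.seed(seed)

    recs <- vector("list", nSegments)
    truths <- vector("list", nSegments)
    for (s in seq_len(nSegments)) {
        segId <- sprintf("seg%03d", s)
        n1 <- spinesPerSegment
        pos1 <- stats::runif(n1, 0, segmentLengthUm)
        surv <- stats::runif(n1) < survivalProb
        nGain <- stats::rpois(1, gainRate * sum(surv))
        posG <- numeric(0)
        for (g in seq_len(nGain)) {
            placed <- FALSE
            for (i in seq_len(10000L)) {
                cand <- stats::runif(1, 0, segmentLengthUm)
                if (length(pos1) == 0 ||
                    min(abs(pos1 - cand)) >= minSeparationUm) {
                    placed <- TRUE
                    break
                }
            }
            if (!placed)
                stop("segment too crowded to place gained spines")
            posG <- c(posG, cand)
        }
        id1 <- sprintf("%s_s1_%03d", segId, seq_len(n1))
        id2stable <- sprintf("%s_s2_%03d", segId, seq_len(sum(surv)))
        id2gain <- sprintf("%s_s2_g%03d", segId, seq_len(nGain))
        s2ids <- c(id2stable, id2gain)
        recs[[s]] <- rbind(
            if (n1 > 0)
                data.frame(segment_id = segId, session = 1L,
                           spine_id = id1, position_um = pos1,
                           stringsAsFactors = FALSE),
            if (length(s2ids) > 0)
                data.frame(segment_id = segId, session = 2L,
                           spine_id = s2ids,
                           position_um = c(pos1[surv], posG),
                           stringsAsFactors = FALSE))
        truths[[s]] <- rbind(
            if (sum(surv) > 0)
                data.frame(segment_id = segId, spine_id_s1 = id1[surv],
                           spine_id_s2 = id2stable, fate = "stable",
                           stringsAsFactors = FALSE),
            if (sum(!surv) > 0)
                data.frame(segment_id = segId, spine_id_s1 = id1[!surv],
                           spine_id_s2 = NA_character_, fate = "lost",
                           stringsAsFactors = FALSE),
            if (nGain > 0)
                data.frame(segment_id = segId, spine_id_s1 = NA_character_,
                           spine_id_s2 = id2gain, fate = "gained",
                           stringsAsFactors = FALSE))
    }
    list(records = do.call(rbind, recs), truth = do.call(rbind, truths))
}

#' Render a dendrite stack with spines of known integrated intensity
#'
#' Builds a synthetic confocal stack containing a two-pixel-wide dendritic
#' shaft (present in every frame) and `nSpines` spine heads, each a 3 x 3
#' pixel blob confined to one frame whose background-free integrated
#' intensity is known exactly, plus a uniform background offset and optional
#' additive Gaussian noise.  Returns matched ground-truth annotations (head /
#' background / shaft masks) so the head-size measurement can be validated by
#' recovery: with a constant shaft the true size of spine j is
#' `spineIntensity[j] / shaftIntensity` AU.
#'
#' @param nSpines number of spines (0 gives shaft + background only).
#' @param spineIntensity true integrated head intensity per spine (recycled).
#' @param shaftIntensity shaft pixel value; a scalar or a profile of length
#'   `nx`.
#' @param backgroundLevel background offset.
#' @param noiseSd additive Gaussian noise SD (intensities are clamped at 0).
#' @param nz,ny,nx stack dimensions; `nx` defaults to the width needed for
#'   the requested spines.
#' @param pixelSizeXY,zStep voxel sizes, um.
#' @param seed optional integer seed.
#' @return list with `stack` ([ImageStack-class]), `annotations` (list of
#'   [SpineAnnotation-class]), and `truth` (data.frame `spine_id`,
#'   `true_integrated`, `true_size_au`).
#' @export
renderDendriteStack <- function(nSpines = 0, spineIntensity = 500,
                                shaftIntensity = 50, backgroundLevel = 10,
                                noiseSd = 0, nz = 7, ny = 48,
                                nx = max(64, 10 * nSpines + 20),
                                pixelSizeXY = 0.2, zStep = 0.5,
                                seed = NULL) {
    if (!is.finite(noiseSd) || noiseSd < 0) stop("'noiseSd' must be >= 0")
    if (any(spineIntensity < 0) || any(shaftIntensity < 0) ||
        backgroundLevel < 0)
        stop("intensities must be non-negative")
    if (nz < 3 || ny < 36 || nx < 10 * nSpines + 14)
        stop("stack too small to contain the requested geometry")
    if (!is.null(seed)) set.seed(seed)
    spineIntensity <- rep_len(spineIntensity, max(nSpines, 1))

    y0 <- 30L  # upper shaft row; head rows 25:27, background rows 10:12
    arr <- array(backgroundLevel, c(nz, ny, nx))
    prof <- rep_len(shaftIntensity, nx)
    for (z in seq_len(nz)) {
        arr[z, y0, ] <- prof
        arr[z, y0 + 1L, ] <- prof
    }
    clean <- arr

    weights <- matrix(c(1, 2, 1, 2, 4, 2, 1, 2, 1) / 16, 3, 3)
    anns <- vector("list", nSpines)
    truth <- data.frame(spine_id = character(), true_integrated = numeric(),
                        true_size_au = numeric(), stringsAsFactors = FALSE)
    zSlots <- if (nz >= 4) 2:(nz - 1) else seq_len(nz)
    for (j in seq_len(nSpines)) {
        xc <- 8L + 10L * (j - 1L)
        zj <- zSlots[((j - 1L) %% length(zSlots)) + 1L]
        ys <- 25:27; xs <- (xc - 1L):(xc + 1L)
        arr[zj, ys, xs] <- arr[zj, ys, xs] + weights * spineIntensity[j]
        clean[zj, ys, xs] <- arr[zj, ys, xs]

        headCoo <- cbind(z = zj, y = rep(ys, times = 3),
                         x = rep(xs, each = 3))
        bgCoo <- cbind(z = zj, y = rep(10:12, times = 3),
                       x = rep(xs, each = 3))
        shX <- max(1L, xc - 4L):min(nx, xc + 4L)
        shCoo <- cbind(z = zj, y = rep(c(y0, y0 + 1L), each = length(shX)),
                       x = rep(shX, times = 2))
        spId <- sprintf("spine%03d", j)
        anns[[j]] <- SpineAnnotation(spId, headCoo, bgCoo, shCoo,
                                     dendriteId = "d1",
                                     positionUm = xc * pixelSizeXY)
        shVals <- sort(clean[shCoo], decreasing = TRUE)
        nTop <- max(1L, ceiling(0.1 * length(shVals)))
        truth <- rbind(truth, data.frame(
            spine_id = spId, true_integrated = spineIntensity[j],
            true_size_au = spineIntensity[j] / mean(shVals[seq_len(nTop)]),
            stringsAsFactors = FALSE))
    }
    if (noiseSd > 0)
        arr <- pmax(arr + stats::rnorm(length(arr), 0, noiseSd), 0)
    list(stack = ImageStack(arr, pixelSizeXY, zStep), annotations = anns,
         truth = truth)
}

#' Simulate trial-structured calcium traces with a blank channel
#'
#' Generates raw fluorescence traces on the standard trial grid (164 samples
#' at 7 Hz by default, stimulus onset at sample 70, 2 s stimulus).  Each
#' responsive cell-odor pair carries a difference-of-exponentials transient
#' (rise 0.1 s, decay 1.5 s by default, resembling GCaMP3 kinetics) whose
#' continuous-time peak equals the requested deltaF/F amplitude; a blank
#' channel with amplitude `blankAmplitude` (default 0) is appended; and
#' Gaussian noise of SD `noiseSd` (in deltaF/F units) is added to every
#' sample.  Note that sampling plus the span-5 smoothing used downstream
#' attenuate the recovered peak slightly below the nominal amplitude.
#'
#' @param nCells number of cells.
#' @param amplitudes numeric matrix `[cell, odor]` of deltaF/F peak
#'   amplitudes (default all 0); a scalar is recycled.
#' @param nOdors odors excluding the blank (default 8).
#' @param trialsPerOdor trials per odor (default 3).
#' @param samplingRate Hz (default 7).
#' @param nSamples samples per trial (default 164).
#' @param stimOnsetSample onset sample (default 70, i.e. ~10 s).
#' @param stimDurationSec stimulus duration, s (default 2).
#' @param riseTauSec,decayTauSec transient kinetics, s.
#' @param noiseSd Gaussian noise SD in deltaF/F units (default 0.05).
#' @param blankAmplitude transient amplitude on the blank channel (default 0).
#' @param baselineF baseline fluorescence (default 100).
#' @param seed optional integer seed.
#' @return a [TrialSet-class]; the ground-truth amplitude matrix is attached
#'   as `attr(, "amplitudes")`.
#' @export
simulateCalciumTrials <- function(nCells, amplitudes = 0, nOdors = 8,
                                  trialsPerOdor = 3, samplingRate = 7,
                                  nSamples = 164, stimOnsetSample = 70,
                                  stimDurationSec = 2, riseTauSec = 0.1,
                                  decayTauSec = 1.5, noiseSd = 0.05,
                                  blankAmplitude = 0, baselineF = 100,
                                  seed = NULL) {
    if (riseTauSec <= 0 || decayTauSec <= 0 || riseTauSec >= decayTauSec)
        stop("kinetics require 0 < riseTauSec < decayTauSec")
    if (samplingRate <= 0) stop("'samplingRate' must be positive")
    if (noiseSd < 0) stop("'noiseSd' must be >= 0")
    if (stimOnsetSample + stimDurationSec * samplingRate >= nSamples)
        stop("stimulus must end before the trial does")
    if (any(amplitudes < 0) || blankAmplitude < 0)
        stop("amplitudes must be >= 0")
    if (!is.null(seed)) set.seed(seed)

    if (!is.matrix(amplitudes))
        amplitudes <- matrix(amplitudes, nCells, nOdors)
    stopifnot(nrow(amplitudes) == nCells, ncol(amplitudes) == nOdors)

    tSec <- (seq_len(nSamples) - stimOnsetSample) / samplingRate
    tPk <- log(decayTauSec / riseTauSec) * riseTauSec * decayTauSec /
        (decayTauSec - riseTauSec)
    hPk <- exp(-tPk / decayTauSec) - exp(-tPk / riseTauSec)
    h <- ifelse(tSec < 0, 0,
                (exp(-tSec / decayTauSec) - exp(-tSec / riseTauSec)) / hPk)

    cells <- sprintf("cell%04d", seq_len(nCells))
    odors <- c(sprintf("odor%d", seq_len(nOdors)), "blank")
    amp <- cbind(amplitudes, blank = rep(blankAmplitude, nCells))
    arr <- array(0, c(nCells, nOdors + 1L, trialsPerOdor, nSamples),
                 dimnames = list(cells, odors, NULL, NULL))
    for (oi in seq_len(nOdors + 1L)) {
        base <- outer(amp[, oi], h)  # cells x samples, deltaF/F
        for (tr in seq_len(trialsPerOdor)) {
            noise <- if (noiseSd > 0)
                matrix(stats::rnorm(nCells * nSamples, 0, noiseSd),
                       nCells, nSamples)
            else 0
            arr[, oi, tr, ] <- baselineF * (1 + base + noise)
        }
    }
    ts <- TrialSet(arr, samplingRate = samplingRate,
                   stimOnsetSample = stimOnsetSample,
                   stimDurationSec = stimDurationSec, blankOdor = "blank")
    attr(ts, "amplitudes") <- amplitudes
    ts
}

#' Render a two-channel microglia / dendrite scene with planted contacts
#'
#' Builds matched dendrite and microglia channels on one voxel grid: a
#' dendritic shaft spanning the stack, `nSpines` spine heads, a configurable
#' number of planted microglia-shaft contacts (every second one spans two
#' adjacent focal planes, exercising the cross-plane merge rule), planted
#' contacts on the first `nContactedSpines` spines, and two distractor
#' microglial processes touching nothing.  Binary masks and intensity
#' renders are both returned, together with the planted truth.
#'
#' @param nSpines number of spines on the dendrite.
#' @param nShaftContacts planted microglia-shaft contacts.
#' @param nContactedSpines number of spines contacted (<= `nSpines`).
#' @param noiseSd Gaussian noise SD added to the intensity channels.
#' @param nz,ny stack dimensions (x is sized from the geometry).
#' @param pixelSizeXY,zStep voxel sizes, um.
#' @param seed optional integer seed.
#' @return list with `dendrite` and `microglia` ([ImageStack-class]),
#'   `shaftMask`, `spineMasks`, `microgliaMask` (logical arrays), and
#'   `truth` (list `nShaftContacts`, `contactedSpineIds`, `nSpines`,
#'   `shaftLengthUm`).
#' @export
renderContactScene <- function(nSpines = 20, nShaftContacts = 5,
                               nContactedSpines = 3, noiseSd = 0, nz = 7,
                               ny = 40, pixelSizeXY = 0.2, zStep = 0.5,
                               seed = NULL) {
    if (nContactedSpines > nSpines)
        stop("cannot contact more spines than exist")
    if (!is.null(seed)) set.seed(seed)
    nSlots <- max(nSpines, nShaftContacts)
    nx <- max(64L, 10L * nSlots + 20L)
    if (10L * nSlots + 14L > nx)
        stop("stack too small for the requested geometry")
    zc <- (nz + 1L) %/% 2L
    y0 <- 20L

    dMask <- array(FALSE, c(nz, ny, nx))
    dMask[, y0:(y0 + 1L), ] <- TRUE  # shaft present in every frame
    spineMasks <- list()
    for (j in seq_len(nSpines)) {
        xs <- (6L + 10L * (j - 1L)):(7L + 10L * (j - 1L))
        m <- array(FALSE, c(nz, ny, nx))
        m[zc, 16:17, xs] <- TRUE
        spineMasks[[sprintf("spine%03d", j)]] <- m
        dMask[zc, 16:17, xs] <- TRUE
    }
    shaftMask <- array(FALSE, c(nz, ny, nx))
    shaftMask[, y0:(y0 + 1L), ] <- TRUE

    mMask <- array(FALSE, c(nz, ny, nx))
    for (k in seq_len(nShaftContacts)) {
        xs <- (11L + 10L * (k - 1L)):(12L + 10L * (k - 1L))
        mMask[zc, y0:(y0 + 1L), xs] <- TRUE
        if (k %% 2L == 1L && zc + 1L <= nz)
            mMask[zc + 1L, y0:(y0 + 1L), xs] <- TRUE
    }
    contacted <- character(0)
    for (j in seq_len(nContactedSpines)) {
        xs <- (6L + 10L * (j - 1L)):(7L + 10L * (j - 1L))
        mMask[zc, 16:17, xs] <- TRUE
        contacted <- c(contacted, sprintf("spine%03d", j))
    }
    mMask[1L, 5:6, 5:8] <- TRUE  # distractors away from the dendrite
    mMask[nz, 32:33, (nx - 8L):(nx - 5L)] <- TRUE

    render <- function(mask) {
        arr <- array(10, dim(mask))
        arr[mask] <- 100
        if (noiseSd > 0)
            arr <- pmax(arr + stats::rnorm(length(arr), 0, noiseSd), 0)
        ImageStack(arr, pixelSizeXY, zStep)
    }
    list(dendrite = render(dMask), microglia = render(mMask),
         shaftMask = shaftMask, spineMasks = spineMasks,
         microgliaMask = mMask,
         truth = list(nShaftContacts = nShaftContacts,
                      contactedSpineIds = contacted, nSpines = nSpines,
                      shaftLengthUm = nx * pixelSizeXY))
}

#' Threshold an intensity stack into a binary mask
#'
#' Fixed-threshold binarizer for rendered fixtures: voxels strictly above
#' `threshold` become `TRUE`.
#'
#' @param stack an [ImageStack-class] or 3-D array.
#' @param threshold intensity cut.
#' @return logical array with the stack's dimensions.
#' @export
binarizeStack <- function(stack, threshold) {
    arr <- if (is(stack, "ImageStack")) intensity(stack) else stack
    arr > threshold
}

#' Read / write spine annotations as JSON
#'
#' @param annotations list of [SpineAnnotation-class] objects.
#' @param path JSON file path.
#' @return `readSpineAnnotations()` a list of `SpineAnnotation`;
#'   `writeSpineAnnotations()` the path, invisibly.
#' @export
writeSpineAnnotations <- function(annotations, path) {
    payload <- lapply(annotations, function(a) list(
        spine_id = a@spineId, dendrite_id = a@dendriteId,
        position_um = a@positionUm, head = unname(a@head),
        background = unname(a@background), shaft = unname(a@shaft)))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeSpineAnnotations
#' @export
readSpineAnnotations <- function(path) {
    payload <- jsonlite::read_json(path, simplifyVector = TRUE)
    lapply(seq_len(nrow(payload)), function(i) {
        row <- payload[i, ]
        SpineAnnotation(row$spine_id, row$head[[1]], row$background[[1]],
                        row$shaft[[1]], dendriteId = row$dendrite_id,
                        positionUm = row$position_um)
    })
}
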