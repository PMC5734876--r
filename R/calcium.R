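#' Moving-average smoothing with shrinking symmetric edge windows
#'
#' Centered moving average of span 5 (by default), the per-trial smoothing
#' applied to raw fluorescence before computing relative changes.  Near the
#' trace ends the window shrinks symmetrically (1, 3, 5, ... points), so the
#' output has the same length as the input and a linear trend passes through
#' unchanged in the interior.
#'
#' @param trace numeric vector.
#' @param span odd window length in samples (default 5).
#' @return smoothed numeric vector, same length.
#' @examples
#' smoothTrace(c(0, 0, 1, 0, 0))  # 0, 1/3, 1/5, 1/3, 0
#' @export
smoothTrace <- function(trace, span = 5L) {
    if (length(span) != 1L || !is.finite(span) || span < 1 || span %% 2 == 0)
        stop("'span' must be a single odd integer >= 1")
    n <- length(trace)
    if (n == 0L) stop("'trace' is empty")
    if (!all(is.finite(trace))) stop("'trace' must be finite")
    k <- (span - 1L) / 2L
    i <- seq_len(n)
    h <- pmin(k, i - 1L, n - i)
    cs <- cumsum(c(0, trace))
    (cs[i + h + 1L] - cs[i - h]) / (2 * h + 1)
}

#' Relative fluorescence change (deltaF/F)
#'
#' `dff(t) = (F(t) - F0) / F0` with the baseline `F0` taken as the mean
#' fluorescence over the `baselineSec` seconds (default 4 s, i.e. 28 samples
#' at 7 Hz) immediately preceding stimulus onset.
#'
#' @param trace numeric fluorescence vector (usually already smoothed).
#' @param onsetSample 1-based stimulus onset sample.
#' @param samplingRate Hz.
#' @param baselineSec baseline window length, s (default 4).
#' @return deltaF/F vector, same length as `trace`.
#' @export
dff <- function(trace, onsetSample, samplingRate, baselineSec = 4) {
    nb <- round(baselineSec * samplingRate)
    if (onsetSample <= nb)
        stop("onset must leave room for the ", baselineSec, " s baseline")
    if (onsetSample > length(trace))
        stop("'onsetSample' beyond the end of the trace")
    f0 <- mean(trace[(onsetSample - nb):(onsetSample - 1L)])
    if (!is.finite(f0) || f0 <= 0)
        stop("baseline fluorescence F0 must be positive")
    (trace - f0) / f0
}

#' Blank-referenced response statistic for one trial
#'
#' The response window starts at stimulus onset and spans the stimulus
#' duration plus `extensionSec` seconds (default 3 s).  The response
#' magnitude is the peak deltaF/F of the odor trace in that window minus the
#' peak of the blank (no-odor) trace in the parallel window; the trial noise
#' is the sample standard deviation of the blank in the window; and
#' `Z = magnitude / noise`.
#'
#' @param odorDff,blankDff deltaF/F traces of an odor trial and the matched
#'   blank trial on the same time grid.
#' @param onsetSample 1-based onset sample.
#' @param samplingRate Hz.
#' @param stimDurationSec stimulus duration, s.
#' @param extensionSec window extension beyond the stimulus, s (default 3).
#' @return list with `magnitude`, `noise`, `z` (`NA` with `zeroNoise = TRUE`
#'   when the blank is flat in the window).
#' @export
responseStatistic <- function(odorDff, blankDff, onsetSample, samplingRate,
                              stimDurationSec, extensionSec = 3) {
    if (length(odorDff) != length(blankDff))
        stop("odor and blank traces must share the time grid")
    wlen <- round((stimDurationSec + extensionSec) * samplingRate)
    w <- onsetSample:(onsetSample + wlen - 1L)
    if (max(w) > length(odorDff))
        stop("response window does not fit inside the trial")
    magnitude <- max(odorDff[w]) - max(blankDff[w])
    noise <- stats::sd(blankDff[w])
    if (noise == 0)
        list(magnitude = magnitude, noise = 0, z = NA_real_,
             zeroNoise = TRUE)
    else
        list(magnitude = magnitude, noise = noise, z = magnitude / noise,
             zeroNoise = FALSE)
}

#' Classify one cell-odor pair as responsive or not
#'
#' Each raw trial (odor and its matched blank trial) is smoothed
#' ([smoothTrace()]), converted to deltaF/F ([dff()]), and scored with
#' [responseStatistic()].  The mean trace is the pointwise mean of the
#' smoothed single-trial deltaF/F traces.  The pair is significant when at
#' least two single trials *and* the mean trace have Z strictly above the
#' threshold (default 2; thresholds between 1.5 and 3 behave similarly on
#' typical data).  The reported response magnitude is the mean-trace
#' magnitude.
#'
#' @param odorTrials,blankTrials numeric matrices `[trial, sample]` of raw
#'   fluorescence; trial `i` of the odor is referenced to blank trial `i`.
#' @param samplingRate Hz.
#' @param onsetSample 1-based stimulus onset sample.
#' @param stimDurationSec stimulus duration, s.
#' @param threshold Z threshold (default 2, strict inequality).
#' @param minTrials minimum trials required, and the number of single-trial
#'   Z exceedances required for significance (default 2).
#' @param baselineSec,extensionSec,smoothSpan see [dff()],
#'   [responseStatistic()], [smoothTrace()].
#' @return list with `zTrials`, `zMean`, `magnitude`, `significant`,
#'   `classifiable`.
#' @export
classifyCellOdor <- function(odorTrials, blankTrials, samplingRate,
                             onsetSample, stimDurationSec, threshold = 2,
                             minTrials = 2, baselineSec = 4,
                             extensionSec = 3, smoothSpan = 5L) {
    odorTrials <- rbind(odorTrials); blankTrials <- rbind(blankTrials)
    nT <- nrow(odorTrials)
    if (nrow(blankTrials) != nT)
        stop("odor and blank must have the same number of trials")
    if (nT < minTrials)
        return(list(zTrials = rep(NA_real_, nT), zMean = NA_real_,
                    magnitude = NA_real_, significant = NA,
                    classifiable = FALSE))
    prep <- function(m) t(apply(m, 1, function(tr)
        dff(smoothTrace(tr, smoothSpan), onsetSample, samplingRate,
            baselineSec)))
    od <- prep(odorTrials); bd <- prep(blankTrials)
    zTrials <- vapply(seq_len(nT), function(i)
        responseStatistic(od[i, ], bd[i, ], onsetSample, samplingRate,
                          stimDurationSec, extensionSec)$z, numeric(1))
    meanStat <- responseStatistic(colMeans(od), colMeans(bd), onsetSample,
                                  samplingRate, stimDurationSec, extensionSec)
    nAbove <- sum(zTrials > threshold, na.rm = TRUE)
    sig <- nAbove >= minTrials && !is.na(meanStat$z) &&
        meanStat$z > threshold
    list(zTrials = zTrials, zMean = meanStat$z,
         magnitude = meanStat$magnitude, significant = sig,
         classifiable = TRUE)
}

#' Classify every cell-odor pair of a TrialSet
#'
#' Applies [classifyCellOdor()] to every non-blank odor of every cell.
#'
#' @param trialSet a [TrialSet-class].
#' @param threshold,minTrials,baselineSec,extensionSec,smoothSpan see
#'   [classifyCellOdor()].
#' @return data.frame with one row per cell-odor pair: `cell_id`, `odor`,
#'   `z_mean`, `magnitude`, `n_trials_above`, `significant`, plus a
#'   `z_trials` list-column of per-trial Z scores.
#' @export
classifyResponses <- function(trialSet, threshold = 2, minTrials = 2,
                              baselineSec = 4, extensionSec = 3,
                              smoothSpan = 5L) {
    stopifnot(is(trialSet, "TrialSet"))
    tr <- trialSet@traces
    cells <- dimnames(tr)[[1]]; odors <- dimnames(tr)[[2]]
    blank <- trialSet@blankOdor
    rows <- vector("list", length(cells) * (length(odors) - 1L))
    k <- 0L
    for (ci in seq_along(cells)) {
        blankTr <- matrix(tr[ci, blank, , ], nrow = dim(tr)[3])
        for (od in setdiff(odors, blank)) {
            odorTr <- matrix(tr[ci, od, , ], nrow = dim(tr)[3])
            cl <- classifyCellOdor(odorTr, blankTr, trialSet@samplingRate,
                                   trialSet@stimOnsetSample,
                                   trialSet@stimDurationSec, threshold,
                                   minTrials, baselineSec, extensionSec,
                                   smoothSpan)
            k <- k + 1L
            rows[[k]] <- data.frame(
                cell_id = cells[ci], odor = od, z_mean = cl$zMean,
                magnitude = cl$magnitude,
                n_trials_above = sum(cl$zTrials > threshold, na.rm = TRUE),
                significant = cl$significant, stringsAsFactors = FALSE)
            rows[[k]]$z_trials <- I(list(cl$zTrials))
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Quality-control filter for imaged cells
#'
#' A cell is excluded when any of its blank trials shows a deltaF/F above
#' `blankLimit` (default 0.3) inside the response window (a blank "response"
#' means the null reference is unusable), or, failing that, when any trial of
#' any odor shows an absolute deltaF/F excursion above `preStimLimit`
#' (default 0.5) before stimulus onset (an acquisition artifact).
#'
#' @param trialSet a [TrialSet-class].
#' @param blankLimit blank-response threshold, deltaF/F.
#' @param preStimLimit pre-stimulus artifact threshold, |deltaF/F|.
#' @param baselineSec,extensionSec,smoothSpan as in [classifyCellOdor()].
#' @return data.frame `cell_id`, `excluded`, `reason` (one of
#'   `"blank_response"`, `"pre_stim_artifact"`, `"none"`).
#' @export
qcFilter <- function(trialSet, blankLimit = 0.3, preStimLimit = 0.5,
                     baselineSec = 4, extensionSec = 3, smoothSpan = 5L) {
    stopifnot(is(trialSet, "TrialSet"))
    tr <- trialSet@traces
    cells <- dimnames(tr)[[1]]; odors <- dimnames(tr)[[2]]
    onset <- trialSet@stimOnsetSample
    rate <- trialSet@samplingRate
    wlen <- round((trialSet@stimDurationSec + extensionSec) * rate)
    w <- onset:(onset + wlen - 1L)
    pre <- seq_len(onset - 1L)
    out <- lapply(seq_along(cells), function(ci) {
        dffs <- lapply(odors, function(od) {
            m <- matrix(tr[ci, od, , ], nrow = dim(tr)[3])
            t(apply(m, 1, function(x)
                dff(smoothTrace(x, smoothSpan), onset, rate, baselineSec)))
        })
        names(dffs) <- odors
        reason <- "none"
        if (any(dffs[[trialSet@blankOdor]][, w] > blankLimit))
            reason <- "blank_response"
        else if (any(vapply(dffs, function(d)
                 any(abs(d[, pre, drop = FALSE]) > preStimLimit),
                 logical(1))))
            reason <- "pre_stim_artifact"
        data.frame(cell_id = cells[ci], excluded = reason != "none",
                   reason = reason, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Population summaries of response calls
#'
#' From a table of per-pair response calls (see [classifyResponses()])
#' computes (a) the tuning breadth of every cell -- the number of odors with
#' a significant call -- with its distribution and cumulative distribution
#' over 0..`nOdors`, and (b) the response magnitudes of all significant
#' pairs, the quantities compared across imaging sessions at the population
#' level.
#'
#' @param calls data.frame from [classifyResponses()].
#' @param nOdors number of odors presented (default: number of distinct
#'   odors in `calls`).
#' @return list with `breadth` (data.frame `cell_id`, `n_responsive`),
#'   `breadthDistribution` (data.frame `n_odors`, `proportion`,
#'   `cumulative`), and `magnitudes` (numeric vector over significant pairs).
#' @export
populationSummary <- function(calls, nOdors = NULL) {
    if (nrow(calls) == 0L) stop("empty call set")
    if (is.null(nOdors)) nOdors <- length(unique(calls$odor))
    breadth <- stats::aggregate(significant ~ cell_id, data = calls,
                                FUN = function(s) sum(s, na.rm = TRUE))
    names(breadth)[2] <- "n_responsive"
    counts <- vapply(0:nOdors, function(k) sum(breadth$n_responsive == k),
                     numeric(1))
    prop <- counts / nrow(breadth)
    list(breadth = breadth,
         breadthDistribution = data.frame(n_odors = 0:nOdors,
                                          proportion = prop,
                                          cumulative = cumsum(prop)),
         magnitudes = calls$magnitude[calls$significant %in% TRUE])
}

#' Paired cell-odor responses across two imaging sessions
#'
#' For cells re-identified in both sessions, keeps the cell-odor pairs that
#' were significant in at least one session and reports both magnitudes plus
#' the group change in mean magnitude as a percentage of the first session.
#'
#' @param callsPre,callsPost call tables from [classifyResponses()] for the
#'   two sessions.
#' @param cellMap optional data.frame `cell_id_pre`, `cell_id_post` mapping
#'   re-identified cells; by default cells are matched by identical id.
#' @return list with `pairs` (data.frame `cell_id_pre`, `cell_id_post`,
#'   `odor`, `magnitude_pre`, `magnitude_post`) and `percentChange`
#'   (100 x (mean post - mean pre) / mean pre over the retained pair set).
#' @export
pairedResponses <- function(callsPre, callsPost, cellMap = NULL) {
    if (is.null(cellMap)) {
        shared <- intersect(callsPre$cell_id, callsPost$cell_id)
        cellMap <- data.frame(cell_id_pre = shared, cell_id_post = shared,
                              stringsAsFactors = FALSE)
    }
    pre <- merge(callsPre[, c("cell_id", "odor", "magnitude", "significant")],
                 cellMap, by.x = "cell_id", by.y = "cell_id_pre")
    names(pre)[names(pre) == "cell_id"] <- "cell_id_pre"
    post <- callsPost[, c("cell_id", "odor", "magnitude", "significant")]
    names(post) <- c("cell_id_post", "odor", "magnitude_post",
                     "significant_post")
    both <- merge(pre, post, by = c("cell_id_post", "odor"))
    keep <- both$significant %in% TRUE | both$significant_post %in% TRUE
    both <- both[keep, , drop = FALSE]
    pairs <- data.frame(cell_id_pre = both$cell_id_pre,
                        cell_id_post = both$cell_id_post, odor = both$odor,
                        magnitude_pre = both$magnitude,
                        magnitude_post = both$magnitude_post,
                        stringsAsFactors = FALSE)
    pc <- if (nrow(pairs) > 0)
        100 * (mean(pairs$magnitude_post) - mean(pairs$magnitude_pre)) /
            mean(pairs$magnitude_pre)
    else NA_real_
    list(pairs = pairs, percentChange = pc)
}

#' Read / write trial tables as CSV
#'
#' Long-format interchange for trial-structured calcium traces: columns
#' `cell_id`, `odor`, `trial`, `sample_index`, `fluorescence`.  Timing
#' metadata travels in a small YAML file with fields `sampling_rate_hz`,
#' `stim_onset_sample`, `stim_duration_sec`, `blank_odor`.
#'
#' @param trialSet a [TrialSet-class].
#' @param path CSV path.
#' @param configPath optional YAML path for the timing metadata.
#' @return `readTrialSet()` a `TrialSet`; `writeTrialSet()` the CSV path,
#'   invisibly.
#' @export
writeTrialSet <- function(trialSet, path, configPath = NULL) {
    tr <- trialSet@traces
    dn <- dimnames(tr)
    d <- dim(tr)
    long <- expand.grid(cell_id = dn[[1]], odor = dn[[2]],
                        trial = seq_len(d[3]), sample_index = seq_len(d[4]),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    long$fluorescence <- as.vector(tr)
    utils::write.csv(long, path, row.names = FALSE)
    if (!is.null(configPath))
        yaml::write_yaml(list(sampling_rate_hz = trialSet@samplingRate,
                              stim_onset_sample = trialSet@stimOnsetSample,
                              stim_duration_sec = trialSet@stimDurationSec,
                              blank_odor = trialSet@blankOdor), configPath)
    invisible(path)
}

#' @rdname writeTrialSet
#' @param samplingRate,stimOnsetSample,stimDurationSec,blankOdor timing
#'   metadata, used when no `configPath` is given.
#' @export
readTrialSet <- function(path, configPath = NULL, samplingRate = 7,
                         stimOnsetSample = 70, stimDurationSec = 2,
                         blankOdor = "blank") {
    if (!is.null(configPath)) {
        cfg <- yaml::read_yaml(configPath)
        samplingRate <- cfg$sampling_rate_hz
        stimOnsetSample <- cfg$stim_onset_sample
        stimDurationSec <- cfg$stim_duration_sec
        blankOdor <- cfg$blank_odor
    }
    long <- utils::read.csv(path, stringsAsFactors = FALSE)
    cells <- unique(long$cell_id); odors <- unique(long$odor)
    trials <- sort(unique(long$trial)); samples <- sort(unique(long$sample_index))
    arr <- array(NA_real_,
                 c(length(cells), length(odors), length(trials),
                   length(samples)),
                 dimnames = list(cells, odors, NULL, NULL))
    idx <- cbind(match(long$cell_id, cells), match(long$odor, odors),
                 match(long$trial, trials),
                 match(long$sample_index, samples))
    arr[idx] <- long$fluorescence
    if (anyNA(arr))
        stop("trial table does not cover the full cell x odor x trial x sample grid")
    TrialSet(arr, samplingRate = samplingRate,
             stimOnsetSample = stimOnsetSample,
             stimDurationSec = stimDurationSec, blankOdor = blankOdor)
}
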