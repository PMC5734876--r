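#' Match spines across two imaging sessions by position
#'
#' One-to-one matching of spine records from two sessions of the same
#' dendritic segment, using arc-length positions on a common frame.  Among
#' all matchings whose pairs lie within `radius`, the one with the maximum
#' number of pairs is chosen, and among those the one with the smallest total
#' distance.  Because positions live on a line and all pairs share one
#' radius, an optimal matching is non-crossing, so it is found exactly by
#' dynamic programming over the position-sorted records (ties in position
#' are ordered by spine id, making the result deterministic).  A
#' consequence worth noting: records at identical positions are always
#' paired with each other.  Unmatched session-1 records correspond to lost
#' spines, unmatched session-2 records to gained spines.
#'
#' @param session1,session2 data.frames with columns `spine_id` and
#'   `position_um` (an optional `segment_id` column must be constant and
#'   shared between the two sessions).
#' @param radius maximum matching distance in um (default 1.0, about the
#'   lateral resolution limit for telling neighbouring spines apart).
#' @return list with `pairs` (data.frame `id1`, `id2`, `distance`; ordered
#'   by position along the segment), `lostIds` and `gainedIds`.
#' @export
matchSpines <- function(session1, session2, radius = 1.0) {
    chk <- function(d, nm) {
        if (!all(c("spine_id", "position_um") %in% names(d)))
            stop(sprintf("'%s' needs columns spine_id and position_um", nm))
        if (nrow(d) > 0 && !all(is.finite(d$position_um)))
            stop(sprintf("'%s' has non-finite positions", nm))
    }
    chk(session1, "session1"); chk(session2, "session2")
    segs <- unique(c(session1$segment_id, session2$segment_id))
    if (length(segs) > 1L)
        stop("records from mixed segments; match one segment at a time")
    if (!is.finite(radius) || radius < 0)
        stop("'radius' must be non-negative")

    n1 <- nrow(session1); n2 <- nrow(session2)
    pairs <- data.frame(id1 = character(), id2 = character(),
                        distance = numeric(), stringsAsFactors = FALSE)
    if (n1 > 0 && n2 > 0) {
        o1 <- order(session1$position_um, as.character(session1$spine_id))
        o2 <- order(session2$position_um, as.character(session2$spine_id))
        p1 <- session1$position_um[o1]; p2 <- session2$position_um[o2]
        ## dp over sorted prefixes: maximize pair count, then minimize total
        ## distance; transitions: pair i-j (if within radius), skip j, skip i
        cnt <- matrix(0L, n1 + 1L, n2 + 1L)
        cost <- matrix(0, n1 + 1L, n2 + 1L)
        move <- matrix(0L, n1 + 1L, n2 + 1L)  # 1 pair, 2 skip j, 3 skip i
        for (i in seq_len(n1)) {
            for (j in seq_len(n2)) {
                bc <- cnt[i, j + 1L]; bco <- cost[i, j + 1L]; mv <- 3L
                if (cnt[i + 1L, j] > bc ||
                    (cnt[i + 1L, j] == bc && cost[i + 1L, j] < bco)) {
                    bc <- cnt[i + 1L, j]; bco <- cost[i + 1L, j]; mv <- 2L
                }
                d <- abs(p1[i] - p2[j])
                if (d <= radius) {
                    pc <- cnt[i, j] + 1L; pco <- cost[i, j] + d
                    if (pc > bc || (pc == bc && pco < bco)) {
                        bc <- pc; bco <- pco; mv <- 1L
                    }
                }
                cnt[i + 1L, j + 1L] <- bc
                cost[i + 1L, j + 1L] <- bco
                move[i + 1L, j + 1L] <- mv
            }
        }
        i <- n1; j <- n2
        m1 <- integer(0); m2 <- integer(0)
        while (i > 0L && j > 0L) {
            mv <- move[i + 1L, j + 1L]
            if (mv == 1L) {
                m1 <- c(i, m1); m2 <- c(j, m2)
                i <- i - 1L; j <- j - 1L
            } else if (mv == 2L) j <- j - 1L
            else i <- i - 1L
        }
        if (length(m1) > 0)
            pairs <- data.frame(
                id1 = as.character(session1$spine_id)[o1[m1]],
                id2 = as.character(session2$spine_id)[o2[m2]],
                distance = abs(p1[m1] - p2[m2]), stringsAsFactors = FALSE)
    }
    list(pairs = pairs,
         lostIds = setdiff(as.character(session1$spine_id), pairs$id1),
         gainedIds = setdiff(as.character(session2$spine_id), pairs$id2))
}

#' Classify spine fates from a two-session matching
#'
#' Matched spines are stable, unmatched session-1 spines are lost, unmatched
#' session-2 spines are gained.
#'
#' @param matching result of [matchSpines()].
#' @return list with `counts` (data.frame `n_stable`, `n_lost`, `n_gained`)
#'   and `labels` (data.frame `spine_id_s1`, `spine_id_s2`, `fate`).
#' @export
classifyFates <- function(matching) {
    if (!is.list(matching) ||
        !all(c("pairs", "lostIds", "gainedIds") %in% names(matching)))
        stop("'matching' must be the result of matchSpines()")
    p <- matching$pairs
    labels <- rbind(
        if (nrow(p) > 0)
            data.frame(spine_id_s1 = p$id1, spine_id_s2 = p$id2,
                       fate = "stable", stringsAsFactors = FALSE),
        if (length(matching$lostIds) > 0)
            data.frame(spine_id_s1 = matching$lostIds,
                       spine_id_s2 = NA_character_, fate = "lost",
                       stringsAsFactors = FALSE),
        if (length(matching$gainedIds) > 0)
            data.frame(spine_id_s1 = NA_character_,
                       spine_id_s2 = matching$gainedIds, fate = "gained",
                       stringsAsFactors = FALSE))
    if (is.null(labels))
        labels <- data.frame(spine_id_s1 = character(),
                             spine_id_s2 = character(), fate = character(),
                             stringsAsFactors = FALSE)
    list(counts = data.frame(n_stable = nrow(p),
                             n_lost = length(matching$lostIds),
                             n_gained = length(matching$gainedIds)),
         labels = labels)
}

#' Build a per-segment fate table from two-session spine records
#'
#' Runs [matchSpines()] and [classifyFates()] on every dendritic segment of a
#' long-format record table and assembles the fate counts.  Segments with no
#' spines in either session are dropped with a message.
#'
#' @param records data.frame with columns `segment_id`, `session` (1 or 2),
#'   `spine_id`, `position_um`.
#' @param radius matching radius in um.
#' @return data.frame with one row per segment: `segment_id`, `n_stable`,
#'   `n_lost`, `n_gained`, `n_session1`, `n_session2`.
#' @export
spineFateTable <- function(records, radius = 1.0) {
    need <- c("segment_id", "session", "spine_id", "position_um")
    if (!all(need %in% names(records)))
        stop("'records' needs columns ", paste(need, collapse = ", "))
    if (!all(records$session %in% c(1, 2)))
        stop("'session' must be 1 or 2")
    segs <- unique(records$segment_id)
    rows <- lapply(segs, function(s) {
        seg <- records[records$segment_id == s, , drop = FALSE]
        m <- matchSpines(seg[seg$session == 1, , drop = FALSE],
                         seg[seg$session == 2, , drop = FALSE],
                         radius = radius)
        cf <- classifyFates(m)$counts
        cbind(data.frame(segment_id = s, stringsAsFactors = FALSE), cf)
    })
    tab <- do.call(rbind, rows)
    tab$n_session1 <- tab$n_stable + tab$n_lost
    tab$n_session2 <- tab$n_stable + tab$n_gained
    empty <- tab$n_session1 + tab$n_session2 == 0
    if (any(empty)) {
        message(sum(empty), " segment(s) with no spines in either session dropped")
        tab <- tab[!empty, , drop = FALSE]
    }
    rownames(tab) <- NULL
    tab
}

#' Per-segment fate fractions with group summary
#'
#' Fractions follow the session-wise denominators used for time-lapse spine
#' scoring: stable = Nstable/(Nstable + Nlost), lost = Nlost/(Nstable +
#' Nlost), gained = Ngained/(Nstable + Ngained).  Segments with a zero
#' denominator yield `NA` for the affected fraction, are excluded from the
#' group summary, and trigger a warning.
#'
#' @param fateTable data.frame as returned by [spineFateTable()] (columns
#'   `n_stable`, `n_lost`, `n_gained`; `segment_id` optional).
#' @return list with `perSegment` (the table plus `frac_stable`, `frac_lost`,
#'   `frac_gained`) and `summary` (data.frame `category`, `mean`, `sem`, `n`
#'   across segments).
#' @export
fateFractions <- function(fateTable) {
    need <- c("n_stable", "n_lost", "n_gained")
    if (!all(need %in% names(fateTable)))
        stop("'fateTable' needs columns ", paste(need, collapse = ", "))
    ft <- fateTable
    den1 <- ft$n_stable + ft$n_lost
    den2 <- ft$n_stable + ft$n_gained
    if (any(den1 == 0) || any(den2 == 0))
        warning("zero denominators: affected fractions set to NA and excluded from the summary")
    ft$frac_stable <- ifelse(den1 > 0, ft$n_stable / den1, NA_real_)
    ft$frac_lost <- ifelse(den1 > 0, ft$n_lost / den1, NA_real_)
    ft$frac_gained <- ifelse(den2 > 0, ft$n_gained / den2, NA_real_)
    sem <- function(x) stats::sd(x) / sqrt(length(x))
    summ <- do.call(rbind, lapply(
        c(stable = "frac_stable", lost = "frac_lost", gained = "frac_gained"),
        function(col) {
            v <- ft[[col]][!is.na(ft[[col]])]
            data.frame(mean = mean(v), sem = sem(v), n = length(v))
        }))
    summ <- cbind(data.frame(category = c("stable", "lost", "gained"),
                             stringsAsFactors = FALSE), summ)
    rownames(summ) <- NULL
    list(perSegment = ft, summary = summ)
}

#' Spine turnover rate (TOR)
#'
#' TOR = (Nlost + Ngained) / (Ntotal session 1 + Ntotal session 2), computed
#' per dendritic segment; the group statistic is the mean across segments
#' with its SEM (segments are the unit of analysis).  A pooled TOR over all
#' spines is also reported for transparency.  TOR is bounded in `[0, 1]` and
#' is 0 exactly when no spine was lost or gained.
#'
#' @param fateTable data.frame as returned by [spineFateTable()].
#' @return list with `perSegment` (the table plus a `tor` column), `mean`,
#'   `sem`, `n` (segments) and `pooled`.
#' @examples
#' turnoverRate(data.frame(n_stable = 7, n_lost = 3, n_gained = 2))$mean
#' # 5/19
#' @export
turnoverRate <- function(fateTable) {
    need <- c("n_stable", "n_lost", "n_gained")
    if (!all(need %in% names(fateTable)))
        stop("'fateTable' needs columns ", paste(need, collapse = ", "))
    ft <- fateTable
    n1 <- ft$n_stable + ft$n_lost
    n2 <- ft$n_stable + ft$n_gained
    empty <- n1 + n2 == 0
    if (any(empty)) {
        warning(sum(empty), " empty segment(s) excluded from TOR")
        ft <- ft[!empty, , drop = FALSE]
        n1 <- n1[!empty]; n2 <- n2[!empty]
    }
    ft$tor <- (ft$n_lost + ft$n_gained) / (n1 + n2)
    list(perSegment = ft, mean = mean(ft$tor),
         sem = stats::sd(ft$tor) / sqrt(nrow(ft)), n = nrow(ft),
         pooled = sum(ft$n_lost + ft$n_gained) / sum(n1 + n2))
}

#' Read / write two-session spine record CSVs
#'
#' Long-format interchange for time-lapse spine records: one row per spine
#' per session with columns `segment_id`, `session`, `spine_id`,
#' `position_um`.
#'
#' @param path CSV file path.
#' @param records data.frame in the format above.
#' @return `readSpineRecords()` a data.frame; `writeSpineRecords()` the path,
#'   invisibly.
#' @export
readSpineRecords <- function(path) {
    rec <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("segment_id", "session", "spine_id", "position_um")
    if (!all(need %in% names(rec)))
        stop("record CSV needs columns ", paste(need, collapse = ", "))
    rec
}

#' @rdname readSpineRecords
#' @export
writeSpineRecords <- function(records, path) {
    utils::write.csv(records, path, row.names = FALSE)
    invisible(path)
}
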