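# Independent brute-force oracles used to cross-check the implementation.
# These deliberately take the slowest, most literal route.

# per-pixel sorted-window median with the window clipped at the borders
bruteMedianFilter <- function(frame, size = 3L) {
    k <- (size - 1L) / 2L
    ny <- nrow(frame); nx <- ncol(frame)
    out <- frame
    for (y in seq_len(ny)) {
        for (x in seq_len(nx)) {
            ys <- max(1, y - k):min(ny, y + k)
            xs <- max(1, x - k):min(nx, x + k)
            v <- sort(as.vector(frame[ys, xs]))
            n <- length(v)
            out[y, x] <- if (n %% 2 == 1) v[(n + 1) / 2]
                         else (v[n / 2] + v[n / 2 + 1]) / 2
        }
    }
    out
}

# sup |ECDF_a - ECDF_b| evaluated at every pooled point
bruteKS <- function(a, b) {
    pooled <- sort(unique(c(a, b)))
    max(vapply(pooled, function(t)
        abs(mean(a <= t) - mean(b <= t)), numeric(1)))
}

# maximum bipartite matching cardinality under the radius constraint,
# by exhaustive branch and bound
bruteMaxMatching <- function(p1, p2, radius) {
    n1 <- length(p1); n2 <- length(p2)
    if (n1 == 0 || n2 == 0) return(0L)
    adj <- abs(outer(p1, p2, "-")) <= radius
    best <- 0L
    rec <- function(i, used, cnt) {
        if (cnt + (n1 - i + 1) <= best) return()
        if (i > n1) { best <<- max(best, cnt); return() }
        for (j in which(adj[i, ] & !used)) {
            used[j] <- TRUE
            rec(i + 1, used, cnt + 1L)
            used[j] <- FALSE
        }
        rec(i + 1, used, cnt)
    }
    rec(1L, rep(FALSE, n2), 0L)
    best
}

# contact events by the literal two-stage rule: flood-fill 8-connected
# components per z-plane, then merge components of consecutive planes that
# share a (y, x) column; returns the sorted event voxel counts
bruteContactEvents <- function(overlap) {
    nz <- dim(overlap)[1]
    planeComps <- list()  # each: list(z=, cells=matrix(y,x))
    for (z in seq_len(nz)) {
        m <- overlap[z, , ]
        lab <- matrix(0L, nrow(m), ncol(m))
        cur <- 0L
        for (y in seq_len(nrow(m))) for (x in seq_len(ncol(m))) {
            if (m[y, x] && lab[y, x] == 0L) {
                cur <- cur + 1L
                queue <- list(c(y, x)); lab[y, x] <- cur
                while (length(queue)) {
                    p <- queue[[1]]; queue <- queue[-1]
                    for (dy in -1:1) for (dx in -1:1) {
                        yy <- p[1] + dy; xx <- p[2] + dx
                        if (yy >= 1 && yy <= nrow(m) && xx >= 1 &&
                            xx <= ncol(m) && m[yy, xx] &&
                            lab[yy, xx] == 0L) {
                            lab[yy, xx] <- cur
                            queue <- c(queue, list(c(yy, xx)))
                        }
                    }
                }
            }
        }
        for (cc in seq_len(cur)) {
            cells <- which(lab == cc, arr.ind = TRUE)
            planeComps[[length(planeComps) + 1L]] <-
                list(z = z, cells = cells)
        }
    }
    n <- length(planeComps)
    if (n == 0L) return(integer(0))
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (abs(planeComps[[i]]$z - planeComps[[j]]$z) == 1L) {
            ki <- paste(planeComps[[i]]$cells[, 1],
                        planeComps[[i]]$cells[, 2])
            kj <- paste(planeComps[[j]]$cells[, 1],
                        planeComps[[j]]$cells[, 2])
            if (length(intersect(ki, kj)) > 0) {
                ri <- find(i); rj <- find(j)
                if (ri != rj) parent[ri] <- rj
            }
        }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    sizes <- tapply(vapply(planeComps, function(p) nrow(p$cells),
                           integer(1)), roots, sum)
    sort(as.integer(sizes))
}

# split-plot interaction F from first-principles sums of squares
bruteMixedAnovaF <- function(d) {
    grand <- mean(d$value)
    cats <- levels(factor(d$category)); grps <- levels(factor(d$group))
    subjs <- unique(d$subject)
    c <- length(cats); g <- length(grps); nS <- length(subjs)
    ssTotal <- sum((d$value - grand)^2)
    subjMean <- tapply(d$value, d$subject, mean)
    ssSubj <- c * sum((subjMean - grand)^2)
    grpMean <- tapply(d$value, d$group, mean)
    nPerGrp <- table(d$group) / c
    ssGroup <- c * sum(nPerGrp * (grpMean - grand)^2)
    catMean <- tapply(d$value, d$category, mean)
    ssCat <- nS * sum((catMean - grand)^2)
    cellMean <- tapply(d$value, list(d$group, d$category), mean)
    ssInt <- 0
    for (gi in grps) for (ci in cats) {
        nCell <- sum(d$group == gi & d$category == ci)
        ssInt <- ssInt + nCell * (cellMean[gi, ci] - grpMean[gi] -
                                  catMean[ci] + grand)^2
    }
    ssWithin <- ssTotal - ssSubj
    ssErr <- ssWithin - ssCat - ssInt
    df1 <- (g - 1) * (c - 1)
    df2 <- (nS - g) * (c - 1)
    list(F = as.numeric((ssInt / df1) / (ssErr / df2)), df1 = df1,
         df2 = df2)
}
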