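test_that("matching pairs identical sessions completely and disjoint ones not at all", {
    s <- data.frame(spine_id = paste0("a", 1:6),
                    position_um = c(1, 3, 5.5, 9, 12, 20))
    s2 <- s; s2$spine_id <- paste0("b", 1:6)
    m <- matchSpines(s, s2)
    expect_equal(nrow(m$pairs), 6)
    expect_length(m$lostIds, 0)
    expect_length(m$gainedIds, 0)
    expect_true(all(m$pairs$distance == 0))

    far <- data.frame(spine_id = paste0("c", 1:3),
                      position_um = c(40, 50, 60))
    m2 <- matchSpines(s, far)
    expect_equal(nrow(m2$pairs), 0)
    expect_setequal(m2$lostIds, s$spine_id)
    expect_setequal(m2$gainedIds, far$spine_id)

    sMixed <- s; sMixed$segment_id <- c(rep("x", 5), "y")
    expect_error(matchSpines(sMixed, s2), "mixed")
})

test_that("matched-pair count equals the optimal bipartite cardinality", {
    set.seed(17)
    for (rep in 1:100) {
        n1 <- sample(0:8, 1); n2 <- sample(0:8, 1)
        p1 <- runif(n1, 0, 10); p2 <- runif(n2, 0, 10)
        s1 <- data.frame(
            spine_id = if (n1 > 0) paste0("a", 1:n1) else character(0),
            position_um = p1)
        s2 <- data.frame(
            spine_id = if (n2 > 0) paste0("b", 1:n2) else character(0),
            position_um = p2)
        m <- matchSpines(s1, s2, radius = 1.0)
        expect_identical(nrow(m$pairs),
                         as.integer(bruteMaxMatching(p1, p2, 1.0)))
        # all pairs respect the radius
        if (nrow(m$pairs) > 0)
            expect_true(all(m$pairs$distance <= 1.0))
    }
})

test_that("fate classification follows matched/unmatched status", {
    m <- list(pairs = data.frame(id1 = paste0("a", 1:7),
                                 id2 = paste0("b", 1:7),
                                 distance = rep(0, 7)),
              lostIds = paste0("a", 8:10), gainedIds = paste0("b", 8:9))
    cf <- classifyFates(m)
    expect_equal(unlist(cf$counts), c(n_stable = 7, n_lost = 3,
                                      n_gained = 2))
    empty <- classifyFates(list(pairs = data.frame(id1 = character(),
                                                   id2 = character(),
                                                   distance = numeric()),
                                lostIds = character(),
                                gainedIds = character()))
    expect_equal(unlist(empty$counts), c(n_stable = 0, n_lost = 0,
                                         n_gained = 0))
})

test_that("classified fates equal planted labels on jitter-free cohorts", {
    sim <- simulateSpineSessions(80, 30, 0.7, 0.557, seed = 23)
    key <- function(d) sort(paste(d$spine_id_s1, d$spine_id_s2, d$fate))
    for (s in unique(sim$records$segment_id)) {
        seg <- sim$records[sim$records$segment_id == s, ]
        cf <- classifyFates(matchSpines(seg[seg$session == 1, ],
                                        seg[seg$session == 2, ]))
        tr <- sim$truth[sim$truth$segment_id == s,
                        c("spine_id_s1", "spine_id_s2", "fate")]
        expect_identical(key(cf$labels), key(tr))
    }
})

test_that("fate fractions implement the session-wise denominators", {
    ft <- data.frame(n_stable = 7, n_lost = 3, n_gained = 2)
    ff <- fateFractions(ft)
    expect_equal(ff$perSegment$frac_stable, 0.7)
    expect_equal(ff$perSegment$frac_lost, 0.3)
    expect_equal(ff$perSegment$frac_gained, 2 / 9)

    allStable <- fateFractions(data.frame(n_stable = 11, n_lost = 0,
                                          n_gained = 0))
    expect_equal(allStable$perSegment$frac_stable, 1)
    expect_equal(allStable$perSegment$frac_gained, 0)

    expect_warning(
        zz <- fateFractions(data.frame(n_stable = c(0, 5),
                                       n_lost = c(0, 5),
                                       n_gained = c(2, 0))),
        "denominator")
    expect_true(is.na(zz$perSegment$frac_stable[1]))
    expect_equal(zz$summary$n[zz$summary$category == "stable"], 1)

    # stable + lost share a denominator and always sum to one
    sim <- simulateSpineSessions(40, 25, 0.6, 0.4, seed = 31)
    ffs <- fateFractions(spineFateTable(sim$records))$perSegment
    expect_equal(ffs$frac_stable + ffs$frac_lost, rep(1, nrow(ffs)))
})

test_that("turnover rate follows its definition and bounds", {
    ft <- data.frame(n_stable = 7, n_lost = 3, n_gained = 2)
    expect_equal(turnoverRate(ft)$mean, 5 / 19)
    expect_equal(turnoverRate(data.frame(n_stable = 9, n_lost = 0,
                                         n_gained = 0))$mean, 0)
    expect_equal(turnoverRate(data.frame(n_stable = 0, n_lost = 4,
                                         n_gained = 3))$mean, 1)
    expect_warning(turnoverRate(data.frame(n_stable = c(3, 0),
                                           n_lost = c(1, 0),
                                           n_gained = c(0, 0))), "empty")

    sim <- simulateSpineSessions(60, 20, 0.5, 0.8, seed = 37)
    tor <- turnoverRate(spineFateTable(sim$records))
    expect_true(all(tor$perSegment$tor >= 0 & tor$perSegment$tor <= 1))
    expect_true(all((tor$perSegment$tor == 0) ==
                    (tor$perSegment$n_lost + tor$perSegment$n_gained == 0)))
})

test_that("counts are invariant to record order", {
    sim <- simulateSpineSessions(10, 15, 0.7, 0.5, seed = 41)
    ft1 <- spineFateTable(sim$records)
    set.seed(41)
    shuffled <- sim$records[sample(nrow(sim$records)), ]
    ft2 <- spineFateTable(shuffled)
    ft2 <- ft2[match(ft1$segment_id, ft2$segment_id), ]
    rownames(ft2) <- NULL
    expect_equal(ft1, ft2)
})

test_that("survival probability is recovered across generative regimes", {
    for (surv in c(0.5, 0.7, 0.85)) {
        sim <- simulateSpineSessions(200, 30, surv, 0.3,
                                     seed = round(1000 * surv))
        ff <- fateFractions(spineFateTable(sim$records))
        est <- ff$summary$mean[ff$summary$category == "stable"]
        sem <- ff$summary$sem[ff$summary$category == "stable"]
        expect_lt(abs(est - surv), 2 * sem + 1e-12)
    }
})
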