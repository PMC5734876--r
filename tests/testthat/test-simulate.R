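test_that("spine-session generator honours degenerate parameter regimes", {
    allStable <- simulateSpineSessions(5, 12, survivalProb = 1, gainRate = 0,
                                       seed = 1)
    expect_true(all(allStable$truth$fate == "stable"))
    expect_equal(sum(allStable$records$session == 2), 5 * 12)

    allLost <- simulateSpineSessions(5, 12, survivalProb = 0, gainRate = 0,
                                     seed = 1)
    expect_true(all(allLost$truth$fate == "lost"))
    expect_equal(sum(allLost$records$session == 2), 0)
})

test_that("spine-session generator rejects invalid configurations", {
    expect_error(simulateSpineSessions(5, 10, 1.2, 0.5), "survivalProb")
    expect_error(simulateSpineSessions(5, 10, 0.5, -1), "gainRate")
    expect_error(simulateSpineSessions(0, 10, 0.5, 0.5), "nSegments")
    expect_error(simulateSpineSessions(5, 10, NaN, 0.5), "survivalProb")
})

test_that("generators are deterministic under a fixed seed", {
    expect_identical(simulateSpineSessions(8, 20, 0.7, 0.5, seed = 99),
                     simulateSpineSessions(8, 20, 0.7, 0.5, seed = 99))
    r1 <- renderDendriteStack(5, noiseSd = 1, seed = 99)
    r2 <- renderDendriteStack(5, noiseSd = 1, seed = 99)
    expect_identical(intensity(r1$stack), intensity(r2$stack))
    t1 <- simulateCalciumTrials(3, 0.4, nOdors = 2, seed = 99)
    t2 <- simulateCalciumTrials(3, 0.4, nOdors = 2, seed = 99)
    expect_identical(t1@traces, t2@traces)
    c1 <- renderContactScene(6, 3, 2, noiseSd = 1, seed = 99)
    c2 <- renderContactScene(6, 3, 2, noiseSd = 1, seed = 99)
    expect_identical(intensity(c1$microglia), intensity(c2$microglia))
})

test_that("generated fate labels reproduce configured probabilities", {
    # law of large numbers on the generator's own labels
    sim <- simulateSpineSessions(200, 30, 0.70, 0.557, seed = 5)
    stableFrac <- mean(sim$truth$fate[!is.na(sim$truth$spine_id_s1)] ==
                       "stable")
    expect_lt(abs(stableFrac - 0.70), 0.02)

    # self-consistency within 3 binomial SE at n >= 10,000
    big <- simulateSpineSessions(400, 30, 0.70, 0.557, seed = 6)
    s1fates <- big$truth$fate[!is.na(big$truth$spine_id_s1)]
    n <- length(s1fates)
    expect_gte(n, 10000)
    se <- sqrt(0.7 * 0.3 / n)
    expect_lt(abs(mean(s1fates == "stable") - 0.70), 3 * se)
})

test_that("rendered dendrite stacks carry exact ground truth", {
    # no spines: shaft and background only
    bare <- renderDendriteStack(0)
    expect_length(bare$annotations, 0)
    expect_equal(nrow(bare$truth), 0)
    expect_setequal(unique(as.vector(intensity(bare$stack))), c(10, 50))

    # single noiseless spine: the analytic 10 AU case
    one <- renderDendriteStack(1, spineIntensity = 500, shaftIntensity = 50)
    res <- measureSpineHeadSize(one$stack, one$annotations[[1]])
    expect_equal(res$size_au, 10)
    expect_equal(one$truth$true_size_au, 10)

    # annotations index only voxels inside rendered structures
    r <- renderDendriteStack(4, spineIntensity = 300)
    arr <- intensity(r$stack)
    for (a in r$annotations) {
        expect_true(all(arr[a@head] > 10))     # head above background
        expect_true(all(arr[a@background] == 10))
        expect_true(all(arr[a@shaft] == 50))
    }
    expect_error(renderDendriteStack(10, nx = 20), "too small")
})

test_that("rendered spine sizes are recoverable through measurement", {
    r <- renderDendriteStack(50, spineIntensity = seq(100, 1000,
                                                      length.out = 50),
                             noiseSd = 0.02 * 50, seed = 11)
    sz <- measureSpineHeadSizes(r$stack, r$annotations)
    relErr <- abs(sz$size_au - r$truth$true_size_au) / r$truth$true_size_au
    expect_gte(mean(relErr <= 0.10), 0.90)
})

test_that("calcium trial generator matches its timing contract", {
    # amplitudes 0, noise 0: every trace constant at baseline
    flat <- simulateCalciumTrials(2, 0, nOdors = 2, noiseSd = 0)
    expect_true(all(flat@traces == 100))

    # one responsive pair, noiseless: peak smoothed deltaF/F equals the
    # amplitude times the analytic sampling+smoothing attenuation
    ts <- simulateCalciumTrials(1, matrix(1.0, 1, 1), nOdors = 1,
                                noiseSd = 0)
    tr <- ts@traces[1, "odor1", 1, ]
    d <- dff(smoothTrace(tr), 70, 7)
    rise <- 0.1; decay <- 1.5
    tSec <- ((1:164) - 70) / 7
    tPk <- log(decay / rise) * rise * decay / (decay - rise)
    hPk <- exp(-tPk / decay) - exp(-tPk / rise)
    h <- ifelse(tSec < 0, 0, (exp(-tSec / decay) - exp(-tSec / rise)) / hPk)
    # the smoothing window leaks the first transient samples into the
    # baseline, so the closed form includes the (slightly inflated) F0
    sh <- smoothTrace(h)
    f0 <- 1 + mean(sh[42:69])
    expect_equal(max(d), (1 + max(sh) - f0) / f0, tolerance = 1e-8)
    expect_lt(max(d), 1.0)   # attenuated below the nominal peak
    expect_gt(max(d), 0.8)

    expect_error(simulateCalciumTrials(1, 0.5, riseTauSec = -1), "kinetics")
    expect_error(simulateCalciumTrials(1, 0.5, riseTauSec = 2,
                                       decayTauSec = 1), "kinetics")
})

test_that("contact scenes plant the exact number of contacts", {
    none <- renderContactScene(10, nShaftContacts = 0, nContactedSpines = 0)
    ev0 <- detectContacts(none$microgliaMask, list(d1 = none$shaftMask),
                          none$spineMasks)
    expect_equal(sum(ev0$target_type == "shaft"), 0)
    expect_equal(sum(ev0$target_type == "spine"), 0)

    sc <- renderContactScene(20, nShaftContacts = 5, nContactedSpines = 3)
    ev <- detectContacts(sc$microgliaMask, list(d1 = sc$shaftMask),
                         sc$spineMasks)
    expect_equal(sum(ev$target_type == "shaft"), 5)
    expect_equal(spineContactFraction(ev, sc$truth$nSpines), 15)
    expect_setequal(unique(ev$target_id[ev$target_type == "spine"]),
                    sc$truth$contactedSpineIds)
    expect_error(renderContactScene(5, nContactedSpines = 7), "contact")
})

test_that("stack, annotation and trial interchange formats round-trip", {
    r <- renderDendriteStack(3, seed = 2)
    tf <- tempfile(fileext = ".tif")
    writeImageStack(r$stack, tf)
    back <- readImageStack(tf)
    expect_identical(dim(back), dim(r$stack))
    # stored as max-normalized float: ratios (and hence AU sizes) preserved
    expect_equal(intensity(back) * max(intensity(r$stack)),
                 intensity(r$stack), tolerance = 1e-6)

    jf <- tempfile(fileext = ".json")
    writeSpineAnnotations(r$annotations, jf)
    back2 <- readSpineAnnotations(jf)
    expect_length(back2, 3)
    expect_identical(back2[[2]]@head, r$annotations[[2]]@head)
    expect_identical(back2[[2]]@spineId, r$annotations[[2]]@spineId)

    ts <- simulateCalciumTrials(2, 0.4, nOdors = 2, noiseSd = 0.02,
                                seed = 9)
    cf <- tempfile(fileext = ".csv"); yf <- tempfile(fileext = ".yaml")
    writeTrialSet(ts, cf, yf)
    ts2 <- readTrialSet(cf, yf)
    expect_equal(ts2@traces, ts@traces, ignore_attr = TRUE,
                 tolerance = 1e-12)
    expect_equal(ts2@samplingRate, 7)
    expect_equal(ts2@blankOdor, "blank")

    rec <- simulateSpineSessions(2, 5, 0.8, 0.3, seed = 3)$records
    rf <- tempfile(fileext = ".csv")
    writeSpineRecords(rec, rf)
    expect_equal(readSpineRecords(rf), rec)
})
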