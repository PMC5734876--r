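test_that("median filter matches the brute-force sorted-window oracle", {
    # constant frame passes through
    const <- array(7, c(2, 6, 6))
    expect_identical(medianFilterFrames(const), const)

    # single hot pixel is replaced by the background value
    hot <- array(10, c(1, 9, 9)); hot[1, 5, 5] <- 999
    expect_equal(medianFilterFrames(hot)[1, 5, 5], 10)

    # random frames against the literal per-pixel oracle, two window sizes
    set.seed(42)
    for (size in c(3L, 5L)) {
        frame <- matrix(rnorm(64), 8, 8)
        arr <- array(0, c(1, 8, 8)); arr[1, , ] <- frame
        expect_equal(medianFilterFrames(arr, size)[1, , ],
                     bruteMedianFilter(frame, size))
    }
    expect_error(medianFilterFrames(const, 4), "odd")
})

test_that("spine-head size follows the analytic contract", {
    # head sum 1000 over 50 px, background mean 10, shaft top-decile 50
    a <- array(10, c(1, 40, 40))
    a[1, 5:9, 5:14] <- 20
    a[1, 30, 1:20] <- 50
    ann <- SpineAnnotation("s1",
        head = cbind(1, rep(5:9, 10), rep(5:14, each = 5)),
        background = cbind(1, 20, 1:10),
        shaft = cbind(1, 30, 1:20))
    res <- measureSpineHeadSize(a, ann)
    expect_equal(res$size_au, 10)
    expect_false(res$flag_negative)

    # dim head below local background is kept negative and flagged
    dim <- a; dim[1, 5:9, 5:14] <- 5
    res2 <- measureSpineHeadSize(dim, ann)
    expect_lt(res2$size_au, 0)
    expect_true(res2$flag_negative)

    # error paths: shaft mask absent at the selected frame
    annBad <- SpineAnnotation("s2", head = cbind(1, 5, 5),
                              background = cbind(1, 20, 1),
                              shaft = cbind(2, 30, 1))
    a2 <- array(10, c(2, 40, 40)); a2[1, 5, 5] <- 100; a2[2, 30, 1] <- 50
    expect_error(measureSpineHeadSize(a2, annBad), "shaft")
})

test_that("size is scale invariant and strictly monotone in head intensity", {
    r <- renderDendriteStack(6, spineIntensity = c(80, 200, 350, 500, 650,
                                                   900), seed = 8)
    base <- measureSpineHeadSizes(r$stack, r$annotations)
    set.seed(8)
    for (c in runif(5, 0.1, 40)) {
        scaled <- ImageStack(intensity(r$stack) * c)
        sc <- measureSpineHeadSizes(scaled, r$annotations)
        expect_equal(sc$size_au, base$size_au, tolerance = 1e-12)
    }
    # raising every head pixel raises the size, background/shaft untouched
    arr <- intensity(r$stack)
    ann <- r$annotations[[1]]
    arr2 <- arr; arr2[ann@head] <- arr2[ann@head] + 5
    expect_gt(measureSpineHeadSize(arr2, ann)$size_au,
              measureSpineHeadSize(arr, ann)$size_au)
})

test_that("frame selection equals the exhaustive per-frame argmax", {
    set.seed(13)
    for (rep in 1:5) {
        arr <- array(runif(4 * 20 * 20, 5, 50), c(4, 20, 20))
        headCoo <- cbind(z = rep(1:4, each = 4),
                         y = rep(c(3, 3, 4, 4), 4),
                         x = rep(c(3, 4, 3, 4), 4))
        ann <- SpineAnnotation("s", headCoo,
            background = cbind(z = rep(1:4, each = 2), y = 10,
                               x = rep(c(1, 2), 4)),
            shaft = cbind(z = rep(1:4, each = 3), y = 15,
                          x = rep(c(1, 2, 3), 4)))
        sums <- vapply(1:4, function(z) {
            hz <- headCoo[headCoo[, "z"] == z, , drop = FALSE]
            sum(arr[hz])
        }, numeric(1))
        expect_equal(measureSpineHeadSize(arr, ann)$frame,
                     which.max(sums))
    }
})

test_that("measured sizes on a rendered cohort stay in the plausible range", {
    r <- renderDendriteStack(50,
        spineIntensity = exp(seq(log(25), log(3000), length.out = 50)),
        noiseSd = 1, seed = 21)
    sz <- measureSpineHeadSizes(r$stack, r$annotations)
    expect_true(all(sz$size_au >= 0.15 & sz$size_au <= 70))
})

test_that("spine density counts every head over the arc length", {
    expect_equal(spineDensity(50, 0)$density_per_um, 0)
    expect_equal(spineDensity(50, 20)$density_per_um, 0.4)
    # a two-headed protrusion plus three single spines: 5 heads on 10 um
    expect_equal(spineDensity(10, 2 + 3)$density_per_um, 0.5)
    expect_equal(spineDensity(10, 5)$density_per_10um, 5)

    tr <- DendriteTrace("d1", cbind(z = c(1, 1), y = c(10, 10),
                                    x = c(1, 251)), pixelSizeXY = 0.2)
    expect_equal(traceLength(tr), 50)
    d <- spineDensity(tr, 20)
    expect_equal(d$density_per_um, 0.4)
    expect_equal(d$dendrite_id, "d1")
    # anisotropic scaling of the z axis
    trz <- DendriteTrace("d2", cbind(z = c(1, 11), y = c(1, 1), x = c(1, 1)),
                         pixelSizeXY = 0.2, zStep = 0.5)
    expect_equal(traceLength(trz), 5)
    expect_error(spineDensity(0, 3), "positive")
    expect_error(spineDensity(50, -1), "non-negative")
})

test_that("size histograms bin correctly and are multinomially consistent", {
    one <- sizeDistributionSummary(rep(12, 5))
    expect_equal(one$freq[one$bin_start == 10], 1)
    expect_equal(sum(one$freq), 1)

    three <- sizeDistributionSummary(c(5, 15, 55))
    expect_equal(three$freq[match(c(0, 10, 50), three$bin_start)],
                 rep(1 / 3, 3))
    expect_equal(sum(three$count), 3)

    set.seed(30)
    unif <- sizeDistributionSummary(runif(7000, 0, 70))
    expect_equal(nrow(unif), 7)
    se <- sqrt((1 / 7) * (6 / 7) / 7000)
    expect_true(all(abs(unif$freq - 1 / 7) < 3 * se))

    expect_error(sizeDistributionSummary(numeric(0)), "non-empty")
    expect_error(sizeDistributionSummary(c(1, NA)), "finite")
})
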