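test_that("region exclusion keeps exactly the in-window points", {
    grid <- seq(0, 12, by = 0.5)
    s <- toySet(matrix(1, 2, length(grid)), grid)
    e <- excludeRegions(s)  # defaults: keep [0.8, 10], drop [4.7, 5.2]
    expect_identical(length(ppm(e)), 18L)
    expect_true(all(ppm(e) >= 0.8 & ppm(e) <= 10))
    expect_false(any(ppm(e) >= 4.7 & ppm(e) <= 5.2))

    set.seed(1)
    grid2 <- sort(runif(300, 0, 11))
    s2 <- toySet(matrix(rnorm(600), 2), grid2)
    e2 <- excludeRegions(s2)
    expect_true(all(ppm(e2) >= 0.8 & ppm(e2) <= 10 &
                    !(ppm(e2) >= 4.7 & ppm(e2) <= 5.2)))
    # idempotent
    expect_identical(intensityMatrix(excludeRegions(e2)),
                     intensityMatrix(e2))
    # identity under wide bounds and no drop list
    wide <- excludeRegions(s2, -1e6, 1e6, drop = list())
    expect_identical(intensityMatrix(wide), intensityMatrix(s2))
    expect_error(excludeRegions(s2, 20, 30), "every spectral point")
})

test_that("PQN matches its analytic small cases", {
    base <- rexp(20) + 0.5
    one <- toySet(matrix(base, 1, 20))
    r1 <- pqnNormalize(one)
    expect_equal(unname(r1$dilutionFactors), 1)
    expect_equal(unname(intensityMatrix(r1$set)[1, ]), base)

    two <- toySet(rbind(base, 2 * base))
    r2 <- pqnNormalize(two)
    expect_equal(unname(r2$dilutionFactors), c(2 / 3, 4 / 3),
                 tolerance = 1e-12)
    out <- intensityMatrix(r2$set)
    expect_equal(unname(out[1, ]), 1.5 * base, tolerance = 1e-12)
    expect_equal(unname(out[2, ]), 1.5 * base, tolerance = 1e-12)
})

test_that("PQN recovers simulated dilution factors", {
    eff <- matrix(0, 1, 31,
                  dimnames = list("WT", metaboliteNames(defaultPeakLibrary())))
    d <- simDesign(eff, nPerClass = 5L, noiseSd = 0, jitterSdPpm = 0,
                   nPoints = 3000L, seed = 8L)
    sim <- simulateDataset(d)
    r <- pqnNormalize(excludeRegions(sim$set))
    dh <- r$dilutionFactors / exp(mean(log(r$dilutionFactors)))
    dt <- sim$truth@dilutionFactors /
        exp(mean(log(sim$truth@dilutionFactors)))
    expect_lt(max(abs(dh / dt - 1)), 1e-6)
})

test_that("PQN is invariant to rescaling one row and flags thin quotients", {
    set.seed(2)
    x <- matrix(rexp(5 * 40) + 0.1, 5, 40)
    x[3, ] <- x[3, ] * 5  # keep it the extreme row so the median is stable
    a <- pqnNormalize(toySet(x))
    x2 <- x; x2[3, ] <- x2[3, ] * 7
    b <- pqnNormalize(toySet(x2))
    expect_equal(intensityMatrix(a$set), intensityMatrix(b$set),
                 tolerance = 1e-12)
    expect_equal(unname(b$dilutionFactors[3] / a$dilutionFactors[3]), 7,
                 tolerance = 1e-12)
    expect_equal(unname(b$dilutionFactors[-3]),
                 unname(a$dilutionFactors[-3]), tolerance = 1e-12)

    thin <- matrix(c(rep(1, 9), rep(-1, 31)), 2, 40, byrow = TRUE)
    thin[2, ] <- abs(thin[1, ])
    expect_error(pqnNormalize(toySet(thin)), "s1.*usable quotient")
})

test_that("alignment is the identity on already-aligned spectra", {
    set.seed(3)
    row <- lorentzRow(400, 100, 3) + lorentzRow(400, 300, 3)
    x <- rbind(row, row, row)
    s <- toySet(x, seq(0, by = 0.002, length.out = 400))
    r <- rspaAlign(s)
    expect_identical(r$referenceSampleId, "s1")  # tie broken to lowest id
    expect_identical(intensityMatrix(r$set), intensityMatrix(s))
    expect_true(all(vapply(r$shiftMap, nrow, integer(1)) == 0L))
})

test_that("alignment recovers a known single-peak displacement", {
    n <- 500L
    for (shift in c(1L, 3L, 6L)) {
        x <- rbind(a = lorentzRow(n, 250, 3),
                   b = lorentzRow(n, 250 + shift, 3))
        s <- toySet(x, seq(0, by = 0.002, length.out = n))
        r <- rspaAlign(s, maxShiftPpm = 0.02)  # window = 10 points
        expect_identical(r$referenceSampleId, "s1")
        applied <- sum(r$shiftMap[["s2"]]$shift_points)
        expect_lte(abs(applied + shift), 1L)
        expect_gt(corSafe(intensityMatrix(r$set)[1, ],
                          intensityMatrix(r$set)[2, ]), 0.999)
    }
})

test_that("recursion aligns opposite displacements in the two halves", {
    n <- 600L
    ref <- lorentzRow(n, 150, 3) + lorentzRow(n, 450, 3)
    tst <- lorentzRow(n, 152, 3) + lorentzRow(n, 448, 3)
    s <- toySet(rbind(ref, tst), seq(0, by = 0.002, length.out = n))
    r <- rspaAlign(s, maxShiftPpm = 0.008)  # 4-point window
    m <- intensityMatrix(r$set)
    expect_identical(which.max(m[2, 1:300]), which.max(m[1, 1:300]))
    expect_identical(which.max(m[2, 301:600]), which.max(m[1, 301:600]))
    sh <- r$shiftMap[["s2"]]$shift_points
    expect_true(any(sh < 0) && any(sh > 0))
})

test_that("alignment respects its window and never reduces correlation", {
    set.seed(4)
    n <- 800L
    grid <- seq(0, by = 0.002, length.out = n)
    w0 <- round(0.02 / 0.002)
    for (rep in 1:5) {
        centers <- sort(sample(50:750, 6))
        mk <- function(jit) Reduce(`+`, lapply(centers, function(ctr)
            lorentzRow(n, ctr + jit(), 2.5, height = runif(1, 0.5, 2))))
        x <- rbind(mk(function() 0),
                   mk(function() sample(-4:4, 1)),
                   mk(function() sample(-4:4, 1)))
        s <- toySet(x + rnorm(3 * n, 0, 0.003), grid)
        r <- rspaAlign(s)
        for (sm in r$shiftMap)
            if (nrow(sm)) expect_true(all(abs(sm$shift_points) <= w0))
        expect_true(all(r$meanCorrelation$post >=
                        r$meanCorrelation$pre - 1e-12))
    }
    bad <- toySet(matrix(rnorm(200), 2), sort(runif(100, 0, 5)))
    expect_error(rspaAlign(bad), "uniform")
})

test_that("log transform converts ratios to offsets and validates", {
    ones <- toySet(matrix(1, 2, 15))
    expect_equal(unname(intensityMatrix(logTransform(ones, 0)$set)),
                 matrix(0, 2, 15))

    base <- rexp(20) + 0.2
    s <- toySet(rbind(base, 2 * base))
    lt <- logTransform(s, 0)
    dif <- intensityMatrix(lt$set)[2, ] - intensityMatrix(lt$set)[1, ]
    expect_equal(unname(dif), rep(log(2), 20), tolerance = 1e-12)

    # strict monotonicity cell-wise
    set.seed(5)
    a <- matrix(rexp(60), 3); b <- a + matrix(rexp(60), 3)
    la <- intensityMatrix(logTransform(toySet(a), 0.1)$set)
    lb <- intensityMatrix(logTransform(toySet(b), 0.1)$set)
    expect_true(all(lb > la))

    expect_equal(logTransform(s, "auto")$logOffset, min(base))
    neg <- toySet(matrix(c(-1, -2, rep(1, 28)), 3, 10))
    expect_error(logTransform(neg, 0.5), "2 cell")
    # noise-floor mode scales with the negative-tail RMS
    nf <- logTransform(neg, "noise-floor")
    expect_equal(nf$logOffset, 20 * sqrt(mean(c(1, 4))), tolerance = 1e-12)
})

test_that("log transform compresses mean-proportional spread", {
    set.seed(6)
    mu <- runif(200, 1, 100)
    x <- t(replicate(40, mu * (1 + rnorm(200, 0, 0.05))))
    spread <- function(m) {
        sds <- apply(m, 2, sd)
        max(sds) / min(sds)
    }
    lx <- intensityMatrix(logTransform(toySet(x), 0)$set)
    expect_gt(spread(x) / spread(lx), 5)
})

test_that("the preprocessing chain reports every stage it ran", {
    sim <- simulateDataset(smallDesign(seed = 11L))
    pp <- preprocessSpectra(sim$set)
    expect_identical(pp$report@stageOrder,
                     c("exclude", "pqn", "rspa", "log"))
    expect_identical(length(pp$report@dilutionFactors), 10L)
    expect_true(pp$report@referenceSampleId %in%
                sampleInfo(sim$set)$sample_id)
    expect_gt(pp$report@logOffset, 0)
    expect_identical(ppm(pp$set), ppm(pp$unlogged))
})
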