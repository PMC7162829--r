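test_that("the one-way F statistic matches hand and stats-package results", {
    x <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 1)
    lab <- rep(c("a", "b"), each = 3)
    av <- anovaPerVariable(x, lab)
    expect_equal(av$F, 13.5, tolerance = 1e-12)
    # p via the equivalent two-sided t on 4 df
    expect_equal(av$p, 2 * pt(-sqrt(13.5), 4), tolerance = 1e-12)
    expect_equal(round(av$p, 4), 0.0213)

    set.seed(14)
    y <- matrix(rnorm(15 * 4), 15, 4)
    lab3 <- rep(c("a", "b", "c"), each = 5)
    av3 <- anovaPerVariable(y, lab3)
    for (j in 1:4) {
        ref <- anova(lm(y[, j] ~ factor(lab3)))
        expect_equal(av3$F[j], ref$`F value`[1], tolerance = 1e-10)
        expect_equal(av3$p[j], ref$`Pr(>F)`[1], tolerance = 1e-10)
    }

    const <- matrix(5, 6, 2)
    avc <- anovaPerVariable(const, lab)
    expect_equal(avc$F, c(0, 0))
    expect_equal(avc$p, c(1, 1))

    sep <- matrix(rep(c(1, 1, 1, 2, 2, 2), 2), ncol = 2)
    avs <- anovaPerVariable(sep, lab)
    expect_identical(avs$F, c(Inf, Inf))
    expect_equal(avs$p, c(1e-300, 1e-300))

    expect_error(anovaPerVariable(x, c("a", "a", "a", "a", "a", "b")),
                 "single sample")
})

test_that("two-group ANOVA equals the squared pooled-variance t test", {
    set.seed(15)
    for (i in 1:10) {
        x <- matrix(rnorm(12 * 3), 12, 3)
        lab <- rep(c("a", "b"), each = 6)
        av <- anovaPerVariable(x, lab)
        for (j in 1:3) {
            tt <- t.test(x[lab == "a", j], x[lab == "b", j],
                         var.equal = TRUE)
            expect_equal(av$F[j], unname(tt$statistic)^2, tolerance = 1e-10)
            expect_equal(av$p[j], tt$p.value, tolerance = 1e-10)
        }
    }
})

test_that("BH adjustment and the pFDR walk match hand step-up results", {
    p <- c(0.001, 0.01, 0.02, 0.8)
    expect_equal(bhAdjust(p), c(0.004, 0.02, 0.8 / 30, 0.8),
                 tolerance = 1e-12)
    expect_equal(pfdrThreshold(p, 0.1), 0.02)

    expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
    expect_equal(bhAdjust(0.037), 0.037)
    expect_true(is.na(pfdrThreshold(rep(0.9, 4), 0.1)))
    small <- c(0.001, 0.002, 0.003)
    expect_equal(pfdrThreshold(small, 0.1), 0.003)  # all significant

    set.seed(16)
    pr <- runif(50)
    q <- bhAdjust(pr)
    expect_true(all(q >= pr))
    perm <- sample(50)
    expect_equal(bhAdjust(pr[perm]), q[perm], tolerance = 1e-15)
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
    expect_error(pfdrThreshold(c(-0.1, 0.5)), "\\[0, 1\\]")
})

test_that("p-values are uniform under the complete null", {
    set.seed(17)
    m <- 10000L
    x <- matrix(rnorm(10 * m), 10, m)
    av <- anovaPerVariable(x, rep(c("a", "b"), each = 5))
    ks <- suppressWarnings(ks.test(av$p, "punif"))
    expect_gt(ks$p.value, 0.01)
})

test_that("fold changes follow group mean ratios with flagged degenerates", {
    x <- rbind(c(4, 1, 2), c(4, 1, 2), c(2, 1, -1), c(2, 1, -1))
    lab <- rep(c("A", "B"), each = 2)
    fc <- log2FoldChanges(x, lab, c("A", "B"))
    expect_equal(fc[1:2], c(1, 0), ignore_attr = TRUE)
    expect_true(is.na(fc[3]))
    expect_identical(attr(fc, "flagged"), 3L)
    expect_error(log2FoldChanges(x, lab, c("A", "Z")), "empty group")
})

test_that("significant variables map to library metabolites within tolerance", {
    lib <- defaultPeakLibrary()
    empty <- assignPeaksToMetabolites(
        data.frame(ppm = numeric(0), mean_diff_log = numeric(0),
                   p = numeric(0), q = numeric(0)), lib)
    expect_identical(nrow(empty), 0L)

    sig <- data.frame(ppm = 6.520, mean_diff_log = -0.4, p = 1e-4,
                      q = 1e-3, log2_fc = -0.6)
    call <- assignPeaksToMetabolites(sig, lib)
    expect_identical(call$name, "Fumarate")
    expect_identical(call$hmdb, "HMDB0000134")
    expect_identical(call$direction, "down")
    expect_equal(call$representative_ppm, 6.520)
    expect_false(call$ambiguous)

    # lactate 1.331 and threonine 1.335 both match a 1.332 variable
    lac <- assignPeaksToMetabolites(
        data.frame(ppm = 1.332, mean_diff_log = -0.4, p = 1e-4, q = 1e-3,
                   log2_fc = -0.6), lib)
    expect_setequal(lac$name, c("Lactate", "Threonine"))
    expect_true(all(lac$ambiguous))

    # creatine (3.041) / creatine phosphate (3.045) style collision
    sig2 <- data.frame(ppm = 3.043, mean_diff_log = 0.5, p = 1e-5,
                       q = 1e-4, log2_fc = 0.7)
    both <- assignPeaksToMetabolites(sig2, lib)
    expect_setequal(both$name, c("Creatine", "Creatine phosphate"))
    expect_true(all(both$ambiguous))

    expect_error(assignPeaksToMetabolites(sig, PeakLibrary(
        peakTable(lib)[0, ])), "no peaks")
})

test_that("enlarging the significant set never removes a metabolite call", {
    lib <- defaultPeakLibrary()
    set.seed(18)
    pool <- data.frame(ppm = runif(40, 0.9, 9.9),
                       mean_diff_log = rnorm(40), p = runif(40, 0, 0.01),
                       q = runif(40, 0, 0.1), log2_fc = rnorm(40))
    sub <- pool[1:15, ]
    callsSub <- assignPeaksToMetabolites(sub, lib)
    callsAll <- assignPeaksToMetabolites(pool, lib)
    expect_true(all(callsSub$name %in% callsAll$name))
})

test_that("heat-map centering removes the across-sample median", {
    one <- heatmapMatrix(matrix(c(2, 5, 7), 1))
    expect_equal(unname(one), matrix(0, 1, 3))
    expect_equal(unname(heatmapMatrix(matrix(c(1, 2, 3), 3))),
                 matrix(c(-1, 0, 1), 3))
    set.seed(19)
    h <- heatmapMatrix(matrix(rnorm(55), 11, 5))
    expect_equal(unname(apply(h, 2, median)), rep(0, 5))
})

test_that("the ANOVA trace is signed toward group A and flags by pFDR", {
    set.seed(20)
    x <- matrix(rnorm(10 * 30), 10, 30)
    x[1:5, 1:4] <- x[1:5, 1:4] + 3  # higher in A
    lab <- rep(c("A", "B"), each = 5)
    tr <- anovaTrace(x, lab, c("A", "B"))
    expect_true(all(tr$stat[1:4] > 0))
    thr <- pfdrThreshold(tr$p, 0.1)
    expect_identical(sum(tr$significant), sum(tr$p <= thr))

    flat <- matrix(rep(seq_len(6), each = 10), 10, 6)
    trF <- anovaTrace(flat, lab, c("A", "B"))
    expect_equal(trF$stat, rep(0, 6))
    expect_error(anovaTrace(x, rep(c("A", "B", "C"), c(4, 3, 3)),
                            c("A", "B")), "pairwise")
})

test_that("the two-group differential stage ties its pieces together", {
    sim <- simulateDataset(smallDesign(seed = 21L))
    pp <- preprocessSpectra(sim$set)
    dr <- differentialAnalysis(pp$set, pp$unlogged, c("MUT", "WT"))
    v <- variableStats(dr)
    expect_identical(names(v), c("ppm", "F", "p", "q", "mean_diff_log",
                                 "sign", "log2_fc", "significant"))
    expect_true(all(v$q >= v$p))
    if (!is.na(pfdr(dr))) {
        expect_equal(pfdr(dr), max(v$p[v$significant]))
        expect_identical(sum(v$significant), sum(v$p <= pfdr(dr)))
    }
    mc <- metaboliteCalls(dr)
    # injected inosine effect is recovered as an up call at its 8.348 singlet
    ino <- mc[mc$name == "Inosine", ]
    expect_identical(ino$direction, "up")
    expect_identical(mc$direction[mc$name == "AMP"], "down")
    expect_true(all(mc$direction == ifelse(mc$log2_fc >= 0, "up", "down") |
                    is.na(mc$log2_fc)))

    paths <- writeDifferentialTables(dr, pp$set, tempfile(), "MUT_vs_WT_")
    expect_true(all(file.exists(paths)))
    tab2 <- read.delim(paths[2])
    expect_identical(names(tab2), c("metabolite", "hmdb", "ppm",
                                    "direction", "p", "q", "log2_fc",
                                    "ambiguous"))
})
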