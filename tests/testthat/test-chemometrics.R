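test_that("PCA matches an independent SVD and its variance bookkeeping", {
    pts <- cbind(1:6, 2 * (1:6) + 3)  # collinear
    m1 <- pcaFit(pts, k = 1)
    expect_equal(m1@explainedVarianceRatio, 1, tolerance = 1e-12)

    set.seed(7)
    x <- matrix(rnorm(50), 5, 10)
    k <- 4
    fit <- pcaFit(x, k = k)
    sv <- svd(scale(x, scale = FALSE))
    for (j in seq_len(k)) {
        expect_equal(abs(fit@loadings[, j]), abs(sv$v[, j]),
                     tolerance = 1e-8)
        expect_equal(abs(fit@scores[, j]),
                     abs(sv$u[, j] * sv$d[j]), tolerance = 1e-8)
    }
    expect_equal(fit@explainedVarianceRatio, sv$d[1:k]^2 / sum(sv$d^2),
                 tolerance = 1e-10)
    # sign convention: dominant loading element positive
    for (j in seq_len(k))
        expect_gt(fit@loadings[which.max(abs(fit@loadings[, j])), j], 0)
    # full-rank variance conservation
    expect_equal(sum(pcaFit(x, k = 4)@explainedVarianceRatio), 1,
                 tolerance = 1e-8)
    expect_error(pcaFit(x, k = 5), "exceeds")

    # identical samples get identical scores
    y <- rbind(x, x[2, ])
    fy <- pcaFit(y, k = 2)
    expect_equal(fy@scores[2, ], fy@scores[6, ], tolerance = 1e-8)
})

test_that("MMC reduces to the mean-difference direction when S_w = 0", {
    x <- rbind(c(1, 2, 3), c(4, 0, 3))
    fit <- mmcFit(x, c("a", "b"), k = 1)
    dir <- (x[1, ] - x[2, ]) / sqrt(sum((x[1, ] - x[2, ])^2))
    cosine <- abs(sum(fit@projection[, 1] * dir))
    expect_gt(cosine, 1 - 1e-8)
})

test_that("MMC is invariant to class label renaming", {
    set.seed(8)
    x <- matrix(rnorm(96), 12, 8)
    lab <- rep(c("g1", "g2", "g3"), each = 4)
    f1 <- mmcFit(x, lab)
    f2 <- mmcFit(x, c(g1 = "zebra", g2 = "ant", g3 = "moth")[lab])
    expect_equal(f1@eigenvalues, f2@eigenvalues, tolerance = 1e-10)
    expect_equal(abs(f1@scores), abs(f2@scores), tolerance = 1e-8)
})

test_that("the fitted MMC projection beats random projections", {
    set.seed(9)
    x <- matrix(rnorm(96), 12, 8)
    lab <- rep(c("g1", "g2", "g3"), each = 4)
    fit <- mmcFit(x, lab, k = 2)
    crit <- mmcCriterion(x, lab, fit@projection)
    for (i in 1:300) {
        Q <- qr.Q(qr(matrix(rnorm(16), 8, 2)))
        expect_gte(crit, mmcCriterion(x, lab, Q) - 1e-9)
    }
    expect_error(mmcFit(x, rep("one", 12)), "two classes")
    expect_error(mmcFit(x, lab, k = 50), "basis rank")
})

test_that("the quadratic discriminant matches hand Gaussian math", {
    # 1-D, gamma = 0: class-specific variances only
    sc <- matrix(c(0, 1, 10, 11), ncol = 1)
    q <- qdaFit(sc, c("A", "A", "B", "B"), regGamma = 0)
    expect_identical(predict(q, matrix(0.9)), "A")
    expect_identical(predict(q, matrix(9.8)), "B")

    # symmetric classes: midpoint is a tie, resolved to the lower label
    sym <- matrix(c(-2, -1, 1, 2), ncol = 1)
    qs <- qdaFit(sym, c("A", "A", "B", "B"), regGamma = 0)
    expect_identical(predict(qs, matrix(0)), "A")

    expect_error(qdaFit(matrix(1:3, ncol = 1), c("A", "A", "B")),
                 "single sample")
})

test_that("full shrinkage reproduces nearest-centroid behavior", {
    set.seed(10)
    mu <- rbind(c(0, 0), c(4, 0), c(0, 4))
    x <- do.call(rbind, lapply(1:3, function(g)
        sweep(matrix(rnorm(12, sd = 0.8), 6, 2), 2, mu[g, ], `+`)))
    lab <- rep(c("a", "b", "c"), each = 6)
    q <- qdaFit(x, lab, regGamma = 1)
    test <- matrix(rnorm(40, sd = 3), 20, 2)
    cents <- rowsum(x, lab) / 6
    nearest <- rownames(cents)[apply(test, 1, function(p)
        which.min(colSums((t(cents) - p)^2)))]
    expect_identical(predict(q, test), nearest)
})

test_that("leave-one-out classification gets easy cases right", {
    set.seed(11)
    x <- rbind(matrix(rnorm(40, 0, 0.2), 5, 8),
               matrix(rnorm(40, 5, 0.2), 5, 8))
    lab <- rep(c("mut", "wt"), each = 5)
    cv <- looCv(x, lab)
    expect_equal(correctRate(cv), 1.0)
    expect_identical(sum(confusion(cv)), 10L)

    # bookkeeping on n = 6
    y <- rbind(matrix(rnorm(12, 0, 0.3), 3, 4),
               matrix(rnorm(12, 3, 0.3), 3, 4))
    cv6 <- looCv(y, rep(c("a", "b"), each = 3))
    expect_identical(nrow(cv6@predictions), 6L)
    expect_identical(sum(confusion(cv6)), 6L)
    expect_equal(correctRate(cv6),
                 sum(diag(confusion(cv6))) / 6)

    expect_error(looCv(y, c("a", "a", "a", "b", "b", "c")), ">= 3")
})

test_that("permuted labels drive the cross-validated rate to chance", {
    set.seed(12)
    x <- matrix(rnorm(12 * 6), 12, 6)
    lab <- rep(c("a", "b"), each = 6)
    rates <- vapply(1:100, function(i)
        correctRate(looCv(x, sample(lab))), numeric(1))
    se <- sd(rates) / sqrt(length(rates))
    expect_lt(abs(mean(rates) - 0.5), 3 * se + 1e-12)
})

test_that("per-fold refitting avoids the leakage of a full-data model", {
    # p >> n with random labels: an honest LOO rate sits near chance while
    # the leaky variant (project + classify with the full-data model)
    # reports a wildly optimistic rate
    set.seed(13)
    x <- matrix(rnorm(10 * 40), 10, 40)
    lab <- rep(c("a", "b"), each = 5)
    honest <- correctRate(looCv(x, lab))
    full <- mmcFit(x, lab)
    q <- qdaFit(full@scores, lab)
    leaky <- mean(predict(q, full@scores) == lab)
    expect_gte(leaky, 0.9)
    expect_lt(honest, leaky)
    expect_lt(honest, 0.9)
})
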