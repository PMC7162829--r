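# centered-data helpers --------------------------------------------------

.asMatrix <- function(x) {
    if (is(x, "SpectrumSet")) intensityMatrix(x) else as.matrix(x)
}

.labelsFor <- function(x, labels) {
    if (is.null(labels) && is(x, "SpectrumSet"))
        labels <- colData(x)$genotype
    if (is.null(labels)) stop("labels required")
    as.character(labels)
}

# fix the sign of each column so its largest-magnitude element is positive
.signConvention <- function(loadings, scores = NULL) {
    for (j in seq_len(ncol(loadings))) {
        i <- which.max(abs(loadings[, j]))
        if (loadings[i, j] < 0) {
            loadings[, j] <- -loadings[, j]
            if (!is.null(scores)) scores[, j] <- -scores[, j]
        }
    }
    list(loadings = loadings, scores = scores)
}

#' Principal component analysis
#'
#' Column-mean-centered SVD decomposition with a deterministic sign
#' convention (each loading's largest-magnitude element is positive).
#' Explained variance ratios are relative to the total centered variance.
#'
#' @param x Samples x variables matrix, or a [SpectrumSet-class].
#' @param k Number of components, `<= min(n - 1, p)`.
#' @return A [PCAModel-class].
#' @export
pcaFit <- function(x, k = 2L) {
    m <- .asMatrix(x)
    n <- nrow(m); p <- ncol(m)
    if (n < 2L) stop("PCA needs at least two samples")
    if (k > min(n - 1L, p))
        stop("k = ", k, " exceeds min(n - 1, p) = ", min(n - 1L, p))
    ctr <- colMeans(m)
    mc <- sweep(m, 2L, ctr)
    sv <- svd(mc, nu = k, nv = k)
    scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
    rownames(scores) <- rownames(m)
    colnames(scores) <- colnames(sv$v) <- paste0("PC", seq_len(k))
    fx <- .signConvention(sv$v, scores)
    tot <- sum(sv$d^2)
    new("PCAModel", center = ctr, loadings = fx$loadings,
        scores = fx$scores,
        explainedVarianceRatio = sv$d[seq_len(k)]^2 / tot,
        totalVariance = tot / (n - 1L))
}

#' Project new samples onto a PCA model
#'
#' @param model A [PCAModel-class].
#' @param x New samples x variables matrix (same variables as the fit).
#' @return Samples x components score matrix.
#' @export
pcaProject <- function(model, x) {
    m <- .asMatrix(x)
    sweep(m, 2L, model@center) %*% model@loadings
}

# between- and within-class scatter (MLE, weights n_g / n) of a score matrix
.scatterMatrices <- function(scores, labels) {
    n <- nrow(scores)
    mu <- colMeans(scores)
    Sb <- matrix(0, ncol(scores), ncol(scores))
    Sw <- matrix(0, ncol(scores), ncol(scores))
    for (g in unique(labels)) {
        idx <- which(labels == g)
        ng <- length(idx)
        mg <- colMeans(scores[idx, , drop = FALSE])
        dmu <- mg - mu
        Sb <- Sb + (ng / n) * tcrossprod(dmu)
        cg <- sweep(scores[idx, , drop = FALSE], 2L, mg)
        Sw <- Sw + crossprod(cg) / n
    }
    list(Sb = Sb, Sw = Sw)
}

#' Maximum margin criterion projection
#'
#' Supervised linear projection maximizing `tr(P' (S_b - S_w) P)`, the gap
#' between between-class and within-class scatter. Computed in the PCA basis
#' of the centered data (rank `min(n - 1, p)`) for numerical stability when
#' variables far outnumber samples, then mapped back to variable space.
#' Unlike LDA no scatter matrix is inverted, so the small-sample singularity
#' problem does not arise.
#'
#' @param x Samples x variables matrix, or a [SpectrumSet-class].
#' @param labels Class labels (defaults to the genotype column of a
#'   [SpectrumSet-class]).
#' @param k Number of discriminant components (default: number of classes
#'   minus one, capped at the basis rank).
#' @return An [MMCModel-class].
#' @export
mmcFit <- function(x, labels = NULL, k = NULL) {
    m <- .asMatrix(x)
    labels <- .labelsFor(x, labels)
    classes <- sort(unique(labels))
    if (length(classes) < 2L) stop("MMC needs at least two classes")
    n <- nrow(m); p <- ncol(m)
    ctr <- colMeans(m)
    mc <- sweep(m, 2L, ctr)
    r <- min(n - 1L, p)
    sv <- svd(mc, nu = r, nv = r)
    keep <- sv$d[seq_len(r)] > max(sv$d) * 1e-10
    r <- max(1L, sum(keep))
    if (is.null(k)) k <- min(length(classes) - 1L, r)
    if (k > r) stop("k = ", k, " exceeds the PCA basis rank ", r)
    V <- sv$v[, seq_len(r), drop = FALSE]
    T <- mc %*% V
    sc <- .scatterMatrices(T, labels)
    eg <- eigen(sc$Sb - sc$Sw, symmetric = TRUE)
    W <- eg$vectors[, seq_len(k), drop = FALSE]
    P <- V %*% W
    scores <- mc %*% P
    colnames(P) <- colnames(scores) <- paste0("MMC", seq_len(k))
    rownames(scores) <- rownames(m)
    fx <- .signConvention(P, scores)
    new("MMCModel", projection = fx$loadings,
        eigenvalues = eg$values[seq_len(k)],
        classLabels = classes, basisRank = as.integer(r), center = ctr,
        scores = fx$scores)
}

#' Project samples onto an MMC model
#'
#' @param model An [MMCModel-class].
#' @param x Samples x variables matrix or [SpectrumSet-class] with the same
#'   variables the model was fit on.
#' @return Samples x components score matrix.
#' @export
mmcProject <- function(model, x) {
    m <- .asMatrix(x)
    sweep(m, 2L, model@center) %*% model@projection
}

#' MMC trace criterion of a projection
#'
#' `tr(P' S_b P) - tr(P' S_w P)` for an arbitrary projection matrix, using
#' the same scatter definitions as [mmcFit()]. Used to verify optimality
#' against random projections.
#'
#' @param x Samples x variables matrix.
#' @param labels Class labels.
#' @param P Variables x components projection matrix.
#' @return Numeric scalar.
#' @export
mmcCriterion <- function(x, labels, P) {
    m <- .asMatrix(x)
    mc <- sweep(m, 2L, colMeans(m))
    sc <- .scatterMatrices(mc, as.character(labels))
    sum(diag(crossprod(P, sc$Sb %*% P))) -
        sum(diag(crossprod(P, sc$Sw %*% P)))
}

#' Fit a regularized quadratic discriminant classifier
#'
#' Gaussian class models with uniform priors and shrunken covariances
#' `(1 - gamma) * S_g + gamma * sigma2 * I + ridge * I`, where `S_g` is the
#' class MLE covariance and `sigma2` the mean diagonal of the pooled
#' within-class covariance. With a handful of replicates per class the raw
#' class covariances are singular; shrinkage toward the spherical pooled
#' variance (default `gamma = 0.5`) keeps the discriminants well defined.
#'
#' @param scores Samples x dimensions matrix (typically MMC scores).
#' @param labels Class labels, each class with at least two samples.
#' @param regGamma Shrinkage weight toward the spherical pooled variance,
#'   in \[0, 1\].
#' @param ridge Small diagonal ridge added unconditionally.
#' @return A [QDAModel-class].
#' @export
qdaFit <- function(scores, labels, regGamma = 0.5, ridge = 1e-6) {
    scores <- as.matrix(scores)
    labels <- as.character(labels)
    stopifnot(regGamma >= 0, regGamma <= 1, ridge >= 0)
    classes <- sort(unique(labels))
    cnt <- table(labels)
    if (any(cnt < 2L))
        stop("class(es) with a single sample: ",
             paste(names(cnt)[cnt < 2L], collapse = ", "),
             "; lower the number of components or pool classes")
    d <- ncol(scores)
    n <- nrow(scores)
    means <- matrix(NA_real_, length(classes), d,
                    dimnames = list(classes, colnames(scores)))
    covs <- vector("list", length(classes))
    names(covs) <- classes
    pooled <- matrix(0, d, d)
    for (g in classes) {
        idx <- which(labels == g)
        means[g, ] <- colMeans(scores[idx, , drop = FALSE])
        cg <- sweep(scores[idx, , drop = FALSE], 2L, means[g, ])
        covs[[g]] <- crossprod(cg) / length(idx)
        pooled <- pooled + crossprod(cg) / n
    }
    sigma2 <- mean(diag(pooled))
    for (g in classes)
        covs[[g]] <- (1 - regGamma) * covs[[g]] +
            diag(regGamma * sigma2 + ridge, d)
    new("QDAModel", classLabels = classes, means = means,
        covariances = covs, regGamma = regGamma, ridge = ridge)
}

#' Classify samples with a quadratic discriminant model
#'
#' Assigns each sample to the class with the largest Gaussian log density
#' (uniform priors). Exact ties go to the lexicographically lowest label.
#'
#' @param object A [QDAModel-class].
#' @param newdata Samples x dimensions matrix.
#' @return Character vector of predicted labels.
#' @export
setMethod("predict", "QDAModel", function(object, newdata) {
    newdata <- as.matrix(newdata)
    disc <- vapply(object@classLabels, function(g) {
        S <- object@covariances[[g]]
        ch <- chol(S)
        dev <- sweep(newdata, 2L, object@means[g, ])
        z <- backsolve(ch, t(dev), transpose = TRUE)
        -sum(log(diag(ch))) - 0.5 * colSums(z^2)
    }, numeric(nrow(newdata)))
    disc <- matrix(disc, nrow = nrow(newdata))
    object@classLabels[apply(disc, 1L, which.max)]
})

#' Leave-one-out cross-validated classification
#'
#' For each sample, the MMC projection and the quadratic discriminant are
#' refit on the remaining samples (no information leakage), the held-out
#' sample is projected and classified, and results are aggregated into a
#' confusion matrix and correct classification rate.
#'
#' @param x Samples x variables matrix or a [SpectrumSet-class]
#'   (log-scale data recommended).
#' @param labels Class labels; every class needs at least three samples so
#'   two remain after leave-out.
#' @param k MMC components (default classes - 1, capped per fold).
#' @param regGamma,ridge Passed to [qdaFit()].
#' @return A [CVResult-class].
#' @export
looCv <- function(x, labels = NULL, k = NULL, regGamma = 0.5, ridge = 1e-6) {
    m <- .asMatrix(x)
    labels <- .labelsFor(x, labels)
    cnt <- table(labels)
    if (any(cnt < 3L))
        stop("every class needs >= 3 samples for leave-one-out; offending: ",
             paste(names(cnt)[cnt < 3L], collapse = ", "))
    n <- nrow(m)
    classes <- sort(unique(labels))
    pred <- character(n)
    for (i in seq_len(n)) {
        tr <- m[-i, , drop = FALSE]
        trLab <- labels[-i]
        kFold <- if (is.null(k)) NULL
                 else min(k, length(unique(trLab)) - 1L)
        mmc <- mmcFit(tr, trLab, k = kFold)
        qda <- qdaFit(mmc@scores, trLab, regGamma, ridge)
        pred[i] <- predict(qda, mmcProject(mmc, m[i, , drop = FALSE]))
    }
    ids <- rownames(m)
    if (is.null(ids)) ids <- as.character(seq_len(n))
    conf <- table(factor(labels, classes), factor(pred, classes))
    conf <- unclass(conf)
    names(dimnames(conf)) <- c("truth", "predicted")
    new("CVResult",
        predictions = data.frame(sample_id = ids, truth = labels,
                                 predicted = pred, stringsAsFactors = FALSE),
        correctRate = mean(pred == labels),
        confusion = conf)
}
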