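#' Exclude chemical-shift regions
#'
#' Retains spectral points `p` with `keepMin <= p <= keepMax` that fall in no
#' `drop` interval (closed-interval exclusion). The defaults discard the
#' region upfield of 0.8 ppm, downfield of 10 ppm and the residual water
#' region 4.7-5.2 ppm. Idempotent; column order is preserved.
#'
#' @param set A [SpectrumSet-class].
#' @param keepMin,keepMax Retained ppm window.
#' @param drop List of length-2 numeric vectors, closed ppm intervals to
#'   exclude.
#' @return A [SpectrumSet-class] restricted to the retained points.
#' @export
excludeRegions <- function(set, keepMin = 0.8, keepMax = 10.0,
                           drop = list(c(4.7, 5.2))) {
    stopifnot(is(set, "SpectrumSet"), keepMin < keepMax)
    p <- ppm(set)
    keep <- p >= keepMin & p <= keepMax
    for (iv in drop) {
        stopifnot(length(iv) == 2L)
        keep <- keep & !(p >= min(iv) & p <= max(iv))
    }
    if (!any(keep))
        stop("region exclusion removed every spectral point")
    set[keep, ]
}

#' Probabilistic quotient normalization
#'
#' Corrects per-sample dilution under a multiplicative model:
#' (1) each spectrum is integral-normalized to the median positive-part row
#' sum; (2) the reference is the element-wise median spectrum (even counts:
#' mean of the middle two); (3) quotients `x_iv / r_v` are formed over
#' variables where both the reference and the sample are positive;
#' (4) the per-sample dilution residual is the median quotient; (5) each
#' spectrum is divided by it. The returned dilution factor per sample is the
#' total factor (integral scale times quotient median), so the output equals
#' the input divided by it.
#'
#' @param set A [SpectrumSet-class] (region-excluded, unlogged intensities).
#' @param minQuotientVars Minimum usable quotient variables per sample below
#'   which the median is deemed unreliable (error).
#' @return List with `set` (normalized [SpectrumSet-class]) and
#'   `dilutionFactors` (named numeric).
#' @export
pqnNormalize <- function(set, minQuotientVars = 10L) {
    stopifnot(is(set, "SpectrumSet"), ncol(set) >= 1L)
    x <- intensityMatrix(set)
    possum <- apply(x, 1L, function(r) sum(r[r > 0]))
    if (any(possum <= 0))
        stop("sample(s) with no positive intensity: ",
             paste(rownames(x)[possum <= 0], collapse = ", "))
    s <- possum / stats::median(possum)
    y <- x / s
    r <- apply(y, 2L, stats::median)
    dq <- vapply(seq_len(nrow(y)), function(i) {
        use <- r > 0 & y[i, ] > 0
        if (sum(use) < minQuotientVars)
            stop("sample '", rownames(x)[i], "' has only ", sum(use),
                 " usable quotient variables (need >= ", minQuotientVars,
                 "); quotient median unreliable")
        stats::median(y[i, use] / r[use])
    }, numeric(1))
    out <- y / dq
    d <- setNames(s * dq, rownames(x))
    list(set = setIntensities(set, out), dilutionFactors = d)
}

# shift a segment by s grid points, filling vacated positions with the edge
# value of the segment (positive s moves intensity toward higher indices)
.shiftSegment <- function(seg, s) {
    L <- length(seg)
    if (s == 0 || abs(s) >= L) return(if (s == 0) seg else rep(seg[1], L))
    if (s > 0) c(rep(seg[1], s), seg[seq_len(L - s)])
    else c(seg[(1 - s):L], rep(seg[L], -s))
}

# best integer shift in [-w, w] maximizing correlation with the reference
# segment; candidates visited in order of increasing |s| (0, -1, +1, ...) so
# ties resolve toward the smallest shift
.bestShift <- function(refSeg, testSeg, w) {
    best <- list(s = 0L, r = corSafe(refSeg, testSeg))
    if (w < 1L) return(best)
    for (a in seq_len(w)) for (s in c(-a, a)) {
        r <- corSafe(refSeg, .shiftSegment(testSeg, s))
        if (r > best$r + 1e-12) best <- list(s = as.integer(s), r = r)
    }
    best
}

#' Recursive segment-wise peak alignment
#'
#' Aligns every spectrum to a reference (the sample with the highest mean
#' Pearson correlation to all others; ties go to the lexicographically lowest
#' sample id) by recursive bisection. At each node the integer shift within
#' the current window that maximizes the Pearson correlation to the reference
#' segment is applied (vacated points filled with the segment edge value);
#' if the correlation is still below `stopCorr` and the segment is long
#' enough, the segment is split at its minimum-intensity point within the
#' middle third and both halves are aligned with a halved window. The window
#' passed to children is additionally capped so that no point accumulates a
#' total shift beyond the initial window. A spectrum whose overall
#' correlation to the reference would decrease is restored unshifted.
#'
#' @param set A [SpectrumSet-class] on a uniform acquisition grid, at least
#'   two samples. Isolated larger gaps left by region exclusion are
#'   permitted: alignment operates in index space with the base grid step.
#' @param maxShiftPpm Maximum (initial window) shift in ppm.
#' @param minSegmentPoints Minimum points per segment; segments shorter than
#'   twice this are not split further.
#' @param stopCorr Correlation at which a segment is considered aligned.
#' @return List with `set` (aligned), `referenceSampleId`, `shiftMap`
#'   (per-sample `data.frame` of applied segment shifts) and `meanCorrelation`
#'   (`data.frame` with pre/post correlation to the reference per sample).
#' @export
rspaAlign <- function(set, maxShiftPpm = 0.02, minSegmentPoints = 30L,
                      stopCorr = 0.98) {
    stopifnot(is(set, "SpectrumSet"))
    if (ncol(set) < 2L)
        stop("alignment needs at least two samples")
    p <- ppm(set)
    if (length(p) < minSegmentPoints)
        stop("fewer spectral points than minSegmentPoints")
    step <- diff(p)
    med <- stats::median(step)
    base <- step[step <= 1.5 * med]  # larger jumps = excluded-region bounds
    if (diff(range(base)) > 1e-6 * med)
        stop("rspaAlign requires a uniform acquisition grid")
    step <- med
    w0 <- as.integer(round(maxShiftPpm / step))
    x <- intensityMatrix(set)
    n <- nrow(x)
    cm <- suppressWarnings(stats::cor(t(x)))
    cm[is.na(cm)] <- 0
    diag(cm) <- NA
    meanCor <- rowMeans(cm, na.rm = TRUE)
    ord <- order(-meanCor, rownames(x))
    refIdx <- ord[1]
    ref <- x[refIdx, ]
    shiftMap <- vector("list", n)
    names(shiftMap) <- rownames(x)
    preCor <- postCor <- numeric(n)
    for (i in seq_len(n)) {
        preCor[i] <- corSafe(ref, x[i, ])
        if (i == refIdx) {
            postCor[i] <- preCor[i]
            shiftMap[[i]] <- data.frame(start_ppm = numeric(0),
                                        end_ppm = numeric(0),
                                        shift_points = integer(0))
            next
        }
        env <- new.env()
        env$row <- x[i, ]
        env$rec <- list()
        alignNode <- function(lo, hi, w, cum) {
            L <- hi - lo + 1L
            wEff <- min(w, w0 - abs(cum))
            b <- .bestShift(ref[lo:hi], env$row[lo:hi],
                            max(0L, min(wEff, L - 1L)))
            if (b$s != 0L) {
                env$row[lo:hi] <- .shiftSegment(env$row[lo:hi], b$s)
                env$rec[[length(env$rec) + 1L]] <-
                    data.frame(start_ppm = p[lo], end_ppm = p[hi],
                               shift_points = b$s)
            }
            cum <- cum + b$s
            if (b$r >= stopCorr || L < 2L * minSegmentPoints || w < 1L)
                return(invisible())
            midLo <- lo + L %/% 3L
            midHi <- hi - L %/% 3L
            sp <- midLo + which.min(env$row[midLo:midHi]) - 1L
            if (sp <= lo || sp >= hi) sp <- lo + L %/% 2L
            alignNode(lo, sp, w %/% 2L, cum)
            alignNode(sp + 1L, hi, w %/% 2L, cum)
            invisible()
        }
        alignNode(1L, length(p), w0, 0L)
        post <- corSafe(ref, env$row)
        if (post < preCor[i]) {  # safety revert; alignment must not hurt
            env$row <- x[i, ]
            env$rec <- list()
            post <- preCor[i]
        }
        x[i, ] <- env$row
        postCor[i] <- post
        shiftMap[[i]] <- if (length(env$rec)) do.call(rbind, env$rec)
                         else data.frame(start_ppm = numeric(0),
                                         end_ppm = numeric(0),
                                         shift_points = integer(0))
    }
    list(set = setIntensities(set, x),
         referenceSampleId = rownames(x)[refIdx],
         shiftMap = shiftMap,
         meanCorrelation = data.frame(sample_id = rownames(x),
                                      pre = preCor, post = postCor,
                                      stringsAsFactors = FALSE))
}

#' Log transformation
#'
#' `y = ln(x + c)`, converting multiplicative intensity noise into additive
#' noise. `offset` may be a non-negative number or one of three automatic
#' modes:
#'
#' * `"auto"`: `c` = the smallest positive intensity in the set (errors if
#'   any value is non-positive after adding it).
#' * `"auto-shift"`: the smallest positive intensity minus the most negative
#'   value; always yields positive arguments.
#' * `"noise-floor"` (pipeline default): `c = 20 * sigma`, where `sigma` is
#'   the additive noise scale estimated from the negative baseline points
#'   (root mean square, the half-normal estimator). This is a
#'   variance-stabilizing choice: baseline cells then fluctuate by at most
#'   about 0.05 log units instead of diverging as `ln` approaches its pole,
#'   while peak intensities, which stand far above the noise floor, keep
#'   their multiplicative-to-additive conversion. Falls back to
#'   `"auto-shift"` when no negative values exist.
#'
#' @param set A [SpectrumSet-class].
#' @param offset Non-negative numeric, `"auto"`, `"auto-shift"`, or
#'   `"noise-floor"`.
#' @return List with `set` (transformed) and `logOffset` (the `c` used).
#' @export
logTransform <- function(set, offset = "auto") {
    stopifnot(is(set, "SpectrumSet"))
    x <- intensityMatrix(set)
    pos <- x[x > 0]
    if (!length(pos))
        stop("no positive intensities; cannot choose a log offset")
    cOff <- if (identical(offset, "auto")) min(pos)
        else if (identical(offset, "auto-shift")) min(pos) - min(0, min(x))
        else if (identical(offset, "noise-floor")) {
            neg <- x[x < 0]
            if (length(neg)) 20 * sqrt(mean(neg^2))
            else min(pos) - min(0, min(x))
        }
        else {
            stopifnot(is.numeric(offset), offset >= 0)
            as.numeric(offset)
        }
    bad <- sum(x + cOff <= 0)
    if (bad > 0)
        stop(bad, " cell(s) non-positive after adding offset ", cOff,
             "; increase the offset")
    list(set = setIntensities(set, log(x + cOff)), logOffset = cOff)
}

#' Run the full preprocessing chain
#'
#' Convenience wrapper applying, in order: region exclusion, probabilistic
#' quotient normalization, recursive segment-wise peak alignment and log
#' transformation. Any stage can be disabled. Returns both the final
#' (log-scale) set and the aligned-but-unlogged set, which downstream fold
#' changes are computed from.
#'
#' @param set A raw [SpectrumSet-class].
#' @param keepMin,keepMax,drop Passed to [excludeRegions()] (set
#'   `exclude = FALSE` to skip).
#' @param exclude,pqn,align,logScale Logical switches for the four stages.
#' @param maxShiftPpm,minSegmentPoints,stopCorr Passed to [rspaAlign()].
#' @param logOffset Passed to [logTransform()]; default `"noise-floor"`.
#' @return List with `set` (final), `unlogged` (post-alignment, pre-log) and
#'   `report` (a [PreprocessReport-class]).
#' @export
preprocessSpectra <- function(set, keepMin = 0.8, keepMax = 10.0,
                              drop = list(c(4.7, 5.2)),
                              exclude = TRUE, pqn = TRUE, align = TRUE,
                              logScale = TRUE, maxShiftPpm = 0.02,
                              minSegmentPoints = 30L, stopCorr = 0.98,
                              logOffset = "noise-floor") {
    stages <- character(0)
    dil <- numeric(0); refId <- NA_character_
    shiftMap <- list(); logOff <- NA_real_
    if (exclude) {
        set <- excludeRegions(set, keepMin, keepMax, drop)
        stages <- c(stages, "exclude")
    }
    if (pqn) {
        res <- pqnNormalize(set)
        set <- res$set; dil <- res$dilutionFactors
        stages <- c(stages, "pqn")
    }
    if (align) {
        res <- rspaAlign(set, maxShiftPpm, minSegmentPoints, stopCorr)
        set <- res$set; refId <- res$referenceSampleId
        shiftMap <- res$shiftMap
        stages <- c(stages, "rspa")
    }
    unlogged <- set
    if (logScale) {
        res <- logTransform(set, logOffset)
        set <- res$set; logOff <- res$logOffset
        stages <- c(stages, "log")
    }
    report <- new("PreprocessReport",
                  excludedRegions = if (exclude) drop else list(),
                  keepRange = if (exclude) c(keepMin, keepMax)
                              else range(ppm(set)),
                  dilutionFactors = dil,
                  referenceSampleId = refId,
                  shiftMap = shiftMap,
                  logOffset = logOff,
                  stageOrder = stages)
    list(set = set, unlogged = unlogged, report = report)
}
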