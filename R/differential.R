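#' Per-variable one-way ANOVA
#'
#' Vectorized one-way F test across all spectral variables:
#' `F = MSB / MSW` with `k - 1` and `n - k` degrees of freedom, p-values from
#' the upper tail of the F distribution. Degenerate variables follow the
#' conventions: `MSW = 0, MSB = 0` gives `F = 0, p = 1`;
#' `MSW = 0, MSB > 0` gives infinite F and p floored at `1e-300`.
#'
#' @param x Samples x variables matrix (log scale recommended), or a
#'   [SpectrumSet-class].
#' @param labels Group labels; at least two groups, each with at least two
#'   samples.
#' @return `data.frame` with columns `F` and `p`, one row per variable.
#' @export
anovaPerVariable <- function(x, labels = NULL) {
    m <- .asMatrix(x)
    labels <- .labelsFor(x, labels)
    f <- factor(labels)
    kk <- nlevels(f)
    n <- nrow(m)
    cnt <- table(f)
    if (kk < 2L) stop("need at least two groups")
    if (any(cnt < 2L))
        stop("group(s) with a single sample: ",
             paste(names(cnt)[cnt < 2L], collapse = ", "))
    gm <- rowsum(m, f) / as.vector(cnt)
    grand <- colMeans(m)
    ssb <- colSums(as.vector(cnt) * sweep(gm, 2L, grand)^2)
    ssw <- colSums((m - gm[as.integer(f), , drop = FALSE])^2)
    msb <- ssb / (kk - 1L)
    msw <- ssw / (n - kk)
    F <- msb / msw
    p <- stats::pf(F, kk - 1L, n - kk, lower.tail = FALSE)
    zeroW <- msw == 0
    F[zeroW & msb == 0] <- 0
    p[zeroW & msb == 0] <- 1
    F[zeroW & msb > 0] <- Inf
    p[zeroW & msb > 0] <- 1e-300
    p <- pmax(p, 1e-300)
    data.frame(F = F, p = p)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up BH adjustment: `q(i) = min_{j >= i} p(j) * m / j` over the
#' ascending-sorted p-values, capped at 1 and returned in input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, `q >= p` element-wise.
#' @export
bhAdjust <- function(p) {
    if (anyNA(p) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' pFDR threshold of the BH procedure
#'
#' The largest raw p-value declared significant by the step-up walk at the
#' given FDR level: the largest `i` (ascending order) with
#' `p(i) <= i * level / m`. Variables with `p <= pFDR` form the significant
#' set.
#'
#' @param p Numeric p-values in \[0, 1\].
#' @param fdrLevel Nominal FDR control level (default 0.1).
#' @return The threshold p-value, or `NA` when nothing qualifies.
#' @export
pfdrThreshold <- function(p, fdrLevel = 0.1) {
    if (anyNA(p) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1]")
    m <- length(p)
    ps <- sort(p)
    ok <- which(ps <= seq_len(m) * fdrLevel / m)
    if (!length(ok)) return(NA_real_)
    ps[max(ok)]
}

#' Per-variable log2 fold changes
#'
#' `log2(mean_A / mean_B)` of group mean intensities per variable, computed
#' on normalized *unlogged* intensities. Variables where either group mean is
#' non-positive get `NA` (flagged, not fatal).
#'
#' @param x Samples x variables matrix of normalized unlogged intensities,
#'   or a [SpectrumSet-class].
#' @param labels Group labels.
#' @param pair Character length-2, `c(A, B)`; the ratio is A over B.
#' @return Numeric vector of log2 fold changes with attribute `"flagged"`
#'   giving the indices of undefined variables.
#' @export
log2FoldChanges <- function(x, labels = NULL, pair) {
    m <- .asMatrix(x)
    labels <- .labelsFor(x, labels)
    stopifnot(length(pair) == 2L)
    ia <- labels == pair[1]; ib <- labels == pair[2]
    if (!any(ia) || !any(ib))
        stop("empty group in pair: ", paste(pair, collapse = " vs "))
    ma <- colMeans(m[ia, , drop = FALSE])
    mb <- colMeans(m[ib, , drop = FALSE])
    bad <- which(ma <= 0 | mb <= 0)
    fc <- suppressWarnings(log2(ma / mb))  # non-positive means flagged below
    fc[bad] <- NA_real_
    attr(fc, "flagged") <- bad
    fc
}

#' Assign significant variables to library metabolites
#'
#' A metabolite is called when at least one significant variable lies within
#' `tolPpm` of any of its library multiplet centers. The representative ppm
#' is the matched variable with the largest `|mean_diff_log|`; the call
#' direction is that variable's sign. Variables matching two or more
#' metabolites are flagged ambiguous and listed under every match (never
#' silently dropped).
#'
#' @param significant `data.frame` of significant variables with columns
#'   `ppm`, `mean_diff_log`, `p`, `q` and optionally `log2_fc`.
#' @param library A [PeakLibrary-class].
#' @param tolPpm Matching tolerance in ppm (default 0.01, intended for
#'   aligned spectra).
#' @return `data.frame` with columns `name`, `hmdb`, `representative_ppm`,
#'   `direction`, `log2_fc`, `p`, `q`, `ambiguous` and list column
#'   `matched_ppms`.
#' @export
assignPeaksToMetabolites <- function(significant, library, tolPpm = 0.01) {
    stopifnot(is(library, "PeakLibrary"))
    pk <- peakTable(library)
    if (nrow(pk) == 0L) stop("empty peak library")
    empty <- data.frame(name = character(0), hmdb = character(0),
                        representative_ppm = numeric(0),
                        direction = character(0), log2_fc = numeric(0),
                        p = numeric(0), q = numeric(0),
                        ambiguous = logical(0))
    empty$matched_ppms <- list()
    if (is.null(significant) || nrow(significant) == 0L) return(empty)
    if (!"log2_fc" %in% names(significant)) significant$log2_fc <- NA_real_
    # variables x metabolites match map
    nmatch <- vapply(seq_len(nrow(significant)), function(i)
        length(unique(pk$name[abs(pk$ppm - significant$ppm[i]) <= tolPpm])),
        integer(1))
    calls <- lapply(metaboliteNames(library), function(nm) {
        centers <- pk$ppm[pk$name == nm]
        hit <- vapply(significant$ppm, function(v)
            any(abs(centers - v) <= tolPpm), logical(1))
        if (!any(hit)) return(NULL)
        sub <- significant[hit, , drop = FALSE]
        rep <- which.max(abs(sub$mean_diff_log))
        data.frame(name = nm, hmdb = pk$hmdb[pk$name == nm][1],
                   representative_ppm = sub$ppm[rep],
                   direction = if (sub$mean_diff_log[rep] >= 0) "up" else "down",
                   log2_fc = sub$log2_fc[rep],
                   p = sub$p[rep], q = sub$q[rep],
                   ambiguous = any(nmatch[hit] > 1L),
                   matched_ppms = I(list(sub$ppm)),
                   stringsAsFactors = FALSE)
    })
    calls <- calls[!vapply(calls, is.null, logical(1))]
    if (!length(calls)) return(empty)
    out <- do.call(rbind, calls)
    rownames(out) <- NULL
    out
}

#' Median-centered heat-map matrix
#'
#' Subtracts the across-sample median from every variable, the display
#' convention where positive values render red (more intense than the median
#' sample) and negative render blue.
#'
#' @param x Samples x variables matrix or a [SpectrumSet-class].
#' @return Matrix of the same shape, column medians zero.
#' @export
heatmapMatrix <- function(x) {
    m <- .asMatrix(x)
    sweep(m, 2L, apply(m, 2L, stats::median))
}

#' Signed ANOVA trace for a two-group comparison
#'
#' Per-variable signed statistic `mean_A - mean_B` on the log scale, with
#' q-values and a significance flag (`p <= pFDR`). Positive entries are
#' variables more intense in group A.
#'
#' @param x Samples x variables log-scale matrix or [SpectrumSet-class].
#' @param labels Group labels.
#' @param pair Character length-2 `c(A, B)`; only these two groups enter.
#' @param qValues Optional precomputed q-values (defaults to BH on the
#'   computed p-values).
#' @param fdrLevel Nominal FDR level for the significance flag.
#' @return `data.frame` with columns `stat`, `p`, `q`, `significant` (plus
#'   `ppm` for [SpectrumSet-class] input).
#' @export
anovaTrace <- function(x, labels = NULL, pair, qValues = NULL,
                       fdrLevel = 0.1) {
    m <- .asMatrix(x)
    labels <- .labelsFor(x, labels)
    stopifnot(length(pair) == 2L)
    if (length(unique(labels)) > 2L)
        stop("anovaTrace is pairwise; got more than two groups")
    use <- labels %in% pair
    if (length(unique(labels[use])) != 2L)
        stop("both groups of 'pair' must be present")
    m <- m[use, , drop = FALSE]
    labels <- labels[use]
    av <- anovaPerVariable(m, labels)
    if (is.null(qValues)) qValues <- bhAdjust(av$p)
    thr <- pfdrThreshold(av$p, fdrLevel)
    stat <- colMeans(m[labels == pair[1], , drop = FALSE]) -
        colMeans(m[labels == pair[2], , drop = FALSE])
    out <- data.frame(stat = stat, p = av$p, q = qValues,
                      significant = !is.na(thr) & av$p <= thr)
    if (is(x, "SpectrumSet")) out <- cbind(ppm = ppm(x), out)
    rownames(out) <- NULL
    out
}

#' Two-group differential analysis with FDR control and metabolite calls
#'
#' The full univariate stage for one mutant-vs-wild-type comparison:
#' per-variable one-way ANOVA on the log-scale data, BH q-values and the
#' pFDR threshold at the chosen FDR level, per-variable log2 fold changes on
#' the normalized unlogged data, and assignment of significant variables to
#' library metabolites with direction and representative fold change.
#'
#' @param logSet Log-transformed [SpectrumSet-class] (post-alignment).
#' @param unloggedSet The matching normalized unlogged [SpectrumSet-class]
#'   (same samples and variables).
#' @param pair Character length-2 `c(A, B)` of genotype labels (A vs B).
#' @param library A [PeakLibrary-class] for metabolite assignment.
#' @param fdrLevel Nominal FDR control level (default 0.1).
#' @param tolPpm Peak-matching tolerance in ppm (default 0.01).
#' @return A [DifferentialResult-class].
#' @export
differentialAnalysis <- function(logSet, unloggedSet, pair,
                                 library = defaultPeakLibrary(),
                                 fdrLevel = 0.1, tolPpm = 0.01) {
    stopifnot(is(logSet, "SpectrumSet"), is(unloggedSet, "SpectrumSet"),
              length(pair) == 2L, fdrLevel > 0, fdrLevel < 1)
    if (!isTRUE(all.equal(ppm(logSet), ppm(unloggedSet))) ||
        !identical(colnames(logSet), colnames(unloggedSet)))
        stop("logSet and unloggedSet must share samples and ppm grid")
    labels <- colData(logSet)$genotype
    use <- labels %in% pair
    if (sum(labels == pair[1]) < 2L || sum(labels == pair[2]) < 2L)
        stop("both groups need >= 2 samples")
    logM <- intensityMatrix(logSet)[use, , drop = FALSE]
    rawM <- intensityMatrix(unloggedSet)[use, , drop = FALSE]
    lab <- labels[use]
    av <- anovaPerVariable(logM, lab)
    q <- bhAdjust(av$p)
    thr <- pfdrThreshold(av$p, fdrLevel)
    mdl <- colMeans(logM[lab == pair[1], , drop = FALSE]) -
        colMeans(logM[lab == pair[2], , drop = FALSE])
    fc <- log2FoldChanges(rawM, lab, pair)
    vars <- data.frame(ppm = ppm(logSet), F = av$F, p = av$p, q = q,
                       mean_diff_log = mdl, sign = sign(mdl),
                       log2_fc = as.numeric(fc),
                       significant = !is.na(thr) & av$p <= thr)
    rownames(vars) <- NULL
    mets <- assignPeaksToMetabolites(vars[vars$significant, , drop = FALSE],
                                     library, tolPpm)
    new("DifferentialResult", comparison = as.character(pair),
        variables = vars, metabolites = mets,
        pfdr = if (is.na(thr)) NA_real_ else thr, fdrLevel = fdrLevel)
}

#' Write the differential output tables
#'
#' Writes the stable tab-separated outputs for one comparison:
#' `variables.tsv` (per-variable statistics), `table2.tsv` (per-metabolite
#' calls: metabolite, hmdb, ppm, p, q, log2_fc), `anova_trace.tsv` and
#' `heatmap.tsv` (median-centered display matrix).
#'
#' @param result A [DifferentialResult-class].
#' @param logSet The log-scale [SpectrumSet-class] the result came from.
#' @param dir Output directory (created if needed).
#' @param prefix Filename prefix, e.g. `"G13D_vs_WT_"`.
#' @return Invisibly, the written paths.
#' @export
writeDifferentialTables <- function(result, logSet, dir, prefix = "") {
    stopifnot(is(result, "DifferentialResult"))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- file.path(dir, paste0(prefix, c("variables.tsv", "table2.tsv",
                                             "anova_trace.tsv",
                                             "heatmap.tsv")))
    utils::write.table(variableStats(result), paths[1], sep = "\t",
                       row.names = FALSE, quote = FALSE)
    mets <- metaboliteCalls(result)
    tab2 <- data.frame(metabolite = mets$name, hmdb = mets$hmdb,
                       ppm = mets$representative_ppm,
                       direction = mets$direction, p = mets$p, q = mets$q,
                       log2_fc = mets$log2_fc, ambiguous = mets$ambiguous)
    utils::write.table(tab2, paths[2], sep = "\t", row.names = FALSE,
                       quote = FALSE)
    labels <- colData(logSet)$genotype
    use <- labels %in% result@comparison
    tr <- anovaTrace(intensityMatrix(logSet)[use, , drop = FALSE],
                     labels[use], result@comparison,
                     fdrLevel = result@fdrLevel)
    utils::write.table(cbind(ppm = ppm(logSet), tr), paths[3], sep = "\t",
                       row.names = FALSE, quote = FALSE)
    hm <- heatmapMatrix(intensityMatrix(logSet)[use, , drop = FALSE])
    utils::write.table(
        data.frame(sample_id = rownames(hm), hm, check.names = FALSE),
        paths[4], sep = "\t", row.names = FALSE, quote = FALSE)
    invisible(paths)
}
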