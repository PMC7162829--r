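#' @describeIn ppm ppm axis stored in `rowData`.
#' @export
setMethod("ppm", "SpectrumSet", function(x) rowData(x)$ppm)

#' @describeIn intensityMatrix samples x points intensity matrix.
#' @export
setMethod("intensityMatrix", "SpectrumSet", function(x) {
    m <- t(assay(x, "intensity"))
    dimnames(m) <- list(colnames(x), format(ppm(x), trim = TRUE))
    m
})

#' @describeIn sampleInfo sample annotation as a base `data.frame`.
#' @export
setMethod("sampleInfo", "SpectrumSet", function(x) {
    cd <- colData(x)
    data.frame(sample_id = rownames(cd),
               genotype = cd$genotype,
               replicate = cd$replicate,
               compartment = cd$compartment,
               stringsAsFactors = FALSE)
})

# internal: replace the intensity matrix (samples x points), keeping metadata
setIntensities <- function(x, m) {
    stopifnot(nrow(m) == ncol(x), ncol(m) == nrow(x))
    assays(x, withDimnames = FALSE)[["intensity"]] <- t(unname(as.matrix(m)))
    validObject(x)
    x
}

#' @importFrom SummarizedExperiment assays<-
NULL

#' @describeIn peakTable full multiplet table.
#' @export
setMethod("peakTable", "PeakLibrary", function(x) x@peaks)

#' @describeIn metaboliteNames unique names in library order.
#' @export
setMethod("metaboliteNames", "PeakLibrary",
          function(x) unique(x@peaks$name))

#' @describeIn metaboliteNames metabolites of the design's library.
#' @export
setMethod("metaboliteNames", "SimDesign",
          function(x) metaboliteNames(x@library))

#' HMDB accessions of a peak library
#'
#' @param x A [PeakLibrary-class].
#' @return Named character vector (names = metabolite names).
#' @export
hmdbIds <- function(x) {
    stopifnot(is(x, "PeakLibrary"))
    tab <- unique(x@peaks[, c("name", "hmdb")])
    setNames(tab$hmdb, tab$name)
}

#' @describeIn pathwayNames names of the member sets.
#' @export
setMethod("pathwayNames", "PathwayLibrary", function(x) names(x@sets))

#' @describeIn pathwayMembers the member sets.
#' @export
setMethod("pathwayMembers", "PathwayLibrary", function(x) x@sets)

#' @describeIn variableStats per-variable table.
#' @export
setMethod("variableStats", "DifferentialResult", function(x) x@variables)

#' @describeIn metaboliteCalls per-metabolite calls.
#' @export
setMethod("metaboliteCalls", "DifferentialResult", function(x) x@metabolites)

#' @describeIn pfdr threshold for the stored comparison.
#' @export
setMethod("pfdr", "DifferentialResult", function(x) x@pfdr)

#' @describeIn correctRate fraction correct.
#' @export
setMethod("correctRate", "CVResult", function(x) x@correctRate)

#' @describeIn confusion count matrix.
#' @export
setMethod("confusion", "CVResult", function(x) x@confusion)

setMethod("show", "SpectrumSet", function(object) {
    p <- ppm(object)
    cat("SpectrumSet:", ncol(object), "samples x", nrow(object),
        "points,", sprintf("%.3f-%.3f ppm\n", min(p), max(p)))
    gt <- table(colData(object)$genotype)
    cat("genotypes:", paste(sprintf("%s(%d)", names(gt), gt), collapse = " "),
        "\n")
})

setMethod("show", "PeakLibrary", function(object) {
    cat("PeakLibrary:", length(metaboliteNames(object)), "metabolites,",
        nrow(object@peaks), "multiplets,",
        sprintf("%.3f-%.3f ppm\n", min(object@peaks$ppm),
                max(object@peaks$ppm)))
})

setMethod("show", "PathwayLibrary", function(object) {
    cat("PathwayLibrary:", length(object@sets), "pathways, set sizes",
        paste(range(lengths(object@sets)), collapse = "-"), "\n")
})

setMethod("show", "SimDesign", function(object) {
    cat("SimDesign:", length(object@classLabels), "classes x",
        paste(unique(object@nPerClass), collapse = "/"), "replicates,",
        length(metaboliteNames(object)), "metabolites\n")
    cat(sprintf("grid %.2f-%.2f ppm (%d points), %g MHz, linewidth %g Hz\n",
                object@gridMin, object@gridMax, object@nPoints,
                object@freqMhz, object@linewidthHz))
    cat(sprintf("jitter sd %g ppm, dilution log-sd %g, noise sd %g, seed %d\n",
                object@jitterSdPpm, object@dilutionLogSd, object@noiseSd,
                object@seed))
})

setMethod("show", "MMCModel", function(object) {
    cat("MMCModel:", ncol(object@projection), "components over",
        length(object@classLabels), "classes (basis rank",
        object@basisRank, ")\n")
    cat("eigenvalues:", paste(signif(object@eigenvalues, 4), collapse = " "),
        "\n")
})

setMethod("show", "CVResult", function(object) {
    cat(sprintf("CVResult: %d samples, correct rate %.1f%%\n",
                nrow(object@predictions), 100 * object@correctRate))
})

setMethod("show", "DifferentialResult", function(object) {
    cat(sprintf("DifferentialResult: %s vs %s, %d variables, %d significant (FDR %.2g)\n",
                object@comparison[1], object@comparison[2],
                nrow(object@variables), sum(object@variables$significant),
                object@fdrLevel))
    if (is.na(object@pfdr)) cat("pFDR: none significant\n")
    else cat(sprintf("pFDR = %.3g; %d metabolite calls\n", object@pfdr,
                     nrow(object@metabolites)))
})
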