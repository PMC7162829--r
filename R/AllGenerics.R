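#' Chemical-shift axis of a SpectrumSet
#'
#' @param x A [SpectrumSet-class].
#' @return Numeric vector of ppm values, strictly ascending.
#' @export
setGeneric("ppm", function(x) standardGeneric("ppm"))

#' Intensity matrix of a SpectrumSet
#'
#' Returns intensities with samples in rows and spectral variables in columns
#' (the orientation all pipeline math uses), with sample ids as row names and
#' formatted ppm values as column names.
#'
#' @param x A [SpectrumSet-class].
#' @return Numeric matrix, samples x points.
#' @export
setGeneric("intensityMatrix", function(x) standardGeneric("intensityMatrix"))

#' Sample annotation of a SpectrumSet
#'
#' @param x A [SpectrumSet-class].
#' @return `data.frame` with columns `sample_id`, `genotype`, `replicate`,
#'   `compartment`.
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' Peak table of a PeakLibrary
#'
#' @param x A [PeakLibrary-class].
#' @return `data.frame` with one row per multiplet.
#' @export
setGeneric("peakTable", function(x) standardGeneric("peakTable"))

#' Metabolite names in a library or design
#'
#' @param x A [PeakLibrary-class] or [SimDesign-class].
#' @return Character vector of unique metabolite names, in library order.
#' @export
setGeneric("metaboliteNames", function(x) standardGeneric("metaboliteNames"))

#' Pathway names of a PathwayLibrary
#'
#' @param x A [PathwayLibrary-class].
#' @return Character vector.
#' @export
setGeneric("pathwayNames", function(x) standardGeneric("pathwayNames"))

#' Pathway member sets
#'
#' @param x A [PathwayLibrary-class].
#' @return Named list of character vectors of HMDB accessions.
#' @export
setGeneric("pathwayMembers", function(x) standardGeneric("pathwayMembers"))

#' Per-variable statistics of a differential result
#'
#' @param x A [DifferentialResult-class].
#' @return `data.frame` of per-variable ANOVA/FDR statistics.
#' @export
setGeneric("variableStats", function(x) standardGeneric("variableStats"))

#' Metabolite calls of a differential result
#'
#' @param x A [DifferentialResult-class].
#' @return `data.frame` of per-metabolite calls (direction, log2 FC, p, q).
#' @export
setGeneric("metaboliteCalls", function(x) standardGeneric("metaboliteCalls"))

#' pFDR threshold of a differential result
#'
#' The largest raw p-value declared significant at the nominal FDR level
#' (`NA` when nothing is significant).
#'
#' @param x A [DifferentialResult-class].
#' @return Numeric scalar or `NA`.
#' @export
setGeneric("pfdr", function(x) standardGeneric("pfdr"))

#' Correct classification rate of a cross-validation result
#'
#' @param x A [CVResult-class].
#' @return Numeric scalar in \[0, 1\].
#' @export
setGeneric("correctRate", function(x) standardGeneric("correctRate"))

#' Confusion matrix of a cross-validation result
#'
#' @param x A [CVResult-class].
#' @return Truth x predicted integer count matrix.
#' @export
setGeneric("confusion", function(x) standardGeneric("confusion"))
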