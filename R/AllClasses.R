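#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
NULL

.MULTIPLICITY_CODES <- c("s", "d", "t", "q", "dd", "m")
.COMPARTMENTS <- c("intracellular", "extracellular")

#' Container for a set of 1D NMR spectra
#'
#' `SpectrumSet` extends [SummarizedExperiment::SummarizedExperiment] and holds
#' a set of one-dimensional spectra on a common chemical-shift grid. Rows are
#' spectral variables (ppm positions, stored strictly ascending), columns are
#' samples. The single assay `"intensity"` carries intensities in arbitrary
#' units; `rowData(x)$ppm` is the chemical-shift axis; `colData(x)` carries the
#' sample annotation (`genotype`, `replicate`, `compartment`).
#'
#' @slot ... inherited from `SummarizedExperiment`.
#' @seealso [SpectrumSet()] for construction from a samples-by-points matrix,
#'   [readSpectrumSet()] to load one from delimited text.
#' @exportClass SpectrumSet
setClass("SpectrumSet", contains = "SummarizedExperiment")

setValidity("SpectrumSet", function(object) {
    msg <- character()
    if (!"intensity" %in% names(assays(object)))
        msg <- c(msg, "assay 'intensity' is required")
    rd <- rowData(object)
    if (!"ppm" %in% names(rd)) {
        msg <- c(msg, "rowData must contain a numeric 'ppm' column")
    } else {
        p <- rd$ppm
        if (!is.numeric(p) || anyNA(p) || any(!is.finite(p)))
            msg <- c(msg, "ppm axis must be finite numeric")
        else if (length(p) > 1L && any(diff(p) <= 0))
            msg <- c(msg, "ppm axis must be strictly increasing")
    }
    if ("intensity" %in% names(assays(object))) {
        a <- assay(object, "intensity")
        if (!is.numeric(a) || any(!is.finite(a)))
            msg <- c(msg, "intensities must be finite numeric")
    }
    cd <- colData(object)
    need <- c("genotype", "replicate", "compartment")
    miss <- setdiff(need, names(cd))
    if (length(miss))
        msg <- c(msg, paste0("colData missing column(s): ",
                             paste(miss, collapse = ", ")))
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids must be unique")
    if ("genotype" %in% names(cd) &&
        (anyNA(cd$genotype) || any(!nzchar(cd$genotype))))
        msg <- c(msg, "genotype labels must be non-empty")
    if ("compartment" %in% names(cd) &&
        !all(cd$compartment %in% .COMPARTMENTS))
        msg <- c(msg, paste0("compartment must be one of: ",
                             paste(.COMPARTMENTS, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Construct a SpectrumSet
#'
#' @param ppm Numeric chemical-shift axis (ppm). May be supplied in any strict
#'   monotone order; it is stored ascending and the intensity columns are
#'   reordered to match.
#' @param intensities Numeric matrix, samples in rows and spectral points in
#'   columns (`nrow == nrow(sampleData)`, `ncol == length(ppm)`).
#' @param sampleData `data.frame` with columns `sample_id`, `genotype`,
#'   `replicate`, `compartment`.
#' @return A [SpectrumSet-class] object.
#' @export
SpectrumSet <- function(ppm, intensities, sampleData) {
    ppm <- as.numeric(ppm)
    intensities <- as.matrix(intensities)
    if (!is.data.frame(sampleData))
        sampleData <- as.data.frame(sampleData)
    need <- c("sample_id", "genotype", "replicate", "compartment")
    miss <- setdiff(need, names(sampleData))
    if (length(miss))
        stop("sampleData missing column(s): ", paste(miss, collapse = ", "))
    if (nrow(intensities) != nrow(sampleData))
        stop("intensity row count (", nrow(intensities),
             ") does not match number of samples (", nrow(sampleData), ")")
    if (ncol(intensities) != length(ppm))
        stop("intensity column count does not match length of ppm axis")
    if (anyDuplicated(ppm))
        stop("duplicate ppm values in axis")
    ord <- order(ppm)
    ppm <- ppm[ord]
    intensities <- intensities[, ord, drop = FALSE]
    ids <- as.character(sampleData$sample_id)
    if (anyDuplicated(ids))
        stop("duplicate sample_id: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    storage.mode(intensities) <- "double"
    cd <- DataFrame(genotype = as.character(sampleData$genotype),
                    replicate = as.integer(sampleData$replicate),
                    compartment = as.character(sampleData$compartment),
                    row.names = ids)
    se <- SummarizedExperiment(
        assays = list(intensity = t(unname(intensities))),
        rowData = DataFrame(ppm = ppm),
        colData = cd)
    new("SpectrumSet", se)
}

#' Metabolite peak library
#'
#' A table of metabolites and their 1H NMR multiplets: chemical-shift center
#' (ppm), multiplicity code (`s`, `d`, `t`, `q`, `dd`, `m`), coupling constant
#' J (Hz) and relative intensity. Used both by the forward simulator and for
#' peak-to-metabolite assignment of significant spectral variables.
#'
#' @slot peaks `data.frame` with one row per multiplet and columns
#'   `name`, `hmdb`, `ppm`, `multiplicity`, `j_hz`, `rel_intensity`.
#' @seealso [readPeakLibrary()], [defaultPeakLibrary()]
#' @exportClass PeakLibrary
setClass("PeakLibrary", representation(peaks = "data.frame"))

setValidity("PeakLibrary", function(object) {
    pk <- object@peaks
    msg <- character()
    need <- c("name", "hmdb", "ppm", "multiplicity", "j_hz", "rel_intensity")
    miss <- setdiff(need, names(pk))
    if (length(miss))
        return(paste0("peaks missing column(s): ", paste(miss, collapse = ", ")))
    if (nrow(pk) == 0L)
        msg <- c(msg, "library has no peaks")
    bad <- setdiff(unique(pk$multiplicity), .MULTIPLICITY_CODES)
    if (length(bad))
        msg <- c(msg, paste0("unknown multiplicity code(s): ",
                             paste(bad, collapse = ", ")))
    if (any(pk$ppm < 0 | pk$ppm > 12))
        msg <- c(msg, "peak ppm outside [0, 12]")
    if (any(pk$rel_intensity <= 0))
        msg <- c(msg, "rel_intensity must be > 0")
    if (any(pk$j_hz < 0))
        msg <- c(msg, "j_hz must be >= 0")
    nm <- unique(pk[, c("name", "hmdb")])
    if (anyDuplicated(nm$name))
        msg <- c(msg, paste0("duplicate metabolite name: ",
                             paste(nm$name[duplicated(nm$name)], collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Construct a PeakLibrary from a peak table
#'
#' @param peaks `data.frame` with columns `name`, `hmdb`, `ppm`,
#'   `multiplicity`, `j_hz`, `rel_intensity` (one row per multiplet).
#' @return A [PeakLibrary-class] object. HMDB accessions are normalized to the
#'   11-character zero-padded form (e.g. `HMDB00190` becomes `HMDB0000190`).
#' @export
PeakLibrary <- function(peaks) {
    peaks <- as.data.frame(peaks, stringsAsFactors = FALSE)
    peaks$name <- as.character(peaks$name)
    peaks$hmdb <- normalizeHmdb(as.character(peaks$hmdb))
    peaks$ppm <- as.numeric(peaks$ppm)
    peaks$multiplicity <- as.character(peaks$multiplicity)
    peaks$j_hz <- as.numeric(peaks$j_hz)
    peaks$rel_intensity <- as.numeric(peaks$rel_intensity)
    rownames(peaks) <- NULL
    new("PeakLibrary", peaks = peaks)
}

#' Pathway (metabolite-set) library
#'
#' Named metabolite sets keyed by HMDB accession, as parsed from a GMT file.
#'
#' @slot sets Named list of character vectors of HMDB accessions.
#' @slot descriptions Named character vector, one description per pathway.
#' @seealso [readPathwayLibrary()], [ora()]
#' @exportClass PathwayLibrary
setClass("PathwayLibrary",
         representation(sets = "list", descriptions = "character"))

setValidity("PathwayLibrary", function(object) {
    msg <- character()
    nm <- names(object@sets)
    if (is.null(nm) || anyNA(nm) || any(!nzchar(nm)))
        msg <- c(msg, "every pathway needs a non-empty name")
    else if (anyDuplicated(nm))
        msg <- c(msg, paste0("duplicate pathway name: ",
                             paste(nm[duplicated(nm)], collapse = ", ")))
    if (any(lengths(object@sets) == 0L))
        msg <- c(msg, "pathway member sets must be non-empty")
    if (!identical(names(object@descriptions), names(object@sets)))
        msg <- c(msg, "descriptions must be named like sets")
    if (length(msg)) msg else TRUE
})

#' Construct a PathwayLibrary
#'
#' @param sets Named list of character vectors (member HMDB accessions).
#' @param descriptions Optional character vector of pathway descriptions.
#' @return A [PathwayLibrary-class] object.
#' @export
PathwayLibrary <- function(sets, descriptions = NULL) {
    sets <- lapply(sets, function(v) unique(normalizeHmdb(trimws(v))))
    if (is.null(descriptions))
        descriptions <- setNames(rep("", length(sets)), names(sets))
    descriptions <- setNames(as.character(descriptions), names(sets))
    new("PathwayLibrary", sets = sets, descriptions = descriptions)
}

#' Simulation design for synthetic spectra
#'
#' Defines a multi-class experiment for the forward simulator: a peak library,
#' per-class per-metabolite log2 concentration effects, replicate counts, and
#' the acquisition/noise model (spectrometer frequency, ppm grid, Lorentzian
#' linewidth, chemical-shift jitter, log-normal dilution, additive noise).
#'
#' @slot library A [PeakLibrary-class].
#' @slot classLabels Character vector of genotype labels, one per class.
#' @slot effects Numeric matrix (classes x metabolites) of log2 effects
#'   relative to baseline concentration; dimnames required.
#' @slot nPerClass Integer replicate count per class.
#' @slot baselineConc Named positive baseline concentrations per metabolite.
#' @slot freqMhz,gridMin,gridMax,nPoints,linewidthHz,jitterSdPpm,dilutionLogSd,noiseSd
#'   Acquisition and noise parameters (see [simDesign()]).
#' @slot seed Integer RNG seed.
#' @exportClass SimDesign
setClass("SimDesign",
         representation(library = "PeakLibrary",
                        classLabels = "character",
                        effects = "matrix",
                        nPerClass = "integer",
                        baselineConc = "numeric",
                        freqMhz = "numeric",
                        gridMin = "numeric",
                        gridMax = "numeric",
                        nPoints = "integer",
                        linewidthHz = "numeric",
                        jitterSdPpm = "numeric",
                        dilutionLogSd = "numeric",
                        noiseSd = "numeric",
                        seed = "integer"))

setValidity("SimDesign", function(object) {
    msg <- character()
    mets <- metaboliteNames(object@library)
    if (length(object@classLabels) < 1L)
        msg <- c(msg, "at least one class required")
    if (anyDuplicated(object@classLabels))
        msg <- c(msg, "class labels must be unique")
    if (nrow(object@effects) != length(object@classLabels) ||
        !identical(colnames(object@effects), mets))
        msg <- c(msg, "effects must be a classes x metabolites matrix keyed by library metabolites")
    if (length(object@nPerClass) != length(object@classLabels) ||
        any(object@nPerClass < 1L))
        msg <- c(msg, "nPerClass must give >= 1 replicate per class")
    if (!identical(names(object@baselineConc), mets) ||
        any(object@baselineConc <= 0))
        msg <- c(msg, "baselineConc must be positive and keyed by library metabolites")
    if (object@gridMin >= object@gridMax)
        msg <- c(msg, "grid min must be < max")
    if (object@nPoints < 2L)
        msg <- c(msg, "grid needs >= 2 points")
    if (object@linewidthHz <= 0)
        msg <- c(msg, "linewidthHz must be > 0")
    if (object@jitterSdPpm < 0 || object@dilutionLogSd < 0 || object@noiseSd < 0)
        msg <- c(msg, "jitterSdPpm, dilutionLogSd and noiseSd must be >= 0")
    if (object@freqMhz <= 0)
        msg <- c(msg, "freqMhz must be > 0")
    if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated dataset
#'
#' @slot concentrations Samples x metabolites matrix of true concentrations
#'   `c_im = baseline_m * 2^beta_{g(i),m}`.
#' @slot dilutionFactors Per-sample positive dilution factors.
#' @slot shiftOffsets Samples x metabolites matrix of chemical-shift jitter
#'   (ppm) applied coherently to each metabolite's multiplets.
#' @slot classLabels Per-sample genotype labels.
#' @slot effects The class x metabolite log2 effect matrix used.
#' @exportClass GroundTruth
setClass("GroundTruth",
         representation(concentrations = "matrix",
                        dilutionFactors = "numeric",
                        shiftOffsets = "matrix",
                        classLabels = "character",
                        effects = "matrix"))

#' Principal component analysis model
#'
#' @slot center Per-variable means removed before decomposition.
#' @slot loadings Variables x components matrix with orthonormal columns.
#' @slot scores Samples x components score matrix (column means zero).
#' @slot explainedVarianceRatio Fraction of total centered variance per
#'   component, non-increasing.
#' @slot totalVariance Total centered variance of the input.
#' @exportClass PCAModel
setClass("PCAModel",
         representation(center = "numeric", loadings = "matrix",
                        scores = "matrix",
                        explainedVarianceRatio = "numeric",
                        totalVariance = "numeric"))

setValidity("PCAModel", function(object) {
    msg <- character()
    G <- crossprod(object@loadings)
    if (max(abs(G - diag(ncol(G)))) > 1e-8)
        msg <- c(msg, "loadings must be orthonormal")
    evr <- object@explainedVarianceRatio
    if (length(evr) && (any(diff(evr) > 1e-12) || sum(evr) > 1 + 1e-8))
        msg <- c(msg, "explainedVarianceRatio must be non-increasing with sum <= 1")
    if (length(object@scores) && max(abs(colMeans(object@scores))) > 1e-8)
        msg <- c(msg, "score columns must be centered")
    if (length(msg)) msg else TRUE
})

#' Maximum margin criterion projection model
#'
#' Supervised projection maximizing `tr(P' (S_b - S_w) P)` where `S_b` and
#' `S_w` are the between- and within-class scatter matrices, computed in a PCA
#' basis of the centered data for numerical stability when variables far
#' outnumber samples.
#'
#' @slot projection Variables x components matrix (columns unit norm).
#' @slot eigenvalues Eigenvalues of `S_b - S_w`, sorted descending.
#' @slot classLabels Ordered class label vector used in fitting.
#' @slot basisRank Rank of the PCA basis the scatter matrices were formed in.
#' @slot center Per-variable means removed before projection.
#' @slot scores Samples x components projected training scores.
#' @exportClass MMCModel
setClass("MMCModel",
         representation(projection = "matrix", eigenvalues = "numeric",
                        classLabels = "character", basisRank = "integer",
                        center = "numeric", scores = "matrix"))

setValidity("MMCModel", function(object) {
    msg <- character()
    ev <- object@eigenvalues
    if (length(ev) > 1L && any(diff(ev) > 1e-10))
        msg <- c(msg, "eigenvalues must be sorted descending")
    if (ncol(object@projection) != length(ev))
        msg <- c(msg, "one eigenvalue per projection column required")
    if (length(msg)) msg else TRUE
})

#' Regularized quadratic discriminant classifier
#'
#' Gaussian classifier with class-specific shrunken covariances
#' `(1 - gamma) * S_g + gamma * sigma2 * I + ridge * I`, where `sigma2` is the
#' mean diagonal of the pooled within-class covariance. Uniform class priors.
#'
#' @slot classLabels Class labels (lexicographic order).
#' @slot means Classes x dimensions matrix of class means.
#' @slot covariances List of regularized class covariance matrices.
#' @slot regGamma,ridge Regularization parameters used.
#' @exportClass QDAModel
setClass("QDAModel",
         representation(classLabels = "character", means = "matrix",
                        covariances = "list", regGamma = "numeric",
                        ridge = "numeric"))

#' Leave-one-out cross-validation result
#'
#' @slot predictions `data.frame` with columns `sample_id`, `truth`,
#'   `predicted`, one row per sample.
#' @slot correctRate Fraction of correct predictions.
#' @slot confusion Truth x predicted count matrix.
#' @exportClass CVResult
setClass("CVResult",
         representation(predictions = "data.frame", correctRate = "numeric",
                        confusion = "matrix"))

setValidity("CVResult", function(object) {
    n <- nrow(object@predictions)
    if (n && abs(object@correctRate - sum(diag(object@confusion)) / n) > 1e-12)
        return("correctRate must equal trace(confusion)/n")
    TRUE
})

#' Preprocessing report
#'
#' Records what the preprocessing stages did to a [SpectrumSet-class]: the
#' excluded ppm regions, per-sample PQN dilution factors, the alignment
#' reference and applied segment shifts, and the log-transform offset.
#'
#' @slot excludedRegions List of length-2 numeric ppm intervals dropped.
#' @slot keepRange Numeric length-2, the retained ppm window.
#' @slot dilutionFactors Named per-sample PQN dilution factors.
#' @slot referenceSampleId Alignment reference sample id.
#' @slot shiftMap Per-sample list of applied segment shifts
#'   (`data.frame` with `start_ppm`, `end_ppm`, `shift_points`).
#' @slot logOffset Offset added before the log transform.
#' @slot stageOrder Character vector of stages in execution order.
#' @exportClass PreprocessReport
setClass("PreprocessReport",
         representation(excludedRegions = "list", keepRange = "numeric",
                        dilutionFactors = "numeric",
                        referenceSampleId = "character",
                        shiftMap = "list", logOffset = "numeric",
                        stageOrder = "character"))

#' Differential analysis result for a two-group comparison
#'
#' Holds the per-variable one-way ANOVA statistics with Benjamini-Hochberg
#' q-values, the pFDR threshold (largest raw p declared significant at the
#' chosen FDR level), and the per-metabolite calls with direction and log2
#' fold change.
#'
#' @slot comparison Character length-2: group A and group B labels (A minus B
#'   / A over B conventions throughout).
#' @slot variables `data.frame`: `ppm`, `F`, `p`, `q`, `mean_diff_log`,
#'   `sign`, `log2_fc`, `significant`.
#' @slot metabolites `data.frame`: `name`, `hmdb`, `representative_ppm`,
#'   `direction`, `log2_fc`, `p`, `q`, `ambiguous`, `matched_ppms`
#'   (list column).
#' @slot pfdr Largest significant raw p-value (`NA` if none significant).
#' @slot fdrLevel Nominal FDR control level (default 0.1).
#' @exportClass DifferentialResult
setClass("DifferentialResult",
         representation(comparison = "character", variables = "data.frame",
                        metabolites = "data.frame", pfdr = "numeric",
                        fdrLevel = "numeric"))
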