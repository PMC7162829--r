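#' Line positions and weights of a J-coupled multiplet
#'
#' First-order multiplet patterns: singlet/doublet/triplet/quartet with
#' binomial (Pascal) intensity weights and adjacent-line spacing J; `dd` as
#' four equal lines at `+/- J/2 +/- J'/2` with `J' = 0.6 J` by convention;
#' unresolved multiplets (`m`) rendered as a singlet. Offsets are returned in
#' ppm (`Hz / spectrometer frequency in MHz`), symmetric about zero, with
#' weights summing to one.
#'
#' @param multiplicity One of `"s"`, `"d"`, `"t"`, `"q"`, `"dd"`, `"m"`.
#' @param jHz Coupling constant in Hz (ignored for `s`/`m`).
#' @param freqMhz Spectrometer frequency in MHz.
#' @return `data.frame` with columns `offset_ppm`, `weight`.
#' @examples
#' multipletLines("d", 7, 600)   # lines at +/- 3.5 Hz / 600 MHz
#' @export
multipletLines <- function(multiplicity, jHz, freqMhz) {
    stopifnot(jHz >= 0, freqMhz > 0)
    j <- jHz / freqMhz  # ppm
    lines <- switch(multiplicity,
        s = ,
        m = data.frame(offset_ppm = 0, weight = 1),
        d = data.frame(offset_ppm = c(-j / 2, j / 2), weight = c(0.5, 0.5)),
        t = data.frame(offset_ppm = c(-j, 0, j),
                       weight = c(0.25, 0.5, 0.25)),
        q = data.frame(offset_ppm = c(-1.5 * j, -0.5 * j, 0.5 * j, 1.5 * j),
                       weight = c(1, 3, 3, 1) / 8),
        dd = {
            j2 <- 0.6 * j
            data.frame(offset_ppm = c(-(j + j2) / 2, -(j - j2) / 2,
                                      (j - j2) / 2, (j + j2) / 2),
                       weight = rep(0.25, 4))
        },
        stop("unknown multiplicity code: ", multiplicity))
    lines
}

#' Render one clean spectrum from metabolite concentrations
#'
#' Forward model: each library multiplet contributes Lorentzian lines
#' `L(x; gamma) = gamma^2 / (x^2 + gamma^2)` (peaking at 1) centered at
#' `peak ppm + per-metabolite jitter + line offset`, scaled by
#' `concentration * rel_intensity * line weight`. `gamma` is the
#' half-linewidth in ppm, `linewidthHz / (2 * freqMhz)`. The model is linear
#' in each concentration; peaks outside the grid simply contribute truncated
#' tails.
#'
#' @param concentrations Named non-negative concentrations (names must be
#'   library metabolites; missing metabolites default to 0).
#' @param library A [PeakLibrary-class].
#' @param grid Numeric ppm grid (ascending).
#' @param linewidthHz Full linewidth at half maximum, Hz.
#' @param freqMhz Spectrometer frequency, MHz.
#' @param jitter Named per-metabolite chemical-shift offsets in ppm
#'   (default none).
#' @return Numeric intensity vector along `grid`.
#' @export
renderSpectrum <- function(concentrations, library, grid,
                           linewidthHz = 1.5, freqMhz = 600,
                           jitter = NULL) {
    stopifnot(is(library, "PeakLibrary"), all(concentrations >= 0))
    gamma <- linewidthHz / (2 * freqMhz)
    g2 <- gamma^2
    y <- numeric(length(grid))
    pk <- peakTable(library)
    for (nm in names(concentrations)) {
        cm <- concentrations[[nm]]
        if (cm == 0) next
        sub <- pk[pk$name == nm, , drop = FALSE]
        if (nrow(sub) == 0L)
            stop("concentration given for unknown metabolite: ", nm)
        dj <- if (!is.null(jitter) && nm %in% names(jitter)) jitter[[nm]] else 0
        for (i in seq_len(nrow(sub))) {
            lines <- multipletLines(sub$multiplicity[i], sub$j_hz[i], freqMhz)
            for (l in seq_len(nrow(lines))) {
                ctr <- sub$ppm[i] + dj + lines$offset_ppm[l]
                y <- y + cm * sub$rel_intensity[i] * lines$weight[l] *
                    g2 / ((grid - ctr)^2 + g2)
            }
        }
    }
    y
}

#' Construct a simulation design
#'
#' Defaults follow a 600 MHz 1D 1H acquisition of cell extracts: grid
#' 0.8-10.0 ppm at 6000 points, 1.5 Hz Lorentzian linewidth, 0.00025 ppm
#' per-metabolite chemical-shift jitter (0.15 Hz at 600 MHz, the coherent
#' residual drift expected in pH 7.4 phosphate-buffered extracts, and small
#' enough that the recursive aligner can hold every multiplet to within one
#' grid point), log-normal dilution with log-sd 0.1, and additive Gaussian
#' noise with sd equal to 0.5% of the maximum clean signal. These defaults
#' are calibrated so that effect sizes on the scale of the packaged presets
#' are recoverable from five replicates per class.
#'
#' @param library A [PeakLibrary-class] (default: packaged library).
#' @param effects Classes x metabolites numeric matrix of log2 effects; row
#'   names are class (genotype) labels. Columns may be a subset of the
#'   library; missing metabolites get effect 0.
#' @param nPerClass Replicates per class (scalar or per-class vector).
#' @param baselineConc Baseline concentration per metabolite (scalar or named
#'   vector; default 1).
#' @param freqMhz,gridMin,gridMax,nPoints,linewidthHz,jitterSdPpm,dilutionLogSd,noiseSd
#'   Acquisition and noise parameters; see above.
#' @param seed Integer seed used by [simulateDataset()].
#' @return A validated [SimDesign-class].
#' @export
simDesign <- function(effects, nPerClass = 5L, library = defaultPeakLibrary(),
                      baselineConc = 1, freqMhz = 600,
                      gridMin = 0.8, gridMax = 10.0, nPoints = 6000L,
                      linewidthHz = 1.5, jitterSdPpm = 0.00025,
                      dilutionLogSd = 0.1, noiseSd = 0.005, seed = 1L) {
    mets <- metaboliteNames(library)
    effects <- as.matrix(effects)
    if (is.null(rownames(effects)))
        stop("effects needs class labels as row names")
    full <- matrix(0, nrow(effects), length(mets),
                   dimnames = list(rownames(effects), mets))
    if (is.null(colnames(effects))) {
        if (ncol(effects) != length(mets))
            stop("unnamed effects columns must cover every library metabolite")
        colnames(effects) <- mets
    }
    unknown <- setdiff(colnames(effects), mets)
    if (length(unknown))
        stop("effects for metabolites absent from the library: ",
             paste(unknown, collapse = ", "))
    full[, colnames(effects)] <- effects
    if (length(baselineConc) == 1L && is.null(names(baselineConc)))
        baselineConc <- setNames(rep(baselineConc, length(mets)), mets)
    else
        baselineConc <- baselineConc[mets]
    nPerClass <- as.integer(rep(nPerClass, length.out = nrow(full)))
    new("SimDesign", library = library, classLabels = rownames(full),
        effects = full, nPerClass = nPerClass, baselineConc = baselineConc,
        freqMhz = as.numeric(freqMhz), gridMin = as.numeric(gridMin),
        gridMax = as.numeric(gridMax), nPoints = as.integer(nPoints),
        linewidthHz = as.numeric(linewidthHz),
        jitterSdPpm = as.numeric(jitterSdPpm),
        dilutionLogSd = as.numeric(dilutionLogSd),
        noiseSd = as.numeric(noiseSd), seed = as.integer(seed))
}

#' ppm grid of a simulation design
#'
#' @param design A [SimDesign-class].
#' @return Numeric ascending ppm grid.
#' @export
designGrid <- function(design) {
    stopifnot(is(design, "SimDesign"))
    seq(design@gridMin, design@gridMax, length.out = design@nPoints)
}

#' Simulate a dataset of spectra with known ground truth
#'
#' For sample *i* of class *g*: true concentrations
#' `c_im = baseline_m * 2^beta_gm`; per-metabolite shift jitter
#' `~ Normal(0, jitterSdPpm)`; dilution `d_i = exp(Normal(0, dilutionLogSd))`;
#' observed spectrum `d_i * render(c_i) + Normal(0, noiseSd * S)` per point,
#' where `S` is the maximum clean (undiluted, noiseless) intensity over the
#' dataset. Negative noisy values are left as-is. Identical seed gives
#' identical output.
#'
#' @param design A [SimDesign-class].
#' @return List with elements `set` (a [SpectrumSet-class]) and `truth`
#'   (a [GroundTruth-class]).
#' @export
simulateDataset <- function(design) {
    stopifnot(is(design, "SimDesign"))
    validObject(design)
    set.seed(design@seed)
    mets <- metaboliteNames(design@library)
    grid <- designGrid(design)
    labels <- rep(design@classLabels, design@nPerClass)
    reps <- unlist(lapply(design@nPerClass, seq_len))
    ids <- paste0(labels, "_", reps)
    n <- length(ids)
    conc <- matrix(rep(design@baselineConc, each = n), nrow = n,
                   dimnames = list(ids, mets))
    beta <- design@effects[labels, , drop = FALSE]
    conc <- conc * 2^beta
    shifts <- matrix(stats::rnorm(n * length(mets), 0, design@jitterSdPpm),
                     nrow = n, dimnames = list(ids, mets))
    if (design@jitterSdPpm == 0) shifts[] <- 0
    dil <- exp(stats::rnorm(n, 0, design@dilutionLogSd))
    names(dil) <- ids
    clean <- matrix(0, n, length(grid), dimnames = list(ids, NULL))
    for (i in seq_len(n))
        clean[i, ] <- renderSpectrum(conc[i, ], design@library, grid,
                                     design@linewidthHz, design@freqMhz,
                                     jitter = shifts[i, ])
    S <- max(clean)
    intens <- clean * dil
    if (design@noiseSd > 0)
        intens <- intens + matrix(stats::rnorm(length(intens), 0,
                                               design@noiseSd * S),
                                  nrow = n)
    meta <- data.frame(sample_id = ids, genotype = labels,
                       replicate = reps,
                       compartment = "intracellular",
                       stringsAsFactors = FALSE)
    set <- SpectrumSet(ppm = grid, intensities = intens, sampleData = meta)
    truth <- new("GroundTruth", concentrations = conc, dilutionFactors = dil,
                 shiftOffsets = shifts, classLabels = labels,
                 effects = design@effects)
    list(set = set, truth = truth)
}
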