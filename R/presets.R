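# Packaged effect tables for the synthetic presets.
#
# .g13dEffects: signed per-metabolite log2 fold changes for the
# G13D-vs-wild-type comparison (one value per metabolite; where a metabolite
# has several reported multiplet FCs the largest-magnitude one is used).
# .mutantDirections: per-mutant direction (-1/0/+1) of each metabolite
# relative to wild type, for the seven codon 12/13 mutants. Directions are
# combined with the |.g13dEffects| magnitudes (fallback 0.5 for metabolites
# without a reported magnitude) to give every mutant class a distinct effect
# vector of realistic size.

.g13dEffects <- c(
    Leucine = -0.352, Isoleucine = -0.405, Valine = -0.403,
    Glutamate = -0.382, Glutamine = -0.167, Aspartate = -0.412,
    `Creatine phosphate` = -1.060, Phosphocholine = -0.733,
    Glycerophosphocholine = 0.590, Taurine = -0.776,
    `Myo-inositol` = 0.681, AMP = -1.435, Glucose = 0.646,
    `UDP-N-acetylglucosamine` = 0.659, `UDP-N-acetylgalactosamine` = 0.375,
    Uridine = 0.284, Fumarate = -0.281, Tyrosine = -0.163,
    Phenylalanine = -0.177, UMP = -0.483, GTP = -0.238, Inosine = 1.739,
    ATP = -0.363)

.fallbackMagnitude <- 0.5

# Relative baseline concentrations (arbitrary units) of the packaged
# metabolites, on the scale typical of 1H NMR spectra of cell extracts:
# lactate/taurine/glutamate/myo-inositol-class signals dominate, free
# nucleotides and nucleosides sit near the bottom of the dynamic range.
.baselineProfile <- c(
    Isoleucine = 0.5, Leucine = 0.7, Valine = 0.6, Lactate = 3.0,
    Threonine = 0.8, Alanine = 1.2,
    `UDP-N-acetylglucosamine` = 0.5, `UDP-N-acetylgalactosamine` = 0.4,
    Glutamate = 2.5, Glutamine = 1.5, Glutathione = 1.5, Succinate = 0.5,
    Aspartate = 1.0, Creatine = 1.2, `Creatine phosphate` = 0.8,
    Choline = 0.6, Phosphocholine = 0.8, Glycerophosphocholine = 0.6,
    Taurine = 2.5, `Myo-inositol` = 2.0, Inosine = 0.4, Glucose = 0.8,
    Uridine = 0.3, GTP = 0.3, UMP = 0.3, NAD = 0.4, Fumarate = 0.15,
    Tyrosine = 0.3, Phenylalanine = 0.3, AMP = 0.5, ATP = 0.8)

.mutantDirections <- local({
    rows <- list(
        #                        G13D G12S G12A G12C G12D G12V G12R
        Isoleucine            = c(-1,   0,  -1,  -1,  -1,  -1,   0),
        Leucine               = c(-1,   0,  -1,  -1,  -1,  -1,   0),
        Valine                = c(-1,   0,  -1,  -1,  -1,  -1,   0),
        Lactate               = c( 0,   0,   0,   0,  -1,  -1,   0),
        Threonine             = c( 0,   0,  -1,  -1,  -1,   0,   0),
        Alanine               = c( 0,   0,   0,  -1,   0,  -1,   0),
        `UDP-N-acetylglucosamine`   = c(1, -1, -1,  0, -1, -1, -1),
        `UDP-N-acetylgalactosamine` = c(1, -1, -1,  0, -1, -1, -1),
        Glutamate             = c(-1,  -1,   0,  -1,   0,  -1,   0),
        Glutamine             = c( 0,  -1,  -1,  -1,  -1,  -1,  -1),
        Glutathione           = c( 0,   0,   0,  -1,   0,  -1,   0),
        Succinate             = c( 0,   0,   0,  -1,  -1,  -1,   0),
        Aspartate             = c(-1,  -1,  -1,   1,   1,   0,   1),
        Creatine              = c( 0,   0,   0,   0,   0,  -1,   0),
        `Creatine phosphate`  = c(-1,   0,   0,   0,   1,   1,  -1),
        Choline               = c( 0,   0,   0,   1,   0,  -1,   1),
        Phosphocholine        = c(-1,  -1,   0,   0,   0,   0,  -1),
        Glycerophosphocholine = c( 1,   0,   0,  -1,  -1,  -1,  -1),
        Taurine               = c(-1,   0,   0,   0,   1,  -1,   1),
        `Myo-inositol`        = c( 1,  -1,   0,   1,   0,   0,   0),
        Inosine               = c( 1,   0,   1,   1,   1,   1,   1),
        Glucose               = c( 1,   1,   0,   0,   0,   0,   0),
        Uridine               = c( 1,   0,   1,   1,   1,   1,   1),
        GTP                   = c(-1,  -1,   0,  -1,  -1,  -1,  -1),
        UMP                   = c(-1,   0,   0,  -1,  -1,  -1,   0),
        NAD                   = c( 0,   0,   0,   0,  -1,  -1,   0),
        Fumarate              = c(-1,   0,   0,   1,   0,   0,   0),
        Tyrosine              = c(-1,   0,  -1,  -1,  -1,  -1,   0),
        Phenylalanine         = c(-1,   0,  -1,  -1,  -1,  -1,   0),
        AMP                   = c(-1,   0,  -1,  -1,  -1,  -1,  -1),
        ATP                   = c(-1,   0,  -1,  -1,  -1,  -1,   0))
    m <- do.call(rbind, rows)
    colnames(m) <- c("G13D", "G12S", "G12A", "G12C", "G12D", "G12V", "G12R")
    t(m)  # mutants x metabolites
})

#' Packaged simulation presets
#'
#' Two ready-made [SimDesign-class] presets emulating an isogenic colorectal
#' cancer cell-line panel profiled at 600 MHz:
#'
#' * `"g13d_vs_wt"`: two classes (wild type `WT` and `G13D`), five replicates
#'   each; the `G13D` class carries the packaged signed per-metabolite log2
#'   effects (e.g. inosine +1.739, AMP -1.435).
#' * `"codon12_13"`: eight classes (`WT` plus seven codon 12/13 mutants),
#'   five replicates each; each mutant has a distinct effect vector built
#'   from its direction pattern and the packaged effect magnitudes.
#'
#' All other parameters are the [simDesign()] defaults.
#'
#' @param name Preset name, `"codon12_13"` or `"g13d_vs_wt"`.
#' @param seed Integer seed stored in the design.
#' @param ... Overrides passed on to [simDesign()] (e.g. `noiseSd`).
#' @return A [SimDesign-class].
#' @export
presetDesign <- function(name = c("codon12_13", "g13d_vs_wt"), seed = 1L,
                         ...) {
    name <- match.arg(name)
    mets <- colnames(.mutantDirections)
    mag <- setNames(rep(.fallbackMagnitude, length(mets)), mets)
    mag[names(.g13dEffects)] <- abs(.g13dEffects)
    eff <- .mutantDirections * rep(mag, each = nrow(.mutantDirections))
    eff["G13D", names(.g13dEffects)] <- .g13dEffects
    eff <- rbind(WT = 0, eff)
    if (name == "g13d_vs_wt")
        eff <- eff[c("WT", "G13D"), , drop = FALSE]
    args <- list(effects = eff, nPerClass = 5L, seed = seed,
                 baselineConc = defaultBaselineConc())
    extra <- list(...)
    args[names(extra)] <- extra
    do.call(simDesign, args)
}

#' Packaged baseline concentration profile
#'
#' Relative baseline concentrations (arbitrary units) used by the packaged
#' presets, on the scale typical of 1H NMR spectra of cell extracts:
#' abundant lactate, taurine, glutamate and myo-inositol; low-abundance free
#' nucleotides and nucleosides. A realistic dynamic range matters for the
#' probabilistic quotient normalization, whose median quotient is only a
#' faithful dilution estimate when differentially changed signals carry a
#' minority of the total intensity.
#'
#' @return Named numeric vector, one positive value per packaged metabolite.
#' @export
defaultBaselineConc <- function() .baselineProfile

#' Packaged per-metabolite effect anchors
#'
#' The signed log2 fold-change anchors carried by the `G13D` class of the
#' packaged presets. These are injected as simulation ground truth and
#' recovered by the differential analysis in the package's validation suite.
#'
#' @return Named numeric vector of signed log2 effects.
#' @export
presetEffects <- function() .g13dEffects
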