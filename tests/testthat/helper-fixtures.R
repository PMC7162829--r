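# fixtures built in code; no stored binary data

sampleMeta <- function(n, genotype = "WT", prefix = "s",
                       compartment = "intracellular") {
    if (length(genotype) == 1L) genotype <- rep(genotype, n)
    data.frame(sample_id = paste0(prefix, seq_len(n)),
               genotype = genotype,
               replicate = as.integer(ave(seq_len(n), genotype,
                                          FUN = seq_along)),
               compartment = compartment,
               stringsAsFactors = FALSE)
}

toySet <- function(intensities, ppmAxis = NULL, genotype = "WT") {
    intensities <- as.matrix(intensities)
    if (is.null(ppmAxis))
        ppmAxis <- seq(1, 9, length.out = ncol(intensities))
    SpectrumSet(ppmAxis, intensities,
                sampleMeta(nrow(intensities), genotype))
}

# discrete Lorentzian profile by grid index
lorentzRow <- function(n, centerIdx, gammaPts = 2, height = 1) {
    height / (1 + ((seq_len(n) - centerIdx) / gammaPts)^2)
}

tinyLibrary <- function() {
    PeakLibrary(data.frame(
        name = c("MetA", "MetA", "MetB"),
        hmdb = c("HMDB0000001", "HMDB0000001", "HMDB0000002"),
        ppm = c(1.5, 3.0, 7.2),
        multiplicity = c("d", "s", "t"),
        j_hz = c(7, 0, 7),
        rel_intensity = c(1, 2, 1)))
}

# two-class design on a reduced grid for fast end-to-end tests
smallDesign <- function(seed = 1L, nPoints = 1200L, ...) {
    eff <- rbind(WT = 0, MUT = presetEffects()[
        c("Inosine", "AMP", "Taurine", "Glucose")])
    colnames(eff) <- c("Inosine", "AMP", "Taurine", "Glucose")
    simDesign(effects = eff, nPerClass = 5L, nPoints = nPoints,
              seed = seed, ...)
}
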