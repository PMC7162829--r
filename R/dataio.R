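#' Read a SpectrumSet from delimited text
#'
#' The spectrum file is a delimited table whose first column is `sample_id`
#' and whose remaining column headers are ppm values (any strict monotone
#' order; commonly descending, the NMR display convention). The metadata file
#' has columns `sample_id`, `genotype`, `replicate`, `compartment`. The axis
#' is stored ascending in memory regardless of file order.
#'
#' @param spectraPath Path to the spectrum matrix (CSV, or TSV for
#'   `.tsv`/`.txt` extensions).
#' @param metadataPath Path to the sample metadata table.
#' @return A [SpectrumSet-class].
#' @export
readSpectrumSet <- function(spectraPath, metadataPath) {
    sep <- sepForPath(spectraPath)
    tab <- utils::read.table(spectraPath, header = TRUE, sep = sep,
                             check.names = FALSE, stringsAsFactors = FALSE,
                             colClasses = "character")
    if (ncol(tab) < 2L || names(tab)[1] != "sample_id")
        stop("spectrum file must start with a 'sample_id' column: ",
             spectraPath)
    hdr <- names(tab)[-1]
    axis <- suppressWarnings(as.numeric(hdr))
    if (anyNA(axis))
        stop("non-numeric ppm header(s): ",
             paste(hdr[is.na(axis)], collapse = ", "))
    if (anyDuplicated(axis))
        stop("duplicate ppm header: ",
             paste(unique(hdr[duplicated(axis)]), collapse = ", "))
    ids <- tab[[1]]
    vals <- as.matrix(tab[, -1, drop = FALSE])
    num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
    if (anyNA(num)) {
        bad <- which(is.na(num), arr.ind = TRUE)[1, ]
        stop(sprintf("non-numeric intensity at row %d (sample '%s'), column '%s'",
                     bad[1], ids[bad[1]], hdr[bad[2]]))
    }
    msep <- sepForPath(metadataPath)
    meta <- utils::read.table(metadataPath, header = TRUE, sep = msep,
                              check.names = FALSE, stringsAsFactors = FALSE)
    need <- c("sample_id", "genotype", "replicate", "compartment")
    miss <- setdiff(need, names(meta))
    if (length(miss))
        stop("metadata missing column(s): ", paste(miss, collapse = ", "))
    meta$sample_id <- as.character(meta$sample_id)
    unmatched <- setdiff(ids, meta$sample_id)
    if (length(unmatched))
        stop("no metadata row for sample(s): ",
             paste(unmatched, collapse = ", "))
    meta <- meta[match(ids, meta$sample_id), , drop = FALSE]
    SpectrumSet(ppm = axis, intensities = num, sampleData = meta)
}

#' Write a SpectrumSet to delimited text
#'
#' The ppm columns are written in descending order (NMR display convention);
#' [readSpectrumSet()] restores the ascending in-memory order. Values are
#' written with 12 significant digits so a write/read round trip reproduces
#' them to printing precision.
#'
#' @param set A [SpectrumSet-class].
#' @param spectraPath,metadataPath Output paths (CSV; `.tsv`/`.txt` write
#'   tab-separated).
#' @return Invisibly, the two paths.
#' @export
writeSpectrumSet <- function(set, spectraPath, metadataPath) {
    stopifnot(is(set, "SpectrumSet"))
    if (ncol(set) == 0L)
        stop("refusing to write a SpectrumSet with no samples")
    m <- intensityMatrix(set)
    ord <- order(ppm(set), decreasing = TRUE)
    m <- m[, ord, drop = FALSE]
    sep <- sepForPath(spectraPath)
    hdr <- paste(c("sample_id", fmtNum(ppm(set)[ord])), collapse = sep)
    rows <- vapply(seq_len(nrow(m)), function(i)
        paste(c(rownames(m)[i], fmtNum(m[i, ])), collapse = sep),
        character(1))
    writeLines(c(hdr, rows), spectraPath)
    utils::write.table(sampleInfo(set), metadataPath,
                       sep = sepForPath(metadataPath),
                       row.names = FALSE, quote = FALSE)
    invisible(c(spectraPath, metadataPath))
}

#' Read a metabolite peak library from JSON
#'
#' Expected layout: a top-level `metabolites` array of objects with fields
#' `name`, `hmdb` and a `peaks` array of `{ppm, multiplicity, j_hz,
#' rel_intensity}` records. HMDB accessions are normalized to the
#' zero-padded 11-character form on read.
#'
#' @param path Path to the JSON file.
#' @return A validated [PeakLibrary-class].
#' @export
readPeakLibrary <- function(path) {
    doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (is.null(doc$metabolites))
        stop("peak library JSON must contain a 'metabolites' array: ", path)
    rows <- lapply(doc$metabolites, function(m) {
        if (is.null(m$name) || is.null(m$hmdb))
            stop("metabolite entry missing 'name' or 'hmdb'")
        if (length(m$peaks) == 0L)
            stop("metabolite '", m$name, "' has no peaks")
        do.call(rbind, lapply(m$peaks, function(p)
            data.frame(name = m$name, hmdb = m$hmdb,
                       ppm = as.numeric(p$ppm),
                       multiplicity = as.character(p$multiplicity),
                       j_hz = if (is.null(p$j_hz)) 7 else as.numeric(p$j_hz),
                       rel_intensity = if (is.null(p$rel_intensity)) 1
                                       else as.numeric(p$rel_intensity),
                       stringsAsFactors = FALSE)))
    })
    PeakLibrary(do.call(rbind, rows))
}

#' Write a peak library to JSON
#'
#' @param library A [PeakLibrary-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writePeakLibrary <- function(library, path) {
    stopifnot(is(library, "PeakLibrary"))
    pk <- peakTable(library)
    mets <- lapply(metaboliteNames(library), function(nm) {
        sub <- pk[pk$name == nm, , drop = FALSE]
        list(name = nm, hmdb = sub$hmdb[1],
             peaks = lapply(seq_len(nrow(sub)), function(i)
                 list(ppm = sub$ppm[i], multiplicity = sub$multiplicity[i],
                      j_hz = sub$j_hz[i],
                      rel_intensity = sub$rel_intensity[i])))
    })
    jsonlite::write_json(list(metabolites = mets), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(path)
}

#' Read a pathway library from a GMT file
#'
#' One pathway per line, tab-separated: name, description, then member HMDB
#' accessions. Member ids are whitespace-trimmed and normalized to the
#' 11-character HMDB form.
#'
#' @param path Path to the GMT file.
#' @return A [PathwayLibrary-class].
#' @export
readPathwayLibrary <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(lengths(parts) < 3L)
    if (length(short))
        stop("GMT line ", short[1], " has fewer than 3 tab-separated fields")
    nm <- vapply(parts, function(p) trimws(p[1]), character(1))
    if (anyDuplicated(nm))
        stop("duplicate pathway name: ",
             paste(unique(nm[duplicated(nm)]), collapse = ", "))
    desc <- vapply(parts, function(p) trimws(p[2]), character(1))
    sets <- lapply(parts, function(p) trimws(p[-(1:2)]))
    names(sets) <- nm
    PathwayLibrary(sets, setNames(desc, nm))
}

#' Write a pathway library to a GMT file
#'
#' @param library A [PathwayLibrary-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writePathwayLibrary <- function(library, path) {
    stopifnot(is(library, "PathwayLibrary"))
    lines <- vapply(pathwayNames(library), function(nm)
        paste(c(nm, library@descriptions[[nm]], library@sets[[nm]]),
              collapse = "\t"), character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Packaged metabolite peak library
#'
#' The default library of 31 metabolites observed in 1H NMR spectra of
#' colorectal cancer cell extracts, with multiplet positions at their
#' literature chemical shifts and HMDB accessions.
#'
#' @return A [PeakLibrary-class].
#' @export
defaultPeakLibrary <- function() {
    readPeakLibrary(system.file("extdata", "peak_library.json",
                                package = "nmrmetab", mustWork = TRUE))
}

#' Packaged demonstration pathway library
#'
#' A small synthetic metabolite-set file whose memberships are drawn from the
#' packaged peak library (protein biosynthesis, urea cycle, RNA transcription,
#' ammonia recycling and related sets). It is a demonstration fixture for the
#' over-representation analysis, not a curated pathway database.
#'
#' @return A [PathwayLibrary-class].
#' @export
defaultPathwayLibrary <- function() {
    readPathwayLibrary(system.file("extdata", "pathways_synthetic.gmt",
                                   package = "nmrmetab", mustWork = TRUE))
}
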