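# internal helpers

#' Normalize HMDB accessions
#'
#' Pads the numeric part to seven digits so that mixed five- and seven-digit
#' forms (e.g. `HMDB00190`, `HMDB0000190`) compare equal.
#'
#' @param ids Character vector of HMDB accessions.
#' @return Character vector in the canonical 11-character form.
#' @export
normalizeHmdb <- function(ids) {
    ids <- trimws(as.character(ids))
    num <- sub("^HMDB0*", "", ids, ignore.case = TRUE)
    ok <- grepl("^[0-9]+$", num)
    out <- ids
    out[ok] <- sprintf("HMDB%07d", as.integer(num[ok]))
    out
}

# stable per-stage seed derived from a global seed (kept below 2^31)
stageSeed <- function(seed, stage) {
    v <- utf8ToInt(stage)
    h <- sum(v * seq_along(v)) %% 100000L
    as.integer((as.numeric(seed) %% 20000L) * 100000L + h)
}

# Pearson correlation that treats zero-variance input as uncorrelated
corSafe <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
    stats::cor(a, b)
}

# delimiter from file extension (.tsv/.txt -> tab, otherwise comma)
sepForPath <- function(path) {
    if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

fmtNum <- function(x) formatC(x, format = "g", digits = 12)
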