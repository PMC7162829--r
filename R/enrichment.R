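#' Over-representation analysis of metabolite sets
#'
#' One-sided hypergeometric test per pathway: with background size `N`,
#' pathway size `K` (after intersection with the background), significant-set
#' size `n` and overlap `k`, the p-value is `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`, exactly evaluated. Pathways with empty
#' background intersection are skipped. q-values are BH across the tested
#' pathways; results are sorted by p ascending, ties by name. Fold
#' enrichment is `(k/n) / (K/N)` (0 when the significant set is empty).
#'
#' @param significantIds Character vector of significant metabolite HMDB
#'   accessions (must be a subset of the background).
#' @param backgroundIds Character vector, the detectable metabolite universe
#'   (typically the peak library's accessions).
#' @param pathways A [PathwayLibrary-class].
#' @return `data.frame` with columns `pathway`, `description`, `K`, `k`,
#'   `n`, `N`, `p`, `q`, `fold_enrichment`.
#' @export
ora <- function(significantIds, backgroundIds, pathways) {
    stopifnot(is(pathways, "PathwayLibrary"))
    sig <- unique(normalizeHmdb(significantIds))
    bg <- unique(normalizeHmdb(backgroundIds))
    extra <- setdiff(sig, bg)
    if (length(extra))
        stop("significant id(s) not in background: ",
             paste(extra, collapse = ", "))
    N <- length(bg)
    n <- length(sig)
    rows <- lapply(pathwayNames(pathways), function(nm) {
        mem <- intersect(pathways@sets[[nm]], bg)
        K <- length(mem)
        if (K == 0L) return(NULL)
        k <- length(intersect(mem, sig))
        p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
        fe <- if (n > 0L) (k / n) / (K / N) else 0
        data.frame(pathway = nm, description = pathways@descriptions[[nm]],
                   K = K, k = k, n = n, N = N, p = p,
                   fold_enrichment = fe, stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows))
        return(data.frame(pathway = character(0), description = character(0),
                          K = integer(0), k = integer(0), n = integer(0),
                          N = integer(0), p = numeric(0), q = numeric(0),
                          fold_enrichment = numeric(0)))
    out <- do.call(rbind, rows)
    out$q <- bhAdjust(out$p)
    out <- out[order(out$p, out$pathway),
               c("pathway", "description", "K", "k", "n", "N", "p", "q",
                 "fold_enrichment")]
    rownames(out) <- NULL
    out
}
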