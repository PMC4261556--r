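#' Filter probes by spot quality flags
#'
#' Retains exactly the probes whose flag count is at most
#' \code{maxFlags} in every sample ("none or only one flag" under the
#' default), so every retained gene has a complete, trusted expression
#' vector across arrays. Probe order is preserved and the input is not
#' modified.
#'
#' @param study an \linkS4class{ExpressionStudy}.
#' @param maxFlags maximum tolerated flag count per spot (default 1).
#' @return A new \linkS4class{ExpressionStudy} with the retained probes.
#' @export
filterFlags <- function(study, maxFlags = 1L) {
    keep <- apply(flagCounts(study) <= maxFlags, 1, all)
    if (sum(keep) < 2)
        .stopf(paste0("flag filtering at maxFlags=%d retains %d probe(s); ",
                      "at least 2 are required downstream"),
               maxFlags, sum(keep))
    study[keep, ]
}

#' Lowess normalization against a virtual reference array
#'
#' One-color intensity-dependent normalization. The virtual reference is
#' the per-probe mean log2 intensity across all arrays (A); for each
#' array the deviation from the reference (M = sample - A) is regressed
#' on A with lowess, and the fitted trend is subtracted from that
#' array. A trend-free array is left (nearly) unchanged, and a
#' single-sample study is returned exactly unchanged because the array
#' is its own reference.
#'
#' @param study an \linkS4class{ExpressionStudy} with log2 intensities.
#' @param span lowess smoother span (fraction of probes in each local
#'   fit, default 0.3).
#' @return A new \linkS4class{ExpressionStudy} with normalized
#'   intensities; shape, probe and sample identity are unchanged.
#' @export
lowessNormalize <- function(study, span = 0.3) {
    x <- intensities(study)
    if (nrow(x) < 10)
        .stopf("lowess normalization needs >= 10 probes (got %d); %s",
               nrow(x), "increase the probe set or the span")
    ref <- rowMeans(x)
    out <- x
    for (j in seq_len(ncol(x))) {
        m <- x[, j] - ref
        fit <- stats::lowess(ref, m, f = span)
        trend <- stats::approx(fit$x, fit$y, xout = ref, rule = 2,
                               ties = mean)$y
        out[, j] <- x[, j] - trend
    }
    replaceIntensities(study, out)
}

# swap the intensity assay, keeping everything else
replaceIntensities <- function(study, x) {
    SummarizedExperiment::assay(study, "intensities") <- x
    study
}

#' Collapse probes to unique gene symbols
#'
#' When several retained probes map to the same gene symbol, keeps the
#' probe with the highest mean intensity (the conventional choice for
#' one-color arrays). Applied after normalization and before
#' differential expression; the result is indexed by gene symbol.
#'
#' @param study an \linkS4class{ExpressionStudy}.
#' @return An \linkS4class{ExpressionStudy} with one row per gene
#'   symbol, rownames set to the symbols.
#' @export
collapseProbes <- function(study) {
    sym <- geneSymbols(study)
    mean_int <- rowMeans(intensities(study))
    ord <- order(-mean_int)
    keep <- ord[!duplicated(sym[ord])]
    keep <- sort(keep)  # preserve original probe order
    out <- study[keep, ]
    rownames(out) <- unname(sym[keep])
    out
}
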