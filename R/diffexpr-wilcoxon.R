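#' Exact Wilcoxon-Mann-Whitney differential expression
#'
#' Two-sided exact rank-sum test per gene, computed by full enumeration
#' of the null distribution: every assignment of the observed values to
#' the two groups (all \eqn{\binom{n_1+n_2}{n_1}} subsets) is evaluated
#' on the gene's mid-ranks, and the p-value is the null probability of a
#' rank sum at least as far from its expectation
#' \eqn{E[W] = n_1(N+1)/2} as the observed one. With small group sizes
#' (5-8 per group, the regime of postmortem microarray studies) the
#' exact enumeration is both feasible and necessary: the normal
#' approximation is unreliable and the achievable significance levels
#' are discrete. Ties are handled by mid-ranks; because enumeration
#' permutes the observed values themselves, the tied null is exact. A
#' zero-variance gene has p = 1 and is never significant.
#'
#' @param study an \linkS4class{ExpressionStudy} (typically flag-filtered,
#'   normalized and probe-collapsed) containing both groups.
#' @param alpha raw significance cutoff; a gene is significant iff
#'   p < alpha (the convention of reporting uncorrected P at a strict
#'   cutoff such as 0.005 or 0.01).
#' @return A \linkS4class{DEResult} with method \code{"wilcoxon"}. The
#'   statistic column is the Mann-Whitney U of the case (PD) group;
#'   direction is the sign of the case-minus-control median difference.
#' @examples
#' m <- rbind(g1 = c(1, 2, 3, 4, 5, 6))
#' colnames(m) <- c("c1", "c2", "c3", "p1", "p2", "p3")
#' es <- ExpressionStudy(m, groups = c(c1 = "CT", c2 = "CT", c3 = "CT",
#'                                     p1 = "PD", p2 = "PD", p3 = "PD"))
#' deTable(wilcoxonDE(es, alpha = 0.2))  # exact p = 2/20 = 0.1
#' @export
wilcoxonDE <- function(study, alpha = 0.005) {
    g <- sampleGroups(study)
    ct <- which(g == "CT"); pd <- which(g == "PD")
    if (length(ct) < 2 || length(pd) < 2)
        .stopf("wilcoxonDE needs >= 2 samples per group (CT=%d, PD=%d)",
               length(ct), length(pd))
    x <- intensities(study)
    n <- ncol(x); n1 <- length(ct)

    # all size-n1 subsets as a 0/1 indicator matrix (columns = subsets)
    comb <- utils::combn(n, n1)
    ind <- matrix(0, n, ncol(comb))
    ind[cbind(as.vector(comb), rep(seq_len(ncol(comb)), each = n1))] <- 1

    ranks <- t(apply(x, 1, rank))          # mid-ranks per gene
    if (nrow(x) == 1) ranks <- matrix(rank(x[1, ]), 1, n)
    W <- ranks %*% ind                      # null rank sums, gene x subset
    EW <- n1 * (n + 1) / 2
    wobs <- rowSums(ranks[, ct, drop = FALSE])
    p <- rowMeans(abs(W - EW) >= abs(wobs - EW))

    med_diff <- apply(x[, pd, drop = FALSE], 1, stats::median) -
        apply(x[, ct, drop = FALSE], 1, stats::median)
    # Mann-Whitney U of the PD group from the CT rank sum
    u_pd <- n1 * length(pd) - (wobs - n1 * (n1 + 1) / 2)

    tab <- data.frame(
        gene = rownames(x),
        statistic = unname(u_pd),
        p_value = unname(p),
        q_or_fdr = NA_real_,
        direction = ifelse(med_diff > 0, "up_in_case",
                    ifelse(med_diff < 0, "down_in_case", NA_character_)),
        significant = unname(p < alpha),
        stringsAsFactors = FALSE)
    methods::new("DEResult", table = tab, method = "wilcoxon",
                 params = list(alpha = alpha, n_ct = n1, n_pd = length(pd)))
}

#' Accessors for DEResult
#'
#' \code{deTable} returns the per-gene result table;
#' \code{significantGenes} the sorted significant gene names.
#'
#' @param x a \linkS4class{DEResult}.
#' @name DEResult-accessors
NULL

#' @rdname DEResult-accessors
#' @export
setMethod("deTable", "DEResult", function(x) x@table)

#' @rdname DEResult-accessors
#' @export
setMethod("significantGenes", "DEResult", function(x)
    sort(x@table$gene[x@table$significant]))

setMethod("show", "DEResult", function(object) {
    cat(sprintf("DEResult (%s): %d genes tested, %d significant\n",
                object@method, nrow(object@table),
                sum(object@table$significant)))
    if (object@method == "sam")
        cat(sprintf("  s0 = %.4g, delta = %.4g, est. FDR = %.3g\n",
                    object@params$s0, object@params$delta,
                    object@params$fdr))
    invisible(NULL)
})

#' Restrict significant genes to the GO-annotated set
#'
#' Returns the deduplicated, sorted list of significant genes that are
#' GO-annotated -- the node candidate set for network construction.
#'
#' @param result a \linkS4class{DEResult}.
#' @param study the \linkS4class{ExpressionStudy} the result was computed
#'   from (source of the GO annotation).
#' @return Character vector of gene symbols.
#' @export
selectDEGenes <- function(result, study) {
    sig <- significantGenes(result)
    go <- tapply(goAnnotated(study), geneSymbols(study), any)
    keep <- sig[sig %in% names(go)[go]]
    keep <- sort(unique(keep))
    if (length(keep) == 0)
        .stopf("no significant GO-annotated genes; %s",
               "network construction needs at least 2")
    keep
}
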