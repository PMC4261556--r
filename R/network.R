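#' Build a hard-threshold Pearson coexpression network
#'
#' Computes the Pearson correlation of every gene pair across all
#' samples of \code{study} (pass a single-condition study to obtain that
#' condition's network) and keeps an edge when the correlation meets the
#' hard threshold: \code{|r| >= threshold} under \code{mode="absolute"}
#' (the default) or \code{r >= threshold} under \code{mode="positive"}.
#' All requested genes are retained as nodes, so N equals the selected
#' gene count regardless of isolates; use \code{dropIsolates=TRUE} to
#' keep only connected genes. Genes with zero variance cannot be
#' correlated and are excluded with a warning.
#'
#' @param study an \linkS4class{ExpressionStudy} whose rownames contain
#'   \code{geneList} (typically probe-collapsed, one condition).
#' @param geneList genes to use as nodes (>= 2); input order is
#'   irrelevant, nodes are stored in canonical sorted order.
#' @param threshold correlation cutoff in (0, 1].
#' @param mode "absolute" or "positive".
#' @param label free-text condition label stored with the network.
#' @param dropIsolates drop zero-degree nodes from the node list.
#' @return A \linkS4class{CoexpressionNetwork}.
#' @export
buildNetwork <- function(study, geneList, threshold, mode = "absolute",
                         label = "", dropIsolates = FALSE) {
    mode <- match.arg(mode, c("absolute", "positive"))
    if (length(threshold) != 1 || threshold <= 0 || threshold > 1)
        .stopf("threshold must be a single value in (0, 1], got %s",
               paste(threshold, collapse = ","))
    geneList <- sort(unique(as.character(geneList)))
    if (length(geneList) < 2)
        .stopf("need at least 2 genes, got %d", length(geneList))
    missing <- setdiff(geneList, rownames(study))
    if (length(missing))
        .stopf("gene(s) not in study: %s",
               paste(utils::head(missing, 5), collapse = ", "))

    x <- intensities(study)[geneList, , drop = FALSE]
    v <- apply(x, 1, stats::var)
    if (any(v == 0)) {
        warning(sprintf("excluding %d zero-variance gene(s): %s",
                        sum(v == 0),
                        paste(utils::head(geneList[v == 0], 5),
                              collapse = ", ")))
        x <- x[v > 0, , drop = FALSE]
    }
    edges <- data.frame(gene_a = character(0), gene_b = character(0),
                        r = numeric(0), stringsAsFactors = FALSE)
    if (nrow(x) >= 2) {
        cm <- stats::cor(t(x))
        idx <- which(upper.tri(cm), arr.ind = TRUE)
        r <- cm[idx]
        keep <- if (mode == "absolute") abs(r) >= threshold else r >= threshold
        idx <- idx[keep, , drop = FALSE]
        if (nrow(idx)) {
            edges <- data.frame(gene_a = rownames(cm)[idx[, 1]],
                                gene_b = rownames(cm)[idx[, 2]],
                                r = r[keep], stringsAsFactors = FALSE)
            swap <- edges$gene_a > edges$gene_b
            tmp <- edges$gene_a[swap]
            edges$gene_a[swap] <- edges$gene_b[swap]
            edges$gene_b[swap] <- tmp
            edges <- edges[order(edges$gene_a, edges$gene_b), ]
            rownames(edges) <- NULL
        }
    }
    genes <- geneList
    if (dropIsolates)
        genes <- sort(intersect(genes, c(edges$gene_a, edges$gene_b)))
    methods::new("CoexpressionNetwork", genes = genes, edges = edges,
                 threshold = threshold, mode = mode, label = label)
}

#' Mean connectivity k = 2L/N
#'
#' The average degree of an undirected network with L edges and N
#' nodes. \code{meanConnectivity} returns full precision; published
#' network tables conventionally display it truncated (not rounded) to
#' two decimals, which \code{formatConnectivity} reproduces.
#'
#' @param network a \linkS4class{CoexpressionNetwork}, or a node count N
#'   when \code{L} is given.
#' @param L edge count, when \code{network} is a node count.
#' @return Mean connectivity (numeric); \code{formatConnectivity}
#'   returns a string with exactly two decimals.
#' @examples
#' meanConnectivity(206, L = 670)           # 6.504854
#' formatConnectivity(meanConnectivity(209, L = 586))  # "5.60", truncated
#' @export
meanConnectivity <- function(network, L = NULL) {
    if (is(network, "CoexpressionNetwork")) {
        N <- length(network@genes)
        L <- nrow(network@edges)
    } else {
        N <- network
        if (is.null(L)) .stopf("L is required when network is a node count")
    }
    if (N < 1) .stopf("mean connectivity needs N >= 1")
    2 * L / N
}

#' @rdname meanConnectivity
#' @param k a mean-connectivity value.
#' @export
formatConnectivity <- function(k) {
    sprintf("%.2f", truncateDecimals(k, 2))
}

#' Choose the hard threshold reaching a target edge count
#'
#' Returns the largest threshold drawn from the observed pairwise
#' correlations such that the resulting network has at least
#' \code{targetEdges} edges -- i.e. the minimal network reaching the
#' target (ties at the cut value may push the edge count above it).
#' Deterministic given the data.
#'
#' @inheritParams buildNetwork
#' @param targetEdges desired minimum number of edges (>= 1).
#' @return The chosen threshold (numeric scalar).
#' @export
chooseThreshold <- function(study, geneList, targetEdges, mode = "absolute") {
    mode <- match.arg(mode, c("absolute", "positive"))
    geneList <- sort(unique(as.character(geneList)))
    if (targetEdges < 1) .stopf("targetEdges must be >= 1")
    x <- intensities(study)[geneList, , drop = FALSE]
    v <- apply(x, 1, stats::var)
    x <- x[v > 0, , drop = FALSE]
    cm <- stats::cor(t(x))
    r <- cm[upper.tri(cm)]
    vals <- if (mode == "absolute") abs(r) else r
    if (targetEdges > length(vals))
        .stopf("targetEdges (%d) exceeds the %d available gene pairs",
               targetEdges, length(vals))
    sort(vals, decreasing = TRUE)[targetEdges]
}

#' Degree table and hub calls for one network
#'
#' Computes per-gene degree (number of gene-gene links) and flags the
#' most connected genes as hubs, the operational definition of a hub in
#' coexpression network studies. Two rules are supported:
#' \code{top_n} (default, n = 10) flags the genes with the n highest
#' degrees, including all genes tied with the boundary degree;
#' \code{quantile} flags genes with degree at or above the given degree
#' quantile. Zero-degree genes are never hubs.
#'
#' @param network a \linkS4class{CoexpressionNetwork}.
#' @param rule "top_n" or "quantile".
#' @param n number of hubs under "top_n".
#' @param q degree quantile (in [0,1]) under "quantile".
#' @return A \linkS4class{HubTable}, sorted by decreasing degree with
#'   alphabetical tie-break.
#' @export
degreeTable <- function(network, rule = c("top_n", "quantile"), n = 10L,
                        q = 0.95) {
    rule <- match.arg(rule)
    deg <- nodeDegrees(network)
    ord <- order(-deg, names(deg))
    deg <- deg[ord]
    if (rule == "top_n") {
        boundary <- if (length(deg) >= n) deg[n] else 0
        is_hub <- deg >= max(boundary, 1L)
    } else {
        cutoff <- stats::quantile(deg, q, names = FALSE)
        is_hub <- deg >= cutoff & deg >= 1L
    }
    tab <- data.frame(gene = names(deg), degree = unname(deg),
                      is_hub = unname(is_hub), stringsAsFactors = FALSE)
    methods::new("HubTable", table = tab, label = network@label,
                 rule = if (rule == "top_n") list(rule = rule, n = n)
                        else list(rule = rule, q = q))
}

#' Accessors for CoexpressionNetwork
#'
#' \code{networkGenes}, \code{networkEdges}, \code{networkThreshold} and
#' \code{conditionLabel} return the corresponding slots;
#' \code{nodeDegrees} the named per-gene degree vector; \code{asIgraph}
#' converts to an \pkg{igraph} graph (edge attribute \code{weight} = r).
#'
#' @param x a \linkS4class{CoexpressionNetwork}.
#' @param ... unused.
#' @name CoexpressionNetwork-accessors
NULL

#' @rdname CoexpressionNetwork-accessors
#' @export
setMethod("networkGenes", "CoexpressionNetwork", function(x) x@genes)

#' @rdname CoexpressionNetwork-accessors
#' @export
setMethod("networkEdges", "CoexpressionNetwork", function(x) x@edges)

#' @rdname CoexpressionNetwork-accessors
#' @export
setMethod("networkThreshold", "CoexpressionNetwork", function(x) x@threshold)

#' @rdname CoexpressionNetwork-accessors
#' @export
setMethod("conditionLabel", "CoexpressionNetwork", function(x) x@label)

#' @rdname CoexpressionNetwork-accessors
#' @export
setMethod("nodeDegrees", "CoexpressionNetwork", function(x) {
    deg <- stats::setNames(integer(length(x@genes)), x@genes)
    if (nrow(x@edges)) {
        t1 <- table(factor(x@edges$gene_a, levels = x@genes))
        t2 <- table(factor(x@edges$gene_b, levels = x@genes))
        deg <- stats::setNames(as.integer(t1 + t2), x@genes)
    }
    deg
})

#' @rdname CoexpressionNetwork-accessors
#' @export
setMethod("asIgraph", "CoexpressionNetwork", function(x, ...) {
    g <- igraph::graph_from_data_frame(
        x@edges[, c("gene_a", "gene_b"), drop = FALSE],
        directed = FALSE,
        vertices = data.frame(name = x@genes, stringsAsFactors = FALSE))
    if (nrow(x@edges)) igraph::E(g)$weight <- x@edges$r
    g
})

setMethod("show", "CoexpressionNetwork", function(object) {
    N <- length(object@genes); L <- nrow(object@edges)
    cat(sprintf(
        "CoexpressionNetwork%s: N = %d genes, L = %d links (threshold %.3g, %s), k = %s\n",
        if (nzchar(object@label)) paste0(" [", object@label, "]") else "",
        N, L, object@threshold, object@mode,
        formatConnectivity(meanConnectivity(object))))
    invisible(NULL)
})

#' Accessors for HubTable
#'
#' \code{hubTable} returns the degree-sorted table; \code{hubGenes} the
#' hub-flagged gene names.
#'
#' @param x a \linkS4class{HubTable}.
#' @name HubTable-accessors
NULL

#' @rdname HubTable-accessors
#' @export
setMethod("hubTable", "HubTable", function(x) x@table)

#' @rdname HubTable-accessors
#' @export
setMethod("hubGenes", "HubTable", function(x)
    x@table$gene[x@table$is_hub])

setMethod("show", "HubTable", function(object) {
    cat(sprintf("HubTable%s: %d genes, %d hubs (%s)\n",
                if (nzchar(object@label)) paste0(" [", object@label, "]")
                else "",
                nrow(object@table), sum(object@table$is_hub),
                paste(names(object@rule), unlist(object@rule),
                      sep = "=", collapse = ", ")))
    print(utils::head(object@table, 10), row.names = FALSE)
    invisible(NULL)
})
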