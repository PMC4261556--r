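# Small studies built in code for the unit tests.

# Study from an explicit matrix with nCT/nPD samples.
matrixStudy <- function(m, nCT, nPD, flags = NULL, annotation = NULL) {
    colnames(m) <- c(paste0("c", seq_len(nCT)), paste0("p", seq_len(nPD)))
    if (is.null(rownames(m))) rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
    if (!is.null(flags)) dimnames(flags) <- dimnames(m)
    groups <- stats::setNames(rep(c("CT", "PD"), c(nCT, nPD)), colnames(m))
    ExpressionStudy(m, flags, groups, annotation)
}

# Random null study (no structure), fixed seed.
nullStudy <- function(nGenes, nCT, nPD, seed = 1, sd = 1) {
    set.seed(seed)
    m <- matrix(rnorm(nGenes * (nCT + nPD), mean = 8, sd = sd),
                nGenes, nCT + nPD)
    matrixStudy(m, nCT, nPD)
}

# Independent brute-force enumeration oracle for the exact two-sided
# Mann-Whitney p-value: per-gene loop over all CT subsets of the
# observed values, two-sided by distance of the rank sum from its mean.
bruteWilcoxonP <- function(values, nCT) {
    n <- length(values)
    r <- rank(values)
    ew <- nCT * (n + 1) / 2
    wobs <- sum(r[seq_len(nCT)])
    subsets <- utils::combn(n, nCT)
    wall <- apply(subsets, 2, function(ix) sum(r[ix]))
    mean(abs(wall - ew) >= abs(wobs - ew))
}

# Hand-rolled Newman-Girvan modularity as an oracle.
modularityOracle <- function(edges, assignment) {
    L <- nrow(edges)
    deg <- table(c(edges$gene_a, edges$gene_b))
    q <- 0
    for (m in unique(assignment)) {
        genes <- names(assignment)[assignment == m]
        lm <- sum(edges$gene_a %in% genes & edges$gene_b %in% genes)
        dm <- sum(deg[names(deg) %in% genes])
        q <- q + lm / L - (dm / (2 * L))^2
    }
    q
}

# Directly assemble a CoexpressionNetwork from an edge list.
toyNetwork <- function(edges, genes = NULL, threshold = 0.9,
                       mode = "absolute", label = "") {
    if (is.null(genes)) genes <- sort(unique(c(edges$gene_a, edges$gene_b)))
    swap <- edges$gene_a > edges$gene_b
    tmp <- edges$gene_a[swap]
    edges$gene_a[swap] <- edges$gene_b[swap]
    edges$gene_b[swap] <- tmp
    edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
    rownames(edges) <- NULL
    methods::new("CoexpressionNetwork", genes = sort(genes), edges = edges,
                 threshold = threshold, mode = mode, label = label)
}

starEdges <- function(center, nLeaves, r = 0.95, prefix = "L") {
    data.frame(gene_a = center,
               gene_b = sprintf("%s%02d", prefix, seq_len(nLeaves)),
               r = r, stringsAsFactors = FALSE)
}
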