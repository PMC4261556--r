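#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' ExpressionStudy: probe-by-sample microarray intensities with QC flags
#'
#' The container for a one-color microarray case-control study. It extends
#' \linkS4class{SummarizedExperiment} with two assays, \code{"intensities"}
#' (log2 intensity, probes in rows, samples in columns) and \code{"flags"}
#' (non-negative integer count of quality flags per spot), a per-sample
#' group label (\code{CT} control or \code{PD} case) in \code{colData},
#' and a per-probe annotation (\code{gene_symbol}, logical
#' \code{go_annotated}) in \code{rowData}.
#'
#' Subsetting, dimnames and assay access are inherited from
#' \code{SummarizedExperiment}; use the accessors \code{\link{intensities}},
#' \code{\link{flagCounts}}, \code{\link{sampleGroups}},
#' \code{\link{geneSymbols}} and \code{\link{goAnnotated}}.
#'
#' @seealso \code{\link{ExpressionStudy}} (constructor),
#'   \code{\link{readStudy}}, \code{\link{generateStudy}}
#' @export
setClass("ExpressionStudy", contains = "SummarizedExperiment")

.validExpressionStudy <- function(object) {
    msg <- character(0)
    an <- SummarizedExperiment::assayNames(object)
    if (!all(c("intensities", "flags") %in% an))
        return("assays must contain 'intensities' and 'flags'")
    if (is.null(rownames(object)) || is.null(colnames(object)))
        msg <- c(msg, "probe and sample ids (dimnames) are required")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate probe ids")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate sample ids")
    fl <- SummarizedExperiment::assay(object, "flags")
    if (any(fl < 0) || any(fl != round(fl)))
        msg <- c(msg, "flags must be non-negative integer counts")
    cd <- SummarizedExperiment::colData(object)
    if (!"group" %in% colnames(cd)) {
        msg <- c(msg, "colData must contain a 'group' column")
    } else {
        g <- as.character(cd$group)
        bad <- setdiff(unique(g), c("CT", "PD"))
        if (length(bad))
            msg <- c(msg, sprintf("unknown group label(s): %s",
                                  paste(bad, collapse = ", ")))
    }
    rd <- SummarizedExperiment::rowData(object)
    if (!all(c("gene_symbol", "go_annotated") %in% colnames(rd)))
        msg <- c(msg, "rowData must contain 'gene_symbol' and 'go_annotated'")
    if (length(msg)) msg else TRUE
}

setValidity("ExpressionStudy", .validExpressionStudy)

#' SyntheticTruth: planted structure of a generated study
#'
#' Ground truth attached to a synthetic \linkS4class{ExpressionStudy}:
#' module membership of each annotated gene (NA for background genes),
#' the designated hub gene of each planted module, and the genes given a
#' case-group expression shift.
#'
#' @slot moduleOf named integer vector over annotated gene symbols;
#'   \code{NA} means the gene belongs to no module.
#' @slot hubGenes character, one designated hub per module (the member
#'   with the highest factor loading).
#' @slot deGenes character, genes upregulated in the case (PD) group.
#' @export
setClass("SyntheticTruth", representation(
    moduleOf = "integer",
    hubGenes = "character",
    deGenes = "character"
))

setValidity("SyntheticTruth", function(object) {
    msg <- character(0)
    if (is.null(names(object@moduleOf)))
        msg <- c(msg, "moduleOf must be a named vector")
    inmod <- names(object@moduleOf)[!is.na(object@moduleOf)]
    if (!all(object@hubGenes %in% inmod))
        msg <- c(msg, "every hub gene must belong to a module")
    nmod <- length(unique(object@moduleOf[!is.na(object@moduleOf)]))
    if (length(object@hubGenes) != nmod)
        msg <- c(msg, "exactly one hub per module is required")
    if (length(msg)) msg else TRUE
})

#' DEResult: differential-expression calls for one contrast
#'
#' Per-gene results of either the exact Wilcoxon-Mann-Whitney selector or
#' the SAM selector. The \code{table} slot holds one row per gene with
#' columns \code{gene}, \code{statistic} (rank-sum W or SAM d-score),
#' \code{p_value} (Wilcoxon only, NA otherwise), \code{q_or_fdr}
#' (SAM only: estimated FDR of the calling threshold), \code{direction}
#' (\code{"up_in_case"} / \code{"down_in_case"}) and logical
#' \code{significant}.
#'
#' @slot table data.frame as described above.
#' @slot method "wilcoxon" or "sam".
#' @slot params list of calling parameters (alpha, or target FDR, chosen
#'   delta, fudge factor s0, permutation count).
#' @export
setClass("DEResult", representation(
    table = "data.frame",
    method = "character",
    params = "list"
))

setValidity("DEResult", function(object) {
    need <- c("gene", "statistic", "p_value", "q_or_fdr", "direction",
              "significant")
    if (!all(need %in% colnames(object@table)))
        return(sprintf("table must have columns: %s",
                       paste(need, collapse = ", ")))
    if (!object@method %in% c("wilcoxon", "sam"))
        return("method must be 'wilcoxon' or 'sam'")
    if (object@method == "wilcoxon" && !all(is.na(object@table$q_or_fdr)))
        return("q_or_fdr must be NA for the Wilcoxon method")
    if (object@method == "sam" && !all(is.na(object@table$p_value)))
        return("p_value must be NA for the SAM method")
    TRUE
})

#' CoexpressionNetwork: hard-threshold Pearson coexpression graph
#'
#' Undirected graph over a fixed gene set. Nodes are all genes passed to
#' \code{\link{buildNetwork}} (isolated genes are retained); edges connect
#' pairs whose Pearson correlation meets the hard threshold, and carry the
#' correlation as weight.
#'
#' @slot genes character, canonical (sorted) node list.
#' @slot edges data.frame with columns \code{gene_a}, \code{gene_b}
#'   (\code{gene_a < gene_b} lexicographically) and numeric \code{r}.
#' @slot threshold the correlation cutoff that produced the edge set.
#' @slot mode "absolute" (edge iff |r| >= threshold) or "positive"
#'   (edge iff r >= threshold).
#' @slot label free-text condition label, e.g. "VA-CT".
#' @export
setClass("CoexpressionNetwork", representation(
    genes = "character",
    edges = "data.frame",
    threshold = "numeric",
    mode = "character",
    label = "character"
))

setValidity("CoexpressionNetwork", function(object) {
    msg <- character(0)
    e <- object@edges
    if (!all(c("gene_a", "gene_b", "r") %in% colnames(e)))
        return("edges must have columns gene_a, gene_b, r")
    if (nrow(e)) {
        if (any(e$gene_a == e$gene_b))
            msg <- c(msg, "self-loops are not allowed")
        if (any(e$gene_a > e$gene_b))
            msg <- c(msg, "edges must be stored with gene_a < gene_b")
        if (anyDuplicated(paste(e$gene_a, e$gene_b)))
            msg <- c(msg, "duplicate edges")
        if (!all(e$gene_a %in% object@genes) ||
            !all(e$gene_b %in% object@genes))
            msg <- c(msg, "edge endpoints must be network genes")
        ok <- if (identical(object@mode, "positive")) e$r else abs(e$r)
        if (any(ok < object@threshold - 1e-12))
            msg <- c(msg, "edge correlations below threshold")
    }
    if (!object@mode %in% c("absolute", "positive"))
        msg <- c(msg, "mode must be 'absolute' or 'positive'")
    if (length(object@threshold) != 1 || object@threshold <= 0 ||
        object@threshold > 1)
        msg <- c(msg, "threshold must be a single value in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' HubTable: degree-ranked genes of one network
#'
#' One row per network gene with its degree (number of gene-gene links)
#' and a hub flag, sorted by decreasing degree with alphabetical
#' tie-break -- the structure of a per-condition hub table.
#'
#' @slot table data.frame with columns \code{gene}, \code{degree},
#'   \code{is_hub}.
#' @slot label condition label of the source network.
#' @slot rule list describing the hub rule applied (\code{top_n} or
#'   \code{quantile} and its value).
#' @export
setClass("HubTable", representation(
    table = "data.frame",
    label = "character",
    rule = "list"
))

#' ModulePartition: module assignment of network genes
#'
#' @slot assignment named integer vector mapping every network gene to a
#'   module id (contiguous from 1; isolated genes form singleton modules
#'   under the components method).
#' @slot modularity Newman-Girvan modularity of the partition on the
#'   unweighted thresholded graph.
#' @slot method "components" or "greedy_modularity".
#' @export
setClass("ModulePartition", representation(
    assignment = "integer",
    modularity = "numeric",
    method = "character"
))

setValidity("ModulePartition", function(object) {
    a <- object@assignment
    if (length(a) && is.null(names(a)))
        return("assignment must be named by gene")
    ids <- sort(unique(unname(a)))
    if (length(ids) && !identical(ids, seq_along(ids)))
        return("module ids must be contiguous from 1")
    TRUE
})

#' ComparisonReport: condition-vs-control network comparison
#'
#' The cross-network report: one row per hub of either network with its
#' degree in both networks (a gene absent from a network has degree 0 and
#' \code{present_*} FALSE), the hub status (\code{CT}, \code{PD},
#' \code{both}, \code{neither}), a per-network topology summary
#' (N, L, threshold, mean connectivity k, number of modules containing at
#' least one hub), and the common-hub gene set.
#'
#' @slot hubRows data.frame with columns \code{gene}, \code{degree_ct},
#'   \code{degree_pd}, \code{present_ct}, \code{present_pd}, \code{hub_in}.
#' @slot summary data.frame, one row per condition with columns
#'   \code{condition}, \code{n_genes}, \code{n_edges}, \code{threshold},
#'   \code{k}, \code{hub_modules}.
#' @slot commonHubs character, genes ranked as hubs in both networks.
#' @export
setClass("ComparisonReport", representation(
    hubRows = "data.frame",
    summary = "data.frame",
    commonHubs = "character"
))

setValidity("ComparisonReport", function(object) {
    r <- object@hubRows
    need <- c("gene", "degree_ct", "degree_pd", "present_ct", "present_pd",
              "hub_in")
    if (!all(need %in% colnames(r)))
        return(sprintf("hubRows must have columns: %s",
                       paste(need, collapse = ", ")))
    both <- sort(r$gene[r$hub_in == "both"])
    if (!identical(both, sort(object@commonHubs)))
        return("commonHubs must equal the genes with hub_in == 'both'")
    TRUE
})
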