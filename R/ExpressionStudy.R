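#' Construct an ExpressionStudy
#'
#' Assemble a validated \linkS4class{ExpressionStudy} from its parts.
#'
#' @param intensities numeric probe x sample matrix of log2 intensities,
#'   with probe ids as rownames and sample ids as colnames.
#' @param flags integer matrix of the same shape: number of QC flags per
#'   spot (0 = clean). Defaults to an all-zero matrix.
#' @param groups named character vector (or factor) mapping every sample
#'   id to \code{"CT"} or \code{"PD"}.
#' @param annotation data.frame with columns \code{probe_id},
#'   \code{gene_symbol}, \code{go_annotated} covering every probe, or
#'   \code{NULL} to annotate each probe by its own id (all GO-annotated).
#' @param requireTwoPerGroup enforce at least two samples in every group
#'   present (the design minimum for correlation and testing). Per-group
#'   subsets produced downstream may relax this.
#'
#' @return An \linkS4class{ExpressionStudy}.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("p", 1:3), paste0("s", 1:4)))
#' es <- ExpressionStudy(m, groups = c(s1 = "CT", s2 = "CT",
#'                                     s3 = "PD", s4 = "PD"))
#' @export
ExpressionStudy <- function(intensities, flags = NULL, groups,
                            annotation = NULL,
                            requireTwoPerGroup = TRUE) {
    if (!is.matrix(intensities) || !is.numeric(intensities))
        stop("'intensities' must be a numeric matrix")
    if (is.null(rownames(intensities)) || is.null(colnames(intensities)))
        stop("'intensities' must have probe rownames and sample colnames")
    if (is.null(flags)) {
        flags <- matrix(0L, nrow(intensities), ncol(intensities),
                        dimnames = dimnames(intensities))
    }
    if (!identical(dim(flags), dim(intensities)))
        stop("'flags' must have the same dimensions as 'intensities'")
    dimnames(flags) <- dimnames(intensities)
    storage.mode(flags) <- "integer"

    samples <- colnames(intensities)
    groups <- vapply(groups, as.character, character(1))
    missing <- setdiff(samples, names(groups))
    if (length(missing))
        stop("no group label for sample(s): ", paste(missing, collapse = ", "))
    g <- groups[samples]
    if (requireTwoPerGroup) {
        tab <- table(g)
        if (any(tab < 2))
            stop("each group needs at least 2 samples; got ",
                 paste(sprintf("%s=%d", names(tab), tab), collapse = ", "))
    }

    probes <- rownames(intensities)
    if (is.null(annotation)) {
        annotation <- data.frame(probe_id = probes, gene_symbol = probes,
                                 go_annotated = TRUE,
                                 stringsAsFactors = FALSE)
    }
    need <- c("probe_id", "gene_symbol", "go_annotated")
    if (!all(need %in% colnames(annotation)))
        stop("'annotation' must have columns ", paste(need, collapse = ", "))
    miss <- setdiff(probes, annotation$probe_id)
    if (length(miss))
        stop("no annotation for probe(s): ",
             paste(utils::head(miss, 5), collapse = ", "))
    ann <- annotation[match(probes, annotation$probe_id), , drop = FALSE]

    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(intensities = intensities, flags = flags),
        rowData = S4Vectors::DataFrame(
            gene_symbol = as.character(ann$gene_symbol),
            go_annotated = as.logical(ann$go_annotated),
            row.names = probes),
        colData = S4Vectors::DataFrame(group = unname(g),
                                       row.names = samples))
    methods::new("ExpressionStudy", se)
}

#' Accessors for ExpressionStudy
#'
#' \code{intensities} returns the log2 intensity matrix;
#' \code{flagCounts} the per-spot QC flag count matrix;
#' \code{sampleGroups} the named CT/PD group vector;
#' \code{geneSymbols} the probe-to-gene-symbol map;
#' \code{goAnnotated} the named logical GO-annotation flag.
#'
#' @param x an \linkS4class{ExpressionStudy}.
#' @return See the description per accessor.
#' @name ExpressionStudy-accessors
#' @aliases intensities flagCounts sampleGroups geneSymbols goAnnotated
NULL

#' @rdname ExpressionStudy-accessors
#' @export
setMethod("intensities", "ExpressionStudy", function(x)
    SummarizedExperiment::assay(x, "intensities"))

#' @rdname ExpressionStudy-accessors
#' @export
setMethod("flagCounts", "ExpressionStudy", function(x)
    SummarizedExperiment::assay(x, "flags"))

#' @rdname ExpressionStudy-accessors
#' @export
setMethod("sampleGroups", "ExpressionStudy", function(x) {
    g <- as.character(SummarizedExperiment::colData(x)$group)
    names(g) <- colnames(x)
    g
})

#' @rdname ExpressionStudy-accessors
#' @export
setMethod("geneSymbols", "ExpressionStudy", function(x) {
    s <- as.character(SummarizedExperiment::rowData(x)$gene_symbol)
    names(s) <- rownames(x)
    s
})

#' @rdname ExpressionStudy-accessors
#' @export
setMethod("goAnnotated", "ExpressionStudy", function(x) {
    s <- as.logical(SummarizedExperiment::rowData(x)$go_annotated)
    names(s) <- rownames(x)
    s
})

#' Split a study into its per-group sub-studies
#'
#' Returns one \linkS4class{ExpressionStudy} per group label, in label
#' order, each containing only that group's samples. Used to build one
#' coexpression network per condition.
#'
#' @param study an \linkS4class{ExpressionStudy}.
#' @return Named list of \linkS4class{ExpressionStudy}, e.g.
#'   \code{list(CT = ..., PD = ...)}.
#' @export
splitByGroup <- function(study) {
    g <- sampleGroups(study)
    lapply(split(names(g), g), function(s) study[, s])
}

setMethod("show", "ExpressionStudy", function(object) {
    g <- table(sampleGroups(object))
    cat(sprintf("ExpressionStudy: %d probes x %d samples (%s)\n",
                nrow(object), ncol(object),
                paste(sprintf("%s=%d", names(g), g), collapse = ", ")))
    cat(sprintf("  GO-annotated probes: %d | flagged spots (>=1 flag): %d\n",
                sum(goAnnotated(object)), sum(flagCounts(object) >= 1)))
    invisible(NULL)
})
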