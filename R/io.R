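#' Read an ExpressionStudy from its four TSV files
#'
#' Reads the tab-delimited interchange format: an expression matrix and a
#' flag matrix (header row of sample ids, first column \code{probe_id}),
#' a probe annotation table (\code{probe_id}, \code{gene_symbol},
#' \code{go_annotated} coded 0/1) and a sample-group table
#' (\code{sample_id}, \code{group} with values CT/PD). Row and column
#' order are taken from the files. Dimension mismatches, duplicated ids,
#' unknown group labels and samples missing from the group table are
#' load errors naming the offender.
#'
#' @param expr_path,flags_path,annotation_path,groups_path file paths.
#' @return A validated \linkS4class{ExpressionStudy}.
#' @seealso \code{\link{writeStudy}} for the inverse.
#' @export
readStudy <- function(expr_path, flags_path, annotation_path, groups_path) {
    readTsv <- function(p) {
        if (!file.exists(p)) .stopf("file not found: %s", p)
        utils::read.delim(p, check.names = FALSE, stringsAsFactors = FALSE)
    }
    readMatrix <- function(p, what) {
        d <- readTsv(p)
        ids <- as.character(d[[1]])
        if (anyDuplicated(ids))
            .stopf("duplicate probe id in %s: %s", what,
                   ids[duplicated(ids)][1])
        m <- as.matrix(d[, -1, drop = FALSE])
        if (anyDuplicated(colnames(m)))
            .stopf("duplicate sample id in %s: %s", what,
                   colnames(m)[duplicated(colnames(m))][1])
        rownames(m) <- ids
        m
    }
    expr <- readMatrix(expr_path, "expression matrix")
    flags <- readMatrix(flags_path, "flag matrix")
    if (!identical(dim(expr), dim(flags)) ||
        !identical(dimnames(expr), dimnames(flags)))
        .stopf("flag matrix does not match expression matrix (%dx%d vs %dx%d)",
               nrow(flags), ncol(flags), nrow(expr), ncol(expr))

    groups_df <- readTsv(groups_path)
    if (!all(c("sample_id", "group") %in% colnames(groups_df)))
        .stopf("groups file needs columns sample_id, group")
    missing <- setdiff(colnames(expr), groups_df$sample_id)
    if (length(missing))
        .stopf("sample(s) present in expression but absent from groups: %s",
               paste(missing, collapse = ", "))
    groups <- stats::setNames(as.character(groups_df$group),
                              groups_df$sample_id)

    ann <- readTsv(annotation_path)
    if (!all(c("probe_id", "gene_symbol", "go_annotated") %in% colnames(ann)))
        .stopf("annotation file needs columns probe_id, gene_symbol, go_annotated")
    ann$go_annotated <- as.logical(as.integer(ann$go_annotated))

    ExpressionStudy(expr, flags, groups, ann)
}

#' Write an ExpressionStudy to its four TSV files
#'
#' Writes the expression matrix, flag matrix, annotation and group
#' tables in the format \code{\link{readStudy}} reads. Intensities are
#' written with 15 significant digits so the round trip is the identity
#' up to text precision.
#'
#' @param study an \linkS4class{ExpressionStudy}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Invisibly, the named vector of the four file paths.
#' @export
writeStudy <- function(study, dir, prefix = "study") {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- c(
        expression = file.path(dir, paste0(prefix, "_expression.tsv")),
        flags = file.path(dir, paste0(prefix, "_flags.tsv")),
        annotation = file.path(dir, paste0(prefix, "_annotation.tsv")),
        groups = file.path(dir, paste0(prefix, "_groups.tsv")))
    writeMatrix <- function(m, p, fmt = "%.15g") {
        df <- data.frame(probe_id = rownames(m),
                         apply(m, 2, function(col) sprintf(fmt, col)),
                         check.names = FALSE, stringsAsFactors = FALSE)
        colnames(df) <- c("probe_id", colnames(m))
        utils::write.table(df, p, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    writeMatrix(intensities(study), paths["expression"])
    writeMatrix(flagCounts(study), paths["flags"], fmt = "%d")
    ann <- data.frame(probe_id = rownames(study),
                      gene_symbol = unname(geneSymbols(study)),
                      go_annotated = as.integer(goAnnotated(study)),
                      stringsAsFactors = FALSE)
    utils::write.table(ann, paths["annotation"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    g <- sampleGroups(study)
    utils::write.table(
        data.frame(sample_id = names(g), group = unname(g)),
        paths["groups"], sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(paths)
}

#' Write planted truth to JSON
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param path output JSON path.
#' @return Invisibly, \code{path}.
#' @export
writeTruthJSON <- function(truth, path) {
    mo <- truthModules(truth)
    jsonlite::write_json(
        list(module_of_gene = as.list(stats::setNames(
                 ifelse(is.na(mo), "none", as.character(mo)), names(mo))),
             hub_genes = hubGenes(truth),
             de_genes = truthDEGenes(truth)),
        path, auto_unbox = TRUE, pretty = TRUE)
    invisible(path)
}

#' Export a network in Cytoscape SIF format
#'
#' One line per undirected edge,
#' \code{geneA<TAB>coexp<TAB>geneB} with the lexicographically smaller
#' gene first; isolated genes are written as bare single-token lines so
#' the node set survives the export.
#'
#' @param network a \linkS4class{CoexpressionNetwork}.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writeNetworkSIF <- function(network, path) {
    e <- networkEdges(network)
    lines <- if (nrow(e)) paste(e$gene_a, "coexp", e$gene_b, sep = "\t")
             else character(0)
    iso <- setdiff(networkGenes(network), c(e$gene_a, e$gene_b))
    writeLines(c(lines, iso), path)
    invisible(path)
}

#' Export a network edge list as TSV
#'
#' Columns \code{gene_a}, \code{gene_b}, \code{r}; header always
#' written, so an empty network yields a header-only file.
#'
#' @inheritParams writeNetworkSIF
#' @return Invisibly, \code{path}.
#' @export
writeEdgeList <- function(network, path) {
    e <- networkEdges(network)
    e$r <- sprintf("%.15g", e$r)
    utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Export a network as GraphML
#'
#' Nodes carry \code{symbol} and \code{degree} attributes; edges carry
#' the correlation as \code{weight}. The file is readable by Cytoscape
#' and any GraphML parser.
#'
#' @inheritParams writeNetworkSIF
#' @return Invisibly, \code{path}.
#' @export
writeNetworkGraphML <- function(network, path) {
    g <- asIgraph(network)
    igraph::V(g)$symbol <- igraph::V(g)$name
    igraph::V(g)$degree <- igraph::degree(g)
    igraph::write_graph(g, path, format = "graphml")
    invisible(path)
}
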