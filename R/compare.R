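#' Compare a control and a case coexpression network
#'
#' Builds the condition-vs-control report in the style of published
#' case-control hub tables: the row set is the union of both networks'
#' hubs, each row carries the gene's degree in both networks (0 with an
#' absence marker when the gene is not a node of a network), and genes
#' ranked as hubs in both networks are flagged as common hubs. The
#' summary block reports per network N, L, threshold, mean connectivity
#' k and -- when partitions are supplied -- the number of modules
#' containing at least one hub.
#'
#' @param netCT,netPD \linkS4class{CoexpressionNetwork}s of the control
#'   and case condition of the same contrast.
#' @param hubsCT,hubsPD \linkS4class{HubTable}s computed from those
#'   networks.
#' @param partitions optional list with elements \code{CT} and \code{PD}
#'   (\linkS4class{ModulePartition}s) for the hub-module dispersion
#'   summary.
#' @return A \linkS4class{ComparisonReport}.
#' @export
compareNetworks <- function(netCT, netPD, hubsCT, hubsPD,
                            partitions = NULL) {
    if (!length(intersect(networkGenes(netCT), networkGenes(netPD))))
        .stopf("the two networks share no genes; %s",
               "are they from the same contrast?")
    hct <- hubGenes(hubsCT); hpd <- hubGenes(hubsPD)
    rows <- sort(union(hct, hpd))
    dct <- nodeDegrees(netCT); dpd <- nodeDegrees(netPD)
    degree_ct <- ifelse(rows %in% names(dct), dct[rows], 0L)
    degree_pd <- ifelse(rows %in% names(dpd), dpd[rows], 0L)
    hub_in <- ifelse(rows %in% hct & rows %in% hpd, "both",
              ifelse(rows %in% hct, "CT",
              ifelse(rows %in% hpd, "PD", "neither")))
    hubRows <- data.frame(
        gene = rows,
        degree_ct = as.integer(degree_ct),
        degree_pd = as.integer(degree_pd),
        present_ct = rows %in% networkGenes(netCT),
        present_pd = rows %in% networkGenes(netPD),
        hub_in = hub_in,
        stringsAsFactors = FALSE)
    ord <- order(-pmax(hubRows$degree_ct, hubRows$degree_pd), hubRows$gene)
    hubRows <- hubRows[ord, ]
    rownames(hubRows) <- NULL

    hubmod <- function(cond, net, hubs) {
        if (is.null(partitions) || is.null(partitions[[cond]]))
            return(NA_integer_)
        hubModuleProfile(partitions[[cond]], hubs)$n_hub_modules
    }
    summary <- data.frame(
        condition = c("CT", "PD"),
        n_genes = c(length(networkGenes(netCT)),
                    length(networkGenes(netPD))),
        n_edges = c(nrow(networkEdges(netCT)), nrow(networkEdges(netPD))),
        threshold = c(networkThreshold(netCT), networkThreshold(netPD)),
        k = c(meanConnectivity(netCT), meanConnectivity(netPD)),
        hub_modules = c(hubmod("CT", netCT, hubsCT),
                        hubmod("PD", netPD, hubsPD)),
        stringsAsFactors = FALSE)

    methods::new("ComparisonReport", hubRows = hubRows, summary = summary,
                 commonHubs = sort(intersect(hct, hpd)))
}

#' Accessors for ComparisonReport
#'
#' \code{comparisonRows} returns the per-gene hub rows;
#' \code{comparisonSummary} the per-network topology summary;
#' \code{commonHubs} the genes ranked as hubs in both networks.
#'
#' @param x a \linkS4class{ComparisonReport}.
#' @name ComparisonReport-accessors
NULL

#' @rdname ComparisonReport-accessors
#' @export
setMethod("comparisonRows", "ComparisonReport", function(x) x@hubRows)

#' @rdname ComparisonReport-accessors
#' @export
setMethod("comparisonSummary", "ComparisonReport", function(x) x@summary)

#' @rdname ComparisonReport-accessors
#' @export
setMethod("commonHubs", "ComparisonReport", function(x) x@commonHubs)

setMethod("show", "ComparisonReport", function(object) {
    s <- object@summary
    cat("ComparisonReport\n")
    for (i in seq_len(nrow(s)))
        cat(sprintf("  %s: N = %d, L = %d, threshold = %.3g, k = %s%s\n",
                    s$condition[i], s$n_genes[i], s$n_edges[i],
                    s$threshold[i], formatConnectivity(s$k[i]),
                    if (is.na(s$hub_modules[i])) ""
                    else sprintf(", hub modules = %d", s$hub_modules[i])))
    cat(sprintf("  common hubs (%d): %s\n", length(object@commonHubs),
                paste(object@commonHubs, collapse = ", ")))
    invisible(NULL)
})

#' Default configuration for runContrast
#'
#' @param de_method "wilcoxon" or "sam".
#' @param alpha Wilcoxon raw-p cutoff.
#' @param target_fdr SAM target FDR.
#' @param n_permutations SAM permutation budget.
#' @param max_flags spot-flag tolerance for \code{\link{filterFlags}}.
#' @param span lowess span.
#' @param collapse collapse probes to gene symbols before testing.
#' @param threshold_ct,threshold_pd fixed per-condition correlation
#'   thresholds; leave \code{NULL} to derive each from
#'   \code{target_edges}.
#' @param target_edges per-condition target edge count for
#'   \code{\link{chooseThreshold}} (used when thresholds are NULL).
#' @param mode correlation thresholding mode ("absolute" or "positive").
#' @param drop_isolates drop zero-degree genes from the networks.
#' @param hub_top_n hub rule: top-n with boundary ties.
#' @param module_method module detection method.
#' @param seed seed for SAM permutations.
#' @param label contrast label, e.g. "VA".
#' @return A named list of class \code{"ContrastConfig"}.
#' @export
contrastConfig <- function(de_method = c("wilcoxon", "sam"),
                           alpha = 0.005, target_fdr = 0.05,
                           n_permutations = 200L,
                           max_flags = 1L, span = 0.3, collapse = TRUE,
                           threshold_ct = NULL, threshold_pd = NULL,
                           target_edges = 650L, mode = "absolute",
                           drop_isolates = FALSE,
                           hub_top_n = 10L,
                           module_method = "components",
                           seed = 1L, label = "") {
    cfg <- list(de_method = match.arg(de_method), alpha = alpha,
                target_fdr = target_fdr,
                n_permutations = as.integer(n_permutations),
                max_flags = as.integer(max_flags), span = span,
                collapse = collapse,
                threshold_ct = threshold_ct, threshold_pd = threshold_pd,
                target_edges = as.integer(target_edges), mode = mode,
                drop_isolates = drop_isolates,
                hub_top_n = as.integer(hub_top_n),
                module_method = module_method,
                seed = as.integer(seed), label = label)
    class(cfg) <- "ContrastConfig"
    cfg
}

#' Read a contrast configuration from YAML or JSON
#'
#' @param path file whose keys are \code{\link{contrastConfig}}
#'   arguments.
#' @return A \code{"ContrastConfig"}.
#' @export
readContrastConfig <- function(path) {
    do.call(contrastConfig, yaml::read_yaml(path))
}

#' Run the full case-control coexpression contrast
#'
#' The end-to-end pipeline for one anatomical contrast, in the stated
#' order: spot-flag filtering, lowess normalization, probe collapsing,
#' differential-expression selection on the full two-group study
#' (Wilcoxon or SAM per config), restriction to GO-annotated significant
#' genes, then one hard-threshold network per condition over the SAME
#' selected gene list using only that condition's samples, hub ranking,
#' module detection, and the cross-network comparison report. Fully
#' reproducible from the study, config and seed. Stage failures are
#' re-raised with the stage name attached.
#'
#' @param study an \linkS4class{ExpressionStudy} containing both groups.
#' @param config a \code{\link{contrastConfig}}.
#' @param outDir optional directory; when given, all artifacts are
#'   written there (report TSV/JSON, SIF, GraphML and edge list per
#'   network, DE table).
#' @return A list with elements \code{report}
#'   (\linkS4class{ComparisonReport}), \code{de}
#'   (\linkS4class{DEResult}), \code{genes} (selected gene list),
#'   \code{networks}, \code{hubs}, \code{partitions} (per-condition
#'   lists).
#' @export
runContrast <- function(study, config = contrastConfig(), outDir = NULL) {
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            .stopf("[%s] %s", name, conditionMessage(e)))
    }
    st <- stage("filter", filterFlags(study, config$max_flags))
    st <- stage("normalize", lowessNormalize(st, config$span))
    if (isTRUE(config$collapse))
        st <- stage("collapse", collapseProbes(st))

    de <- stage("de", switch(config$de_method,
        wilcoxon = wilcoxonDE(st, alpha = config$alpha),
        sam = samDE(st, targetFDR = config$target_fdr,
                    nPermutations = config$n_permutations,
                    seed = config$seed)))
    genes <- stage("select", selectDEGenes(de, st))
    if (length(genes) < 2)
        .stopf("[select] %d selected gene(s); need >= 2", length(genes))

    halves <- splitByGroup(st)
    nets <- hubs <- parts <- list()
    for (cond in c("CT", "PD")) {
        sub <- halves[[cond]]
        thr <- config[[paste0("threshold_", tolower(cond))]]
        if (is.null(thr))
            thr <- stage(paste0("threshold-", cond),
                         chooseThreshold(sub, genes, config$target_edges,
                                         config$mode))
        lab <- paste0(if (nzchar(config$label))
                          paste0(config$label, "-") else "", cond)
        nets[[cond]] <- stage(paste0("network-", cond),
            buildNetwork(sub, genes, thr, config$mode, label = lab,
                         dropIsolates = config$drop_isolates))
        hubs[[cond]] <- degreeTable(nets[[cond]], "top_n",
                                    n = config$hub_top_n)
        parts[[cond]] <- detectModules(nets[[cond]], config$module_method,
                                       seed = config$seed)
    }
    report <- stage("compare",
        compareNetworks(nets$CT, nets$PD, hubs$CT, hubs$PD, parts))

    if (!is.null(outDir)) writeContrastArtifacts(
        outDir, report, de, nets, config)
    list(report = report, de = de, genes = genes, networks = nets,
         hubs = hubs, partitions = parts)
}

writeContrastArtifacts <- function(outDir, report, de, nets, config) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    utils::write.table(comparisonRows(report),
                       file.path(outDir, "report_hubs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    s <- comparisonSummary(report)
    s$k <- formatConnectivity(s$k)
    utils::write.table(s, file.path(outDir, "report_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
        list(summary = s, common_hubs = commonHubs(report),
             config = unclass(config)),
        file.path(outDir, "report.json"), auto_unbox = TRUE, pretty = TRUE,
        digits = NA)
    utils::write.table(deTable(de), file.path(outDir, "de_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (cond in names(nets)) {
        writeNetworkSIF(nets[[cond]],
                        file.path(outDir, sprintf("network_%s.sif", cond)))
        writeNetworkGraphML(nets[[cond]],
                            file.path(outDir,
                                      sprintf("network_%s.graphml", cond)))
        writeEdgeList(nets[[cond]],
                      file.path(outDir, sprintf("edges_%s.tsv", cond)))
    }
    invisible(outDir)
}
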