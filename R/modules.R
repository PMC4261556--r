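#' Detect modules in a coexpression network
#'
#' Partitions the thresholded graph into modules (densely
#' interconnected gene sets). Two transparent methods are provided:
#' \code{"components"} (default) takes the connected components, which
#' matches how visually separated subnetworks are read off a network
#' layout; \code{"greedy_modularity"} runs agglomerative modularity
#' maximization (fast-greedy) on the unweighted graph, which splits
#' components that are internally organized into several dense blocks
#' joined by sparse bridges. Both are deterministic given the canonical
#' node order; \code{seed} is accepted for interface stability but no
#' randomness is involved.
#'
#' @param network a \linkS4class{CoexpressionNetwork}.
#' @param method "components" or "greedy_modularity".
#' @param seed unused by the current methods; kept for reproducibility
#'   bookkeeping.
#' @return A \linkS4class{ModulePartition}; module ids are contiguous
#'   from 1, isolated genes form singleton modules, and the
#'   Newman-Girvan modularity of the partition on the unweighted graph
#'   is recorded.
#' @export
detectModules <- function(network, method = c("components",
                                              "greedy_modularity"),
                          seed = 1L) {
    method <- match.arg(method)
    g <- asIgraph(network)
    if ("weight" %in% igraph::edge_attr_names(g))
        g <- igraph::delete_edge_attr(g, "weight")  # threshold already encodes strength
    if (igraph::vcount(g) == 0) {
        return(methods::new("ModulePartition",
                            assignment = stats::setNames(integer(0),
                                                         character(0)),
                            modularity = NA_real_, method = method))
    }
    memb <- if (method == "components") {
        igraph::components(g)$membership
    } else {
        igraph::membership(igraph::cluster_fast_greedy(g))
    }
    # contiguous ids from 1, numbered by first appearance in node order
    ids <- as.integer(factor(as.integer(memb),
                             levels = unique(as.integer(memb))))
    names(ids) <- igraph::V(g)$name
    mod <- if (igraph::ecount(g) > 0)
        igraph::modularity(g, ids) else NA_real_
    methods::new("ModulePartition", assignment = ids, modularity = mod,
                 method = method)
}

#' Accessors for ModulePartition
#'
#' \code{moduleAssignment} returns the named gene-to-module id map;
#' \code{modularityScore} the partition modularity; \code{nModules} the
#' number of modules.
#'
#' @param x a \linkS4class{ModulePartition}.
#' @name ModulePartition-accessors
NULL

#' @rdname ModulePartition-accessors
#' @export
setMethod("moduleAssignment", "ModulePartition", function(x) x@assignment)

#' @rdname ModulePartition-accessors
#' @export
setMethod("modularityScore", "ModulePartition", function(x) x@modularity)

#' @rdname ModulePartition-accessors
#' @export
setMethod("nModules", "ModulePartition", function(x)
    length(unique(unname(x@assignment))))

setMethod("show", "ModulePartition", function(object) {
    sizes <- table(object@assignment)
    cat(sprintf(
        "ModulePartition (%s): %d modules over %d genes, modularity %.3f\n",
        object@method, length(sizes), length(object@assignment),
        object@modularity))
    cat("  sizes:", paste(utils::head(sort(as.integer(sizes),
                                           decreasing = TRUE), 10),
                          collapse = ", "), "\n")
    invisible(NULL)
})

#' Group a network's hubs by module
#'
#' Cross-tabulates hub identity against module membership, yielding the
#' per-module hub lists and the headline contrast statistic of
#' case-control network comparisons: the number of modules containing
#' at least one hub (hub dispersion). Control networks typically spread
#' their hubs over several modules while disease networks concentrate
#' them in one.
#'
#' @param partition a \linkS4class{ModulePartition}.
#' @param hubs a \linkS4class{HubTable} from the same network.
#' @return A list with \code{by_module} (named list, module id ->
#'   character vector of hubs; only modules with >= 1 hub appear) and
#'   \code{n_hub_modules} (its length).
#' @export
hubModuleProfile <- function(partition, hubs) {
    hg <- hubGenes(hubs)
    a <- moduleAssignment(partition)
    missing <- setdiff(hg, names(a))
    if (length(missing))
        .stopf("hub gene(s) not in the partition (inputs from different networks?): %s",
               paste(utils::head(missing, 5), collapse = ", "))
    by_module <- split(hg, a[hg])
    list(by_module = by_module, n_hub_modules = length(by_module))
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between a detected module partition and a
#' reference labeling (e.g. planted truth), used as the module-recovery
#' metric. 1 = identical partitions, ~0 = chance agreement.
#'
#' @param a,b labelings of the same genes: named vectors (matched by
#'   name) or equal-length vectors.
#' @return The adjusted Rand index (numeric scalar).
#' @export
adjustedRand <- function(a, b) {
    if (!is.null(names(a)) && !is.null(names(b))) {
        common <- intersect(names(a), names(b))
        a <- a[common]; b <- b[common]
    }
    if (length(a) != length(b))
        .stopf("labelings must cover the same genes")
    tab <- table(a, b)
    nij <- sum(choose(tab, 2))
    ai <- sum(choose(rowSums(tab), 2))
    bj <- sum(choose(colSums(tab), 2))
    n2 <- choose(sum(tab), 2)
    expected <- ai * bj / n2
    maxidx <- (ai + bj) / 2
    if (maxidx == expected) return(1)
    (nij - expected) / (maxidx - expected)
}
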