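#' @rdname ExpressionStudy-accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname ExpressionStudy-accessors
#' @export
setGeneric("flagCounts", function(x) standardGeneric("flagCounts"))

#' @rdname ExpressionStudy-accessors
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname ExpressionStudy-accessors
#' @export
setGeneric("geneSymbols", function(x) standardGeneric("geneSymbols"))

#' @rdname ExpressionStudy-accessors
#' @export
setGeneric("goAnnotated", function(x) standardGeneric("goAnnotated"))

#' @rdname CoexpressionNetwork-accessors
#' @export
setGeneric("networkGenes", function(x) standardGeneric("networkGenes"))

#' @rdname CoexpressionNetwork-accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname CoexpressionNetwork-accessors
#' @export
setGeneric("networkThreshold", function(x) standardGeneric("networkThreshold"))

#' @rdname CoexpressionNetwork-accessors
#' @export
setGeneric("conditionLabel", function(x) standardGeneric("conditionLabel"))

#' @rdname CoexpressionNetwork-accessors
#' @export
setGeneric("nodeDegrees", function(x) standardGeneric("nodeDegrees"))

#' @rdname CoexpressionNetwork-accessors
#' @export
setGeneric("asIgraph", function(x, ...) standardGeneric("asIgraph"))

#' @rdname DEResult-accessors
#' @export
setGeneric("deTable", function(x) standardGeneric("deTable"))

#' @rdname DEResult-accessors
#' @export
setGeneric("significantGenes", function(x) standardGeneric("significantGenes"))

#' @rdname HubTable-accessors
#' @export
setGeneric("hubGenes", function(x) standardGeneric("hubGenes"))

#' @rdname HubTable-accessors
#' @export
setGeneric("hubTable", function(x) standardGeneric("hubTable"))

#' @rdname ModulePartition-accessors
#' @export
setGeneric("moduleAssignment", function(x) standardGeneric("moduleAssignment"))

#' @rdname ModulePartition-accessors
#' @export
setGeneric("modularityScore", function(x) standardGeneric("modularityScore"))

#' @rdname ModulePartition-accessors
#' @export
setGeneric("nModules", function(x) standardGeneric("nModules"))

#' @rdname SyntheticTruth-accessors
#' @export
setGeneric("truthModules", function(x) standardGeneric("truthModules"))

#' @rdname SyntheticTruth-accessors
#' @export
setGeneric("truthDEGenes", function(x) standardGeneric("truthDEGenes"))

#' @rdname ComparisonReport-accessors
#' @export
setGeneric("commonHubs", function(x) standardGeneric("commonHubs"))

#' @rdname ComparisonReport-accessors
#' @export
setGeneric("comparisonSummary", function(x) standardGeneric("comparisonSummary"))

#' @rdname ComparisonReport-accessors
#' @export
setGeneric("comparisonRows", function(x) standardGeneric("comparisonRows"))
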