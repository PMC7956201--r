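#' @rdname FlowCellSet-accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname FlowCellSet-accessors
#' @export
setGeneric("markerNames", function(x) standardGeneric("markerNames"))

#' @rdname FlowCellSet-accessors
#' @export
setGeneric("cellData", function(x) standardGeneric("cellData"))

#' @rdname FlowCellSet-accessors
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname DiscretizedCells-accessors
#' @export
setGeneric("binLabels", function(x) standardGeneric("binLabels"))

#' @rdname DiscretizedCells-accessors
#' @export
setGeneric("binEdges", function(x) standardGeneric("binEdges"))

#' @rdname DiscretizedCells-accessors
#' @export
setGeneric("nLevels", function(x) standardGeneric("nLevels"))

#' @rdname BayesianNetwork-accessors
#' @export
setGeneric("bnNodes", function(x) standardGeneric("bnNodes"))

#' @rdname BayesianNetwork-accessors
#' @export
setGeneric("bnParents", function(x, node) standardGeneric("bnParents"))

#' @rdname BayesianNetwork-accessors
#' @export
setGeneric("bnChildren", function(x, node) standardGeneric("bnChildren"))

#' @rdname BayesianNetwork-accessors
#' @export
setGeneric("arcs", function(x) standardGeneric("arcs"))

#' @rdname BayesianNetwork-accessors
#' @export
setGeneric("networkScore", function(x) standardGeneric("networkScore"))

#' @rdname BayesianNetwork-accessors
#' @export
setGeneric("edgeStrengths", function(x) standardGeneric("edgeStrengths"))

#' @rdname BayesianNetwork-accessors
#' @export
setGeneric("cpt", function(x, node) standardGeneric("cpt"))

#' @rdname discretizeCells
#' @export
setGeneric("discretizeCells", function(x, k = 3L, ...)
    standardGeneric("discretizeCells"))

#' @rdname learnNetwork
#' @export
setGeneric("learnNetwork", function(x, ...) standardGeneric("learnNetwork"))

#' @rdname poolWithContrast
#' @export
setGeneric("poolWithContrast", function(datasets, spec, ...)
    standardGeneric("poolWithContrast"))

#' @rdname buildSupergraph
#' @export
setGeneric("buildSupergraph", function(x, contrastVars, ...)
    standardGeneric("buildSupergraph"))

#' @rdname conditionOnContrast
#' @export
setGeneric("conditionOnContrast", function(x, spec, state, ...)
    standardGeneric("conditionOnContrast"))
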