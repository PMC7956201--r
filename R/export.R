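#' Export a network as DOT
#'
#' Renders a learned network in Graphviz DOT following the figure
#' conventions of the analysis: highlighted (response/contrast) nodes in
#' red, strong Markov-neighborhood members dark grey, weak members light
#' grey, and every edge labeled with its strength rounded to 3
#' significant digits.
#'
#' @param net a \linkS4class{BayesianNetwork}.
#' @param highlight node names to render in red.
#' @param mn optional \linkS4class{MarkovNeighborhood}; its strong/weak
#'   members get the grey fills.
#' @param file optional path to write the DOT text to.
#' @return the DOT text, invisibly when \code{file} is given.
#' @export
exportDOT <- function(net, highlight = character(), mn = NULL,
                      file = NULL) {
    quoteId <- function(x) paste0("\"", gsub("\"", "\\\\\"", x), "\"")
    lines <- c("digraph BN {",
               "  node [style=filled, fillcolor=white, shape=ellipse];")
    for (v in net@nodes) {
        fill <- if (v %in% highlight) "red"
        else if (!is.null(mn) && v %in% mn@strong) "grey40"
        else if (!is.null(mn) && v %in% mn@weak) "grey80"
        else "white"
        lines <- c(lines,
                   sprintf("  %s [fillcolor=%s];", quoteId(v), fill))
    }
    es <- net@edgeStrengths
    for (i in seq_len(nrow(es))) {
        lab <- if (is.na(es$strength[i])) ""
        else sprintf(" [label=\"%s\"]", signif(es$strength[i], 3))
        lines <- c(lines, sprintf("  %s -> %s%s;", quoteId(es$from[i]),
                                  quoteId(es$to[i]), lab))
    }
    lines <- c(lines, "}")
    txt <- paste(lines, collapse = "\n")
    if (!is.null(file)) {
        writeLines(txt, file)
        return(invisible(txt))
    }
    txt
}

#' Export a network structure dump as JSON
#'
#' Serializes nodes, cardinalities, parent sets, family scores, total
#' score, edge strengths and (optionally) the CPTs.
#'
#' @param net a \linkS4class{BayesianNetwork}.
#' @param file optional output path.
#' @param cpts include the conditional probability tables.
#' @return the JSON string, invisibly when \code{file} is given.
#' @export
exportNetworkJSON <- function(net, file = NULL, cpts = FALSE) {
    obj <- list(
        nodes = net@nodes,
        nLevels = as.list(net@nLevels),
        parents = net@parents,
        familyScores = as.list(net@familyScores),
        totalScore = sum(net@familyScores),
        ess = net@ess,
        edges = net@edgeStrengths)
    if (cpts)
        obj$cpts <- lapply(net@cpts, function(m) unclass(as.data.frame(m)))
    txt <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE,
                            pretty = TRUE, dataframe = "rows")
    if (!is.null(file)) {
        writeLines(txt, file)
        return(invisible(txt))
    }
    txt
}
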