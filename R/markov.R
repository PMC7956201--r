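#' Markov neighborhood of a target node
#'
#' The Markov neighborhood (MN) of a node is the set of nodes directly
#' linked to it, as parent or child; it is the simplified Markov blanket
#' used to "zoom in" on the variables most relevant to a clinical response
#' node. Each member carries the strength of its edge to the target, and
#' the members are partitioned into strong and weak by a relative
#' threshold (see [classifyEdges()]).
#'
#' @param net a \linkS4class{BayesianNetwork}.
#' @param target node name.
#' @param relThreshold relative strong/weak cut, in (0, 1): a member is
#'   strong iff its strength is at least this fraction of the maximum
#'   strength in the neighborhood.
#' @return A \linkS4class{MarkovNeighborhood}.
#' @examples
#' # in a chain A -> B -> C, MN(B) = {A, C}
#' @export
markovNeighborhood <- function(net, target, relThreshold = 0.3) {
    if (!target %in% net@nodes) stop("unknown node: ", target)
    pa <- bnParents(net, target)
    ch <- bnChildren(net, target)
    members <- union(pa, ch)
    strengths <- numeric(length(members))
    names(strengths) <- members
    es <- net@edgeStrengths
    for (m in pa)
        strengths[[m]] <- es$strength[es$from == m & es$to == target]
    for (m in setdiff(ch, pa))
        strengths[[m]] <- es$strength[es$from == target & es$to == m]
    mn <- new("MarkovNeighborhood", target = target, members = members,
              strengths = strengths, strong = members,
              weak = character(), relThreshold = relThreshold)
    classifyEdges(mn, relThreshold)
}

#' Markov blanket of a target node
#'
#' Parents, children, and the children's other parents; conditioning on
#' the blanket renders the target independent of the remaining nodes. The
#' Markov neighborhood is always a subset of the blanket.
#'
#' @param net a \linkS4class{BayesianNetwork}.
#' @param target node name.
#' @return character vector of blanket members.
#' @export
markovBlanket <- function(net, target) {
    if (!target %in% net@nodes) stop("unknown node: ", target)
    pa <- bnParents(net, target)
    ch <- bnChildren(net, target)
    spouses <- unlist(lapply(ch, function(c) bnParents(net, c)))
    setdiff(union(union(pa, ch), spouses), target)
}

#' Partition Markov-neighborhood edges into strong and weak
#'
#' A member is strong iff its edge strength is at least
#' \code{relThreshold} times the maximum strength within the neighborhood.
#' The rule is relative, hence invariant to rescaling all strengths by a
#' positive constant, and a single member is always strong.
#'
#' @param mn a \linkS4class{MarkovNeighborhood}.
#' @param relThreshold relative cut in (0, 1).
#' @return The re-partitioned \linkS4class{MarkovNeighborhood}.
#' @export
classifyEdges <- function(mn, relThreshold = 0.3) {
    stopifnot(relThreshold > 0, relThreshold < 1)
    if (!length(mn@members)) {
        mn@strong <- character(); mn@weak <- character()
        mn@relThreshold <- relThreshold
        return(mn)
    }
    cut <- relThreshold * max(mn@strengths)
    strong <- names(mn@strengths)[mn@strengths >= cut]
    mn@strong <- strong
    mn@weak <- setdiff(mn@members, strong)
    mn@relThreshold <- relThreshold
    validObject(mn)
    mn
}

setMethod("show", "MarkovNeighborhood", function(object) {
    cat("MarkovNeighborhood of", object@target, "(",
        length(object@members), "members )\n")
    if (length(object@members)) {
        ord <- order(-object@strengths)
        for (i in ord) {
            m <- names(object@strengths)[i]
            cat(sprintf("  %-12s %10.4g  %s\n", m, object@strengths[[i]],
                        if (m %in% object@strong) "strong" else "weak"))
        }
    } else cat("  (empty)\n")
})

#' Markov-neighborhood report table
#'
#' Tabulates an MN: member, edge direction relative to the target, edge
#' strength, strong/weak class, and an advisory artifact flag. A weak
#' member is flagged "possible artifact" when it shares a skeleton edge
#' with a strong member that is at least \code{artifactFactor} times
#' stronger than its own edge to the target -- the typical signature of an
#' indirect dependence leaking into the neighborhood. Flagging is
#' advisory; no edge is removed.
#'
#' @param net the \linkS4class{BayesianNetwork} the MN came from.
#' @param mn a \linkS4class{MarkovNeighborhood}.
#' @param artifactFactor how much stronger the bypass edge must be.
#' @param file optional path; when given the table is written as TSV.
#' @return data.frame(member, direction, strength, class, artifact).
#' @export
mnTable <- function(net, mn, artifactFactor = 3, file = NULL) {
    members <- names(sort(mn@strengths, decreasing = TRUE))
    es <- net@edgeStrengths
    rows <- lapply(members, function(m) {
        dir <- if (m %in% bnParents(net, mn@target)) "parent" else "child"
        cls <- if (m %in% mn@strong) "strong" else "weak"
        flag <- ""
        if (cls == "weak") {
            for (s in mn@strong) {
                side <- es$strength[(es$from == m & es$to == s) |
                                    (es$from == s & es$to == m)]
                if (length(side) &&
                    max(side) >= artifactFactor * mn@strengths[[m]]) {
                    flag <- "possible artifact"
                    break
                }
            }
        }
        data.frame(member = m, direction = dir,
                   strength = mn@strengths[[m]], class = cls,
                   artifact = flag)
    })
    out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    if (is.null(out))
        out <- data.frame(member = character(), direction = character(),
                          strength = numeric(), class = character(),
                          artifact = character())
    if (!is.null(file))
        utils::write.table(out, file, sep = "\t", row.names = FALSE,
                           quote = FALSE)
    out
}
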