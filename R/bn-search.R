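# Random-restart hill climbing over DAG structures within sparse candidate
# pools, with add/delete/reverse moves scored by BDeu deltas.

#' Structure-search configuration
#'
#' @param kCandidates sparse-candidate pool size per node.
#' @param restarts number of random restarts (the search returns the best
#'   local optimum across restarts).
#' @param seed RNG seed; the whole search is deterministic given the seed.
#' @param ess BDeu equivalent sample size.
#' @param maxParents per-node parent-set cap.
#' @return A \linkS4class{SearchConfig}.
#' @export
SearchConfig <- function(kCandidates = 8L, restarts = 20L, seed = 1L,
                         ess = 1, maxParents = 4L) {
    new("SearchConfig", kCandidates = as.integer(kCandidates),
        restarts = as.integer(restarts), seed = as.integer(seed),
        ess = as.numeric(ess), maxParents = as.integer(maxParents))
}

setMethod("show", "SearchConfig", function(object) {
    cat("SearchConfig: kCandidates =", object@kCandidates,
        "restarts =", object@restarts, "seed =", object@seed,
        "ess =", object@ess, "maxParents =", object@maxParents, "\n")
})

# Does a directed path v ~> u exist? children: list of integer vectors.
.reachesIdx <- function(v, u, children) {
    if (v == u) return(TRUE)
    stack <- children[[v]]
    seen <- logical(length(children))
    while (length(stack)) {
        w <- stack[[length(stack)]]
        stack <- stack[-length(stack)]
        if (w == u) return(TRUE)
        if (!seen[[w]]) {
            seen[[w]] <- TRUE
            stack <- c(stack, children[[w]])
        }
    }
    FALSE
}

.randomStartDAG <- function(p, candIdx, maxParents, edgeProb = 0.25) {
    parents <- rep(list(integer()), p)
    children <- rep(list(integer()), p)
    for (v in sample.int(p)) {
        pool <- candIdx[[v]]
        if (!length(pool)) next
        for (u in pool[sample.int(length(pool))]) {
            if (length(parents[[v]]) >= maxParents) break
            if (stats::runif(1L) > edgeProb) next
            if (.reachesIdx(v, u, children)) next  # u -> v would close a cycle
            parents[[v]] <- c(parents[[v]], u)
            children[[u]] <- c(children[[u]], v)
        }
    }
    list(parents = parents, children = children)
}

# One greedy local search from a given start. Returns parents + total score.
.localSearch <- function(X, cards, candIdx, maxParents, ess, cache,
                         start, scanOrder, tol = 1e-9) {
    p <- ncol(X)
    parents <- start$parents
    children <- start$children
    fs <- function(v, pa) .cachedFamilyScore(cache, X, cards, v, pa, ess)
    cur <- vapply(seq_len(p), function(v) fs(v, parents[[v]]), 0)
    repeat {
        bestDelta <- tol
        move <- NULL
        for (v in scanOrder) {
            pav <- parents[[v]]
            for (u in candIdx[[v]]) {
                if (u %in% pav) {
                    # delete u -> v
                    d <- fs(v, setdiff(pav, u)) - cur[[v]]
                    if (d > bestDelta) { bestDelta <- d; move <- c(1L, u, v) }
                    # reverse u -> v  (u must be reachable as child of v)
                    if (v %in% candIdx[[u]] &&
                        length(parents[[u]]) < maxParents) {
                        children[[u]] <- setdiff(children[[u]], v)
                        ok <- !.reachesIdx(u, v, children)
                        children[[u]] <- c(children[[u]], v)
                        if (ok) {
                            d <- (fs(v, setdiff(pav, u)) - cur[[v]]) +
                                 (fs(u, c(parents[[u]], v)) - cur[[u]])
                            if (d > bestDelta) {
                                bestDelta <- d; move <- c(3L, u, v)
                            }
                        }
                    }
                } else if (u != v && length(pav) < maxParents &&
                           !.reachesIdx(v, u, children)) {
                    # add u -> v
                    d <- fs(v, c(pav, u)) - cur[[v]]
                    if (d > bestDelta) { bestDelta <- d; move <- c(2L, u, v) }
                }
            }
        }
        if (is.null(move)) break
        u <- move[[2L]]; v <- move[[3L]]
        if (move[[1L]] == 1L) {            # delete
            parents[[v]] <- setdiff(parents[[v]], u)
            children[[u]] <- setdiff(children[[u]], v)
        } else if (move[[1L]] == 2L) {     # add
            parents[[v]] <- c(parents[[v]], u)
            children[[u]] <- c(children[[u]], v)
        } else {                           # reverse
            parents[[v]] <- setdiff(parents[[v]], u)
            children[[u]] <- setdiff(children[[u]], v)
            parents[[u]] <- c(parents[[u]], v)
            children[[v]] <- c(children[[v]], u)
            cur[[u]] <- fs(u, parents[[u]])
        }
        cur[[v]] <- fs(v, parents[[v]])
        if (move[[1L]] == 3L) cur[[u]] <- fs(u, parents[[u]])
    }
    list(parents = parents, total = sum(cur))
}

#' Hill-climbing structure search with random restarts
#'
#' Learns a DAG over the variables of \code{data} by greedy add / delete /
#' reverse moves restricted to the candidate parent pools, starting from
#' \code{restarts} random acyclic graphs and keeping the highest-scoring
#' local optimum. Cycle-creating moves are silently skipped. A restart
#' terminates when no move improves the BDeu total by more than 1e-9.
#' The search is deterministic given \code{config@seed}: equal-score moves
#' are resolved by a fixed lexicographic scan order.
#'
#' @param data a \linkS4class{DiscretizedCells}.
#' @param candidates named list of candidate parents per variable, as from
#'   [sparseCandidates()].
#' @param config a \linkS4class{SearchConfig}.
#' @return A \linkS4class{BayesianNetwork} with CPTs (posterior-mean under
#'   the BDeu prior), family scores and edge strengths filled in.
#' @export
hillClimb <- function(data, candidates, config = SearchConfig()) {
    ld <- .learnData(data)
    p <- length(ld$vars)
    if (!setequal(names(candidates), ld$vars))
        stop("candidates must be keyed by the data variables")
    candIdx <- lapply(ld$vars, function(v) {
        idx <- match(candidates[[v]], ld$vars)
        if (anyNA(idx)) stop("unknown candidate for ", v)
        sort(idx[idx != match(v, ld$vars)])
    })
    scanOrder <- order(ld$vars)
    cache <- .scoreCache()
    best <- NULL
    for (rs in seq_len(config@restarts)) {
        set.seed(.deriveSeed(config@seed, rs))
        start <- if (rs == 1L)
            list(parents = rep(list(integer()), p),
                 children = rep(list(integer()), p))
        else .randomStartDAG(p, candIdx, config@maxParents)
        res <- .localSearch(ld$X, ld$cards, candIdx, config@maxParents,
                            config@ess, cache, start, scanOrder)
        if (is.null(best) || res$total > best$total + 1e-9) best <- res
    }
    .buildNetwork(ld, best$parents, config@ess, cache)
}

# Assemble the S4 network object from an index-based parent list.
.buildNetwork <- function(ld, parentsIdx, ess, cache = .scoreCache()) {
    vars <- ld$vars
    parents <- stats::setNames(
        lapply(seq_along(vars), function(v) vars[parentsIdx[[v]]]), vars)
    famScores <- vapply(seq_along(vars), function(v)
        .cachedFamilyScore(cache, ld$X, ld$cards, v, parentsIdx[[v]], ess), 0)
    names(famScores) <- vars
    cpts <- stats::setNames(lapply(seq_along(vars), function(v)
        .estimateCPT(ld$X, ld$cards, v, parentsIdx[[v]], ess)), vars)
    es <- data.frame(from = character(), to = character(),
                     strength = numeric())
    for (v in seq_along(vars)) {
        for (u in parentsIdx[[v]]) {
            s <- famScores[[v]] -
                .cachedFamilyScore(cache, ld$X, ld$cards, v,
                                   setdiff(parentsIdx[[v]], u), ess)
            es <- rbind(es, data.frame(from = vars[u], to = vars[v],
                                       strength = s))
        }
    }
    nl <- stats::setNames(as.integer(ld$cards), vars)
    net <- new("BayesianNetwork", nodes = vars, nLevels = nl,
               parents = parents, cpts = cpts, familyScores = famScores,
               edgeStrengths = es, ess = ess)
    validObject(net)
    net
}

# Posterior-mean CPT under the scoring prior: (N_jk + a_jk) / (N_j + a_j).
.estimateCPT <- function(X, cards, child, parIdx, ess) {
    r <- cards[[child]]
    pc <- .parentConfigIndex(X, parIdx, cards)
    q <- pc$q
    Njk <- tabulate((pc$idx - 1L) * r + X[, child], nbins = q * r)
    dim(Njk) <- c(r, q)
    theta <- sweep(Njk + ess / (q * r), 2L, colSums(Njk) + ess / q, "/")
    rownames(theta) <- as.character(seq_len(r) - 1L)
    theta
}

#' Learn a Bayesian network from cell-level data
#'
#' The composed pipeline step: equal-frequency discretization of the
#' markers, optional inclusion of already-categorical per-cell covariates
#' (clinical response, contrast indicators), sparse candidate selection,
#' and random-restart hill climbing under the BDeu score.
#'
#' @param x a \linkS4class{FlowCellSet} (markers get discretized with
#'   \code{kBins}) or a \linkS4class{DiscretizedCells} (used as-is).
#' @param kBins bins for marker discretization (FlowCellSet method only).
#' @param config a \linkS4class{SearchConfig}. \code{kCandidates} is
#'   clamped to the number of variables minus one.
#' @param extraVars names of \code{cellData} columns to include as
#'   categorical network variables (FlowCellSet method only).
#' @param forced variables forced into every candidate pool (contrast
#'   indicators); see [sparseCandidates()].
#' @param ... unused.
#' @return A \linkS4class{BayesianNetwork}.
#' @rdname learnNetwork
#' @export
setMethod("learnNetwork", "FlowCellSet",
    function(x, kBins = 3L, config = SearchConfig(),
             extraVars = character(), forced = character(), ...) {
        disc <- discretizeCells(x, kBins)
        for (v in extraVars) {
            if (!v %in% colnames(colData(x)))
                stop("extra variable '", v, "' not found in cellData")
            disc <- appendDiscreteVar(disc, v, colData(x)[[v]])
        }
        learnNetwork(disc, config = config, forced = forced)
    })

#' @rdname learnNetwork
#' @export
setMethod("learnNetwork", "DiscretizedCells",
    function(x, config = SearchConfig(), forced = character(), ...) {
        k <- min(config@kCandidates, nrow(x) - 1L)
        cand <- sparseCandidates(x, k, forced = forced)
        hillClimb(x, cand, config)
    })

#' Marginal-likelihood edge strength
#'
#' The strength of a directed edge is the log marginal-likelihood ratio
#' between the network with and without the edge:
#' \code{familyScore(child, parents) - familyScore(child, parents \\ from)}.
#' It is strictly local to the child's family, so deleting unrelated edges
#' leaves it unchanged. Strengths are comparable within a single network
#' only.
#'
#' @param net a \linkS4class{BayesianNetwork}.
#' @param data the \linkS4class{DiscretizedCells} the network was learned
#'   from.
#' @param from,to the edge (must be present in \code{net}).
#' @return numeric log-ratio.
#' @export
edgeStrength <- function(net, data, from, to) {
    pa <- net@parents[[to]]
    if (is.null(pa) || !from %in% pa)
        stop("edge ", from, " -> ", to, " not present in the network")
    familyScore(data, to, pa, net@ess) -
        familyScore(data, to, setdiff(pa, from), net@ess)
}

#' Accessors for BayesianNetwork
#'
#' \code{bnNodes} returns the node names; \code{bnParents} /
#' \code{bnChildren} the parents / children of one node; \code{arcs} the
#' directed edge list with strengths; \code{networkScore} the total BDeu
#' log marginal likelihood (sum of family scores); \code{edgeStrengths}
#' the per-edge log marginal-likelihood ratios; \code{cpt} one node's
#' conditional probability table (states x parent configurations).
#'
#' @param x a \linkS4class{BayesianNetwork}.
#' @param node a node name.
#' @name BayesianNetwork-accessors
#' @aliases bnNodes bnParents bnChildren arcs networkScore edgeStrengths cpt
NULL

#' @rdname BayesianNetwork-accessors
#' @export
setMethod("bnNodes", "BayesianNetwork", function(x) x@nodes)

#' @rdname BayesianNetwork-accessors
#' @export
setMethod("bnParents", "BayesianNetwork", function(x, node) {
    if (!node %in% x@nodes) stop("unknown node: ", node)
    x@parents[[node]]
})

#' @rdname BayesianNetwork-accessors
#' @export
setMethod("bnChildren", "BayesianNetwork", function(x, node) {
    if (!node %in% x@nodes) stop("unknown node: ", node)
    x@nodes[vapply(x@nodes, function(v) node %in% x@parents[[v]], TRUE)]
})

#' @rdname BayesianNetwork-accessors
#' @export
setMethod("arcs", "BayesianNetwork", function(x) x@edgeStrengths)

#' @rdname BayesianNetwork-accessors
#' @export
setMethod("networkScore", "BayesianNetwork",
          function(x) sum(x@familyScores))

#' @rdname BayesianNetwork-accessors
#' @export
setMethod("edgeStrengths", "BayesianNetwork", function(x) x@edgeStrengths)

#' @rdname BayesianNetwork-accessors
#' @export
setMethod("cpt", "BayesianNetwork", function(x, node) {
    if (!node %in% x@nodes) stop("unknown node: ", node)
    x@cpts[[node]]
})

setMethod("show", "BayesianNetwork", function(object) {
    cat("BayesianNetwork:", length(object@nodes), "nodes,",
        nrow(object@edgeStrengths), "edges, score",
        format(sum(object@familyScores), digits = 8), "\n")
    if (nrow(object@edgeStrengths)) {
        es <- object@edgeStrengths
        es <- es[order(-es$strength), , drop = FALSE]
        top <- utils::head(es, 5L)
        for (i in seq_len(nrow(top)))
            cat(sprintf("  %s -> %s  (%.3g)\n", top$from[i], top$to[i],
                        top$strength[i]))
        if (nrow(es) > 5L) cat("  ...\n")
    }
})
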