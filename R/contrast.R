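#' Define an indicator ("contrast") variable
#'
#' @param name variable name, e.g. "Contrast", "Response", "Day".
#' @param states ordered state labels (at least two).
#' @param assignment named character mapping subdataset ids to states.
#' @return A \linkS4class{ContrastSpec}.
#' @examples
#' contrastSpec("Contrast",
#'              c("day1_NR", "day1_R", "day21_NR", "day21_R"),
#'              c(d1nr = "day1_NR", d1r = "day1_R",
#'                d21nr = "day21_NR", d21r = "day21_R"))
#' @export
contrastSpec <- function(name, states, assignment) {
    new("ContrastSpec", name = name, states = states,
        assignment = assignment)
}

.checkAssignment <- function(spec, ids) {
    missing <- setdiff(ids, names(spec@assignment))
    if (length(missing))
        stop("no contrast state assigned to dataset(s): ",
             paste(missing, collapse = ", "))
}

#' Pool subdatasets with a contrast indicator
#'
#' Concatenates the datasets cell-wise and attaches one categorical
#' variable (named after the spec) holding each cell's regime state, so a
#' single "supergraph" network can be learned over the pooled data. All
#' datasets must share the same variables; a mismatch is reported with the
#' differing names. Splitting the pooled object back by state recovers
#' the original datasets' cells exactly.
#'
#' @param datasets named list of \linkS4class{FlowCellSet} or
#'   \linkS4class{DiscretizedCells} objects (all the same class); names
#'   are the subdataset ids the spec's assignment refers to.
#' @param spec a \linkS4class{ContrastSpec}.
#' @param ... unused.
#' @return Pooled object of the same class as the inputs. For
#'   FlowCellSets the contrast state is a \code{cellData} column; for
#'   DiscretizedCells it is an additional categorical variable.
#' @rdname poolWithContrast
#' @export
setMethod("poolWithContrast", "list", function(datasets, spec, ...) {
    if (!length(datasets)) stop("no datasets to pool")
    if (is.null(names(datasets)) || anyDuplicated(names(datasets)))
        stop("datasets must be uniquely named")
    .checkAssignment(spec, names(datasets))
    ref <- rownames(datasets[[1L]])
    for (id in names(datasets)) {
        vars <- rownames(datasets[[id]])
        if (!identical(sort(vars), sort(ref))) {
            d1 <- setdiff(ref, vars); d2 <- setdiff(vars, ref)
            stop("variable mismatch in dataset '", id, "': missing {",
                 paste(d1, collapse = ", "), "}, extra {",
                 paste(d2, collapse = ", "), "}")
        }
    }
    states <- factor(rep(spec@assignment[names(datasets)],
                         vapply(datasets, ncol, 0L)),
                     levels = spec@states)
    if (is(datasets[[1L]], "FlowCellSet")) {
        vals <- do.call(cbind, lapply(datasets, function(d)
            assay(d, "intensities")[ref, , drop = FALSE]))
        cd <- do.call(rbind, lapply(datasets, function(d)
            as.data.frame(colData(d))[.REQUIRED_ANNOTATIONS]))
        cd[[spec@name]] <- states
        out <- FlowCellSet(t(vals), ref, cd,
                           timepoints = metadata(datasets[[1L]])$timepoints)
        return(out)
    }
    if (is(datasets[[1L]], "DiscretizedCells")) {
        labs <- do.call(cbind, lapply(datasets, function(d)
            assay(d, "labels")[ref, , drop = FALSE]))
        pooled <- DiscretizedCells(labs, datasets[[1L]]@nLevels,
                                   binEdges = datasets[[1L]]@binEdges,
                                   levelNames = datasets[[1L]]@levelNames)
        return(appendDiscreteVar(pooled, spec@name, states))
    }
    stop("datasets must be FlowCellSet or DiscretizedCells objects")
})

#' Learn a pooled "supergraph" network
#'
#' Learns a network over the pooled data with the contrast indicator(s)
#' included as ordinary categorical nodes -- except that they are forced
#' into every node's candidate pool, because detecting contrast linkage is
#' the point of the analysis and the MI-based candidate pruning could mask
#' weak but real linkage. Any regime-specific difference in the joint
#' distribution of two variables (an edge present in one regime only, or a
#' pure location shift of one marker) pulls the contrast node into the
#' Markov blanket of the affected variables.
#'
#' Markers are discretized on the pooled sample with \code{kBins = 8} by
#' default: the stratified/contrast analyses favor specificity (lower edge
#' density) over sensitivity.
#'
#' @param x pooled \linkS4class{FlowCellSet} (contrast states in
#'   \code{cellData}) or \linkS4class{DiscretizedCells} (contrast already
#'   a categorical variable).
#' @param contrastVars name(s) of the contrast variable(s); one for a
#'   single indicator, two for a Response x Day design.
#' @param kBins marker discretization (FlowCellSet method only).
#' @param config a \linkS4class{SearchConfig}.
#' @param ... unused.
#' @return A \linkS4class{BayesianNetwork}.
#' @rdname buildSupergraph
#' @export
setMethod("buildSupergraph", "FlowCellSet",
    function(x, contrastVars, kBins = 8L, config = SearchConfig(), ...) {
        missing <- setdiff(contrastVars, colnames(colData(x)))
        if (length(missing))
            stop("contrast variable(s) not in cellData: ",
                 paste(missing, collapse = ", "))
        learnNetwork(x, kBins = kBins, config = config,
                     extraVars = contrastVars, forced = contrastVars)
    })

#' @rdname buildSupergraph
#' @export
setMethod("buildSupergraph", "DiscretizedCells",
    function(x, contrastVars, config = SearchConfig(), ...) {
        missing <- setdiff(contrastVars, rownames(x))
        if (length(missing))
            stop("contrast variable(s) not in data: ",
                 paste(missing, collapse = ", "))
        learnNetwork(x, config = config, forced = contrastVars)
    })

#' Report the contrast node's Markov neighborhood(s)
#'
#' For each contrast node, extracts its Markov neighborhood with
#' strengths and the strong/weak partition: the members are the markers
#' whose behavior differentiates the pooled regime states. An isolated
#' contrast node yields an empty neighborhood flagged as showing no
#' differentiating markers.
#'
#' @param net a supergraph \linkS4class{BayesianNetwork}.
#' @param contrastNodes contrast node name(s).
#' @param relThreshold strong/weak cut, see [classifyEdges()].
#' @return named list, one entry per contrast node:
#'   \code{list(neighborhood = MarkovNeighborhood, differentiating =
#'   logical)}.
#' @export
contrastReport <- function(net, contrastNodes, relThreshold = 0.3) {
    missing <- setdiff(contrastNodes, net@nodes)
    if (length(missing))
        stop("contrast node(s) not in network: ",
             paste(missing, collapse = ", "))
    out <- lapply(contrastNodes, function(v) {
        mn <- markovNeighborhood(net, v, relThreshold)
        list(neighborhood = mn,
             differentiating = length(mn@members) > 0L)
    })
    names(out) <- contrastNodes
    out
}

#' Condition a pooled dataset on a contrast state
#'
#' Filters the pooled cells to one regime state, drops the contrast
#' variable, and relearns the stratified network -- the operational form
#' of conditioning the supergraph on the contrast: a regime's network is
#' the supergraph conditioned on its contrast state. The returned network
#' is learned from exactly the rows the datasets assigned to that state
#' contributed.
#'
#' @param x pooled \linkS4class{FlowCellSet} or
#'   \linkS4class{DiscretizedCells} from [poolWithContrast()].
#' @param spec the \linkS4class{ContrastSpec} used for pooling.
#' @param state one of \code{spec@states}.
#' @param kBins marker discretization (FlowCellSet method only; default 8
#'   as in the stratified analyses).
#' @param config a \linkS4class{SearchConfig}.
#' @param ... unused.
#' @return A \linkS4class{BayesianNetwork} for the stratum.
#' @rdname conditionOnContrast
#' @export
setMethod("conditionOnContrast", "FlowCellSet",
    function(x, spec, state, kBins = 8L, config = SearchConfig(), ...) {
        if (!state %in% spec@states) stop("unknown state: ", state)
        sel <- colData(x)[[spec@name]] == state
        if (!any(sel)) stop("no cells in stratum '", state, "'")
        sub <- x[, sel]
        cd <- as.data.frame(colData(sub))
        cd[[spec@name]] <- NULL
        sub2 <- FlowCellSet(intensities(sub), rownames(sub), cd,
                            timepoints = metadata(x)$timepoints)
        learnNetwork(sub2, kBins = kBins, config = config)
    })

#' @rdname conditionOnContrast
#' @export
setMethod("conditionOnContrast", "DiscretizedCells",
    function(x, spec, state, config = SearchConfig(), ...) {
        if (!state %in% spec@states) stop("unknown state: ", state)
        lv <- x@levelNames[[spec@name]]
        if (is.null(lv)) stop("contrast variable '", spec@name,
                              "' not found in data")
        sel <- assay(x, "labels")[spec@name, ] == match(state, lv) - 1L
        if (!any(sel)) stop("no cells in stratum '", state, "'")
        keepVars <- setdiff(rownames(x), spec@name)
        sub <- DiscretizedCells(
            assay(x, "labels")[keepVars, sel, drop = FALSE],
            x@nLevels[keepVars],
            cellData = colData(x)[sel, , drop = FALSE],
            binEdges = x@binEdges[intersect(names(x@binEdges), keepVars)],
            levelNames = x@levelNames[intersect(names(x@levelNames),
                                                keepVars)])
        learnNetwork(sub, config = config)
    })

#' Skeleton difference between two networks
#'
#' Compares two networks over the same node set at the skeleton level
#' (edge presence ignoring direction): edges only in \code{a}, only in
#' \code{b}, and shared edges with both strengths and a flag for direction
#' flips between the two DAGs (Markov-equivalent structures can legally
#' disagree on direction).
#'
#' @param a,b \linkS4class{BayesianNetwork} objects over identical nodes.
#' @return list with data.frames \code{onlyA}, \code{onlyB},
#'   \code{shared} (columns from, to of a's orientation, strengthA,
#'   strengthB, directionFlip).
#' @export
diffNetworks <- function(a, b) {
    if (!setequal(a@nodes, b@nodes))
        stop("networks must share the same node set")
    skel <- function(net) {
        es <- net@edgeStrengths
        if (!nrow(es))
            return(data.frame(n1 = character(), n2 = character(),
                              from = character(), to = character(),
                              strength = numeric()))
        data.frame(n1 = pmin(es$from, es$to), n2 = pmax(es$from, es$to),
                   from = es$from, to = es$to, strength = es$strength)
    }
    sa <- skel(a); sb <- skel(b)
    ka <- paste(sa$n1, sa$n2); kb <- paste(sb$n1, sb$n2)
    onlyA <- sa[!ka %in% kb, c("from", "to", "strength"), drop = FALSE]
    onlyB <- sb[!kb %in% ka, c("from", "to", "strength"), drop = FALSE]
    sharedKeys <- intersect(ka, kb)
    ia <- match(sharedKeys, ka); ib <- match(sharedKeys, kb)
    shared <- data.frame(
        from = sa$from[ia], to = sa$to[ia],
        strengthA = sa$strength[ia], strengthB = sb$strength[ib],
        directionFlip = sa$from[ia] != sb$from[ib])
    rownames(onlyA) <- rownames(onlyB) <- rownames(shared) <- NULL
    list(onlyA = onlyA, onlyB = onlyB, shared = shared)
}
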