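# Ground-truth network generation, forward sampling, and cohort simulation.

#' Random ground-truth discrete network
#'
#' Builds a random DAG with concentrated, monotone CPTs suitable as a
#' ground truth for structure-recovery experiments: nodes are ordered
#' topologically, each node draws up to \code{maxParents} parents from its
#' predecessors, and every parent configuration puts probability
#' \code{contrast} on a dominant child state that increases with the mean
#' normalized parent state (so every edge induces marginal as well as
#' conditional dependence and the structure is identifiable). Root
#' distributions are mildly non-uniform.
#'
#' @param nNodes number of nodes.
#' @param nLevels states per node (scalar or vector).
#' @param maxParents cap on ground-truth in-degree.
#' @param edgeProb probability a candidate predecessor becomes a parent.
#' @param contrast CPT mass on the dominant state, in (1/nLevels, 1).
#' @param seed RNG seed.
#' @param nodeNames optional node names (default V1..Vn).
#' @return A \linkS4class{BayesianNetwork} with full CPTs.
#' @export
randomDiscreteNetwork <- function(nNodes, nLevels = 3L, maxParents = 2L,
                                  edgeProb = 0.4, contrast = 0.8,
                                  seed = 1L, nodeNames = NULL) {
    set.seed(seed)
    if (is.null(nodeNames))
        nodeNames <- sprintf("V%d", seq_len(nNodes))
    cards <- rep_len(as.integer(nLevels), nNodes)
    names(cards) <- nodeNames
    parents <- stats::setNames(rep(list(character()), nNodes), nodeNames)
    for (v in seq_len(nNodes)[-1L]) {
        pool <- seq_len(v - 1L)
        picks <- pool[stats::runif(length(pool)) < edgeProb]
        if (length(picks) > maxParents)
            picks <- sort(sample(picks, maxParents))
        parents[[v]] <- nodeNames[picks]
    }
    cpts <- vector("list", nNodes)
    names(cpts) <- nodeNames
    for (v in nodeNames) {
        r <- cards[[v]]
        paCards <- cards[parents[[v]]]
        q <- prod(paCards)
        theta <- matrix(0, r, q)
        if (!length(paCards)) {
            w <- stats::rgamma(r, shape = 4)
            theta[, 1L] <- w / sum(w)
        } else {
            for (j in seq_len(q)) {
                s <- .decodeConfig(j, paCards)
                norm <- mean((s - 1) / pmax(paCards - 1, 1))
                dom <- 1L + round(norm * (r - 1))
                theta[, j] <- (1 - contrast) / (r - 1)
                theta[dom, j] <- contrast
            }
        }
        rownames(theta) <- as.character(seq_len(r) - 1L)
        cpts[[v]] <- theta
    }
    .networkFromCPTs(nodeNames, cards, parents, cpts)
}

.networkFromCPTs <- function(nodes, cards, parents, cpts) {
    fam <- stats::setNames(rep(NA_real_, length(nodes)), nodes)
    es <- data.frame(from = character(), to = character(),
                     strength = numeric())
    for (v in nodes) for (u in parents[[v]])
        es <- rbind(es, data.frame(from = u, to = v,
                                   strength = NA_real_))
    new("BayesianNetwork", nodes = nodes,
        nLevels = stats::setNames(as.integer(cards), nodes),
        parents = parents, cpts = cpts, familyScores = fam,
        edgeStrengths = es, ess = 1)
}

#' Ancestral sampling from a Bayesian network
#'
#' Draws \code{n} joint samples by topological-order (ancestral)
#' sampling from the network's CPTs. Deterministic given \code{seed};
#' with \code{seed = NULL} the current RNG stream is used.
#'
#' @param net a \linkS4class{BayesianNetwork} with full CPTs.
#' @param n sample count.
#' @param seed RNG seed or NULL.
#' @return A \linkS4class{DiscretizedCells} with 0-based labels.
#' @export
sampleBN <- function(net, n, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    nodes <- net@nodes
    miss <- nodes[vapply(nodes, function(v) is.null(net@cpts[[v]]), TRUE)]
    if (length(miss))
        stop("missing CPT for node(s): ", paste(miss, collapse = ", "))
    cards <- net@nLevels
    S <- matrix(0L, nrow = n, ncol = length(nodes),
                dimnames = list(NULL, nodes))
    for (v in .topoOrder(net@parents, nodes)) {
        r <- cards[[v]]
        pa <- net@parents[[v]]
        theta <- net@cpts[[v]]
        cfg <- if (length(pa))
            .parentConfigIndex(S[, pa, drop = FALSE], seq_along(pa),
                               cards[pa])$idx
        else rep.int(1L, n)
        cum <- apply(theta, 2L, cumsum)      # r x q
        u <- stats::runif(n)
        st <- rep.int(1L, n)
        if (r > 1L) for (k in seq_len(r - 1L))
            st <- st + (u > cum[k, cfg])
        S[, v] <- st
    }
    DiscretizedCells(t(S) - 1L, cards)
}

#' Remove an edge with exact CPT marginalization
#'
#' Returns the network with edge \code{from -> to} removed and the
#' child's CPT replaced by the conditional distribution of the child
#' given its remaining parents under the original network -- computed by
#' exact enumeration of the joint when the state space permits, otherwise
#' from a large forward sample. Removing an edge whose CPT does not
#' actually depend on the dropped parent leaves the child's distribution
#' unchanged.
#'
#' @param net a \linkS4class{BayesianNetwork}.
#' @param from,to the edge to remove.
#' @param nsim forward-sample size for the fallback estimate.
#' @param seed seed for the fallback estimate.
#' @return A \linkS4class{BayesianNetwork}.
#' @export
removeEdge <- function(net, from, to, nsim = 2e5, seed = 707L) {
    if (!from %in% net@parents[[to]])
        stop("edge ", from, " -> ", to, " not present")
    keep <- setdiff(net@parents[[to]], from)
    cards <- net@nLevels
    r <- cards[[to]]
    q <- prod(cards[keep])
    total <- prod(as.numeric(cards))
    if (total <= 3e5) {
        joint <- .exactJoint(net)            # states matrix + prob vector
        cfg <- .parentConfigIndex(joint$S, match(keep, colnames(joint$S)),
                                  cards[colnames(joint$S)])$idx
        cell <- (cfg - 1L) * r + joint$S[, to]
        w <- vapply(seq_len(q * r), function(i)
            sum(joint$p[cell == i]), 0)
        dim(w) <- c(r, q)
        colTot <- colSums(w)
        theta <- matrix(1 / r, r, q)
        ok <- colTot > 0
        theta[, ok] <- sweep(w[, ok, drop = FALSE], 2L, colTot[ok], "/")
    } else {
        sm <- sampleBN(net, nsim, seed = seed)
        X <- t(assay(sm, "labels")) + 1L
        cfg <- .parentConfigIndex(X, match(keep, colnames(X)),
                                  cards[colnames(X)])$idx
        w <- tabulate((cfg - 1L) * r + X[, to], nbins = q * r) + 0.5
        dim(w) <- c(r, q)
        theta <- sweep(w, 2L, colSums(w), "/")
    }
    rownames(theta) <- as.character(seq_len(r) - 1L)
    parents <- net@parents
    parents[[to]] <- keep
    cpts <- net@cpts
    cpts[[to]] <- theta
    .networkFromCPTs(net@nodes, cards, parents, cpts)
}

# Exact joint over all configurations (small nets only).
.exactJoint <- function(net) {
    cards <- net@nLevels[net@nodes]
    grid <- as.matrix(expand.grid(lapply(cards, seq_len),
                                  KEEP.OUT.ATTRS = FALSE))
    storage.mode(grid) <- "integer"
    colnames(grid) <- net@nodes
    p <- rep(1, nrow(grid))
    for (v in net@nodes) {
        pa <- net@parents[[v]]
        cfg <- if (length(pa))
            .parentConfigIndex(grid, match(pa, net@nodes),
                               cards[net@nodes])$idx
        else rep.int(1L, nrow(grid))
        p <- p * net@cpts[[v]][cbind(grid[, v], cfg)]
    }
    list(S = grid, p = p)
}

#' Two-regime scenario differing by one edge
#'
#' Builds the canonical test bed for contrast-variable detection: regime 0
#' is sampled from the base network; regime 1 from the base network with
#' one edge removed (the child's CPT marginalized exactly, see
#' [removeEdge()]). The two samples differ only through that edge's
#' dependence.
#'
#' @param base a \linkS4class{BayesianNetwork}.
#' @param changedEdge character c(from, to), an edge of \code{base}.
#' @param nPerRegime cells per regime.
#' @param seed RNG seed.
#' @return list(regime0, regime1, base, altered, changedEdge); the
#'   regimes are \linkS4class{DiscretizedCells}.
#' @export
makeContrastScenario <- function(base, changedEdge, nPerRegime,
                                 seed = 1L) {
    from <- changedEdge[[1L]]; to <- changedEdge[[2L]]
    altered <- removeEdge(base, from, to)
    r0 <- sampleBN(base, nPerRegime, seed = .deriveSeed(seed, 1L))
    r1 <- sampleBN(altered, nPerRegime, seed = .deriveSeed(seed, 2L))
    list(regime0 = r0, regime1 = r1, base = base, altered = altered,
         changedEdge = c(from = from, to = to))
}

#' Default synthetic cohort specification
#'
#' A cohort emulating a small immunotherapy study: 13 patients (4
#' responders, 9 nonresponders), a 14-marker panel, 1000 cells per patient
#' and timepoint, sampled at days 1 and 21. Latent per-cell marker states
#' follow a random ground-truth network (3 levels, concentrated CPTs);
#' continuous intensities are log-normal around state-dependent log-means
#' (heavy right tails, strictly positive -- the shape of compensated
#' cytometry intensities). Regime effects: responders carry a +2 sd
#' location shift of marker M01 at both days, and the responders'
#' post-treatment regime (day 21) loses one ground-truth edge.
#'
#' @param seed seed for the ground-truth network draw.
#' @return A \linkS4class{CohortSpec}.
#' @export
defaultCohortSpec <- function(seed = 20210226L) {
    markers <- sprintf("M%02d", 1:14)
    net <- randomDiscreteNetwork(14L, nLevels = 3L, maxParents = 2L,
                                 edgeProb = 0.25, contrast = 0.8,
                                 seed = seed, nodeNames = markers)
    es <- net@edgeStrengths
    dropEdge <- es[nrow(es), ]   # an arbitrary but fixed ground-truth edge
    new("CohortSpec",
        nPatients = 13L, nResponders = 4L, cellsPerPatient = 1000L,
        days = c(1L, 21L), markers = markers, network = net,
        baseLocation = stats::setNames(rep(log(300), 14), markers),
        baseScale = stats::setNames(rep(0.6, 14), markers),
        levelSpacing = 1,
        shiftEffects = data.frame(marker = "M01",
                                  regime = c("day1_R", "day21_R"),
                                  shift = 2),
        edgeEffects = data.frame(from = dropEdge$from, to = dropEdge$to,
                                 regime = "day21_R"))
}

.regimeName <- function(day, responder) {
    paste0("day", day, "_", if (responder) "R" else "NR")
}

#' Simulate a FACS-like cohort
#'
#' Generates annotated cell-level intensity data from a
#' \linkS4class{CohortSpec}: per patient and day, latent discrete marker
#' states are ancestrally sampled from the regime's ground-truth network
#' (the base network with that regime's edge removals applied), then
#' mapped to continuous intensities as
#' \code{exp(location + state * spacing * scale + shift * scale + scale * N(0,1))}.
#' Responders receive the spec's location shifts and edge differences.
#' Patient tumor-size changes are drawn consistently with the response
#' label (responders below -25, nonresponders above).
#'
#' @param spec a \linkS4class{CohortSpec}.
#' @param seed RNG seed; the full cohort is deterministic given the seed.
#' @return list(cells = \linkS4class{FlowCellSet},
#'   truth = list(spec, regimeNetworks, latentStates)).
#' @export
simulateCohort <- function(spec, seed = 1L) {
    validObject(spec)
    regimes <- unlist(lapply(spec@days, function(d)
        c(.regimeName(d, FALSE), .regimeName(d, TRUE))))
    # regime networks are deterministic; build them before seeding so any
    # sampling-based marginalization inside removeEdge cannot pin the stream
    regimeNets <- stats::setNames(lapply(regimes, function(rg) {
        net <- spec@network
        ee <- spec@edgeEffects
        if (nrow(ee)) for (i in which(ee$regime == rg))
            net <- removeEdge(net, ee$from[i], ee$to[i])
        net
    }), regimes)
    set.seed(seed)
    responder <- seq_len(spec@nPatients) <= spec@nResponders
    tsize <- ifelse(responder, stats::runif(spec@nPatients, -60, -30),
                    stats::runif(spec@nPatients, -15, 25))
    blocks <- list(); annBlocks <- list(); latent <- list()
    for (p in seq_len(spec@nPatients)) {
        pid <- sprintf("P%02d", p)
        for (d in spec@days) {
            rg <- .regimeName(d, responder[p])
            nc <- if (length(spec@cellsPerPatient) == 2L)
                sample(spec@cellsPerPatient[1L]:spec@cellsPerPatient[2L], 1L)
            else spec@cellsPerPatient
            states <- assay(sampleBN(regimeNets[[rg]], nc), "labels")
            vals <- matrix(0, nrow = length(spec@markers), ncol = nc,
                           dimnames = list(spec@markers, NULL))
            for (m in spec@markers) {
                sh <- spec@shiftEffects
                shift <- if (nrow(sh))
                    sum(sh$shift[sh$marker == m & sh$regime == rg])
                else 0
                mu <- spec@baseLocation[[m]] +
                    (states[m, ] * spec@levelSpacing + shift) *
                    spec@baseScale[[m]]
                vals[m, ] <- exp(stats::rnorm(nc, mu, spec@baseScale[[m]]))
            }
            blocks[[length(blocks) + 1L]] <- vals
            latent[[length(latent) + 1L]] <- states
            annBlocks[[length(annBlocks) + 1L]] <- data.frame(
                patient_id = rep(pid, nc), day = rep(d, nc),
                tsize = rep(tsize[p], nc))
        }
    }
    values <- t(do.call(cbind, blocks))
    ann <- do.call(rbind, annBlocks)
    cells <- FlowCellSet(values, spec@markers, ann,
                         timepoints = spec@days)
    list(cells = cells,
         truth = list(spec = spec, regimeNetworks = regimeNets,
                      latentStates = latent))
}
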