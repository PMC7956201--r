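#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData colData<-
NULL

#' Cell-level flow cytometry intensities with per-cell annotations
#'
#' A \code{FlowCellSet} holds compensated fluorescence intensities for one
#' FACS panel: one column per cell (event), one row per marker, stored as a
#' \linkS4class{SummarizedExperiment} with a single \code{"intensities"}
#' assay. Per-cell annotations live in \code{colData}: \code{patient_id},
#' \code{day} (study timepoint), \code{response} (factor,
#' \code{"nonresponder"}/\code{"responder"}) and \code{tsize} (percent tumor
#' radius change; responders are cells from patients with
#' \code{tsize < -25}).
#'
#' Intensities are taken as exported from the acquisition software: already
#' compensated, untransformed, and possibly negative after compensation.
#'
#' @slot .Data inherits all SummarizedExperiment slots.
#' @seealso [FlowCellSet()], [readFCS()], [readCellTable()]
#' @export
setClass("FlowCellSet", contains = "SummarizedExperiment")

.REQUIRED_ANNOTATIONS <- c("patient_id", "day", "response", "tsize")

setValidity("FlowCellSet", function(object) {
    msg <- character()
    if (!"intensities" %in% names(assays(object)))
        msg <- c(msg, "assay 'intensities' is missing")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "marker names must be unique")
    missing <- setdiff(.REQUIRED_ANNOTATIONS, colnames(colData(object)))
    if (length(missing))
        msg <- c(msg, paste0("missing cell annotations: ",
                             paste(missing, collapse = ", ")))
    tp <- metadata(object)$timepoints
    if (!is.null(tp) && "day" %in% colnames(colData(object))) {
        day <- colData(object)$day
        bad <- !is.na(day) & !(day %in% tp)
        if (any(bad))
            msg <- c(msg, paste0("annotated days outside declared timepoints (",
                                 paste(tp, collapse = ", "), ")"))
    }
    if (length(msg)) msg else TRUE
})

#' Discretized cell-level data
#'
#' Integer bin labels for every variable (marker or categorical covariate)
#' and every cell, stored as a \linkS4class{SummarizedExperiment} with a
#' single \code{"labels"} assay (variables x cells). Labels run from 0
#' (\dQuote{low}) to \code{k - 1} (\dQuote{high}). For markers discretized
#' by [discretizeCells()], \code{binEdges} records the interior cut points
#' used; categorical variables (response labels, contrast indicators) carry
#' an empty edge vector and a \code{levelNames} entry instead.
#'
#' @slot binEdges named list, per variable: numeric vector of interior bin
#'   edges (empty for categorical variables).
#' @slot nLevels named integer, per variable: number of states.
#' @slot levelNames named list, per variable: state labels (categorical
#'   variables only).
#' @export
setClass("DiscretizedCells",
    contains = "SummarizedExperiment",
    representation(binEdges = "list", nLevels = "integer",
                   levelNames = "list"))

setValidity("DiscretizedCells", function(object) {
    msg <- character()
    if (!"labels" %in% names(assays(object)))
        msg <- c(msg, "assay 'labels' is missing")
    vars <- rownames(object)
    if (anyDuplicated(vars))
        msg <- c(msg, "variable names must be unique")
    if (!all(vars %in% names(object@nLevels)))
        msg <- c(msg, "every variable needs an nLevels entry")
    if (any(object@nLevels[vars] < 2L))
        msg <- c(msg, "every variable needs at least 2 levels")
    lab <- assay(object, "labels")
    if (ncol(lab)) {
        mx <- apply(lab, 1L, max)
        mn <- apply(lab, 1L, min)
        if (any(mn < 0L) || any(mx > object@nLevels[vars] - 1L))
            msg <- c(msg, "labels must lie in [0, nLevels - 1]")
    }
    if (length(msg)) msg else TRUE
})

#' Discrete Bayesian network
#'
#' A directed acyclic graph over discrete variables together with the
#' quantities the structure search produces: per-node parent sets,
#' conditional probability tables (posterior-mean estimates under the same
#' BDeu Dirichlet prior used for scoring), per-family BDeu log marginal
#' likelihoods, and per-edge strengths. An edge strength is the log
#' marginal-likelihood ratio between the network with and without that edge
#' (strictly local to the child's family); strengths are comparable within
#' one network but not across networks.
#'
#' @slot nodes character, variable names.
#' @slot nLevels named integer, state counts per node.
#' @slot parents named list of character vectors (ordered parent sets).
#' @slot cpts named list; for node \code{v} a \code{r x q} matrix of
#'   P(v = state | parent configuration), parent configurations indexed with
#'   the first listed parent varying fastest.
#' @slot familyScores named numeric, BDeu log marginal likelihood per family.
#' @slot edgeStrengths data.frame with columns \code{from}, \code{to},
#'   \code{strength}.
#' @slot ess numeric, equivalent sample size of the BDeu prior.
#' @export
setClass("BayesianNetwork",
    representation(nodes = "character", nLevels = "integer",
                   parents = "list", cpts = "list",
                   familyScores = "numeric", edgeStrengths = "data.frame",
                   ess = "numeric"))

setValidity("BayesianNetwork", function(object) {
    msg <- character()
    p <- length(object@nodes)
    if (anyDuplicated(object@nodes))
        msg <- c(msg, "node names must be unique")
    if (!setequal(names(object@parents), object@nodes))
        msg <- c(msg, "parents must be keyed by node name")
    for (v in object@nodes) {
        pa <- object@parents[[v]]
        if (v %in% pa) msg <- c(msg, paste0("node ", v, " is its own parent"))
        if (!all(pa %in% object@nodes))
            msg <- c(msg, paste0("unknown parent of ", v))
    }
    if (.hasCycle(object@parents, object@nodes))
        msg <- c(msg, "graph contains a directed cycle")
    for (v in names(object@cpts)) {
        cs <- colSums(object@cpts[[v]])
        if (any(abs(cs - 1) > 1e-9))
            msg <- c(msg, paste0("CPT columns of ", v, " must sum to 1"))
    }
    if (length(msg)) msg else TRUE
})

#' Structure-search configuration
#'
#' Settings for the sparse-candidates + hill-climbing search:
#' \code{kCandidates} pairwise-MI candidate parents per node,
#' \code{restarts} random restarts, the RNG \code{seed}, the BDeu
#' equivalent sample size \code{ess}, and the per-node parent-set cap
#' \code{maxParents}.
#'
#' @export
setClass("SearchConfig",
    representation(kCandidates = "integer", restarts = "integer",
                   seed = "integer", ess = "numeric", maxParents = "integer"))

setValidity("SearchConfig", function(object) {
    msg <- character()
    if (object@kCandidates < object@maxParents)
        msg <- c(msg, "kCandidates must be >= maxParents")
    if (object@maxParents < 1L) msg <- c(msg, "maxParents must be >= 1")
    if (object@restarts < 1L) msg <- c(msg, "restarts must be >= 1")
    if (object@ess <= 0) msg <- c(msg, "ess must be > 0")
    if (length(msg)) msg else TRUE
})

#' Gating cutoffs for the four T-cell stratification markers
#'
#' High/low thresholds on compensated intensity for CD4, CD8, CCR7 and
#' CD45RA, defined per panel because panels are calibrated separately.
#' A value equal to the cutoff counts as "high".
#'
#' @export
setClass("PanelCutoffs",
    representation(panel = "character", thresholds = "numeric"))

.GATING_MARKERS <- c("CD4", "CD8", "CCR7", "CD45RA")

setValidity("PanelCutoffs", function(object) {
    if (!setequal(names(object@thresholds), .GATING_MARKERS))
        return("thresholds must be defined for exactly CD4, CD8, CCR7, CD45RA")
    TRUE
})

#' Major T-cell subset membership rule
#'
#' A named set of 4-bit patterns over (CD4, CD8, CCR7, CD45RA), bit = 1 iff
#' the marker is at or above its cutoff. The four built-in rules are
#' NaiveCD4 = \{1011\}, NaiveCD8 = \{0111\},
#' NonNaiveCD4 = \{1010, 1001, 1000\}, NonNaiveCD8 = \{0110, 0101, 0100\}.
#'
#' @export
setClass("CellTypeRule",
    representation(name = "character", patterns = "character"))

setValidity("CellTypeRule", function(object) {
    if (!all(grepl("^[01]{4}$", object@patterns)))
        return("patterns must be 4-bit strings over (CD4, CD8, CCR7, CD45RA)")
    TRUE
})

#' Markov neighborhood of a network node
#'
#' All nodes directly linked to the target (as parent or child), with the
#' corresponding edge strengths and a strong/weak partition (a member is
#' strong iff its strength is at least \code{relThreshold} times the
#' maximum strength within the neighborhood).
#'
#' @export
setClass("MarkovNeighborhood",
    representation(target = "character", members = "character",
                   strengths = "numeric", strong = "character",
                   weak = "character", relThreshold = "numeric"))

setValidity("MarkovNeighborhood", function(object) {
    msg <- character()
    if (!setequal(c(object@strong, object@weak), object@members))
        msg <- c(msg, "strong and weak must partition the members")
    if (length(intersect(object@strong, object@weak)))
        msg <- c(msg, "strong and weak must be disjoint")
    if (length(msg)) msg else TRUE
})

#' Marker-configuration table
#'
#' Observed joint configurations of discretized markers with their empirical
#' frequency and the conditional probability of clinical response
#' (responder-cell fraction) given the configuration. Frequencies over all
#' observed configurations sum to 1 and their frequency-weighted response
#' probabilities equal the overall responder-cell fraction.
#'
#' @slot markers character, ordered marker list.
#' @slot table data.frame: one column per marker (integer labels), then
#'   \code{frequency} and \code{p_response}.
#' @slot sortMode "none", "frequency_then_probability" or
#'   "probability_only".
#' @slot cutoff integer, number of rows retained by the last sort (NA if
#'   untruncated).
#' @slot nCells integer, cells the table was built from.
#' @slot responderFraction numeric, overall responder-cell fraction.
#' @export
setClass("ConfigTable",
    representation(markers = "character", table = "data.frame",
                   sortMode = "character", cutoff = "integer",
                   nCells = "integer", responderFraction = "numeric"))

setValidity("ConfigTable", function(object) {
    msg <- character()
    tab <- object@table
    need <- c(object@markers, "frequency", "p_response")
    if (!all(need %in% colnames(tab)))
        msg <- c(msg, "table must have one column per marker plus frequency and p_response")
    else {
        if (any(tab$p_response < -1e-12 | tab$p_response > 1 + 1e-12))
            msg <- c(msg, "p_response must lie in [0, 1]")
        if (identical(object@sortMode, "none") &&
            abs(sum(tab$frequency) - 1) > 1e-9)
            msg <- c(msg, "frequencies over all configurations must sum to 1")
    }
    if (length(msg)) msg else TRUE
})

#' Indicator ("contrast") variable specification
#'
#' Defines how pooled subdatasets map to the states of an indicator
#' variable: the variable's \code{name} (e.g. "Contrast", "Response",
#' "Day"), its ordered \code{states}, and an \code{assignment} from
#' subdataset id to state. Every pooled cell inherits exactly one state.
#'
#' @export
setClass("ContrastSpec",
    representation(name = "character", states = "character",
                   assignment = "character"))

setValidity("ContrastSpec", function(object) {
    msg <- character()
    if (length(object@states) < 2L)
        msg <- c(msg, "a contrast variable needs at least 2 states")
    if (!all(object@assignment %in% object@states))
        msg <- c(msg, "assignment values must be declared states")
    if (is.null(names(object@assignment)) || anyDuplicated(names(object@assignment)))
        msg <- c(msg, "assignment must be uniquely keyed by subdataset id")
    if (length(msg)) msg else TRUE
})

#' Synthetic cohort specification
#'
#' Describes a simulated immunotherapy cohort: patient counts, cells per
#' patient and day, the marker panel, a ground-truth discrete network over
#' latent per-cell marker states, the log-normal intensity model mapping
#' latent states to continuous intensities, and regime-specific effects
#' (single-marker location shifts, single-edge removals) distinguishing
#' responders/nonresponders before and after treatment.
#'
#' @slot nPatients,nResponders integer.
#' @slot cellsPerPatient integer scalar or length-2 range.
#' @slot days integer study timepoints.
#' @slot markers character panel.
#' @slot network \linkS4class{BayesianNetwork} over latent marker states.
#' @slot baseLocation,baseScale named numeric, log-scale mean and sd per
#'   marker.
#' @slot levelSpacing numeric, log-mean increment per latent level, in
#'   units of \code{baseScale}.
#' @slot shiftEffects data.frame(marker, regime, shift): location shift in
#'   units of \code{baseScale}, applied in the given regime.
#' @slot edgeEffects data.frame(from, to, regime): ground-truth edges
#'   absent in the given regime (child CPT re-derived by marginalization).
#' @export
setClass("CohortSpec",
    representation(nPatients = "integer", nResponders = "integer",
                   cellsPerPatient = "integer", days = "integer",
                   markers = "character", network = "BayesianNetwork",
                   baseLocation = "numeric", baseScale = "numeric",
                   levelSpacing = "numeric", shiftEffects = "data.frame",
                   edgeEffects = "data.frame"))

.REGIMES <- c("day1_NR", "day1_R", "day21_NR", "day21_R")

setValidity("CohortSpec", function(object) {
    msg <- character()
    if (object@nResponders > object@nPatients)
        msg <- c(msg, "nResponders must not exceed nPatients")
    if (!setequal(object@markers, object@network@nodes))
        msg <- c(msg, "ground-truth network must cover exactly the markers")
    if (nrow(object@shiftEffects) &&
        !all(object@shiftEffects$marker %in% object@markers))
        msg <- c(msg, "shift effect on unknown marker")
    if (nrow(object@shiftEffects) &&
        !all(object@shiftEffects$regime %in% .REGIMES))
        msg <- c(msg, "shift effect on unknown regime")
    if (nrow(object@edgeEffects)) {
        if (!all(object@edgeEffects$regime %in% .REGIMES))
            msg <- c(msg, "edge effect on unknown regime")
        for (i in seq_len(nrow(object@edgeEffects))) {
            fr <- object@edgeEffects$from[i]; to <- object@edgeEffects$to[i]
            if (!fr %in% object@network@parents[[to]])
                msg <- c(msg, paste0("edge effect on absent edge ", fr, "->", to))
        }
    }
    if (length(msg)) msg else TRUE
})
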