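#' Equal-frequency bin edges
#'
#' Computes the interior cut points for equal-frequency discretization of a
#' continuous marker into \code{k} bins, anchored at the empirical type-1
#' (inverse-ECDF) quantiles at i/k, i = 1..k-1. Bin i ends exactly at its
#' quantile, so each interior edge is the smallest data value strictly
#' above that quantile; every edge is therefore a data value and the rule
#' is tie-safe. Duplicate edges arising from heavy ties are collapsed,
#' which reduces the effective bin count; identical raw values never
#' straddle a bin boundary.
#'
#' The label rule is half-open: a value v maps to the largest bin b with
#' v >= edge_b (bin 0 if v is below the first edge), so labels are
#' monotone in v and 0 means "low", k-1 means "high".
#'
#' @param values numeric vector (nonempty).
#' @param k integer number of bins, 2..8.
#' @return numeric vector of strictly ascending interior edges (length at
#'   most k-1; shorter when ties collapse edges).
#' @examples
#' equalFrequencyEdges(1:9, 3)   # c(4, 7): bins 1-3, 4-6, 7-9
#' @export
equalFrequencyEdges <- function(values, k) {
    if (!length(values)) stop("values must be nonempty")
    if (anyNA(values)) stop("values must not contain NA")
    k <- as.integer(k)
    if (k < 2L || k > 8L) stop("k must lie in [2, 8]")
    if (length(unique(values)) == 1L)
        stop("constant marker, cannot discretize")
    xs <- sort(values)
    n <- length(xs)
    q <- xs[ceiling(n * seq_len(k - 1L) / k)]
    edges <- vapply(q, function(qi) {
        above <- xs[xs > qi]
        if (length(above)) above[1L] else NA_real_
    }, 0)
    unique(edges[!is.na(edges)])
}

#' Apply bin edges to values
#'
#' @param values numeric vector.
#' @param edges ascending interior edges from [equalFrequencyEdges()].
#' @return integer labels in 0..length(edges).
#' @export
applyBinEdges <- function(values, edges) {
    findInterval(values, edges)  # v >= edge_b -> bin b; below first edge -> 0
}

#' Full-sample equal-frequency discretization of a FlowCellSet
#'
#' Discretizes every marker independently into \code{k} equal-frequency
#' bins, with edges computed on the full pooled sample (all patients and
#' cells in the object) exactly as the downstream network analyses assume.
#' Annotations are carried over unchanged.
#'
#' @param x a \linkS4class{FlowCellSet}.
#' @param k integer number of bins, 2..8.
#' @param ... unused.
#' @return A \linkS4class{DiscretizedCells}; labels run 0 ("low") to
#'   k-1 ("high") per marker (fewer when ties collapse bins).
#' @rdname discretizeCells
#' @examples
#' fs <- FlowCellSet(cbind(A = 1:300, B = sample(300)),
#'                   cellData = data.frame(patient_id = "P1", day = 1,
#'                                         tsize = 0))
#' table(binLabels(discretizeCells(fs, 3))["A", ])
#' @export
setMethod("discretizeCells", "FlowCellSet", function(x, k = 3L, ...) {
    vals <- assay(x, "intensities")
    markers <- rownames(x)
    lab <- matrix(0L, nrow = nrow(vals), ncol = ncol(vals),
                  dimnames = dimnames(vals))
    edgeMap <- vector("list", length(markers))
    names(edgeMap) <- markers
    nLev <- integer(length(markers))
    names(nLev) <- markers
    for (m in markers) {
        edges <- tryCatch(equalFrequencyEdges(vals[m, ], k),
                          error = function(e)
                              stop("marker '", m, "': ", conditionMessage(e),
                                   call. = FALSE))
        lab[m, ] <- applyBinEdges(vals[m, ], edges)
        edgeMap[[m]] <- edges
        nLev[[m]] <- length(edges) + 1L
    }
    se <- SummarizedExperiment(assays = list(labels = lab),
                               colData = colData(x))
    out <- new("DiscretizedCells", se, binEdges = edgeMap, nLevels = nLev,
               levelNames = list())
    metadata(out) <- metadata(x)
    validObject(out)
    out
})

#' Accessors for DiscretizedCells
#'
#' \code{binLabels} returns the variables-by-cells integer label matrix
#' (0-based), \code{binEdges} the per-marker interior edge map, and
#' \code{nLevels} the per-variable state counts.
#'
#' @param x a \linkS4class{DiscretizedCells}.
#' @name DiscretizedCells-accessors
#' @aliases binLabels binEdges nLevels
NULL

#' @rdname DiscretizedCells-accessors
#' @export
setMethod("binLabels", "DiscretizedCells", function(x) assay(x, "labels"))

#' @rdname DiscretizedCells-accessors
#' @export
setMethod("binEdges", "DiscretizedCells", function(x) x@binEdges)

#' @rdname DiscretizedCells-accessors
#' @export
setMethod("nLevels", "DiscretizedCells", function(x) x@nLevels)

setMethod("show", "DiscretizedCells", function(object) {
    cat("DiscretizedCells:", nrow(object), "variables x", ncol(object),
        "cells\n")
    k <- object@nLevels[rownames(object)]
    cat("  levels:", paste(range(k), collapse = "-"), "\n")
})

#' Construct a DiscretizedCells from a label matrix
#'
#' Low-level constructor used by the synthetic samplers and pooling
#' helpers; labels are 0-based.
#'
#' @param labels integer matrix, variables x cells.
#' @param nLevels named integer state counts (default: per-row max + 1).
#' @param cellData optional per-cell annotations.
#' @param binEdges optional per-variable edge map.
#' @param levelNames optional per-variable state labels.
#' @return A \linkS4class{DiscretizedCells}.
#' @export
DiscretizedCells <- function(labels, nLevels = NULL, cellData = NULL,
                             binEdges = list(), levelNames = list()) {
    labels <- as.matrix(labels)
    storage.mode(labels) <- "integer"
    colnames(labels) <- NULL
    if (is.null(rownames(labels)))
        stop("labels must have variable row names")
    if (is.null(nLevels))
        nLevels <- apply(labels, 1L, max) + 1L
    nLevels <- stats::setNames(as.integer(nLevels), names(nLevels))
    cd <- if (is.null(cellData))
        S4Vectors::DataFrame(row.names = seq_len(ncol(labels)))
    else S4Vectors::DataFrame(as.data.frame(cellData), row.names = NULL)
    se <- SummarizedExperiment(assays = list(labels = labels), colData = cd)
    new("DiscretizedCells", se, binEdges = binEdges, nLevels = nLevels,
        levelNames = levelNames)
}

#' Append a categorical variable to discretized data
#'
#' Adds an already-categorical per-cell variable (clinical response label,
#' contrast indicator, ...) as a new row of the label matrix, exempt from
#' discretization.
#'
#' @param disc a \linkS4class{DiscretizedCells}.
#' @param name variable name.
#' @param values factor (or coercible) of length \code{nCells(disc)}.
#' @return A \linkS4class{DiscretizedCells} with one more variable.
#' @export
appendDiscreteVar <- function(disc, name, values) {
    if (name %in% rownames(disc))
        stop("variable '", name, "' already present")
    f <- if (is.factor(values)) values else factor(values)
    if (length(f) != ncol(disc))
        stop("values must have one entry per cell")
    if (nlevels(f) < 2L)
        stop("categorical variable '", name, "' needs at least 2 observed ",
             "levels")
    lab <- rbind(assay(disc, "labels"),
                 matrix(as.integer(f) - 1L, nrow = 1L,
                        dimnames = list(name, NULL)))
    nLev <- c(disc@nLevels, stats::setNames(nlevels(f), name))
    lv <- disc@levelNames
    lv[[name]] <- levels(f)
    DiscretizedCells(lab, nLev, colData(disc), disc@binEdges, lv)
}

#' Serialize a bin-edge map
#'
#' Writes the per-marker interior bin edges of a discretization as JSON so
#' a binning can be recorded alongside results and re-applied later.
#'
#' @param disc a \linkS4class{DiscretizedCells}.
#' @param path output path.
#' @export
writeBinEdges <- function(disc, path) {
    jsonlite::write_json(lapply(disc@binEdges, unclass), path,
                         digits = NA, pretty = TRUE)
    invisible(path)
}
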