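#' Build a marker-configuration table
#'
#' Enumerates the observed joint configurations of the given discretized
#' markers (typically the Markov-neighborhood members of the response
#' node), with the empirical frequency of each configuration and the raw
#' conditional probability of clinical response given the configuration
#' (the responder-cell fraction among the cells showing it; cells inherit
#' their patient's label and all patients are pooled unweighted).
#' Configurations never observed are omitted. With five ternary markers
#' the configuration space has 3^5 = 243 cells, of which only the observed
#' ones appear.
#'
#' @param data a \linkS4class{DiscretizedCells}.
#' @param markers character, the marker subset (columns of the table, in
#'   this order).
#' @param response per-cell binary labels: either the name of a
#'   \code{cellData} column (default \code{"response"}) or a vector/factor
#'   aligned with the cells whose second level (or \code{TRUE}) marks
#'   responders.
#' @return A \linkS4class{ConfigTable}, rows in decreasing frequency.
#' @examples
#' lab <- matrix(c(0L,0L, 1L,1L, 0L,0L, 1L,1L), nrow = 2,
#'               dimnames = list(c("A","B"), NULL))
#' d <- DiscretizedCells(lab, c(A = 2L, B = 2L),
#'        cellData = data.frame(response = c("nonresponder","responder",
#'                                           "nonresponder","responder")))
#' configTable(buildConfigTable(d, c("A","B")))
#' @export
buildConfigTable <- function(data, markers, response = "response") {
    if (!all(markers %in% rownames(data)))
        stop("unknown marker(s): ",
             paste(setdiff(markers, rownames(data)), collapse = ", "))
    resp <- .responseVector(data, response)
    lab <- assay(data, "labels")[markers, , drop = FALSE]
    n <- ncol(lab)
    cards <- data@nLevels[markers]
    # mixed-radix key, first marker fastest
    key <- numeric(n); stride <- 1
    for (m in markers) {
        key <- key + lab[m, ] * stride
        stride <- stride * cards[[m]]
    }
    counts <- table(key)
    respCounts <- tapply(as.integer(resp), key, sum)
    keys <- as.numeric(names(counts))
    cfgm <- vapply(keys, function(kk) {
        s <- integer(length(markers))
        for (i in seq_along(markers)) {
            s[i] <- as.integer(kk %% cards[[i]])
            kk <- kk %/% cards[[i]]
        }
        s
    }, integer(length(markers)))
    if (length(markers) == 1L) cfgm <- matrix(cfgm, nrow = 1L)
    cfg <- t(cfgm)
    colnames(cfg) <- markers
    tab <- data.frame(cfg, check.names = FALSE)
    tab$frequency <- as.numeric(counts) / n
    tab$p_response <- as.numeric(respCounts[names(counts)]) /
        as.numeric(counts)
    ord <- order(-tab$frequency, do.call(paste, tab[markers]))
    tab <- tab[ord, , drop = FALSE]
    rownames(tab) <- NULL
    new("ConfigTable", markers = markers, table = tab, sortMode = "none",
        cutoff = NA_integer_, nCells = n,
        responderFraction = mean(as.integer(resp)))
}

.responseVector <- function(data, response) {
    if (is.character(response) && length(response) == 1L) {
        if (!response %in% colnames(colData(data)))
            stop("response column '", response, "' not found")
        response <- colData(data)[[response]]
    }
    if (length(response) != ncol(data))
        stop("response labels must align with the cells")
    if (is.factor(response)) {
        if (nlevels(response) != 2L)
            stop("response must be binary")
        return(response == levels(response)[2L])
    }
    if (is.logical(response)) return(response)
    u <- sort(unique(response))
    if (length(u) != 2L) stop("response must be binary")
    response == u[2L]
}

#' Sort a configuration table
#'
#' Two strategies: \code{"frequency_then_probability"} keeps the
#' \code{topN} most frequent configurations and re-sorts those by
#' decreasing response probability (favoring statistically robust,
#' frequent configurations); \code{"probability_only"} sorts all rows by
#' decreasing response probability (surfacing rare configurations with
#' extreme response rates). Ties in probability are broken by higher
#' frequency, then by configuration labels.
#'
#' @param x a \linkS4class{ConfigTable}.
#' @param mode sorting strategy.
#' @param topN rows to keep under frequency-then-probability (all rows if
#'   larger than the table).
#' @return The sorted (and possibly truncated) \linkS4class{ConfigTable}.
#' @export
sortConfigTable <- function(x,
                            mode = c("frequency_then_probability",
                                     "probability_only"),
                            topN = Inf) {
    mode <- match.arg(mode)
    tab <- x@table
    tiebreak <- do.call(paste, tab[x@markers])
    if (mode == "frequency_then_probability") {
        keep <- utils::head(order(-tab$frequency, tiebreak),
                            min(topN, nrow(tab)))
        tab <- tab[keep, , drop = FALSE]
        tab <- tab[order(-tab$p_response, -tab$frequency,
                         do.call(paste, tab[x@markers])), , drop = FALSE]
    } else {
        tab <- tab[order(-tab$p_response, -tab$frequency, tiebreak), ,
                   drop = FALSE]
    }
    rownames(tab) <- NULL
    x@table <- tab
    x@sortMode <- mode
    x@cutoff <- nrow(tab)
    x
}

#' Frequency-dropoff cutoff selection
#'
#' Scans a descending frequency vector for the first noticeable relative
#' dropoff -- index i with (f_i - f_(i+1)) / f_i at least
#' \code{minRelDrop} -- and returns that i as the number of configurations
#' to keep; \code{maxRows} caps the scan and is returned when no drop
#' qualifies. A dropoff from ~0.020 to ~0.017 (relative drop 0.15)
#' qualifies at the default threshold.
#'
#' @param frequencies numeric, sorted descending.
#' @param minRelDrop minimum relative drop, in (0, 1).
#' @param maxRows scan cap.
#' @return integer cutoff (0 for an empty vector).
#' @export
selectCutoff <- function(frequencies, minRelDrop = 0.15, maxRows = 40L) {
    if (!length(frequencies)) return(0L)
    if (is.unsorted(rev(frequencies)))
        stop("frequencies must be sorted in descending order")
    upper <- min(maxRows, length(frequencies) - 1L)
    for (i in seq_len(max(upper, 0L))) {
        # tiny slack so drops sitting numerically at the threshold qualify
        if ((frequencies[i] - frequencies[i + 1L]) / frequencies[i] >=
            minRelDrop - 1e-9)
            return(i)
    }
    as.integer(min(maxRows, length(frequencies)))
}

#' Two-bin response probabilities for a single marker
#'
#' Re-discretizes one marker into two equal-frequency bins on the full
#' pooled sample and returns the responder-cell fraction among high-bin
#' and low-bin cells -- the single-marker summary used to gauge a
#' candidate predictor from the response node's neighborhood.
#'
#' @param cells a \linkS4class{FlowCellSet}.
#' @param marker marker name.
#' @param response as in [buildConfigTable()].
#' @return named numeric c(p_high, p_low).
#' @export
binaryMarkerResponse <- function(cells, marker, response = "response") {
    if (!marker %in% rownames(cells)) stop("unknown marker: ", marker)
    vals <- assay(cells, "intensities")[marker, ]
    edges <- equalFrequencyEdges(vals, 2L)
    high <- applyBinEdges(vals, edges) == 1L
    resp <- .responseVector(cells, response)
    c(p_high = mean(resp[high]), p_low = mean(resp[!high]))
}

#' @rdname ConfigTable-accessors
#' @export
configTable <- function(x) x@table

#' Accessors for ConfigTable
#'
#' \code{configTable} returns the underlying data.frame.
#'
#' @param x a \linkS4class{ConfigTable}.
#' @name ConfigTable-accessors
NULL

setMethod("show", "ConfigTable", function(object) {
    cat("ConfigTable over (", paste(object@markers, collapse = ", "),
        "): ", nrow(object@table), " configurations, sort = ",
        object@sortMode, "\n", sep = "")
    print(utils::head(object@table, 10L))
    if (nrow(object@table) > 10L) cat("...\n")
})

#' Write a configuration table as TSV
#'
#' Column layout mirrors the analysis tables: the configuration tuple in
#' one column, then frequency and probability of response.
#'
#' @param x a \linkS4class{ConfigTable}.
#' @param file output path.
#' @export
writeConfigTable <- function(x, file) {
    tab <- x@table
    out <- data.frame(
        configuration = paste0("(", do.call(paste, tab[x@markers]), ")"),
        frequency = tab$frequency,
        p_response = tab$p_response)
    utils::write.table(out, file, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    invisible(file)
}
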