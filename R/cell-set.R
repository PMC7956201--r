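#' Construct a FlowCellSet from a cells-by-markers matrix
#'
#' @param values numeric matrix, one row per cell, one column per marker.
#'   Intensities are compensated fluorescence values; negatives are accepted
#'   (compensation can push signals below zero) and are not clipped.
#' @param markerNames character, unique marker names (defaults to the
#'   column names of \code{values}).
#' @param cellData data.frame or DataFrame of per-cell annotations. Must
#'   contain \code{patient_id}, \code{day} and \code{tsize} (or an explicit
#'   \code{response}); if \code{response} is absent it is derived as
#'   responder iff \code{tsize < -25} (percent tumor radius change).
#' @param timepoints integer, the declared study timepoints annotated days
#'   must belong to.
#' @return A \linkS4class{FlowCellSet}.
#' @examples
#' m <- matrix(abs(rnorm(20, 100, 20)), 10, 2,
#'             dimnames = list(NULL, c("CD4", "CD8")))
#' ann <- data.frame(patient_id = "P01", day = 1, tsize = -40)
#' fs <- FlowCellSet(m, cellData = ann)
#' nCells(fs)
#' @export
FlowCellSet <- function(values, markerNames = colnames(values), cellData,
                        timepoints = c(1L, 21L)) {
    values <- as.matrix(values)
    if (is.null(markerNames))
        stop("marker names are required")
    if (anyDuplicated(markerNames))
        stop("duplicate marker names: ",
             paste(unique(markerNames[duplicated(markerNames)]), collapse = ", "))
    if (length(markerNames) != ncol(values))
        stop("markerNames length must equal the number of columns")
    cellData <- as.data.frame(cellData)
    if (nrow(cellData) == 1L && nrow(values) > 1L)
        cellData <- cellData[rep(1L, nrow(values)), , drop = FALSE]
    if (nrow(cellData) != nrow(values))
        stop("cellData must have one record per cell")
    cellData <- .completeAnnotations(cellData)
    se <- SummarizedExperiment(
        assays = list(intensities = t(values)),
        rowData = S4Vectors::DataFrame(marker = markerNames),
        colData = S4Vectors::DataFrame(cellData, row.names = NULL))
    rownames(se) <- markerNames
    obj <- new("FlowCellSet", se)
    metadata(obj)$timepoints <- as.integer(timepoints)
    validObject(obj)
    obj
}

.completeAnnotations <- function(df) {
    if (!"response" %in% colnames(df)) {
        if (!"tsize" %in% colnames(df))
            stop("annotations need either 'response' or 'tsize'")
        df$response <- ifelse(df$tsize < -25, "responder", "nonresponder")
    }
    if (!is.factor(df$response))
        df$response <- factor(df$response,
                              levels = c("nonresponder", "responder"))
    if (!"tsize" %in% colnames(df)) df$tsize <- NA_real_
    if (!"patient_id" %in% colnames(df)) df$patient_id <- NA_character_
    if (!"day" %in% colnames(df)) df$day <- NA_integer_
    df$day <- as.integer(df$day)
    df[, unique(c(.REQUIRED_ANNOTATIONS, colnames(df))), drop = FALSE]
}

#' Accessors for FlowCellSet
#'
#' \code{intensities} returns the cells-by-markers intensity matrix,
#' \code{markerNames} the marker panel, \code{cellData} the per-cell
#' annotation DataFrame, and \code{nCells} the number of cells (events).
#'
#' @param x a \linkS4class{FlowCellSet}.
#' @name FlowCellSet-accessors
#' @aliases intensities markerNames cellData nCells
NULL

#' @rdname FlowCellSet-accessors
#' @export
setMethod("intensities", "FlowCellSet", function(x) t(assay(x, "intensities")))

#' @rdname FlowCellSet-accessors
#' @export
setMethod("markerNames", "FlowCellSet", function(x) rownames(x))

#' @rdname FlowCellSet-accessors
#' @export
setMethod("cellData", "FlowCellSet", function(x) colData(x))

#' @rdname FlowCellSet-accessors
#' @export
setMethod("nCells", "FlowCellSet", function(x) ncol(x))

#' @rdname DiscretizedCells-accessors
#' @export
setMethod("nCells", "DiscretizedCells", function(x) ncol(x))

setMethod("show", "FlowCellSet", function(object) {
    cat("FlowCellSet:", nrow(object), "markers x", ncol(object), "cells\n")
    cd <- colData(object)
    if ("patient_id" %in% colnames(cd)) {
        pats <- unique(cd$patient_id)
        cat("  patients:", length(pats[!is.na(pats)]),
            " days:", paste(sort(unique(cd$day[!is.na(cd$day)])), collapse = ", "),
            "\n")
        if ("response" %in% colnames(cd))
            cat("  responder cells:",
                sum(cd$response == "responder", na.rm = TRUE), "/",
                nrow(cd), "\n")
    }
    cat("  markers:", paste(utils::head(rownames(object), 8L), collapse = ", "),
        if (nrow(object) > 8L) "..." else "", "\n")
})

#' Read cell-level intensities and annotations from delimited text
#'
#' Reads a header-bearing delimited file (comma or tab, sniffed from the
#' header line unless \code{sep} is given) with one row per cell. Marker
#' columns must be numeric; annotation columns are mapped through
#' \code{annotationColumns}. When no response column is mapped, the
#' responder label is derived from the tumor-size change as
#' \code{tsize < -25}.
#'
#' @param path file path.
#' @param markerColumns character, names of the intensity columns.
#' @param annotationColumns named character/list mapping any of
#'   \code{patient_id}, \code{day}, \code{response}, \code{tsize} to column
#'   names in the file.
#' @param sep field separator; \code{NULL} to sniff "," vs tab.
#' @param timepoints declared study timepoints.
#' @return A \linkS4class{FlowCellSet}.
#' @export
readCellTable <- function(path, markerColumns,
                          annotationColumns = list(patient_id = "patient_id",
                                                   day = "day",
                                                   tsize = "tsize"),
                          sep = NULL, timepoints = c(1L, 21L)) {
    header <- readLines(path, n = 1L)
    if (is.null(sep))
        sep <- if (grepl("\t", header)) "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, check.names = FALSE)
    missing <- setdiff(markerColumns, colnames(df))
    if (length(missing))
        stop("missing marker column(s): ", paste(missing, collapse = ", "))
    ann <- list()
    for (field in names(annotationColumns)) {
        col <- annotationColumns[[field]]
        if (is.null(col) || is.na(col)) next
        if (!col %in% colnames(df))
            stop("missing annotation column: ", col)
        ann[[field]] <- df[[col]]
    }
    vals <- df[, markerColumns, drop = FALSE]
    for (j in seq_along(vals)) {
        v <- suppressWarnings(as.numeric(vals[[j]]))
        bad <- which(is.na(v) & !is.na(vals[[j]]))
        if (length(bad))
            stop("non-numeric intensity in column '", markerColumns[j],
                 "', row ", bad[1L])
        vals[[j]] <- v
    }
    FlowCellSet(as.matrix(vals), markerColumns, as.data.frame(ann),
                timepoints = timepoints)
}

#' Write a FlowCellSet as delimited text
#'
#' Writes one row per cell: annotation columns followed by marker
#' intensities. The file round-trips through [readCellTable()].
#'
#' @param x a \linkS4class{FlowCellSet}.
#' @param path output path.
#' @param sep field separator.
#' @export
writeCellTable <- function(x, path, sep = ",") {
    df <- cbind(as.data.frame(colData(x)), as.data.frame(intensities(x)))
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
    invisible(path)
}
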