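# Minimal FCS 3.0/3.1 reader and writer. Only list-mode data with a single
# dataset is supported; values are returned exactly as stored (no
# transformation or compensation beyond what the file holds).

.fcsReadHeader <- function(con) {
    magic <- rawToChar(readBin(con, "raw", 6L))
    if (!magic %in% c("FCS3.0", "FCS3.1"))
        stop("not an FCS 3.0/3.1 file (magic '", magic, "')")
    readBin(con, "raw", 4L)  # spaces
    offs <- vapply(1:6, function(i) {
        s <- trimws(rawToChar(readBin(con, "raw", 8L)))
        if (s == "") 0 else suppressWarnings(as.numeric(s))
    }, 0)
    if (anyNA(offs)) stop("malformed FCS header offsets")
    names(offs) <- c("textStart", "textEnd", "dataStart", "dataEnd",
                     "anaStart", "anaEnd")
    offs
}

.fcsParseText <- function(raw) {
    delim <- rawToChar(raw[1L])
    body <- rawToChar(raw[-1L])
    parts <- strsplit(body, delim, fixed = TRUE)[[1L]]
    # trailing delimiter leaves an even number of key/value fields
    if (length(parts) %% 2L == 1L) {
        if (nzchar(trimws(parts[length(parts)])))
            stop("malformed TEXT segment: unpaired keyword near '",
                 parts[length(parts)], "'")
        parts <- parts[-length(parts)]
    }
    keys <- parts[seq(1L, length(parts), 2L)]
    vals <- parts[seq(2L, length(parts), 2L)]
    stats::setNames(vals, toupper(trimws(keys)))
}

.fcsKeyword <- function(kw, name, default = NULL) {
    if (name %in% names(kw)) return(kw[[name]])
    if (is.null(default))
        stop("FCS TEXT segment lacks required keyword ", name)
    default
}

#' Read an FCS 3.0/3.1 file
#'
#' Reads list-mode events from a binary FCS file into a
#' \linkS4class{FlowCellSet}, one row per event. Parameter (marker) names
#' are taken from the $PnS keywords with $PnN as fallback. Values are read
#' exactly as stored: float ($DATATYPE F/D) or unsigned integer
#' ($DATATYPE I), honoring $BYTEORD.
#'
#' FCS files carry no patient metadata, so the clinical annotations for all
#' events in the file are supplied as arguments (one file per
#' patient/timepoint acquisition is the usual layout).
#'
#' @param path path to an FCS 3.0/3.1 file.
#' @param patient_id,day,tsize,response per-file annotations applied to
#'   every event; \code{response} defaults to \code{tsize < -25} when a
#'   tumor-size change is given.
#' @param timepoints declared study timepoints.
#' @return A \linkS4class{FlowCellSet}.
#' @seealso [writeFCS()]
#' @export
readFCS <- function(path, patient_id = NA_character_, day = NA_integer_,
                    tsize = NA_real_, response = NULL,
                    timepoints = c(1L, 21L)) {
    con <- file(path, "rb")
    on.exit(close(con))
    offs <- .fcsReadHeader(con)
    seek(con, offs[["textStart"]])
    textLen <- offs[["textEnd"]] - offs[["textStart"]] + 1
    if (textLen <= 1) stop("malformed FCS header: empty TEXT segment")
    kw <- .fcsParseText(readBin(con, "raw", textLen))

    nPar <- as.integer(.fcsKeyword(kw, "$PAR"))
    nTot <- as.integer(.fcsKeyword(kw, "$TOT"))
    dtype <- toupper(.fcsKeyword(kw, "$DATATYPE"))
    byteord <- .fcsKeyword(kw, "$BYTEORD")
    endian <- if (startsWith(byteord, "1")) "little" else "big"
    mode <- toupper(.fcsKeyword(kw, "$MODE", "L"))
    if (mode != "L") stop("only list-mode ($MODE L) FCS data is supported")

    dataStart <- offs[["dataStart"]]
    dataEnd <- offs[["dataEnd"]]
    if (dataStart == 0) {
        dataStart <- as.numeric(.fcsKeyword(kw, "$BEGINDATA"))
        dataEnd <- as.numeric(.fcsKeyword(kw, "$ENDDATA"))
    }

    bits <- vapply(seq_len(nPar), function(i)
        as.integer(.fcsKeyword(kw, paste0("$P", i, "B"))), 0L)
    shortNames <- vapply(seq_len(nPar), function(i)
        .fcsKeyword(kw, paste0("$P", i, "N")), "")
    stainNames <- vapply(seq_len(nPar), function(i)
        .fcsKeyword(kw, paste0("$P", i, "S"), ""), "")
    nm <- ifelse(nzchar(stainNames), stainNames, shortNames)
    if (anyDuplicated(nm))
        stop("duplicate parameter names in FCS file: ",
             paste(unique(nm[duplicated(nm)]), collapse = ", "))

    seek(con, dataStart)
    vals <- switch(dtype,
        F = {
            if (any(bits != 32L))
                stop("$DATATYPE F requires $PnB 32 (keyword $P",
                     which(bits != 32L)[1L], "B)")
            readBin(con, "numeric", n = nPar * nTot, size = 4L,
                    endian = endian)
        },
        D = {
            if (any(bits != 64L))
                stop("$DATATYPE D requires $PnB 64 (keyword $P",
                     which(bits != 64L)[1L], "B)")
            readBin(con, "numeric", n = nPar * nTot, size = 8L,
                    endian = endian)
        },
        I = {
            if (length(unique(bits)) != 1L || !bits[1L] %in% c(16L, 32L))
                stop("$DATATYPE I supported only with uniform $PnB 16 or 32")
            v <- readBin(con, "integer", n = nPar * nTot,
                         size = bits[1L] / 8L, signed = bits[1L] > 16L,
                         endian = endian)
            as.numeric(v)
        },
        stop("unsupported $DATATYPE '", dtype, "'"))
    if (length(vals) != nPar * nTot)
        stop("FCS DATA segment truncated (expected ", nPar * nTot,
             " values, read ", length(vals), ")")
    m <- matrix(vals, nrow = nTot, ncol = nPar, byrow = TRUE)
    colnames(m) <- nm

    ann <- data.frame(patient_id = patient_id, day = day, tsize = tsize)
    if (!is.null(response)) ann$response <- response
    FlowCellSet(m, nm, ann, timepoints = timepoints)
}

#' Write events to a minimal FCS 3.0 file
#'
#' Writes a cells-by-markers matrix as single-dataset, list-mode FCS 3.0
#' with float32 values and little-endian byte order. Primarily useful for
#' building reproducible test inputs for [readFCS()]; values round-trip
#' within float32 precision.
#'
#' @param values numeric matrix, cells x markers.
#' @param path output path.
#' @param shortNames $PnN keywords (default P1, P2, ...).
#' @param stainNames $PnS keywords (default the column names).
#' @export
writeFCS <- function(values, path, shortNames = NULL, stainNames = NULL) {
    values <- as.matrix(values)
    nPar <- ncol(values); nTot <- nrow(values)
    if (is.null(stainNames)) stainNames <- colnames(values)
    if (is.null(shortNames)) shortNames <- paste0("P", seq_len(nPar))
    d <- "/"
    paramKw <- character()
    for (i in seq_len(nPar)) {
        rng <- max(1, ceiling(max(values[, i], 1)))
        paramKw <- c(paramKw,
            paste0("$P", i, "N"), shortNames[i],
            paste0("$P", i, "B"), "32",
            paste0("$P", i, "E"), "0,0",
            paste0("$P", i, "R"), as.character(rng))
        if (!is.null(stainNames) && nzchar(stainNames[i]))
            paramKw <- c(paramKw, paste0("$P", i, "S"), stainNames[i])
    }
    buildText <- function(dataStart, dataEnd) {
        kv <- c("$DATATYPE", "F", "$MODE", "L", "$BYTEORD", "1,2,3,4",
                "$PAR", as.character(nPar), "$TOT", as.character(nTot),
                "$NEXTDATA", "0",
                "$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
                "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
                "$BEGINDATA", sprintf("%010d", dataStart),
                "$ENDDATA", sprintf("%010d", dataEnd),
                paramKw)
        paste0(d, paste(kv, collapse = d), d)
    }
    textStart <- 58L
    textLen <- nchar(buildText(0L, 0L))  # fixed-width offsets keep this stable
    dataStart <- textStart + textLen
    dataLen <- 4L * nPar * nTot
    dataEnd <- dataStart + dataLen - 1L
    text <- buildText(dataStart, dataEnd)
    header <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d",
                      textStart, textStart + textLen - 1L,
                      dataStart, dataEnd, 0L, 0L)
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(header), con)
    writeBin(charToRaw(text), con)
    writeBin(as.numeric(t(values)), con, size = 4L, endian = "little")
    invisible(path)
}
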