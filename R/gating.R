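#' Panel gating cutoffs
#'
#' Construct the high/low cutoffs used to stratify cells into major T-cell
#' subsets. The built-in calibrations are \code{"Checkpoint"}
#' (CD4 = 1500, CD8 = 750, CCR7 = 150, CD45RA = 400) and \code{"Adaptive"}
#' (CD4 = 1000, CD8 = 1000, CCR7 = 150, CD45RA = 1000); custom thresholds
#' may be supplied instead.
#'
#' @param panel panel name; one of the built-ins unless \code{thresholds}
#'   is given.
#' @param thresholds named numeric over exactly CD4, CD8, CCR7, CD45RA.
#' @return A \linkS4class{PanelCutoffs}.
#' @examples
#' panelCutoffs("Adaptive")
#' @export
panelCutoffs <- function(panel, thresholds = NULL) {
    presets <- list(
        Checkpoint = c(CD4 = 1500, CD8 = 750, CCR7 = 150, CD45RA = 400),
        Adaptive   = c(CD4 = 1000, CD8 = 1000, CCR7 = 150, CD45RA = 1000))
    if (is.null(thresholds)) {
        if (!panel %in% names(presets))
            stop("no built-in cutoffs for panel '", panel,
                 "'; supply thresholds explicitly")
        thresholds <- presets[[panel]]
    }
    new("PanelCutoffs", panel = panel,
        thresholds = thresholds[.GATING_MARKERS])
}

#' Major T-cell subset membership rules
#'
#' Returns the membership rule for one of the four major T-cell subsets,
#' expressed as 4-bit patterns over (CD4, CD8, CCR7, CD45RA) where bit = 1
#' means the marker is at or above its cutoff:
#' NaiveCD4 \{1011\}, NaiveCD8 \{0111\},
#' NonNaiveCD4 \{1010, 1001, 1000\}, NonNaiveCD8 \{0110, 0101, 0100\}.
#'
#' @param name one of "NaiveCD4", "NaiveCD8", "NonNaiveCD4", "NonNaiveCD8".
#' @return A \linkS4class{CellTypeRule}.
#' @export
cellTypeRule <- function(name = c("NaiveCD4", "NaiveCD8",
                                  "NonNaiveCD4", "NonNaiveCD8")) {
    name <- match.arg(name)
    patterns <- switch(name,
        NaiveCD4 = "1011",
        NaiveCD8 = "0111",
        NonNaiveCD4 = c("1010", "1001", "1000"),
        NonNaiveCD8 = c("0110", "0101", "0100"))
    new("CellTypeRule", name = name, patterns = patterns)
}

#' Stratify cells into a major T-cell subset by threshold gating
#'
#' Computes each cell's 4-bit high/low pattern over (CD4, CD8, CCR7,
#' CD45RA) -- bit = 1 iff intensity >= cutoff -- and keeps only the cells
#' whose pattern belongs to the rule. The four gating markers are dropped
#' from the returned matrix, since after stratification they no longer
#' vary informatively within the subset.
#'
#' Cells whose pattern matches none of the four built-in subsets (e.g.
#' 1111 double positives or 0000 double negatives) are simply not selected
#' by any rule.
#'
#' @param cells a \linkS4class{FlowCellSet} containing the four gating
#'   markers.
#' @param cutoffs a \linkS4class{PanelCutoffs}.
#' @param rule a \linkS4class{CellTypeRule}.
#' @return A \linkS4class{FlowCellSet} with the selected cells and the
#'   gating markers removed. Empty selections return an empty set with a
#'   warning.
#' @examples
#' m <- cbind(CD4 = c(1200, 900), CD8 = c(500, 1200),
#'            CCR7 = c(200, 160), CD45RA = c(1500, 400), TIGIT = c(5, 7))
#' fs <- FlowCellSet(m, cellData = data.frame(patient_id = "P1", day = 1,
#'                                            tsize = -40))
#' stratifyCellType(fs, panelCutoffs("Adaptive"), cellTypeRule("NaiveCD4"))
#' @export
stratifyCellType <- function(cells, cutoffs, rule) {
    stopifnot(is(cells, "FlowCellSet"), is(cutoffs, "PanelCutoffs"),
              is(rule, "CellTypeRule"))
    missing <- setdiff(.GATING_MARKERS, rownames(cells))
    if (length(missing))
        stop("missing gating marker(s): ", paste(missing, collapse = ", "))
    vals <- assay(cells, "intensities")
    bits <- vapply(.GATING_MARKERS, function(m)
        as.integer(vals[m, ] >= cutoffs@thresholds[[m]]),
        integer(ncol(cells)))
    if (ncol(cells) == 1L) bits <- matrix(bits, nrow = 1L)
    pattern <- apply(bits, 1L, paste0, collapse = "")
    keep <- pattern %in% rule@patterns
    out <- cells[setdiff(rownames(cells), .GATING_MARKERS), keep]
    if (!any(keep))
        warning("no cells match the ", rule@name, " rule; returning an ",
                "empty FlowCellSet")
    out
}
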