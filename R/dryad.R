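#' Headline reproduction checks against the deposited study data
#'
#' Recomputes, from cell-level inputs, the quantities the study tables
#' report for the deposited dataset (Dryad doi:10.5061/dryad.fxpnvx0ng):
#' the two-bin TIGIT response probabilities on the Checkpoint day-1 data,
#' the all-zero (and all-high) configuration frequencies of the three
#' panel configuration tables, and the CXCR3/CD25 responder-vs-nonresponder
#' EMDs on the Adaptive naive CD4+ day-1 subset. This is an integration
#' surface: it requires a local copy of the deposit (the data are not
#' shipped with the package) arranged as delimited files readable by
#' [readCellTable()].
#'
#' @param dir directory containing \code{checkpoint_day1.csv},
#'   \code{innate_day1.csv}, \code{adaptive_day1.csv} and
#'   \code{adaptive_all.csv} (the full Adaptive panel with \code{day}
#'   annotations, gated here to naive CD4+ cells), each with marker
#'   columns plus \code{patient_id}, \code{day}, \code{tsize}.
#' @return named list of recomputed values:
#'   \code{tigit_p_high}, \code{tigit_p_low},
#'   \code{checkpoint_zero_config_freq}, \code{innate_zero_config_freq},
#'   \code{adaptive_high_config_freq}, \code{cxcr3_emd}, \code{cd25_emd}.
#' @export
headlineChecks <- function(dir) {
    need <- c("checkpoint_day1.csv", "innate_day1.csv",
              "adaptive_day1.csv", "adaptive_all.csv")
    paths <- file.path(dir, need)
    if (!all(file.exists(paths)))
        stop("deposited dataset not found under '", dir, "' (need ",
             paste(need, collapse = ", "), ")")
    readPanel <- function(path, markers) {
        readCellTable(path, markers)
    }
    checkpointMN <- c("TIGIT", "CD4", "CD8", "CD160", "4-1BB")
    innateMN <- c("HLA-DR", "PD-L1", "CD3", "CD20", "CD83", "CD1c",
                  "CD14", "CD33")
    adaptiveMN <- c("CXCR3", "CCR4", "CD8", "CXCR5")
    distMarkers <- c("CXCR3", "CCR10", "CD73", "CCR6", "CD25", "ICOS",
                     "CXCR5", "PD-1", "CD127", "CCR4")

    ckp <- readPanel(paths[1L], unique(c(checkpointMN, "TIGIT")))
    tigit <- binaryMarkerResponse(ckp, "TIGIT")
    freqOf <- function(cells, markers, config) {
        tab <- buildConfigTable(discretizeCells(cells, 3L), markers,
                                colData(cells)$response)
        t2 <- tab@table
        hit <- rep(TRUE, nrow(t2))
        for (i in seq_along(markers))
            hit <- hit & t2[[markers[i]]] == config[i]
        if (!any(hit)) 0 else t2$frequency[hit]
    }
    ckpFreq <- freqOf(ckp, checkpointMN, rep(0L, 5L))
    inn <- readPanel(paths[2L], innateMN)
    innFreq <- freqOf(inn, innateMN, rep(0L, 8L))
    ada <- readPanel(paths[3L], adaptiveMN)
    adaFreq <- freqOf(ada, adaptiveMN, rep(2L, 4L))

    adaAll <- readPanel(paths[4L], unique(c(distMarkers, .GATING_MARKERS)))
    naive <- stratifyCellType(adaAll, panelCutoffs("Adaptive"),
                              cellTypeRule("NaiveCD4"))
    day1 <- naive[, colData(naive)$day == 1L]
    dt <- markerDistanceTable(day1)
    list(tigit_p_high = unname(tigit[["p_high"]]),
         tigit_p_low = unname(tigit[["p_low"]]),
         checkpoint_zero_config_freq = ckpFreq,
         innate_zero_config_freq = innFreq,
         adaptive_high_config_freq = adaFreq,
         cxcr3_emd = dt$emd[dt$marker == "CXCR3"],
         cd25_emd = dt$emd[dt$marker == "CD25"])
}
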