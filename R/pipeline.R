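# Pipeline orchestration: one entry point running a configured analysis
# mode end to end and writing its artifact set.

.defaultPipelineConfig <- function() {
    list(mode = "panel_day1", k_bins = NULL, seed = 1L,
         response_node = "response", rel_threshold = 0.3,
         min_rel_drop = 0.15, max_rows = 40L,
         search = list(k_candidates = 8L, restarts = 20L, ess = 1,
                       max_parents = 4L))
}

.loadPipelineConfig <- function(config) {
    if (is.character(config) && length(config) == 1L)
        config <- yaml::read_yaml(config)
    cfg <- utils::modifyList(.defaultPipelineConfig(), config)
    if (is.null(cfg$out_dir)) stop("config requires 'out_dir'")
    if (is.null(cfg$mode) ||
        !cfg$mode %in% c("panel_day1", "stratified", "contrast",
                         "distances"))
        stop("mode must be one of panel_day1, stratified, contrast, ",
             "distances")
    cfg
}

.pipelineSearchConfig <- function(cfg) {
    SearchConfig(kCandidates = cfg$search$k_candidates,
                 restarts = cfg$search$restarts,
                 seed = cfg$seed, ess = cfg$search$ess,
                 maxParents = cfg$search$max_parents)
}

.pipelineInput <- function(cfg) {
    if (!is.null(cfg$cells)) return(cfg$cells)       # in-memory input
    if (!is.null(cfg$input))
        return(readCellTable(cfg$input, cfg$markers,
                             cfg$annotation_columns %||%
                                 list(patient_id = "patient_id",
                                      day = "day", tsize = "tsize")))
    stop("config requires 'input' (delimited text path) or 'cells'")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.writeManifest <- function(cfg, outDir, artifacts) {
    manifest <- list(
        package = "cytoBN",
        version = as.character(utils::packageVersion("cytoBN")),
        mode = cfg$mode, seed = cfg$seed,
        k_bins = cfg$k_bins, search = cfg$search,
        input = if (is.character(cfg$input)) cfg$input else "in-memory",
        input_digest = if (is.character(cfg$input) && file.exists(cfg$input))
            unname(tools::md5sum(cfg$input)) else NA,
        artifacts = artifacts)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
}

#' Run a configured analysis pipeline
#'
#' Executes one analysis mode end to end and writes its artifacts under
#' \code{out_dir}:
#' \describe{
#'   \item{panel_day1}{full-panel network at day 1 with the clinical
#'     response node (3 bins by default): network DOT + JSON, a
#'     Markov-neighborhood report for the response node, and the sorted
#'     configuration table over the MN markers (frequency-dropoff
#'     cutoff, frequency-then-probability order).}
#'   \item{stratified}{per cell-subset networks (8 bins by default):
#'     gating by the configured panel cutoffs and rule, then one network
#'     DOT + JSON per (day, response) regime.}
#'   \item{contrast}{pooled supergraph over regimes with a contrast
#'     indicator (8 bins): supergraph DOT + JSON, contrast MN report,
#'     conditioned per-state networks, and pairwise skeleton diff
#'     reports.}
#'   \item{distances}{per-marker responder/nonresponder EMD and energy
#'     distance table (TSV).}
#' }
#' Every run writes a \code{manifest.json} echoing the configuration,
#' seed, package version and input digest; runs are byte-reproducible
#' given the same configuration and seed.
#'
#' @param config a named list or the path of a YAML file. Common fields:
#'   \code{mode}, \code{input} (delimited text; or \code{cells}, an
#'   in-memory \linkS4class{FlowCellSet} / named list of
#'   \linkS4class{DiscretizedCells} for contrast mode), \code{markers},
#'   \code{out_dir}, \code{seed}, \code{k_bins}, \code{search} (list:
#'   \code{k_candidates}, \code{restarts}, \code{ess},
#'   \code{max_parents}), \code{panel} + \code{cell_type} (stratified /
#'   distances gating), \code{contrast} (list: \code{name},
#'   \code{states}, \code{assignment}).
#' @return named character vector of artifact paths, invisibly.
#' @export
runPipeline <- function(config) {
    cfg <- .loadPipelineConfig(config)
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }
    artifacts <- switch(cfg$mode,
        panel_day1 = .runPanelDay1(cfg, stage),
        stratified = .runStratified(cfg, stage),
        contrast = .runContrast(cfg, stage),
        distances = .runDistances(cfg, stage))
    .writeManifest(cfg, cfg$out_dir, as.list(artifacts))
    invisible(artifacts)
}

.runPanelDay1 <- function(cfg, stage) {
    cells <- stage("input", .pipelineInput(cfg))
    if (!is.null(cfg$day))
        cells <- cells[, !is.na(colData(cells)$day) &
                         colData(cells)$day == cfg$day]
    kBins <- cfg$k_bins %||% 3L
    sc <- .pipelineSearchConfig(cfg)
    net <- stage("learn", learnNetwork(cells, kBins = kBins, config = sc,
                                       extraVars = cfg$response_node))
    mn <- stage("markov", markovNeighborhood(net, cfg$response_node,
                                             cfg$rel_threshold))
    disc <- discretizeCells(cells, kBins)
    strongMarkers <- mn@strong
    out <- c(network_dot = file.path(cfg$out_dir, "network.dot"),
             network_json = file.path(cfg$out_dir, "network.json"),
             mn_report = file.path(cfg$out_dir, "mn_report.tsv"),
             config_table = file.path(cfg$out_dir, "config_table.tsv"))
    exportDOT(net, highlight = cfg$response_node, mn = mn,
              file = out[["network_dot"]])
    exportNetworkJSON(net, file = out[["network_json"]])
    mnTable(net, mn, file = out[["mn_report"]])
    if (length(strongMarkers)) {
        tab <- stage("config_table",
                     buildConfigTable(disc, strongMarkers,
                                      colData(cells)[[cfg$response_node]]))
        cut <- selectCutoff(tab@table$frequency, cfg$min_rel_drop,
                            cfg$max_rows)
        tab <- sortConfigTable(tab, "frequency_then_probability",
                               topN = max(cut, 1L))
        writeConfigTable(tab, out[["config_table"]])
    } else {
        writeLines("configuration\tfrequency\tp_response",
                   out[["config_table"]])
    }
    out
}

.runStratified <- function(cfg, stage) {
    cells <- stage("input", .pipelineInput(cfg))
    cutoffs <- panelCutoffs(cfg$panel %||% "Adaptive")
    rule <- cellTypeRule(cfg$cell_type %||% "NaiveCD4")
    sub <- stage("gating", stratifyCellType(cells, cutoffs, rule))
    kBins <- cfg$k_bins %||% 8L
    sc <- .pipelineSearchConfig(cfg)
    cd <- colData(sub)
    out <- character()
    for (d in sort(unique(cd$day))) for (r in levels(factor(cd$response))) {
        sel <- cd$day == d & cd$response == r
        if (!any(sel)) next
        tag <- paste0("day", d, "_", substr(r, 1L, 1L))
        net <- stage(paste0("learn_", tag),
                     learnNetwork(sub[, sel], kBins = kBins, config = sc))
        dot <- file.path(cfg$out_dir, paste0("network_", tag, ".dot"))
        js <- file.path(cfg$out_dir, paste0("network_", tag, ".json"))
        exportDOT(net, file = dot)
        exportNetworkJSON(net, file = js)
        out[[paste0("network_", tag, "_dot")]] <- dot
        out[[paste0("network_", tag, "_json")]] <- js
    }
    out
}

.contrastSpecFromConfig <- function(cfg, ids) {
    if (!is.null(cfg$contrast))
        return(contrastSpec(cfg$contrast$name %||% "Contrast",
                            unlist(cfg$contrast$states),
                            unlist(cfg$contrast$assignment)))
    contrastSpec("Contrast", ids, stats::setNames(ids, ids))
}

.runContrast <- function(cfg, stage) {
    sc <- .pipelineSearchConfig(cfg)
    if (!is.null(cfg$cells) && is.list(cfg$cells) &&
        !is(cfg$cells, "FlowCellSet")) {
        datasets <- cfg$cells
        spec <- .contrastSpecFromConfig(cfg, names(datasets))
        pooled <- stage("pool", poolWithContrast(datasets, spec))
        net <- stage("supergraph",
                     buildSupergraph(pooled, spec@name, config = sc))
        conditioned <- lapply(spec@states, function(s)
            stage(paste0("condition_", s),
                  conditionOnContrast(pooled, spec, s, config = sc)))
    } else {
        cells <- stage("input", .pipelineInput(cfg))
        cd <- colData(cells)
        split <- interaction(paste0("day", cd$day),
                             ifelse(cd$response == "responder", "R", "NR"),
                             sep = "_", drop = TRUE)
        datasets <- lapply(levels(split), function(s)
            cells[, split == s])
        names(datasets) <- levels(split)
        spec <- .contrastSpecFromConfig(cfg, levels(split))
        pooled <- stage("pool", poolWithContrast(datasets, spec))
        kBins <- cfg$k_bins %||% 8L
        net <- stage("supergraph",
                     buildSupergraph(pooled, spec@name, kBins = kBins,
                                     config = sc))
        conditioned <- lapply(spec@states, function(s)
            stage(paste0("condition_", s),
                  conditionOnContrast(pooled, spec, s, kBins = kBins,
                                      config = sc)))
    }
    names(conditioned) <- spec@states
    out <- c(supergraph_dot = file.path(cfg$out_dir, "supergraph.dot"),
             supergraph_json = file.path(cfg$out_dir, "supergraph.json"),
             contrast_report = file.path(cfg$out_dir,
                                         "contrast_report.tsv"))
    mn <- markovNeighborhood(net, spec@name, cfg$rel_threshold)
    exportDOT(net, highlight = spec@name, mn = mn,
              file = out[["supergraph_dot"]])
    exportNetworkJSON(net, file = out[["supergraph_json"]])
    rep <- contrastReport(net, spec@name, cfg$rel_threshold)
    tab <- mnTable(net, rep[[spec@name]]$neighborhood)
    if (!nrow(tab))
        tab <- data.frame(member = "(none)", direction = "",
                          strength = NA, class = "",
                          artifact = "no differentiating markers")
    utils::write.table(tab, out[["contrast_report"]], sep = "\t",
                       row.names = FALSE, quote = FALSE)
    for (s in spec@states) {
        dot <- file.path(cfg$out_dir, paste0("network_", s, ".dot"))
        js <- file.path(cfg$out_dir, paste0("network_", s, ".json"))
        exportDOT(conditioned[[s]], file = dot)
        exportNetworkJSON(conditioned[[s]], file = js)
        out[[paste0("network_", s, "_dot")]] <- dot
        out[[paste0("network_", s, "_json")]] <- js
    }
    pairs <- utils::combn(spec@states, 2L, simplify = FALSE)
    for (pr in pairs) {
        dd <- diffNetworks(conditioned[[pr[1L]]], conditioned[[pr[2L]]])
        f <- file.path(cfg$out_dir,
                       paste0("diff_", pr[1L], "_vs_", pr[2L], ".tsv"))
        lines <- c(paste0("# edges only in ", pr[1L]),
                   apply(dd$onlyA, 1L, paste, collapse = "\t"),
                   paste0("# edges only in ", pr[2L]),
                   apply(dd$onlyB, 1L, paste, collapse = "\t"),
                   "# shared edges",
                   apply(dd$shared, 1L, paste, collapse = "\t"))
        writeLines(lines, f)
        out[[paste0("diff_", pr[1L], "_vs_", pr[2L])]] <- f
    }
    out
}

.runDistances <- function(cfg, stage) {
    cells <- stage("input", .pipelineInput(cfg))
    if (!is.null(cfg$panel) && !is.null(cfg$cell_type))
        cells <- stage("gating",
                       stratifyCellType(cells, panelCutoffs(cfg$panel),
                                        cellTypeRule(cfg$cell_type)))
    if (!is.null(cfg$day))
        cells <- cells[, !is.na(colData(cells)$day) &
                         colData(cells)$day == cfg$day]
    tab <- stage("distances",
                 markerDistanceTable(cells, by = cfg$response_node))
    out <- c(distance_table = file.path(cfg$out_dir,
                                        "distance_table.tsv"))
    utils::write.table(tab, out[["distance_table"]], sep = "\t",
                       row.names = FALSE, quote = FALSE)
    out
}
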