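# Shared fixtures and independent oracles used across the test files.
# Oracles are deliberately naive (enumeration / O(n^2) / closed form) and
# never call the code paths they check.

annDF <- function(n, patient = "P01", day = 1L, tsize = -40) {
    data.frame(patient_id = rep(patient, n), day = rep(day, n),
               tsize = rep(tsize, n))
}

# small annotated FlowCellSet from a cells x markers matrix
flowSet <- function(values, tsize = -40, day = 1L) {
    FlowCellSet(values, cellData = annDF(nrow(values), day = day,
                                         tsize = tsize))
}

skeletonOf <- function(net) {
    es <- arcs(net)
    if (!nrow(es)) return(character())
    sort(paste(pmin(es$from, es$to), pmax(es$from, es$to)))
}

skeletonSHD <- function(a, b) {
    length(setdiff(a, b)) + length(setdiff(b, a))
}

# brute-force type-1 quantile oracle for equal-frequency edges: bin i ends
# at the i/k type-1 quantile, so each interior edge is the next data value
# strictly above it; duplicates collapse.
edgesOracle <- function(x, k) {
    xs <- sort(x)
    n <- length(xs)
    out <- c()
    for (i in seq_len(k - 1)) {
        q <- xs[ceiling(n * i / k)]
        above <- xs[xs > q]
        if (length(above)) out <- c(out, min(above))
    }
    unique(out)
}

# exact area between two empirical CDFs by direct step evaluation
emdAreaOracle <- function(x, y) {
    Fx <- stats::ecdf(x); Fy <- stats::ecdf(y)
    z <- sort(unique(c(x, y)))
    if (length(z) == 1) return(0)
    mid <- z[-length(z)]
    sum(abs(Fx(mid) - Fy(mid)) * diff(z))
}

# O(n^2) pairwise-mean oracle for the energy statistic (V-statistic)
energyOracle <- function(x, y, rooted = TRUE) {
    e2 <- 2 * mean(abs(outer(x, y, "-"))) -
        mean(abs(outer(x, x, "-"))) - mean(abs(outer(y, y, "-")))
    if (rooted) sqrt(max(e2, 0)) else e2
}

# plug-in mutual information via table(), natural log
miOracle <- function(x, y) {
    tab <- table(x, y) / length(x)
    mi <- 0
    for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
        p <- tab[i, j]
        if (p > 0)
            mi <- mi + p * log(p / (sum(tab[i, ]) * sum(tab[, j])))
    }
    mi
}

# minimal DOT well-formedness check: digraph wrapper, balanced braces,
# every non-brace line a node or edge statement ending in ';'
expectValidDOT <- function(txt) {
    lines <- strsplit(txt, "\n")[[1]]
    expect_match(lines[1], "^digraph\\s+\\w+\\s*\\{$")
    expect_identical(lines[length(lines)], "}")
    body <- lines[-c(1, length(lines))]
    for (ln in body) {
        expect_match(ln, "^\\s*(\"[^\"]+\"|\\w+)(\\s*->\\s*(\"[^\"]+\"|\\w+))?\\s*(\\[[^]]*\\])?;$|^\\s*node\\s*\\[[^]]*\\];$")
    }
    invisible(TRUE)
}

# 6-node ground truth + one removed edge: the canonical two-regime scenario
defaultContrastBase <- function() {
    base <- randomDiscreteNetwork(6, nLevels = 3, maxParents = 2,
                                  edgeProb = 0.4, contrast = 0.85,
                                  seed = 42)
    es <- arcs(base)
    list(base = base,
         changedEdge = c(es$from[nrow(es)], es$to[nrow(es)]))
}

# small continuous cohort for k-bin / pipeline tests
smallCohortSpec <- function(cells = 150L) {
    sp <- defaultCohortSpec()
    sp@cellsPerPatient <- as.integer(cells)
    sp
}
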