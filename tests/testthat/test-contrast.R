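# Contrast pooling, supergraphs, conditioning, and network diffs.

test_that("pooling concatenates and labels; splitting recovers the parts", {
    set.seed(61)
    mk <- function(n, mu) flowSet(cbind(A = rnorm(n, mu),
                                        B = rnorm(n, 2 * mu)))
    d1 <- mk(100, 10); d2 <- mk(150, 12)
    spec <- contrastSpec("Contrast", c("one", "two"),
                         c(d1 = "one", d2 = "two"))
    pooled <- poolWithContrast(list(d1 = d1, d2 = d2), spec)
    expect_identical(nCells(pooled), 250L)
    cc <- cellData(pooled)$Contrast
    expect_identical(as.integer(table(cc)[c("one", "two")]),
                     c(100L, 150L))
    # round trip
    back <- pooled[, cc == "one"]
    expect_equal(unname(intensities(back)), unname(intensities(d1)))
})

test_that("four datasets produce a four-state indicator", {
    set.seed(62)
    parts <- lapply(1:4, function(i)
        flowSet(cbind(A = rnorm(30), B = rnorm(30))))
    names(parts) <- paste0("d", 1:4)
    states <- c("day1_NR", "day1_R", "day21_NR", "day21_R")
    spec <- contrastSpec("Contrast", states,
                         stats::setNames(states, names(parts)))
    pooled <- poolWithContrast(parts, spec)
    expect_identical(nlevels(factor(cellData(pooled)$Contrast)), 4L)
})

test_that("marker mismatches are reported with the differing names", {
    d1 <- flowSet(cbind(A = rnorm(10), B = rnorm(10)))
    d2 <- flowSet(cbind(A = rnorm(10), C = rnorm(10)))
    spec <- contrastSpec("Contrast", c("x", "y"), c(d1 = "x", d2 = "y"))
    expect_error(poolWithContrast(list(d1 = d1, d2 = d2), spec), "C")
    expect_error(poolWithContrast(list(d1 = d1, d3 = d2), spec), "d3")
})

test_that("discrete pooling and conditioning are exact partitions", {
    sc <- defaultContrastBase()
    scen <- makeContrastScenario(sc$base, sc$changedEdge, 400, seed = 5)
    spec <- contrastSpec("Contrast", c("base", "alt"),
                         c(r0 = "base", r1 = "alt"))
    pooled <- poolWithContrast(list(r0 = scen$regime0, r1 = scen$regime1),
                               spec)
    expect_identical(nCells(pooled), 800L)
    expect_true("Contrast" %in% rownames(pooled))
    # conditioning uses exactly the contributing rows
    cfg <- SearchConfig(kCandidates = 4, restarts = 3, seed = 1,
                        maxParents = 3)
    net0 <- conditionOnContrast(pooled, spec, "base", config = cfg)
    direct <- learnNetwork(scen$regime0, config = cfg)
    expect_identical(net0@parents, direct@parents)
    expect_equal(networkScore(net0), networkScore(direct),
                 tolerance = 1e-9)
    expect_false("Contrast" %in% bnNodes(net0))
    expect_error(conditionOnContrast(pooled, spec, "missing"), "unknown")
})

test_that("a single regime-specific edge pulls the contrast in", {
    sc <- defaultContrastBase()
    linked <- vapply(1:3, function(sd) {
        scen <- makeContrastScenario(sc$base, sc$changedEdge, 4000,
                                     seed = sd)
        spec <- contrastSpec("Contrast", c("base", "alt"),
                             c(r0 = "base", r1 = "alt"))
        pooled <- poolWithContrast(list(r0 = scen$regime0,
                                        r1 = scen$regime1), spec)
        net <- buildSupergraph(pooled, "Contrast",
                               config = SearchConfig(kCandidates = 5,
                                                     restarts = 10,
                                                     seed = sd,
                                                     maxParents = 4))
        "Contrast" %in% union(markovBlanket(net, sc$changedEdge[1]),
                              markovBlanket(net, sc$changedEdge[2]))
    }, TRUE)
    expect_true(all(linked))
})

test_that("identical regimes leave the contrast isolated", {
    sc <- defaultContrastBase()
    isolated <- vapply(1:3, function(sd) {
        r0 <- sampleBN(sc$base, 4000, seed = 9000 + sd)
        r1 <- sampleBN(sc$base, 4000, seed = 9500 + sd)
        spec <- contrastSpec("Contrast", c("a", "b"),
                             c(r0 = "a", r1 = "b"))
        pooled <- poolWithContrast(list(r0 = r0, r1 = r1), spec)
        net <- buildSupergraph(pooled, "Contrast",
                               config = SearchConfig(kCandidates = 5,
                                                     restarts = 10,
                                                     seed = sd,
                                                     maxParents = 4))
        length(markovNeighborhood(net, "Contrast")@members) == 0L
    }, TRUE)
    expect_true(all(isolated))
})

test_that("a pure location shift is captured by the contrast", {
    set.seed(65)
    n <- 3000
    mk <- function(shift) {
        m <- cbind(A = rlnorm(n, 5, 0.5), B = rlnorm(n, 5, 0.5),
                   C = rlnorm(n, 5 + shift * 0.5, 0.5),
                   D = rlnorm(n, 5, 0.5))
        flowSet(m)
    }
    spec <- contrastSpec("Contrast", c("ref", "shifted"),
                         c(d0 = "ref", d1 = "shifted"))
    pooled <- poolWithContrast(list(d0 = mk(0), d1 = mk(1.5)), spec)
    net <- buildSupergraph(pooled, "Contrast", kBins = 8,
                           config = SearchConfig(kCandidates = 3,
                                                 restarts = 5, seed = 1,
                                                 maxParents = 3))
    mn <- markovNeighborhood(net, "Contrast")
    expect_true("C" %in% mn@members)
})

test_that("contrast reports cover linked and isolated nodes", {
    es <- data.frame(from = c("X", "Contrast"), to = c("Contrast", "Y"),
                     strength = c(5, 2))
    net <- new("BayesianNetwork",
               nodes = c("Contrast", "X", "Y", "Day"),
               nLevels = c(Contrast = 4L, X = 3L, Y = 3L, Day = 2L),
               parents = list(Contrast = "X", X = character(),
                              Y = "Contrast", Day = character()),
               cpts = list(),
               familyScores = c(Contrast = 0, X = 0, Y = 0, Day = 0),
               edgeStrengths = es, ess = 1)
    rep1 <- contrastReport(net, c("Contrast", "Day"))
    expect_setequal(rep1$Contrast$neighborhood@members, c("X", "Y"))
    expect_true(rep1$Contrast$differentiating)
    expect_false(rep1$Day$differentiating)
    expect_length(rep1$Day$neighborhood@members, 0L)
    expect_error(contrastReport(net, "Nope"), "Nope")
})

test_that("network diffs report additions, sharing and flips", {
    mkNet <- function(parents, strengths) {
        nodes <- c("A", "B", "C")
        es <- do.call(rbind, lapply(names(parents), function(v)
            if (length(parents[[v]]))
                data.frame(from = parents[[v]], to = v,
                           strength = strengths[paste(parents[[v]], v)])))
        if (is.null(es))
            es <- data.frame(from = character(), to = character(),
                             strength = numeric())
        pl <- stats::setNames(
            lapply(nodes, function(v)
                if (is.null(parents[[v]])) character() else parents[[v]]),
            nodes)
        new("BayesianNetwork", nodes = nodes,
            nLevels = c(A = 2L, B = 2L, C = 2L), parents = pl,
            cpts = list(), familyScores = c(A = 0, B = 0, C = 0),
            edgeStrengths = es, ess = 1)
    }
    n1 <- mkNet(list(B = "A"), c("A B" = 3))
    n2 <- mkNet(list(B = "A", C = "B"), c("A B" = 2.5, "B C" = 4))
    d <- diffNetworks(n1, n2)
    expect_identical(nrow(d$onlyA), 0L)
    expect_identical(paste(d$onlyB$from, d$onlyB$to), "B C")
    expect_identical(nrow(d$shared), 1L)
    expect_false(d$shared$directionFlip)
    # identical nets: empty difference
    d2 <- diffNetworks(n2, n2)
    expect_identical(nrow(d2$onlyA) + nrow(d2$onlyB), 0L)
    expect_identical(nrow(d2$shared), 2L)
    # direction flip on a shared skeleton edge
    n3 <- mkNet(list(A = "B"), c("B A" = 3))
    d3 <- diffNetworks(n1, n3)
    expect_true(d3$shared$directionFlip)
    # node mismatch
    n4 <- new("BayesianNetwork", nodes = c("A", "B"),
              nLevels = c(A = 2L, B = 2L),
              parents = list(A = character(), B = character()),
              cpts = list(), familyScores = c(A = 0, B = 0),
              edgeStrengths = data.frame(from = character(),
                                         to = character(),
                                         strength = numeric()),
              ess = 1)
    expect_error(diffNetworks(n1, n4), "node set")
})
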