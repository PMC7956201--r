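# Generators: ancestral sampling, exact edge-removal marginalization, and
# the cohort simulator.

test_that("deterministic CPTs force constant columns", {
    onehot <- function(r, k) {
        m <- matrix(0, r, 1); m[k, 1] <- 1
        rownames(m) <- as.character(seq_len(r) - 1L)
        m
    }
    net <- new("BayesianNetwork", nodes = c("A", "B"),
               nLevels = c(A = 3L, B = 3L),
               parents = list(A = character(), B = character()),
               cpts = list(A = onehot(3, 2), B = onehot(3, 3)),
               familyScores = c(A = 0, B = 0),
               edgeStrengths = data.frame(from = character(),
                                          to = character(),
                                          strength = numeric()),
               ess = 1)
    s <- sampleBN(net, 50, seed = 1)
    expect_true(all(binLabels(s)["A", ] == 1L))
    expect_true(all(binLabels(s)["B", ] == 2L))
})

test_that("root frequencies concentrate at the CPT probabilities", {
    p <- c(0.2, 0.8)
    net <- new("BayesianNetwork", nodes = "A", nLevels = c(A = 2L),
               parents = list(A = character()),
               cpts = list(A = matrix(p, 2, 1,
                                      dimnames = list(c("0", "1"), NULL))),
               familyScores = c(A = 0),
               edgeStrengths = data.frame(from = character(),
                                          to = character(),
                                          strength = numeric()),
               ess = 1)
    n <- 1e5
    s <- sampleBN(net, n, seed = 2)
    phat <- mean(binLabels(s)["A", ] == 1L)
    expect_lt(abs(phat - 0.8), 3 * sqrt(0.8 * 0.2 / n))
})

test_that("sampling is seed-deterministic and CPTs are required", {
    net <- randomDiscreteNetwork(4, seed = 3)
    s1 <- sampleBN(net, 100, seed = 9)
    s2 <- sampleBN(net, 100, seed = 9)
    expect_identical(binLabels(s1), binLabels(s2))
    broken <- net
    broken@cpts[["V2"]] <- NULL
    expect_error(sampleBN(broken, 10, seed = 1), "V2")
})

test_that("CPTs re-estimated from large samples recover the truth", {
    net <- randomDiscreteNetwork(5, nLevels = 3, maxParents = 2,
                                 edgeProb = 0.5, contrast = 0.8, seed = 11)
    samp <- sampleBN(net, 1e5, seed = 12)
    ld <- list(X = t(binLabels(samp)) + 1L, cards = nLevels(samp))
    for (v in bnNodes(net)) {
        pa <- bnParents(net, v)
        truth <- cpt(net, v)
        est <- prop.table(table(
            factor(binLabels(samp)[v, ], levels = 0:2)), margin = NULL)
        if (!length(pa)) {
            tv <- sum(abs(as.numeric(est) - truth[, 1])) / 2
            expect_lt(tv, 0.02)
        } else {
            # per-parent-configuration total variation
            cfgAll <- interaction(as.data.frame(t(
                binLabels(samp)[pa, , drop = FALSE])), drop = FALSE)
            for (j in seq_len(ncol(truth))) {
                lev <- levels(cfgAll)[j]
                sel <- cfgAll == lev
                if (sum(sel) < 2000) next   # sparse configs are noisy
                estj <- prop.table(table(
                    factor(binLabels(samp)[v, sel], levels = 0:2)))
                expect_lt(sum(abs(as.numeric(estj) - truth[, j])) / 2,
                          0.02)
            }
        }
    }
})

test_that("removing a chain edge restores the base marginal exactly", {
    # A -> B -> C: dropping B -> C must leave C at its base marginal
    net <- randomDiscreteNetwork(3, nLevels = 3, maxParents = 1,
                                 edgeProb = 1, contrast = 0.9, seed = 31)
    # identify the chain orientation actually generated
    es <- arcs(net)
    expect_identical(nrow(es), 2L)
    mid <- intersect(es$from, es$to)
    last <- setdiff(es$to, mid)
    first <- setdiff(es$from, mid)
    cut <- removeEdge(net, mid, last)
    expect_length(bnParents(cut, last), 0L)
    # analytic marginal of the sink: sum_a P(a) P(m|a) P(c|m)
    pa <- cpt(net, first)[, 1]
    pm <- cpt(net, mid) %*% pa
    pc <- cpt(net, last) %*% pm
    expect_equal(unname(cpt(cut, last)[, 1]), unname(as.numeric(pc)),
                 tolerance = 1e-12)
})

test_that("removing an inert edge leaves the distribution unchanged", {
    # child CPT constant across the parent's states
    theta <- matrix(c(0.3, 0.7, 0.3, 0.7), 2, 2,
                    dimnames = list(c("0", "1"), NULL))
    root <- matrix(c(0.4, 0.6), 2, 1, dimnames = list(c("0", "1"), NULL))
    net <- new("BayesianNetwork", nodes = c("A", "B"),
               nLevels = c(A = 2L, B = 2L),
               parents = list(A = character(), B = "A"),
               cpts = list(A = root, B = theta),
               familyScores = c(A = 0, B = 0),
               edgeStrengths = data.frame(from = "A", to = "B",
                                          strength = NA_real_),
               ess = 1)
    cut <- removeEdge(net, "A", "B")
    expect_equal(unname(cpt(cut, "B")[, 1]), c(0.3, 0.7),
                 tolerance = 1e-12)
})

test_that("the cohort simulator emits the full annotated study design", {
    spec <- smallCohortSpec(100L)
    sim <- simulateCohort(spec, seed = 5)
    cells <- sim$cells
    expect_identical(nCells(cells), 13L * 2L * 100L)
    cd <- cellData(cells)
    expect_identical(length(unique(cd$patient_id)), 13L)
    expect_setequal(unique(cd$day), c(1L, 21L))
    respPatients <- unique(cd$patient_id[cd$response == "responder"])
    expect_length(respPatients, 4L)
    expect_true(all(cd$tsize[cd$response == "responder"] < -25))
    expect_true(all(cd$tsize[cd$response == "nonresponder"] >= -25))
    expect_true(all(intensities(cells) > 0))  # log-normal intensities
    # deterministic
    sim2 <- simulateCohort(spec, seed = 5)
    expect_equal(intensities(sim2$cells), intensities(cells))
})

test_that("effects drive the distance table; no effects, no signal", {
    spec <- smallCohortSpec(400L)
    sim <- simulateCohort(spec, seed = 21)
    d1 <- sim$cells[, cellData(sim$cells)$day == 1]
    tab <- markerDistanceTable(d1)
    expect_identical(tab$marker[1], "M01")
    # a null cohort: drop all effects
    null <- spec
    null@shiftEffects <- data.frame(marker = character(),
                                    regime = character(),
                                    shift = numeric())
    null@edgeEffects <- data.frame(from = character(), to = character(),
                                   regime = character())
    sim0 <- simulateCohort(null, seed = 21)
    d0 <- sim0$cells[, cellData(sim0$cells)$day == 1]
    tab0 <- markerDistanceTable(d0)
    expect_gt(tab$emd[1], 5 * max(tab0$emd))
})

test_that("contrast scenarios feed the supergraph interface", {
    sc <- defaultContrastBase()
    scen <- makeContrastScenario(sc$base, sc$changedEdge, 200, seed = 8)
    expect_identical(nCells(scen$regime0), 200L)
    expect_identical(rownames(scen$regime0), rownames(scen$regime1))
    expect_false(sc$changedEdge[1] %in%
                     bnParents(scen$altered, sc$changedEdge[2]))
    spec <- contrastSpec("Contrast", c("a", "b"), c(x = "a", y = "b"))
    pooled <- poolWithContrast(list(x = scen$regime0, y = scen$regime1),
                               spec)
    expect_identical(nCells(pooled), 400L)
})
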