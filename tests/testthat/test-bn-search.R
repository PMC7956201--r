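# Hill climbing with random restarts: recovery, sparsity, determinism,
# edge strengths, and the bin-count density trend.

test_that("a strong pairwise dependence is recovered", {
    net0 <- randomDiscreteNetwork(2, nLevels = 3, edgeProb = 1,
                                  contrast = 0.9, seed = 3)
    s <- sampleBN(net0, 5000, seed = 1)
    fit <- learnNetwork(s, config = SearchConfig(kCandidates = 1,
                                                 maxParents = 1,
                                                 restarts = 3, seed = 1))
    expect_identical(skeletonOf(fit), skeletonOf(net0))
})

test_that("independent columns yield an empty or near-empty graph", {
    counts <- vapply(1:10, function(sd) {
        set.seed(4000 + sd)
        lab <- matrix(sample(0L:7L, 6 * 5000, TRUE), 6,
                      dimnames = list(paste0("X", 1:6), NULL))
        d <- DiscretizedCells(lab)
        net <- learnNetwork(d, config = SearchConfig(kCandidates = 5,
                                                     restarts = 5,
                                                     seed = sd,
                                                     maxParents = 3))
        nrow(arcs(net))
    }, 0L)
    expect_true(all(counts <= 1L))
})

test_that("the search is deterministic given the seed", {
    set.seed(44)
    lab <- rbind(A = sample(0L:2L, 800, TRUE))
    lab <- rbind(lab, B = (lab["A", ] + sample(0L:1L, 800, TRUE)) %% 3L,
                 C = sample(0L:2L, 800, TRUE))
    d <- DiscretizedCells(lab)
    cfg <- SearchConfig(kCandidates = 2, restarts = 5, seed = 99,
                        maxParents = 2)
    f1 <- learnNetwork(d, config = cfg)
    f2 <- learnNetwork(d, config = cfg)
    expect_identical(f1@parents, f2@parents)
    expect_identical(networkScore(f1), networkScore(f2))
})

test_that("structure recovery reaches the true skeleton on 8-node nets", {
    # light version (3 seeds); the acceptance suite runs the full protocol
    ok <- vapply(1:3, function(sd) {
        truth <- randomDiscreteNetwork(8, nLevels = 3, maxParents = 2,
                                       edgeProb = 0.4, contrast = 0.8,
                                       seed = 100 + sd)
        samp <- sampleBN(truth, 10000, seed = 200 + sd)
        fit <- learnNetwork(samp,
                            config = SearchConfig(kCandidates = 7,
                                                  restarts = 10,
                                                  seed = sd,
                                                  maxParents = 4))
        skeletonSHD(skeletonOf(truth), skeletonOf(fit)) <= 2L
    }, TRUE)
    expect_true(all(ok))
})

test_that("every retained edge has positive strength and is local", {
    truth <- randomDiscreteNetwork(5, nLevels = 3, maxParents = 2,
                                   edgeProb = 0.6, contrast = 0.85,
                                   seed = 21)
    samp <- sampleBN(truth, 3000, seed = 5)
    fit <- learnNetwork(samp, config = SearchConfig(kCandidates = 4,
                                                    restarts = 5, seed = 2,
                                                    maxParents = 3))
    es <- arcs(fit)
    expect_gt(nrow(es), 0L)
    expect_true(all(es$strength > 0))
    # strengths recompute identically through the exported accessor
    for (i in seq_len(nrow(es)))
        expect_equal(edgeStrength(fit, samp, es$from[i], es$to[i]),
                     es$strength[i], tolerance = 1e-9)
    expect_error(edgeStrength(fit, samp, es$to[1], "nonexistent"),
                 "not present|unknown")
    # decomposability: total equals the family-score sum
    expect_equal(networkScore(fit), sum(fit@familyScores),
                 tolerance = 1e-9)
})

test_that("stronger CPT contrast yields larger edge strength", {
    mk <- function(contrast, seed) {
        net <- randomDiscreteNetwork(2, nLevels = 2, edgeProb = 1,
                                     contrast = contrast, seed = 1)
        samp <- sampleBN(net, 5000, seed = seed)
        fit <- learnNetwork(samp, config = SearchConfig(kCandidates = 1,
                                                        maxParents = 1,
                                                        restarts = 3,
                                                        seed = 1))
        if (!nrow(arcs(fit))) 0 else max(arcs(fit)$strength)
    }
    expect_gt(mk(0.9, 11), mk(0.6, 11))
})

test_that("CPT columns are normalized posterior means", {
    truth <- randomDiscreteNetwork(3, nLevels = 3, maxParents = 1,
                                   edgeProb = 1, contrast = 0.9, seed = 2)
    samp <- sampleBN(truth, 2000, seed = 3)
    fit <- learnNetwork(samp, config = SearchConfig(kCandidates = 2,
                                                    restarts = 3, seed = 1,
                                                    maxParents = 2))
    for (v in bnNodes(fit)) {
        theta <- cpt(fit, v)
        expect_true(all(abs(colSums(theta) - 1) < 1e-9))
        expect_true(all(theta > 0))   # Dirichlet smoothing: no zero rows
    }
})

test_that("more bins lower the edge density on continuous data", {
    spec <- smallCohortSpec(150L)
    trend <- vapply(1:3, function(sd) {
        sim <- simulateCohort(spec, seed = 300 + sd)
        d1 <- sim$cells[, cellData(sim$cells)$day == 1]
        cfg <- function(s) SearchConfig(kCandidates = 6, restarts = 5,
                                        seed = s, maxParents = 3)
        e2 <- nrow(arcs(learnNetwork(d1, kBins = 2, config = cfg(sd))))
        e8 <- nrow(arcs(learnNetwork(d1, kBins = 8, config = cfg(sd))))
        c(e2, e8)
    }, c(0, 0))
    expect_lte(mean(trend[2, ]), mean(trend[1, ]))
})

test_that("learning from a full panel covers markers plus response", {
    spec <- smallCohortSpec(80L)
    sim <- simulateCohort(spec, seed = 77)
    d1 <- sim$cells[, cellData(sim$cells)$day == 1]
    net <- learnNetwork(d1, kBins = 3,
                        config = SearchConfig(kCandidates = 5,
                                              restarts = 3, seed = 1,
                                              maxParents = 3),
                        extraVars = "response")
    expect_length(bnNodes(net), 15L)
    expect_true("response" %in% bnNodes(net))
})
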