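test_that("FCS files round-trip through write and read", {
    m <- matrix(c(1.5, 2.25, 100.125, 0.5, 3.75, 2048), nrow = 3,
                dimnames = list(NULL, c("CD4", "TIGIT")))
    path <- withr::local_tempfile(fileext = ".fcs")
    writeFCS(m, path)
    fs <- readFCS(path, patient_id = "P01", day = 1L, tsize = -30)
    expect_s4_class(fs, "FlowCellSet")
    expect_identical(dim(intensities(fs)), c(3L, 2L))
    expect_identical(markerNames(fs), c("CD4", "TIGIT"))
    # float32 storage: round-trip within single precision
    expect_equal(unname(intensities(fs)), unname(m), tolerance = 1e-6)
    expect_identical(as.character(cellData(fs)$response[1]), "responder")
})

test_that("larger random matrices survive the float32 round-trip", {
    set.seed(17)
    m <- matrix(rexp(200 * 4, rate = 1 / 500), ncol = 4,
                dimnames = list(NULL, paste0("M", 1:4)))
    m[5, 2] <- -12.5        # compensation can produce negatives
    path <- withr::local_tempfile(fileext = ".fcs")
    writeFCS(m, path)
    fs <- readFCS(path, patient_id = "P02", day = 21L, tsize = 10)
    expect_equal(unname(intensities(fs)), unname(m), tolerance = 1e-6)
    expect_identical(as.character(cellData(fs)$response[1]),
                     "nonresponder")
})

test_that("duplicate parameter names are rejected at read time", {
    m <- matrix(1:6, nrow = 3, dimnames = list(NULL, c("A", "A")))
    path <- withr::local_tempfile(fileext = ".fcs")
    writeFCS(m, path)
    expect_error(readFCS(path), "duplicate parameter names")
})

test_that("malformed files fail with a format error", {
    path <- withr::local_tempfile(fileext = ".fcs")
    writeLines("this is not an fcs file at all, padded to length", path)
    expect_error(readFCS(path), "FCS")
})

test_that("delimited tables load with derived response labels", {
    path <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("patient_id,day,tsize,CD4,CD8",
                 "P01,1,-30,1200,400",
                 "P01,1,-30,900,800",
                 "P02,1,-10,1100,350",
                 "P02,1,-10,1000,420"), path)
    fs <- readCellTable(path, c("CD4", "CD8"))
    expect_identical(dim(intensities(fs)), c(4L, 2L))
    # responder iff tsize < -25
    expect_identical(as.character(cellData(fs)$response),
                     c("responder", "responder",
                       "nonresponder", "nonresponder"))
})

test_that("table loading reports missing and non-numeric columns", {
    path <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("patient_id,day,tsize,CD4",
                 "P01,1,-30,1200",
                 "P01,1,-30,oops"), path)
    expect_error(readCellTable(path, c("CD4", "CD8")), "CD8")
    expect_error(readCellTable(path, "CD4"), "row 2")
    expect_error(
        readCellTable(path, "CD4",
                      annotationColumns = list(patient_id = "subject")),
        "subject")
})

test_that("threshold gating selects and excludes by the 4-bit pattern", {
    cut <- panelCutoffs("Adaptive")
    m <- rbind(
        c(1200, 500, 200, 1500, 5),   # 1011 -> NaiveCD4
        c(900, 1200, 160, 400, 6),    # 0110 -> NonNaiveCD8
        c(1200, 1200, 200, 1500, 7),  # 1111 -> no subset
        c(100, 100, 10, 10, 8))       # 0000 -> no subset
    colnames(m) <- c("CD4", "CD8", "CCR7", "CD45RA", "TIGIT")
    fs <- flowSet(m)
    naive4 <- stratifyCellType(fs, cut, cellTypeRule("NaiveCD4"))
    expect_identical(nCells(naive4), 1L)
    expect_identical(markerNames(naive4), "TIGIT")  # gating markers dropped
    expect_identical(unname(intensities(naive4)[1, 1]), 5)
    nn8 <- stratifyCellType(fs, cut, cellTypeRule("NonNaiveCD8"))
    expect_identical(unname(intensities(nn8)[1, 1]), 6)
    expect_warning(
        nn4 <- stratifyCellType(fs, cut, cellTypeRule("NonNaiveCD4")),
        "no cells")
    expect_identical(nCells(nn4), 0L)
})

test_that("subset rules partition matching cells and gating is idempotent", {
    set.seed(23)
    n <- 400
    m <- cbind(CD4 = runif(n, 0, 2000), CD8 = runif(n, 0, 2000),
               CCR7 = runif(n, 0, 300), CD45RA = runif(n, 0, 2000),
               X = rnorm(n, 100))
    fs <- flowSet(m)
    cut <- panelCutoffs("Checkpoint")
    rules <- c("NaiveCD4", "NaiveCD8", "NonNaiveCD4", "NonNaiveCD8")
    counts <- integer(4)
    for (i in seq_along(rules)) {
        sub <- suppressWarnings(
            stratifyCellType(fs, cut, cellTypeRule(rules[i])))
        counts[i] <- nCells(sub)
    }
    bits <- cbind(m[, "CD4"] >= 1500, m[, "CD8"] >= 750,
                  m[, "CCR7"] >= 150, m[, "CD45RA"] >= 400)
    pat <- apply(bits, 1, function(b) paste0(as.integer(b), collapse = ""))
    inAny <- pat %in% c("1011", "0111", "1010", "1001", "1000",
                        "0110", "0101", "0100")
    expect_identical(sum(counts), sum(inAny))  # partition, no double counting
    # idempotence on the kept cells' identity (gating markers are consumed)
    sub <- stratifyCellType(fs, cut, cellTypeRule("NonNaiveCD4"))
    expect_identical(nCells(sub), sum(pat %in% c("1010", "1001", "1000")))
})

test_that("intensity exactly at the cutoff counts as high", {
    cut <- panelCutoffs("Checkpoint")
    m <- cbind(CD4 = 1500, CD8 = 750, CCR7 = 150, CD45RA = 400, X = 1)
    fs <- flowSet(m)
    # pattern 1111: selected by no rule, so NaiveCD4 must warn-empty ...
    expect_warning(stratifyCellType(fs, cut, cellTypeRule("NaiveCD4")))
    # ... but lowering CD8 and CCR7 below cutoff gives 1001 -> NonNaiveCD4
    m2 <- cbind(CD4 = 1500, CD8 = 749.99, CCR7 = 149.99, CD45RA = 400,
                X = 1)
    fs2 <- flowSet(m2)
    expect_identical(
        nCells(stratifyCellType(fs2, cut, cellTypeRule("NonNaiveCD4"))),
        1L)
})

test_that("missing gating markers are reported", {
    fs <- flowSet(cbind(CD4 = c(1, 2), CD8 = c(1, 2), TIGIT = c(1, 2)))
    expect_error(
        stratifyCellType(fs, panelCutoffs("Adaptive"),
                         cellTypeRule("NaiveCD4")),
        "CCR7")
})

test_that("cell tables round-trip through write and read", {
    set.seed(4)
    m <- matrix(round(rexp(20, 1 / 300), 3), ncol = 2,
                dimnames = list(NULL, c("M1", "M2")))
    fs <- flowSet(m)
    path <- withr::local_tempfile(fileext = ".csv")
    writeCellTable(fs, path)
    back <- readCellTable(path, c("M1", "M2"))
    expect_equal(unname(intensities(back)), unname(m))
    expect_identical(as.character(cellData(back)$response),
                     as.character(cellData(fs)$response))
})
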