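test_that("the published supportive-vs-unsupportive pattern is recovered", {
    tab <- loadTable1()
    rep <- differentialReport(tab, supportive = "ihPSF",
                              unsupportive = "hPSF")
    ## basement-membrane components detected in ihPSF but not hPSF
    expect_true(all(c("HSPG2", "FBN1", "COL4A1", "COL4A2", "COL12A1",
                      "LAMA5", "LAMB1", "LAMC1", "NID1") %in%
                    rep@uniqueToSupportive))
    ## every hPSF-detected protein of the table is also in ihPSF
    expect_length(rep@uniqueToUnsupportive, 0L)

    enr <- structure(rep@enriched$foldChange,
                     names = rep@enriched$protein)
    expect_equal(round(enr[["FN1"]]), 24)
    expect_true(all(c("COL1A1", "CYR61", "THBS1", "COL6A1", "COL6A2",
                      "COL6A3") %in% names(enr)))
    expect_true(all(rep@enriched$foldChange > 2))
})

test_that("overlapping groups and unknown samples are configuration errors", {
    tab <- loadTable1()
    expect_error(differentialReport(tab, "ihPSF", "ihPSF"), "overlap")
    expect_error(differentialReport(tab, "ihPSF", "nope"), "unknown")
})

test_that("swapping the groups swaps unique sets and inverts folds", {
    tab <- loadTable1()
    fwd <- differentialReport(tab, "ihPSF", "hPSF")
    rev <- differentialReport(tab, "hPSF", "ihPSF")
    expect_setequal(fwd@uniqueToSupportive, rev@uniqueToUnsupportive)
    expect_setequal(fwd@uniqueToUnsupportive, rev@uniqueToSupportive)
    shared <- intersect(fwd@folds$protein, rev@folds$protein)
    expect_equal(
        fwd@folds$foldChange[match(shared, fwd@folds$protein)],
        1 / rev@folds$foldChange[match(shared, rev@folds$protein)])
})

test_that("class filtering and group rules restrict the report", {
    tab <- loadTable1()
    cls <- c(FN1 = "extracellular", HSPG2 = "extracellular",
             KRT1 = "cell_surface", AGRN = "other")
    rep <- differentialReport(tab, "ihPSF", "hPSF", classes = cls)
    expect_true(all(c(rep@uniqueToSupportive, rep@enriched$protein) %in%
                    c("FN1", "HSPG2", "KRT1")))

    ## multi-sample group with all vs any detection rules
    repAll <- differentialReport(tab, c("ihPSF", "HUES1"), "hPSF")
    repAny <- differentialReport(tab, c("ihPSF", "HUES1"), "hPSF",
                                 groupRule = "any")
    expect_true(all(repAll@uniqueToSupportive %in%
                    repAny@uniqueToSupportive))
    ## LAMA1 is HUES1-only: unique under "any" but not under "all"
    expect_false("LAMA1" %in% repAll@uniqueToSupportive)
    expect_true("LAMA1" %in% repAny@uniqueToSupportive)
})

test_that("candidate ranking is deterministic and degree-aware", {
    tab <- loadTable1()
    deg <- c(FN1 = 50, HSPG2 = 20, LAMB1 = 10)
    rep <- differentialReport(tab, "ihPSF", "hPSF", degrees = deg)
    r <- rep@ranking
    ## unique-to-supportive candidates come first
    expect_true(all(which(r$category == "unique_to_supportive") <
                    min(which(r$category == "enriched_in_supportive"))))
    ## within enriched, descending fold
    enr <- r$foldChange[r$category == "enriched_in_supportive"]
    expect_true(all(diff(enr) <= 0))
    ## identical call yields identical ranking
    rep2 <- differentialReport(tab, "ihPSF", "hPSF", degrees = deg)
    expect_identical(r, rep2@ranking)
})

test_that("planted unique and enriched proteins are recovered on synthetic data", {
    recovered <- 0L
    nRuns <- 12L
    for (seed in seq_len(nRuns)) {
        truth <- studyGroundTruth(seed = seed)
        reports <- simulateReports(truth)
        acc <- acceptIdentifications(reports)$accepted
        mat <- buildAbundanceMatrix(acc[!acc$is_decoy, ])
        rep <- differentialReport(mat, "supportive", "unsupportive",
                                  foldThreshold = 2)
        planted <- names(which(
            truth@compositions$unsupportive == 0 &
            truth@compositions$supportive *
                truth@totalSpectra >= 10))
        uniqueOk <- all(planted %in% rep@uniqueToSupportive)
        ## planted folds of 24 and 7 must be flagged enriched
        enrichedOk <- all(c("ECM001", "ECM002") %in% rep@enriched$protein)
        if (uniqueOk && enrichedOk) recovered <- recovered + 1L
    }
    expect_gte(recovered / nRuns, 0.95)
})
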