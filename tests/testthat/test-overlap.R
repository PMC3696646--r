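test_that("euler cardinalities match the enumeration oracle", {
    rep <- eulerCardinalities(list(A = c("x", "y"), B = c("y", "z")))
    expect_equal(rep@regionCardinalities,
                 c(A = 1L, B = 1L, "A&B" = 1L))

    set.seed(11)
    for (i in 1:10) {
        k <- sample(2:4, 1)
        sets <- lapply(seq_len(k), function(j)
            sample(letters[1:12], sample(0:8, 1)))
        names(sets) <- LETTERS[seq_len(k)]
        if (!length(unlist(sets))) next
        rep <- eulerCardinalities(sets)
        expect_equal(rep@regionCardinalities, bruteRegions(sets))
        expect_equal(sum(rep@regionCardinalities),
                     length(unique(unlist(sets))))
        expect_equal(rep@pairwiseShared, t(rep@pairwiseShared))
    }
})

test_that("degenerate set configurations behave", {
    same <- eulerCardinalities(list(A = c("x", "y"), B = c("x", "y")))
    nz <- same@regionCardinalities[same@regionCardinalities > 0]
    expect_equal(nz, c("A&B" = 2L))

    disj <- eulerCardinalities(list(A = "x", B = "y"))
    expect_equal(disj@regionCardinalities[["A&B"]], 0L)

    six <- setNames(replicate(6, "x", simplify = FALSE), letters[1:6])
    expect_error(eulerCardinalities(six), "five")
})

test_that("sharing with HUES1 reproduces the published statistics", {
    tab <- loadTable1()
    real <- rownames(tab)[!rowData(tab)$notInReference]
    tab <- tab[real, ]

    human <- sharedWithReference(tab, "HUES1", c("ihPSF", "hPSF"))
    expect_equal(human$referenceSize, 35L)
    expect_equal(unname(human$counts), c(20L, 10L))
    expect_equal(round(unname(human$percent)), c(57, 29))

    mefs <- sharedWithReference(tab, "HUES1",
                                c("CD1_P4", "CD1_P9", "MF1xCD1_P4",
                                  "MF1xCD1_P9"))
    expect_equal(unname(mefs$counts), c(11L, 13L, 15L, 13L))
    expect_equal(mefs$meanCount, 13.0)
    expect_equal(round(mefs$sdCount, 1), 1.6)
    expect_equal(round(mefs$meanPercent), 37)
    expect_equal(round(mefs$sdPercent, 1), 4.7)

    ## brute-force cross-check of every shared count
    de <- detected(tab)
    for (s in c("ihPSF", "hPSF", "CD1_P4")) {
        brute <- length(intersect(rownames(de)[de[, "HUES1"]],
                                  rownames(de)[de[, s]]))
        expect_equal(unname(sharedWithReference(tab, "HUES1", s)$counts),
                     brute)
    }
})

test_that("class filters and empty references are handled", {
    tab <- loadTable1()
    cls <- c(FN1 = "extracellular", THBS1 = "extracellular",
             KRT1 = "cell_surface", AGRN = "other")
    sh <- sharedWithReference(tab, "HUES1", "ihPSF", classes = cls)
    expect_equal(sh$referenceSize, 3L)      # AGRN filtered out
    sh2 <- sharedWithReference(tab, "HUES1", "ihPSF", classes = cls,
                               classFilter = "extracellular")
    expect_equal(sh2$referenceSize, 2L)
    expect_error(
        sharedWithReference(tab, "HUES1", "ihPSF",
                            classes = c(FN1 = "other")),
        "empty")
    expect_error(sharedWithReference(tab, "nope", "ihPSF"), "unknown")
})
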