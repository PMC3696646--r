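test_that("a degenerate composition yields the full spectrum budget", {
    truth <- GroundTruth(compositions = list(s1 = c(A = 1)),
                         classLabels = c(A = "extracellular"),
                         decoyRate = 0, noiseProbabilityFraction = 0,
                         noisePeptideFraction = 0,
                         totalSpectra = 100, seed = 1)
    rep <- simulateReports(truth)
    expect_equal(nrow(rep), 2L)                 # one row per replicate
    expect_equal(rep$spectrum_count, c(100L, 100L))
    expect_true(all(rep$protein_probability >= 0.99))
    expect_true(all(rep$n_unique_peptides >= 2L))
})

test_that("simulation is deterministic under a fixed seed", {
    truth <- studyGroundTruth(seed = 99)
    expect_identical(simulateReports(truth), simulateReports(truth))
    r1 <- simulateResources(truth)
    r2 <- simulateResources(truth)
    expect_identical(r1$annotations, r2$annotations)
    expect_identical(lapply(r1$edgeLists, function(e) e[order(e$a, e$b), ]),
                     lapply(r2$edgeLists, function(e) e[order(e$a, e$b), ]))
    ## a different seed changes the draw
    expect_false(identical(simulateReports(truth),
                           simulateReports(studyGroundTruth(seed = 100))))
})

test_that("spectrum counts follow the multinomial moments", {
    ## composition {A: 0.5, B: 0.5}, 10,000 spectra: mean count of A over
    ## repeated simulations within 3 SE of 5,000, SE = sqrt(n p (1-p))
    counts <- vapply(1:200, function(s) {
        truth <- GroundTruth(
            compositions = list(s1 = c(A = 0.5, B = 0.5)),
            classLabels = c(A = "extracellular", B = "other"),
            decoyRate = 0, noiseProbabilityFraction = 0,
            noisePeptideFraction = 0, nReplicates = 1L,
            totalSpectra = 10000, seed = s)
        r <- simulateReports(truth)
        r$spectrum_count[r$gene_symbol == "A"]
    }, numeric(1))
    se <- sqrt(10000 * 0.5 * 0.5)
    expect_lt(abs(mean(counts) - 5000), 3 * se / sqrt(200))
    expect_error(
        simulateReports(GroundTruth(
            compositions = list(s1 = c(A = 1)),
            classLabels = c(A = "other"), totalSpectra = 0, seed = 1)),
        "positive")
})

test_that("simulated resources are class-consistent, acyclic and hub-centred", {
    truth <- studyGroundTruth(seed = 5)
    res <- simulateResources(truth)
    cls <- truth@classLabels
    ann <- res$annotations
    for (p in names(cls)[cls == "extracellular"])
        expect_true(any(ann$term[ann$symbol == p] %in%
                        c("GO:0005576", "GO:0005615")))
    for (p in names(cls)[cls == "cell_surface"])
        expect_true(any(ann$term[ann$symbol == p] %in%
                        c("GO:0005886", "GO:0009986")))
    expect_true(isOntologyAcyclic(res$ontology))
    net <- mergeInteractomes(res$edgeLists)
    deg <- igraph::degree(net@graph)
    expect_equal(names(which.max(deg)), res$hub)
    expect_gt(deg[res$hub], max(deg[names(deg) != res$hub]))
    ## mouse aliases map back to the human symbols
    om <- res$orthologMap
    expect_setequal(om$human, names(cls))
    expect_false(any(om$mouse == om$human))
})

test_that("the full pipeline recovers ground-truth parameters", {
    ## noise channels off: the recovery bounds below model multinomial
    ## sampling error only (the noise channels are exercised elsewhere)
    truth <- studyGroundTruth(seed = 11, decoyRate = 0.05,
                              noiseProbabilityFraction = 0,
                              noisePeptideFraction = 0)
    reports <- simulateReports(truth)
    val <- acceptIdentifications(reports)
    acc <- val$accepted

    ## (i) detection sensitivity for proteins with expected count >= 5
    mat <- buildAbundanceMatrix(acc[!acc$is_decoy, ])
    for (s in names(truth@compositions)) {
        expectCount <- truth@compositions[[s]] * truth@totalSpectra
        eligible <- names(which(expectCount >= 5))
        sens <- mean(eligible %in%
                     rownames(mat)[detected(mat)[, s]])
        expect_gte(sens, 0.95)
    }

    ## (ii) estimated normalized fold changes near the planted truth.
    ## Standardized deviations over proteins x seeds: at 3 SE a rare
    ## single exceedance is expected by chance, so allow at most one.
    zs <- c()
    for (sd in c(11, 12, 13, 14)) {
        tr <- studyGroundTruth(seed = sd, noiseProbabilityFraction = 0,
                               noisePeptideFraction = 0)
        m2 <- buildAbundanceMatrix(
            acceptIdentifications(simulateReports(tr))$accepted)
        supp <- tr@compositions$supportive
        unsupp <- tr@compositions$unsupportive
        for (p in c("ECM001", "ECM002", "ECM003")) {
            est <- foldEnrichment(m2, p, "supportive",
                                  "unsupportive")$ratio
            trueFold <- supp[[p]] / unsupp[[p]]
            nS <- supp[[p]] * tr@totalSpectra
            nU <- unsupp[[p]] * tr@totalSpectra
            seLog <- sqrt((1 / nS + 1 / nU) / tr@nReplicates)
            zs <- c(zs, abs(log(est) - log(trueFold)) / seLog)
        }
    }
    expect_lte(sum(zs > 3), 1L)
    expect_lt(max(zs), 5)

    ## (iii) decoy FDR estimate within 2 SE of the configured rate
    fdr <- estimateProteinFdr(acc)
    nTargets <- sum(!acc$is_decoy)
    seFdr <- 100 * sqrt(truth@decoyRate / nTargets)
    expect_lt(abs(fdr - 100 * truth@decoyRate), 2 * seFdr)
})
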