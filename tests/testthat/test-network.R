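test_that("interactome merging symmetrizes, dedups and drops self-loops", {
    e1 <- data.frame(a = c("A", "C"), b = c("B", "C"), source = "pina")
    e2 <- data.frame(a = "B", b = "A", source = "matrixdb")
    net <- mergeInteractomes(list(e1, e2))
    g <- net@graph
    expect_equal(igraph::ecount(g), 1L)
    expect_equal(net@droppedSelfLoops, 1L)
    expect_setequal(strsplit(igraph::E(g)$sources, ",")[[1L]],
                    c("pina", "matrixdb"))

    ## disjoint edges across three sources: plain union
    lists <- list(data.frame(a = "A", b = "B", source = "s1"),
                  data.frame(a = "C", b = "D", source = "s2"),
                  data.frame(a = "E", b = "F", source = "s3"))
    expect_equal(igraph::ecount(mergeInteractomes(lists)@graph), 3L)
})

test_that("ortholog conversion maps, dedups and logs the unmapped", {
    map <- data.frame(mouse = c("Fn1", "Col1a1", "Col1a2", "Actb1",
                                "Actb2"),
                      human = c("FN1", "COL1A1", "COL1A2", "ACTB", "ACTB"))
    out <- mapOrthologs(c("Fn1", "Xyz9"), map)
    expect_equal(out$mapped, "FN1")
    expect_equal(out$unmapped, "Xyz9")
    expect_setequal(mapOrthologs(c("Col1a1", "Col1a2"), map)$mapped,
                    c("COL1A1", "COL1A2"))
    ## many-to-one collapses to a single human symbol
    expect_equal(mapOrthologs(c("Actb1", "Actb2"), map)$mapped, "ACTB")
})

test_that("topology metrics match hand calculations on canonical graphs", {
    tri <- mergeInteractomes(data.frame(a = c("A", "B", "C"),
                                        b = c("B", "C", "A"),
                                        source = "x"))
    m <- induceAndMeasure(tri, c("A", "B", "C"))
    expect_equal(m@nodeMetrics$clusteringCoefficient, rep(1, 3))
    expect_equal(m@density, 1)

    star <- mergeInteractomes(data.frame(a = "HUB",
                                         b = c("L1", "L2", "L3"),
                                         source = "x"))
    m <- induceAndMeasure(star, c("HUB", "L1", "L2", "L3"))
    hub <- m@nodeMetrics[m@nodeMetrics$symbol == "HUB", ]
    expect_equal(hub$degree, 3L)
    expect_equal(hub$clusteringCoefficient, 0)
    expect_equal(m@density, 3 / 6)
    expect_equal(m@nodeMetrics$symbol[1L], "HUB")   # hub ranking

    path <- mergeInteractomes(data.frame(a = c("A", "B"), b = c("B", "C"),
                                         source = "x"))
    m <- induceAndMeasure(path, c("A", "B", "C"))
    b <- m@nodeMetrics[m@nodeMetrics$symbol == "B", ]
    expect_equal(b$degree, 2L)
    expect_equal(b$clusteringCoefficient, 0)
    expect_equal(m@density, 2 / 3)
})

test_that("metrics equal the brute-force oracle on random graphs", {
    set.seed(17)
    for (i in 1:8) {
        n <- sample(10:50, 1)
        adj <- matrix(0L, n, n)
        idx <- which(upper.tri(adj))
        on <- sample(idx, round(0.1 * length(idx)))
        adj[on] <- 1L
        adj <- adj + t(adj)
        syms <- sprintf("N%02d", seq_len(n))
        dimnames(adj) <- list(syms, syms)
        el <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
        net <- mergeInteractomes(data.frame(a = syms[el[, 1]],
                                            b = syms[el[, 2]],
                                            source = "rand"))
        m <- induceAndMeasure(net, syms)
        oracle <- bruteTopology(adj)
        got <- m@nodeMetrics[match(syms, m@nodeMetrics$symbol), ]
        expect_equal(got$degree, unname(as.integer(oracle$degree)))
        expect_equal(got$clusteringCoefficient, unname(oracle$cc))
        expect_equal(m@density, oracle$density)
    }
})

test_that("isolated hits do not change the default density", {
    net <- mergeInteractomes(data.frame(a = c("A", "B"), b = c("B", "C"),
                                        source = "x"))
    with3 <- induceAndMeasure(net, c("A", "B", "C"))
    with4 <- induceAndMeasure(net, c("A", "B", "C", "ZZZ"))  # ZZZ isolated
    expect_equal(with4@density, with3@density)
    expect_true("ZZZ" %in% with4@nodeMetrics$symbol)
    ## include-isolates mode counts it
    incl <- induceAndMeasure(net, c("A", "B", "C", "ZZZ"),
                             includeIsolates = TRUE)
    expect_equal(incl@density, 2 * 2 / (4 * 3))
    expect_error(induceAndMeasure(net, character(0)), "empty")
})
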