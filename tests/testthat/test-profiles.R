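test_that("uncentered Pearson matches the closed form", {
    x <- c(3, 1, 4)
    expect_equal(uncenteredPearson(x, x), 1.0)
    expect_equal(uncenteredPearson(c(1, 0), c(0, 1)), 0.0)
    expect_equal(uncenteredPearson(c(1, 2), c(2, 1)), 0.8)
    ## scale invariance (no mean centering)
    expect_equal(uncenteredPearson(x, 13 * x), 1.0)
    set.seed(3)
    for (i in 1:10) {
        a <- rexp(5); b <- rexp(5); c <- runif(1, 0.1, 50)
        expect_equal(uncenteredPearson(a, c * b), uncenteredPearson(a, b))
    }
    expect_error(uncenteredPearson(c(0, 0), c(1, 2)), "zero-norm")
    expect_error(uncenteredPearson(1, 1), "length")
})

test_that("identical and orthogonal profiles cluster as expected", {
    m <- rbind(A = c(10, 1, 0), B = c(20, 2, 0), C = c(0, 0, 5))
    colnames(m) <- paste0("s", 1:3)
    cs <- clusterProteins(m, threshold = 0.5)
    expect_equal(length(clusters(cs)), 1L)
    expect_setequal(clusters(cs)[[1L]], c("A", "B"))
    expect_equal(cs@singletons, "C")
})

test_that("planted two-group partitions are recovered exactly", {
    set.seed(21)
    for (rep in 1:5) {
        ## two groups enriched in disjoint sample blocks
        g1 <- t(replicate(6, c(runif(3, 50, 100), runif(3, 0, 2))))
        g2 <- t(replicate(5, c(runif(3, 0, 2), runif(3, 50, 100))))
        m <- rbind(g1, g2)
        rownames(m) <- sprintf("P%02d", 1:11)
        colnames(m) <- sprintf("s%d", 1:6)
        perm <- sample(nrow(m))
        cs <- clusterProteins(m[perm, ], threshold = 0.5)
        expect_equal(length(clusters(cs)), 2L)
        got <- lapply(clusters(cs), sort)
        want <- list(sort(rownames(m)[1:6]), sort(rownames(m)[7:11]))
        expect_true(setequal(got, want))
    }
})

test_that("zero-norm profiles are dropped with a warning", {
    m <- rbind(A = c(1, 2), B = c(2, 4), Z = c(0, 0))
    colnames(m) <- c("s1", "s2")
    expect_warning(cs <- clusterProteins(m), "Z")
    expect_equal(cs@dropped, "Z")
    expect_false("Z" %in% cs@leafOrder)
    expect_error(
        suppressWarnings(clusterProteins(rbind(A = c(1, 1), Z = c(0, 0)))),
        "fewer than two")
})

test_that("hypergeometric p-values equal exhaustive enumeration", {
    ## closed-form spot check: all 5 draws in a 5-of-10 term
    r <- enrichCluster(paste0("p", 1:5),
                       data.frame(symbol = paste0("p", 1:5),
                                  term = "GO:X"),
                       background = paste0("p", 1:10))
    expect_equal(r$pValue, 1 / choose(10, 5), tolerance = 1e-12)

    ## enumeration oracle over random configurations, N <= 12
    set.seed(5)
    for (i in 1:15) {
        N <- sample(5:12, 1)
        n <- sample(2:(N - 1), 1)
        K <- sample(1:N, 1)
        bg <- sprintf("g%02d", seq_len(N))
        annotated <- bg[seq_len(K)]
        cluster <- sample(bg, n)
        k <- length(intersect(cluster, annotated))
        if (k == 0) next
        r <- enrichCluster(cluster,
                           data.frame(symbol = annotated, term = "GO:X"),
                           background = bg)
        expect_equal(r$pValue, bruteHyperTail(N, K, n, k),
                     tolerance = 1e-12)
    }
})

test_that("a term covering the whole background has p = 1", {
    bg <- paste0("p", 1:8)
    r <- enrichCluster(bg[1:3],
                       data.frame(symbol = bg, term = "GO:ALL"),
                       background = bg)
    expect_equal(r$pValue, 1)
    expect_false(r$significant)
})

test_that("BH adjustment is the step-up procedure", {
    ## four terms engineered to give p = 0.01, 0.02, 0.03, 0.04 is hard to
    ## construct exactly; check p.adjust behaviour through enrichCluster by
    ## comparing with a hand computation on its own p-values
    bg <- sprintf("g%02d", 1:12)
    ann <- rbind(
        data.frame(symbol = bg[1:4], term = "t1"),
        data.frame(symbol = bg[c(1:3, 5)], term = "t2"),
        data.frame(symbol = bg[c(1:2, 6:7)], term = "t3"),
        data.frame(symbol = bg[c(1, 8:10)], term = "t4"))
    r <- enrichCluster(bg[1:4], ann, background = bg)
    m <- nrow(r)
    byHand <- rev(cummin(rev(sort(r$pValue) * m / seq_len(m))))
    expect_equal(sort(r$qValue), pmin(byHand, 1))
    ## the canonical worked example of the step-up rule
    expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
                 rep(0.04, 4))
})

test_that("EASE variant is more conservative than the plain tail", {
    bg <- sprintf("g%02d", 1:10)
    ann <- data.frame(symbol = bg[1:5], term = "GO:X")
    plain <- enrichCluster(bg[1:4], ann, background = bg)
    ease <- enrichCluster(bg[1:4], ann, background = bg, ease = TRUE)
    expect_gt(ease$pValue, plain$pValue)
})

test_that("shuffled labels rarely produce significant enrichment", {
    ## null simulation: class labels carry no relation to cluster membership
    set.seed(9)
    nSig <- 0L
    nClusters <- 0L
    bg <- sprintf("g%02d", 1:30)
    for (i in 1:40) {
        ann <- data.frame(symbol = sample(bg, 15), term = "GO:NULL")
        cl <- sample(bg, 8)
        r <- enrichCluster(cl, ann, background = bg)
        nClusters <- nClusters + 1L
        if (nrow(r) && any(r$significant)) nSig <- nSig + 1L
    }
    frac <- nSig / nClusters
    se <- sqrt(0.05 * 0.95 / nClusters)
    expect_lte(frac, 0.05 + 2 * se)
})
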