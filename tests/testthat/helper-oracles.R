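## Independent brute-force oracles used across the suite.

## Exclusive-region cardinalities by direct enumeration over the union.
bruteRegions <- function(sets) {
    universe <- unique(unlist(sets, use.names = FALSE))
    out <- integer(0)
    k <- length(sets)
    for (bits in seq_len(2^k - 1L)) {
        inset <- as.logical(bitwAnd(bits, 2^(seq_len(k) - 1L)))
        cnt <- 0L
        for (u in universe) {
            member <- vapply(sets, function(s) u %in% s, logical(1))
            if (all(member == inset)) cnt <- cnt + 1L
        }
        out[paste(names(sets)[inset], collapse = "&")] <- cnt
    }
    out
}

## Local clustering coefficient and density by neighbor-pair enumeration
## over an adjacency matrix.
bruteTopology <- function(adj) {
    n <- nrow(adj)
    deg <- rowSums(adj)
    cc <- numeric(n)
    for (v in seq_len(n)) {
        nb <- which(adj[v, ] == 1)
        k <- length(nb)
        if (k < 2) { cc[v] <- 0; next }
        e <- 0L
        for (i in seq_len(k - 1))
            for (j in (i + 1):k)
                if (adj[nb[i], nb[j]] == 1) e <- e + 1L
        cc[v] <- 2 * e / (k * (k - 1))
    }
    nConn <- sum(deg > 0)
    E <- sum(adj) / 2
    dens <- if (nConn >= 2) 2 * E / (nConn * (nConn - 1)) else NA_real_
    list(degree = deg, cc = cc, density = dens)
}

## Hypergeometric upper tail by exhaustive enumeration of all n-subsets.
bruteHyperTail <- function(N, K, n, k) {
    hits <- utils::combn(N, n, function(draw) sum(draw <= K) >= k)
    mean(hits)
}

## A minimal well-formed identification record set.
makeRecords <- function(symbols, counts, sample = "s1", replicate = "r1",
                        peptides = 3L, prob = 1, decoy = FALSE,
                        species = "human") {
    data.frame(sample_id = sample, replicate_id = replicate,
               accession = paste0("ACC_", symbols, "_", sample, "_",
                                  replicate),
               gene_symbol = symbols, species = species,
               n_unique_peptides = peptides, protein_probability = prob,
               spectrum_count = counts, is_decoy = decoy,
               stringsAsFactors = FALSE)
}
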