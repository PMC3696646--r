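## Interactome merging, ortholog conversion, subnetwork induction and
## topology metrics.

#' Merge interactome edge lists into one undirected network
#'
#' Takes any number of edge lists (e.g. a genome-scale protein
#' interaction network, an ECM-specific interaction database, and a
#' curated adhesion-complex set), symmetrizes them (A-B and B-A collapse
#' to one undirected edge), drops self-loops (counted), deduplicates, and
#' records per-edge source provenance as a comma-joined \code{sources}
#' edge attribute.
#'
#' @param edgeLists a data.frame with columns \code{a}, \code{b},
#'   \code{source}, or a list of such data.frames (see
#'   \code{\link{readEdgeList}}).
#' @return An \code{\linkS4class{InteractionNetwork}} (metrics unset
#'   until \code{\link{induceAndMeasure}}).
#'
#' @examples
#' e1 <- data.frame(a = "A", b = "B", source = "pina")
#' e2 <- data.frame(a = "B", b = "A", source = "matrixdb")
#' net <- mergeInteractomes(list(e1, e2))
#' net
#'
#' @export
mergeInteractomes <- function(edgeLists) {
    if (is.data.frame(edgeLists))
        edgeLists <- list(edgeLists)
    if (!length(edgeLists))
        stop("at least one edge list is required")
    edges <- do.call(rbind, lapply(edgeLists, function(e) {
        if (!all(c("a", "b") %in% names(e)))
            stop("edge lists need columns 'a' and 'b'")
        if (is.null(e$source))
            e$source <- NA_character_
        e[, c("a", "b", "source")]
    }))
    loops <- edges$a == edges$b
    nLoops <- sum(loops)
    edges <- edges[!loops, , drop = FALSE]
    lo <- pmin(edges$a, edges$b)
    hi <- pmax(edges$a, edges$b)
    key <- paste(lo, hi, sep = "\r")
    sources <- vapply(split(edges$source, key), function(s)
        paste(sort(unique(s[!is.na(s)])), collapse = ","), character(1))
    uniq <- !duplicated(key)
    ed <- data.frame(a = lo[uniq], b = hi[uniq], key = key[uniq],
                     stringsAsFactors = FALSE)
    ed <- ed[order(ed$key), ]
    g <- igraph::graph_from_data_frame(ed[, c("a", "b")], directed = FALSE)
    igraph::E(g)$sources <- unname(sources[ed$key])
    new("InteractionNetwork", graph = g,
        nodeMetrics = data.frame(symbol = character(0), degree = integer(0),
                                 clusteringCoefficient = numeric(0)),
        density = NA_real_, includeIsolates = FALSE,
        droppedSelfLoops = as.integer(nLoops))
}

#' Convert mouse symbols to human orthologs
#'
#' Replaces each mouse symbol by its human ortholog from the map;
#' unmapped symbols are excluded and returned in the log, and
#' many-to-one collapses are deduplicated.
#'
#' @param symbols character vector of mouse symbols.
#' @param map data.frame with columns \code{mouse}, \code{human} (see
#'   \code{\link{readOrthologMap}}).
#' @return list with elements \code{mapped} (unique human symbols) and
#'   \code{unmapped} (mouse symbols without an ortholog).
#'
#' @examples
#' mapOrthologs(c("Fn1", "Xyz9"), data.frame(mouse = "Fn1", human = "FN1"))
#'
#' @export
mapOrthologs <- function(symbols, map) {
    lookup <- map$human[match(symbols, map$mouse)]
    unmapped <- symbols[is.na(lookup)]
    list(mapped = unique(lookup[!is.na(lookup)]), unmapped = unmapped)
}

#' Induce a hit subnetwork and compute topology metrics
#'
#' Induces the subgraph of \code{network} on the hit symbols (proteins
#' classified extracellular/cell-surface and detected in a sample), then
#' computes per-node degree \code{k(v)} and local clustering coefficient
#' \code{C(v) = 2 e(v) / (k(v) (k(v) - 1))}, where \code{e(v)} is the
#' number of edges among the neighbors of \code{v} (\code{C(v) = 0} when
#' \code{k(v) < 2}), and the global density \code{rho = 2 E / (N (N - 1))}.
#' By default \code{N} counts only connected nodes (isolated proteins are
#' not displayed in published interaction network figures); set
#' \code{includeIsolates = TRUE} to count every induced node.  Hubs are
#' ranked by descending degree with ties broken by symbol order.
#'
#' @param network an \code{\linkS4class{InteractionNetwork}}.
#' @param hits character vector of hit symbols.
#' @param includeIsolates count isolated nodes in the density denominator.
#' @return An \code{\linkS4class{InteractionNetwork}} for the induced
#'   subnetwork with \code{nodeMetrics} and \code{density} filled in.
#'
#' @examples
#' net <- mergeInteractomes(data.frame(a = c("A", "B", "C"),
#'                                     b = c("B", "C", "A"),
#'                                     source = "demo"))
#' induceAndMeasure(net, c("A", "B", "C"))
#'
#' @export
induceAndMeasure <- function(network, hits, includeIsolates = FALSE) {
    stopifnot(is(network, "InteractionNetwork"))
    if (!length(hits))
        stop("empty hit set")
    g <- network@graph
    present <- intersect(hits, igraph::V(g)$name)
    sub <- igraph::induced_subgraph(g, present)
    ## hits absent from the interactome are isolated nodes of the induced
    ## network
    missing <- setdiff(hits, present)
    if (length(missing))
        sub <- igraph::add_vertices(sub, length(missing), name = missing)
    deg <- igraph::degree(sub)
    cc <- igraph::transitivity(sub, type = "localundirected",
                               isolates = "zero")
    names(cc) <- igraph::V(sub)$name
    cc[deg < 2] <- 0
    nm <- data.frame(symbol = igraph::V(sub)$name,
                     degree = as.integer(deg),
                     clusteringCoefficient = as.numeric(cc),
                     stringsAsFactors = FALSE)
    nm <- nm[order(-nm$degree, nm$symbol), , drop = FALSE]
    rownames(nm) <- NULL
    N <- if (includeIsolates) igraph::vcount(sub) else sum(deg > 0)
    E <- igraph::ecount(sub)
    rho <- if (N >= 2) 2 * E / (N * (N - 1)) else NA_real_
    new("InteractionNetwork", graph = sub, nodeMetrics = nm,
        density = rho, includeIsolates = includeIsolates,
        droppedSelfLoops = network@droppedSelfLoops)
}

#' Export a network as an edge-list TSV
#'
#' @param network an \code{\linkS4class{InteractionNetwork}}.
#' @param path output TSV path (columns \code{a}, \code{b},
#'   \code{sources}).
#' @return \code{path}, invisibly.
#' @export
writeEdgeList <- function(network, path) {
    stopifnot(is(network, "InteractionNetwork"))
    g <- network@graph
    el <- igraph::as_edgelist(g)
    src <- igraph::E(g)$sources
    if (is.null(src))
        src <- rep(NA_character_, nrow(el))
    utils::write.table(
        data.frame(a = el[, 1], b = el[, 2], sources = src),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
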