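## Hierarchical clustering of abundance profiles with uncentered Pearson
## similarity, cluster extraction at a similarity threshold, and
## per-cluster hypergeometric GO enrichment with BH correction.

#' Uncentered Pearson correlation
#'
#' Cosine-like similarity that does not subtract means:
#' \deqn{r_u = \sum x_i y_i / \sqrt{\sum x_i^2 \sum y_i^2}.}
#' Zero-anchored and scale-invariant (\code{r_u(x, c*y) = r_u(x, y)} for
#' \code{c > 0}), which makes normalized spectrum-count profiles
#' comparable without further scaling.  The clustering distance is
#' \code{1 - r_u}.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return similarity in [-1, 1].  A zero-norm vector is an error.
#'
#' @examples
#' uncenteredPearson(c(1, 2), c(2, 1))   # 0.8
#'
#' @export
uncenteredPearson <- function(x, y) {
    if (length(x) != length(y))
        stop("vectors must have equal length")
    if (length(x) < 2L)
        stop("vectors must have length >= 2")
    nx <- sqrt(sum(x^2))
    ny <- sqrt(sum(y^2))
    if (nx == 0 || ny == 0)
        stop("uncentered Pearson is undefined for a zero-norm vector")
    sum(x * y) / (nx * ny)
}

## All pairwise uncentered Pearson similarities of the rows of a matrix.
.uncenteredSimilarity <- function(m) {
    norms <- sqrt(rowSums(m^2))
    s <- (m %*% t(m)) / outer(norms, norms)
    ## numerical guard: clamp to [-1, 1]
    s[s > 1] <- 1
    s[s < -1] <- -1
    s
}

#' Cluster proteins by abundance profile
#'
#' Agglomerative hierarchical clustering of protein abundance profiles
#' using distance \code{1 - r_u} (uncentered Pearson) and the configured
#' linkage (default average).  Clusters are the maximal subtrees whose
#' root merge similarity is at least \code{threshold}; proteins joining
#' the tree only below the threshold are reported as unclustered
#' singletons.  Proteins with all-zero profiles cannot be placed (their
#' similarity is undefined) and are dropped with a warning.  Non-detected
#' cells contribute 0 to the profile vectors.
#'
#' @param x an \code{\linkS4class{AbundanceMatrix}} or a numeric matrix
#'   (proteins x samples).
#' @param linkage one of \code{"average"}, \code{"complete"},
#'   \code{"single"}.
#' @param threshold similarity threshold for cluster extraction
#'   (default 0.5).
#' @return A \code{\linkS4class{ClusterSet}}.
#'
#' @examples
#' m <- rbind(A = c(10, 1), B = c(20, 2), C = c(1, 10))
#' colnames(m) <- c("s1", "s2")
#' clusterProteins(m)
#'
#' @export
clusterProteins <- function(x, linkage = c("average", "complete", "single"),
                            threshold = 0.5) {
    linkage <- match.arg(linkage)
    m <- if (is(x, "AbundanceMatrix")) abundance(x) else as.matrix(x)
    if (is.null(rownames(m)))
        stop("protein (row) names are required")
    norms <- sqrt(rowSums(m^2))
    dropped <- rownames(m)[norms == 0]
    if (length(dropped)) {
        warning("dropping zero-norm profile(s): ",
                paste(dropped, collapse = ", "))
        m <- m[norms > 0, , drop = FALSE]
    }
    if (nrow(m) < 2L)
        stop("fewer than two proteins with non-zero profiles")
    d <- stats::as.dist(1 - .uncenteredSimilarity(m))
    tree <- stats::hclust(d, method = linkage)
    groups <- stats::cutree(tree, h = 1 - threshold)
    leafOrder <- tree$labels[tree$order]
    byGroup <- split(names(groups), groups)
    sizes <- lengths(byGroup)
    clust <- byGroup[sizes >= 2L]
    ## deterministic cluster ids in leaf order of their first member
    if (length(clust)) {
        first <- vapply(clust, function(p)
            min(match(p, leafOrder)), numeric(1))
        clust <- clust[order(first)]
        names(clust) <- sprintf("cluster_%02d", seq_along(clust))
    }
    singletons <- unlist(byGroup[sizes == 1L], use.names = FALSE)
    if (is.null(singletons)) singletons <- character(0)
    new("ClusterSet", tree = tree, clusters = clust,
        singletons = singletons, threshold = threshold,
        leafOrder = leafOrder, dropped = dropped)
}

#' Hypergeometric GO-term enrichment of one cluster
#'
#' Upper-tail hypergeometric test per term: with \code{N} background
#' proteins, \code{K} of them annotated with the term, and \code{k} of
#' the \code{n} cluster proteins annotated,
#' \deqn{p = \sum_{i \ge k} C(K,i) C(N-K, n-i) / C(N,n),}
#' followed by Benjamini-Hochberg adjustment across all terms tested in
#' the cluster.  The optional EASE-style conservative variant replaces
#' \code{k} by \code{k - 1} in the tail.
#'
#' @param cluster character vector of cluster member symbols.
#' @param annotations data.frame with columns \code{symbol}, \code{term}
#'   (restricted by the caller to the GO domain of interest, e.g.
#'   biological process).
#' @param background character vector of background symbols (must contain
#'   the cluster).  The natural background is all classified proteins of
#'   the clustered matrix.
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @param ease use the EASE score (k - 1) variant (default \code{FALSE}).
#'
#' @return data.frame with one row per tested term: \code{term}, \code{k},
#'   \code{K}, \code{n}, \code{N}, \code{pValue}, \code{qValue},
#'   \code{significant}.  Terms annotating no background protein are
#'   skipped with a warning.
#'
#' @examples
#' ann <- data.frame(symbol = c("A", "B", "C"), term = "GO:0007155")
#' enrichCluster(c("A", "B"), ann, background = c("A", "B", "C", "D"))
#'
#' @export
enrichCluster <- function(cluster, annotations, background, alpha = 0.05,
                          ease = FALSE) {
    if (!all(cluster %in% background))
        stop("background must contain every cluster member")
    background <- unique(background)
    cluster <- unique(cluster)
    ann <- annotations[annotations$symbol %in% background, , drop = FALSE]
    outside <- setdiff(unique(annotations$term), unique(ann$term))
    if (length(outside))
        warning("term(s) absent from background skipped: ",
                paste(outside, collapse = ", "))
    terms <- unique(ann$term[ann$symbol %in% cluster])
    N <- length(background)
    n <- length(cluster)
    rows <- lapply(terms, function(t) {
        annotated <- unique(ann$symbol[ann$term == t])
        K <- length(annotated)
        k <- length(intersect(annotated, cluster))
        q <- if (ease) k - 1L else k
        p <- stats::phyper(q - 1L, K, N - K, n, lower.tail = FALSE)
        data.frame(term = t, k = k, K = K, n = n, N = N, pValue = p,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    if (is.null(out))
        out <- data.frame(term = character(0), k = integer(0), K = integer(0),
                          n = integer(0), N = integer(0), pValue = numeric(0))
    out$qValue <- stats::p.adjust(out$pValue, method = "BH")
    out$significant <- out$qValue <= alpha
    out[order(out$pValue, out$term), , drop = FALSE]
}

#' Enrichment of every cluster in a ClusterSet
#'
#' @param clusterSet a \code{\linkS4class{ClusterSet}}.
#' @param annotations annotation data.frame (\code{symbol}, \code{term}).
#' @param background background symbols; defaults to all proteins in the
#'   clustered matrix (clusters plus singletons).
#' @param ... passed to \code{\link{enrichCluster}}.
#' @return data.frame of per-cluster enrichment rows with a leading
#'   \code{cluster} column.
#' @export
enrichClusters <- function(clusterSet, annotations, background = NULL, ...) {
    stopifnot(is(clusterSet, "ClusterSet"))
    if (is.null(background))
        background <- clusterSet@leafOrder
    res <- lapply(names(clusters(clusterSet)), function(id) {
        r <- enrichCluster(clusters(clusterSet)[[id]], annotations,
                           background, ...)
        if (nrow(r))
            cbind(cluster = id, r, stringsAsFactors = FALSE)
        else NULL
    })
    res <- res[!vapply(res, is.null, logical(1))]
    if (!length(res))
        return(data.frame(cluster = character(0), term = character(0),
                          k = integer(0), K = integer(0), n = integer(0),
                          N = integer(0), pValue = numeric(0),
                          qValue = numeric(0), significant = logical(0)))
    do.call(rbind, c(res, list(make.row.names = FALSE)))
}
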