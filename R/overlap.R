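## Multi-set overlap cardinalities and shared-protein statistics.

#' Exclusive-region cardinalities for up to five protein sets
#'
#' Computes, for every non-empty subset of the input sets, the number of
#' proteins lying in exactly that subset (the numbers printed inside an
#' area-proportional Euler diagram), plus the symmetric pairwise
#' intersection counts.
#'
#' @param sets named list of character vectors (2 to 5 sets).
#' @return An \code{\linkS4class{OverlapReport}}.
#'
#' @examples
#' rep <- eulerCardinalities(list(A = c("x", "y"), B = c("y", "z")))
#' rep
#'
#' @export
eulerCardinalities <- function(sets) {
    if (length(sets) < 2L)
        stop("at least two sets are required")
    if (length(sets) > 5L)
        stop("at most five sets are supported (got ", length(sets), ")")
    if (is.null(names(sets)) || any(!nzchar(names(sets))))
        stop("sets must be named")
    sets <- lapply(sets, unique)
    k <- length(sets)
    nms <- names(sets)
    universe <- unique(unlist(sets, use.names = FALSE))
    membership <- vapply(sets, function(s) universe %in% s,
                         logical(length(universe)))
    if (length(universe) == 1L)
        membership <- matrix(membership, nrow = 1L,
                             dimnames = list(NULL, nms))
    regions <- integer(0)
    for (bits in seq_len(2^k - 1L)) {
        inset <- as.logical(bitwAnd(bits, 2^(seq_len(k) - 1L)))
        count <- sum(apply(membership, 1L, function(row)
            all(row == inset)))
        regions[paste(nms[inset], collapse = "&")] <- as.integer(count)
    }
    pair <- matrix(0L, k, k, dimnames = list(nms, nms))
    for (i in seq_len(k))
        for (j in seq_len(k))
            pair[i, j] <- length(intersect(sets[[i]], sets[[j]]))
    new("OverlapReport", sets = sets, regionCardinalities = regions,
        pairwiseShared = pair)
}

#' Proteins shared with a reference sample
#'
#' Counts the proteins of a reference sample's detected set that are also
#' detected in each of a group of other samples, expresses each count as
#' a percentage of the reference detected set, and summarizes counts and
#' percentages across the group as mean and sample standard deviation
#' (n-1 denominator).  Detection is the replicate-level mask of the
#' abundance matrix; an optional classification filter restricts the
#' analysis to, e.g., extracellular/cell-surface proteins before any
#' counting.
#'
#' @param x an \code{\linkS4class{AbundanceMatrix}}.
#' @param reference reference sample id.
#' @param others character vector of other sample ids.
#' @param classes optional named character vector of protein classes
#'   (e.g. from \code{\link{classifyProteins}}).
#' @param classFilter classes retained when \code{classes} is supplied.
#'
#' @return list with elements \code{counts} (named integer), \code{percent}
#'   (named numeric), \code{referenceSize}, \code{meanCount},
#'   \code{sdCount}, \code{meanPercent}, \code{sdPercent}.
#'
#' @examples
#' tab <- loadTable1()
#' real <- rownames(tab)[!rowData(tab)$notInReference]
#' sharedWithReference(tab[real, ], "HUES1", c("ihPSF", "hPSF"))$counts
#'
#' @export
sharedWithReference <- function(x, reference, others, classes = NULL,
                                classFilter = c("extracellular",
                                                "cell_surface")) {
    stopifnot(is(x, "AbundanceMatrix"))
    if (!reference %in% colnames(x))
        stop("unknown reference sample: ", reference)
    if (!all(others %in% colnames(x)))
        stop("unknown sample id(s): ",
             paste(setdiff(others, colnames(x)), collapse = ", "))
    de <- detected(x)
    if (!is.null(classes)) {
        keep <- rownames(de) %in% names(classes)[classes %in% classFilter]
        de <- de[keep, , drop = FALSE]
    }
    refSet <- rownames(de)[de[, reference]]
    if (!length(refSet))
        stop("reference detected set is empty; percentages undefined")
    counts <- vapply(others, function(s)
        sum(de[refSet, s]), integer(1))
    percent <- counts / length(refSet) * 100
    list(counts = counts,
         percent = percent,
         referenceSize = length(refSet),
         meanCount = mean(counts),
         sdCount = stats::sd(counts),
         meanPercent = mean(percent),
         sdPercent = stats::sd(percent))
}
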