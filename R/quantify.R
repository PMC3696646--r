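## Spectrum-count normalization, replicate averaging and fold enrichment.

#' Normalize spectrum counts within one replicate
#'
#' Expresses each accepted protein's unweighted spectrum count as a
#' percentage of the total number of spectra observed in the entire
#' sample replicate, scaled by 10^3 (unit: \% total spectra x 10^3).
#' Decoy records are excluded from both the output and the denominator:
#' they are artifacts of validation, not sample content.  Within a
#' replicate the normalized values sum to 100,000.
#'
#' @param records accepted identification records of a single sample
#'   replicate.
#' @return Named numeric vector of normalized counts per gene symbol
#'   (spectra of accessions sharing a symbol are summed before
#'   normalization).
#'
#' @examples
#' r <- data.frame(gene_symbol = c("A", "B"), spectrum_count = c(3L, 1L),
#'                 is_decoy = FALSE)
#' normalizeCounts(r)   # A 75000, B 25000
#'
#' @export
normalizeCounts <- function(records) {
    if (is.null(records) || nrow(records) == 0L)
        stop("no accepted records in replicate")
    if ("is_decoy" %in% names(records))
        records <- records[!records$is_decoy, , drop = FALSE]
    counts <- tapply(records$spectrum_count, records$gene_symbol, sum)
    counts <- counts[order(names(counts))]
    total <- sum(counts)
    if (total == 0)
        stop("total spectrum count is zero")
    v <- as.vector(counts / total * 100 * 1000)
    names(v) <- names(counts)
    v
}

#' Average normalized counts over replicates
#'
#' Arithmetic mean across all replicates of a sample, with 0 contributed
#' by replicates in which a protein was not accepted (zero-fill).  A
#' protein counts as detected when it was accepted in at least one
#' replicate.
#'
#' @param replicateVectors list of named numeric vectors, one per
#'   replicate, as returned by \code{\link{normalizeCounts}}.
#' @return data.frame with columns \code{gene_symbol}, \code{mean},
#'   \code{detected}.
#' @export
meanOverReplicates <- function(replicateVectors) {
    if (!length(replicateVectors))
        stop("at least one replicate is required")
    proteins <- sort(unique(unlist(lapply(replicateVectors, names))))
    nRep <- length(replicateVectors)
    m <- vapply(proteins, function(p) {
        sum(vapply(replicateVectors,
                   function(v) if (p %in% names(v)) v[[p]] else 0,
                   numeric(1))) / nRep
    }, numeric(1))
    data.frame(gene_symbol = proteins, mean = unname(m),
               detected = rep(TRUE, length(proteins)),
               stringsAsFactors = FALSE)
}

#' Build an abundance matrix from accepted identification records
#'
#' Normalizes each replicate (\code{\link{normalizeCounts}}), zero-fills
#' and averages over the replicates of each sample
#' (\code{\link{meanOverReplicates}}), and assembles the result into an
#' \code{\linkS4class{AbundanceMatrix}} whose detection mask records
#' acceptance in at least one replicate.
#'
#' @param accepted data.frame of accepted identification records (all
#'   samples and replicates).
#' @param samples optional sample ordering; defaults to order of first
#'   appearance.
#' @return An \code{\linkS4class{AbundanceMatrix}}.
#' @export
buildAbundanceMatrix <- function(accepted, samples = NULL) {
    if (is.null(accepted) || nrow(accepted) == 0L)
        stop("no accepted records")
    if (is.null(samples))
        samples <- unique(accepted$sample_id)
    perSample <- lapply(samples, function(s) {
        rs <- accepted[accepted$sample_id == s, , drop = FALSE]
        if (nrow(rs) == 0L)
            return(data.frame(gene_symbol = character(0), mean = numeric(0),
                              detected = logical(0)))
        reps <- split(rs, rs$replicate_id)
        meanOverReplicates(lapply(reps, normalizeCounts))
    })
    proteins <- sort(unique(unlist(lapply(perSample,
                                          function(d) d$gene_symbol))))
    ab <- matrix(0, length(proteins), length(samples),
                 dimnames = list(proteins, samples))
    de <- matrix(FALSE, length(proteins), length(samples),
                 dimnames = list(proteins, samples))
    for (i in seq_along(samples)) {
        d <- perSample[[i]]
        ab[d$gene_symbol, i] <- d$mean
        de[d$gene_symbol, i] <- d$detected
    }
    AbundanceMatrix(ab, detected = de)
}

#' Fold enrichment of one protein between two samples
#'
#' Ratio of mean normalized spectrum counts
#' \code{value(protein, numerator) / value(protein, denominator)}.  A
#' numeric ratio is reported only when the protein is detected in both
#' samples; otherwise the status flags the detection pattern
#' (\code{unique_to_numerator}, \code{unique_to_denominator},
#' \code{absent}) and the ratio is \code{NA}.
#'
#' @param x an \code{\linkS4class{AbundanceMatrix}}.
#' @param protein gene symbol.
#' @param numerator,denominator sample ids.
#' @return list with elements \code{protein}, \code{numerator},
#'   \code{denominator}, \code{ratio}, \code{status}.
#'
#' @examples
#' tab <- loadTable1()
#' foldEnrichment(tab, "FN1", "ihPSF", "hPSF")$ratio   # 24.44
#'
#' @export
foldEnrichment <- function(x, protein, numerator, denominator) {
    stopifnot(is(x, "AbundanceMatrix"))
    if (!protein %in% rownames(x))
        stop("unknown protein: ", protein)
    if (!all(c(numerator, denominator) %in% colnames(x)))
        stop("unknown sample id(s): ",
             paste(setdiff(c(numerator, denominator), colnames(x)),
                   collapse = ", "))
    dNum <- detected(x)[protein, numerator]
    dDen <- detected(x)[protein, denominator]
    status <- if (dNum && dDen) "both_detected"
              else if (dNum) "unique_to_numerator"
              else if (dDen) "unique_to_denominator"
              else "absent"
    ratio <- if (status == "both_detected")
        abundance(x)[protein, numerator] / abundance(x)[protein, denominator]
    else NA_real_
    list(protein = protein, numerator = numerator,
         denominator = denominator, ratio = ratio, status = status)
}
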