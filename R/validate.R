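## Identification filtering and decoy-based protein FDR.

#' Apply identification acceptance criteria
#'
#' Accepts a protein observation in a sample replicate when it carries at
#' least \code{minUniquePeptides} unique validated peptides and a protein
#' probability of at least \code{minProteinProbability} (closed
#' comparisons).  Acceptance is evaluated per (sample, replicate,
#' accession) row, so a protein may be accepted in one replicate and
#' rejected in another.
#'
#' @param records data.frame of identification records (see
#'   \code{\link{readIdentificationReport}} for the columns).
#' @param policy a \code{\link{ValidationPolicy}}.
#'
#' @return A list with elements \code{accepted} (data.frame of accepted
#'   records) and \code{rejected} (data.frame of rejected records with an
#'   extra \code{reason} column naming the first failed criterion,
#'   \code{"peptides"} or \code{"protein_probability"}).  An empty input
#'   yields empty output with a warning.
#'
#' @examples
#' r <- data.frame(sample_id = "s", replicate_id = "r",
#'                 accession = c("P1", "P2"), gene_symbol = c("A", "B"),
#'                 species = "human", n_unique_peptides = c(2L, 1L),
#'                 protein_probability = c(0.99, 1.0),
#'                 spectrum_count = c(10L, 5L), is_decoy = FALSE)
#' acceptIdentifications(r)$rejected$reason   # "peptides" for P2
#'
#' @export
acceptIdentifications <- function(records, policy = ValidationPolicy()) {
    stopifnot(is(policy, "ValidationPolicy"))
    if (is.null(records) || nrow(records) == 0L) {
        warning("no identification records to validate")
        empty <- records[0L, , drop = FALSE]
        rej <- empty
        rej$reason <- character(0)
        return(list(accepted = empty, rejected = rej))
    }
    okPep <- records$n_unique_peptides >= policy@minUniquePeptides
    okProb <- records$protein_probability >= policy@minProteinProbability
    ok <- okPep & okProb
    rejected <- records[!ok, , drop = FALSE]
    rejected$reason <- ifelse(!okPep[!ok], "peptides", "protein_probability")
    rownames(rejected) <- NULL
    accepted <- records[ok, , drop = FALSE]
    rownames(accepted) <- NULL
    list(accepted = accepted, rejected = rejected)
}

#' Estimate the protein false discovery rate from decoys
#'
#' Decoy-ratio estimate over an accepted identification set:
#' \code{FDR\% = 100 * (accepted decoy proteins) / (accepted target
#' proteins)}.
#'
#' @param accepted data.frame of accepted records with an \code{is_decoy}
#'   column.
#' @return FDR as a percentage.  Zero accepted targets is an error (the
#'   ratio is undefined).
#'
#' @examples
#' acc <- data.frame(is_decoy = c(rep(FALSE, 1000), TRUE))
#' estimateProteinFdr(acc)   # 0.1
#'
#' @export
estimateProteinFdr <- function(accepted) {
    if (!"is_decoy" %in% names(accepted))
        stop("accepted records lack an 'is_decoy' column")
    nDecoy <- sum(accepted$is_decoy)
    nTarget <- sum(!accepted$is_decoy)
    if (nTarget == 0L)
        stop("FDR undefined: no accepted target proteins")
    100 * nDecoy / nTarget
}
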