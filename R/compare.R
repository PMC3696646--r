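## Supportive-versus-unsupportive differential comparison and candidate
## ranking.

#' Differential comparison between supportive and unsupportive ECMs
#'
#' Partitions proteins by their detection pattern between a supportive
#' and an unsupportive sample group.  A protein is \emph{unique to
#' supportive} when detected in the supportive group (in all samples
#' under \code{groupRule = "all"}, the default, or in at least one under
#' \code{"any"}) and in no unsupportive sample, and vice versa.  Proteins
#' detected in both groups are \emph{enriched in supportive} when the
#' ratio of group means (mean of per-sample mean normalized counts)
#' strictly exceeds \code{foldThreshold} (\dQuote{greater than
#' n-fold}).  Candidates are ranked deterministically: unique-to-
#' supportive proteins first (by descending supportive abundance), then
#' enriched proteins by descending fold, with interactome degree and
#' symbol as tie-breaks.
#'
#' @param x an \code{\linkS4class{AbundanceMatrix}}.
#' @param supportive,unsupportive disjoint vectors of sample ids.
#' @param classes optional named character vector of protein classes;
#'   when given, only proteins whose class is in \code{classFilter} are
#'   considered.
#' @param classFilter classes retained when \code{classes} is supplied.
#' @param foldThreshold strict fold-change cutoff (default 2).
#' @param groupRule \code{"all"} (default) or \code{"any"}: how many
#'   samples of a group must detect a protein for group-level detection.
#' @param degrees optional named numeric vector of interactome degrees
#'   used as a ranking tie-break.
#'
#' @return A \code{\linkS4class{ComparisonReport}}.
#'
#' @examples
#' tab <- loadTable1()
#' rep <- differentialReport(tab, supportive = "ihPSF",
#'                           unsupportive = "hPSF")
#' rep
#'
#' @export
differentialReport <- function(x, supportive, unsupportive, classes = NULL,
                               classFilter = c("extracellular",
                                               "cell_surface"),
                               foldThreshold = 2,
                               groupRule = c("all", "any"),
                               degrees = NULL) {
    stopifnot(is(x, "AbundanceMatrix"))
    groupRule <- match.arg(groupRule)
    if (length(intersect(supportive, unsupportive)))
        stop("supportive and unsupportive sample lists overlap: ",
             paste(intersect(supportive, unsupportive), collapse = ", "))
    absent <- setdiff(c(supportive, unsupportive), colnames(x))
    if (length(absent))
        stop("unknown sample id(s): ", paste(absent, collapse = ", "))

    ab <- abundance(x)
    de <- detected(x)
    if (!is.null(classes)) {
        keep <- rownames(ab) %in% names(classes)[classes %in% classFilter]
        ab <- ab[keep, , drop = FALSE]
        de <- de[keep, , drop = FALSE]
    }
    groupDet <- function(group) {
        d <- de[, group, drop = FALSE]
        if (groupRule == "all") rowSums(d) == length(group)
        else rowSums(d) > 0
    }
    detS <- groupDet(supportive)
    detU <- groupDet(unsupportive)
    anyU <- rowSums(de[, unsupportive, drop = FALSE]) > 0
    anyS <- rowSums(de[, supportive, drop = FALSE]) > 0
    uniqueS <- rownames(ab)[detS & !anyU]
    uniqueU <- rownames(ab)[detU & !anyS]

    meanS <- rowMeans(ab[, supportive, drop = FALSE])
    meanU <- rowMeans(ab[, unsupportive, drop = FALSE])
    both <- detS & detU
    folds <- data.frame(protein = rownames(ab)[both],
                        meanSupportive = meanS[both],
                        meanUnsupportive = meanU[both],
                        foldChange = meanS[both] / meanU[both],
                        stringsAsFactors = FALSE)
    rownames(folds) <- NULL
    enriched <- folds[folds$foldChange > foldThreshold, , drop = FALSE]
    enriched <- enriched[order(-enriched$foldChange, enriched$protein), ,
                         drop = FALSE]
    rownames(enriched) <- NULL

    degOf <- function(p) {
        if (is.null(degrees)) rep(0, length(p))
        else ifelse(p %in% names(degrees), degrees[p], 0)
    }
    uS <- uniqueS[order(-meanS[uniqueS], -degOf(uniqueS), uniqueS)]
    ranking <- rbind(
        if (length(uS))
            data.frame(protein = uS, category = "unique_to_supportive",
                       foldChange = NA_real_,
                       meanSupportive = unname(meanS[uS]),
                       degree = unname(degOf(uS)),
                       stringsAsFactors = FALSE),
        if (nrow(enriched))
            data.frame(protein = enriched$protein,
                       category = "enriched_in_supportive",
                       foldChange = enriched$foldChange,
                       meanSupportive = enriched$meanSupportive,
                       degree = unname(degOf(enriched$protein)),
                       stringsAsFactors = FALSE))
    if (is.null(ranking))
        ranking <- data.frame(protein = character(0), category = character(0),
                              foldChange = numeric(0),
                              meanSupportive = numeric(0),
                              degree = numeric(0))
    if (nrow(enriched)) {
        ord <- order(match(ranking$category,
                           c("unique_to_supportive",
                             "enriched_in_supportive")),
                     -ifelse(is.na(ranking$foldChange),
                             ranking$meanSupportive, ranking$foldChange),
                     -ranking$degree, ranking$protein)
        ranking <- ranking[ord, , drop = FALSE]
    }
    rownames(ranking) <- NULL

    new("ComparisonReport",
        supportive = supportive, unsupportive = unsupportive,
        uniqueToSupportive = uniqueS, uniqueToUnsupportive = uniqueU,
        enriched = enriched[, c("protein", "foldChange")],
        foldThreshold = foldThreshold, folds = folds, ranking = ranking)
}

#' Serialize a comparison report to a list / JSON-ready structure
#'
#' @param report a \code{\linkS4class{ComparisonReport}}.
#' @return a plain list mirroring the report slots.
#' @export
comparisonAsList <- function(report) {
    stopifnot(is(report, "ComparisonReport"))
    list(supportive = report@supportive,
         unsupportive = report@unsupportive,
         unique_to_supportive = report@uniqueToSupportive,
         unique_to_unsupportive = report@uniqueToUnsupportive,
         fold_threshold = report@foldThreshold,
         enriched_in_supportive = report@enriched,
         ranking = report@ranking)
}
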