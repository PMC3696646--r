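## Extracellular / cell-surface classification from GO annotations.

.EXTRACELLULAR_TERMS <- c("GO:0005576", "GO:0005615")
.CELL_SURFACE_TERMS <- c("GO:0005886", "GO:0009986")

## Closure of a term set over is_a/part_of ancestors.
.propagateTerms <- function(terms, ontology) {
    parents <- split(ontology$parent[nzchar(ontology$parent) &
                                     !is.na(ontology$parent)],
                     ontology$term[nzchar(ontology$parent) &
                                   !is.na(ontology$parent)])
    closed <- unique(terms)
    frontier <- closed
    while (length(frontier)) {
        nxt <- unique(unlist(parents[frontier], use.names = FALSE))
        nxt <- setdiff(nxt, closed)
        closed <- c(closed, nxt)
        frontier <- nxt
    }
    closed
}

#' Classify proteins as extracellular, cell surface, or other
#'
#' A protein is classified \code{extracellular} when annotated with
#' GO:0005576 (extracellular region) or GO:0005615 (extracellular space),
#' and \code{cell_surface} when annotated with GO:0005886 (plasma
#' membrane) or GO:0009986 (cell surface) but with neither extracellular
#' term; extracellular takes precedence when both match.  With
#' \code{propagate = TRUE} each protein's term set is first closed over
#' the is_a/part_of ancestors in \code{ontology}, so propagation can only
#' add classifications, never remove them.
#'
#' @param symbols character vector of protein symbols to classify.
#' @param annotations data.frame with columns \code{symbol}, \code{term}.
#' @param ontology ontology parent table (required when
#'   \code{propagate = TRUE}); annotation terms absent from a supplied
#'   ontology are ignored with a warning.
#' @param propagate close term sets over ancestors before matching
#'   (default \code{FALSE}: direct annotations only, matching curated
#'   association sets that already include the classification terms).
#'
#' @return data.frame with columns \code{symbol}, \code{cls} (factor-free
#'   character: \code{extracellular}, \code{cell_surface}, \code{other})
#'   and \code{terms} (list column of the matched protein's term set).
#'
#' @examples
#' ann <- data.frame(symbol = c("FN1", "PKM2"),
#'                   term = c("GO:0005576", "GO:0005886"))
#' classifyProteins(c("FN1", "PKM2", "ACTB"), ann)
#'
#' @export
classifyProteins <- function(symbols, annotations, ontology = NULL,
                             propagate = FALSE) {
    if (propagate && is.null(ontology))
        stop("'ontology' is required when propagate = TRUE")
    if (!is.null(ontology)) {
        known <- unique(ontology$term)
        unknown <- setdiff(unique(annotations$term), known)
        if (length(unknown)) {
            warning("GO id(s) not in ontology, ignored: ",
                    paste(unknown, collapse = ", "))
            annotations <- annotations[annotations$term %in% known, ,
                                       drop = FALSE]
        }
    }
    termsBySymbol <- split(annotations$term, annotations$symbol)
    cls <- character(length(symbols))
    termSets <- vector("list", length(symbols))
    for (i in seq_along(symbols)) {
        terms <- unique(termsBySymbol[[symbols[i]]])
        if (propagate && length(terms))
            terms <- .propagateTerms(terms, ontology)
        termSets[i] <- list(terms)   # [[<- would drop NULL entries
        cls[i] <- if (any(terms %in% .EXTRACELLULAR_TERMS)) "extracellular"
                  else if (any(terms %in% .CELL_SURFACE_TERMS)) "cell_surface"
                  else "other"
    }
    out <- data.frame(symbol = symbols, cls = cls, stringsAsFactors = FALSE)
    out$terms <- termSets
    out
}
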