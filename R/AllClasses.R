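#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata
NULL

setOldClass("hclust")
setOldClass("igraph")

## ---------------------------------------------------------------------------
## AbundanceMatrix
## ---------------------------------------------------------------------------

#' Protein abundance matrix with detection mask
#'
#' An \code{AbundanceMatrix} holds mean normalized spectrum counts for
#' proteins (rows) across ECM samples (columns), together with a logical
#' detection mask.  Values are in units of percentage of total spectra
#' multiplied by 10^3, so a replicate's un-averaged normalized counts sum
#' to 100,000.  A protein is flagged detected in a sample when it passed
#' identification filtering in at least one replicate of that sample;
#' non-detected cells carry the value 0.
#'
#' The class extends \linkS4class{SummarizedExperiment} with two mandatory
#' assays, \code{abundance} (numeric, non-negative) and \code{detected}
#' (logical).  Row metadata may carry protein names, classification and
#' flags such as \code{notInReference}.
#'
#' @param abundance numeric matrix of mean normalized spectrum counts
#'   (proteins x samples), dimnames required.
#' @param detected logical matrix of the same shape; defaults to
#'   \code{abundance > 0}.
#' @param rowData optional \code{DataFrame}/\code{data.frame} of per-protein
#'   metadata.
#'
#' @return An \code{AbundanceMatrix} object.
#'
#' @examples
#' m <- matrix(c(10, 0, 5, 2), 2, 2,
#'             dimnames = list(c("FN1", "THBS1"), c("s1", "s2")))
#' am <- AbundanceMatrix(m)
#' abundance(am)
#' detected(am)
#'
#' @aliases AbundanceMatrix-class
#' @exportClass AbundanceMatrix
#' @export
AbundanceMatrix <- function(abundance, detected = NULL, rowData = NULL) {
    abundance <- as.matrix(abundance)
    if (is.null(rownames(abundance)) || is.null(colnames(abundance)))
        stop("'abundance' must have row (protein) and column (sample) names")
    storage.mode(abundance) <- "double"
    if (is.null(detected))
        detected <- abundance > 0
    detected <- as.matrix(detected)
    dimnames(detected) <- dimnames(abundance)
    args <- list(assays = list(abundance = abundance, detected = detected))
    if (!is.null(rowData))
        args$rowData <- rowData
    se <- do.call(SummarizedExperiment, args)
    new("AbundanceMatrix", se)
}

setClass("AbundanceMatrix", contains = "SummarizedExperiment")

setValidity("AbundanceMatrix", function(object) {
    an <- assayNames(object)
    if (!all(c("abundance", "detected") %in% an))
        return("assays 'abundance' and 'detected' are required")
    ab <- assay(object, "abundance")
    de <- assay(object, "detected")
    if (!is.numeric(ab))
        return("'abundance' assay must be numeric")
    if (!is.logical(de))
        return("'detected' assay must be logical")
    if (any(ab < 0))
        return("abundance values must be non-negative")
    if (any(ab[!de] != 0))
        return("non-detected cells must carry abundance 0")
    TRUE
})

#' @describeIn AbundanceMatrix extract the numeric abundance assay.
#' @param x,object an \code{AbundanceMatrix}.
#' @export
setGeneric("abundance", function(x) standardGeneric("abundance"))

#' @export
setMethod("abundance", "AbundanceMatrix", function(x)
    assay(x, "abundance"))

#' @describeIn AbundanceMatrix extract the logical detection mask.
#' @export
setGeneric("detected", function(x) standardGeneric("detected"))

#' @export
setMethod("detected", "AbundanceMatrix", function(x)
    assay(x, "detected"))

setMethod("show", "AbundanceMatrix", function(object) {
    cat(sprintf("AbundanceMatrix: %d proteins x %d samples\n",
                nrow(object), ncol(object)))
    cat("  unit: % total spectra x 10^3 (mean over replicates)\n")
    cat(sprintf("  detected cells: %d of %d\n",
                sum(assay(object, "detected")), length(assay(object, "detected"))))
    cat("  samples:", paste(colnames(object), collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## ValidationPolicy
## ---------------------------------------------------------------------------

#' Identification acceptance policy
#'
#' Thresholds used to accept a protein identification in one sample
#' replicate: a minimum number of unique validated peptides (each peptide
#' already validated at \code{minPeptideProbability} upstream, so the
#' peptide count in input records is post-filter), and a minimum protein
#' probability.  All comparisons are closed (\dQuote{at least}).
#' The defaults (2 peptides at >= 0.90, protein probability >= 0.99) are
#' the standard stringent Scaffold-style acceptance settings for
#' spectral-count datasets.
#'
#' @param minUniquePeptides integer >= 1, minimum unique validated peptides.
#' @param minPeptideProbability fraction in [0,1]; documents the peptide-level
#'   validation threshold that the \code{n_unique_peptides} field of input
#'   records is assumed to reflect.
#' @param minProteinProbability fraction in [0,1], minimum protein probability.
#'
#' @return A \code{ValidationPolicy} object.
#'
#' @examples
#' ValidationPolicy()
#' ValidationPolicy(minProteinProbability = 0.95)
#'
#' @aliases ValidationPolicy-class
#' @exportClass ValidationPolicy
#' @export
ValidationPolicy <- function(minUniquePeptides = 2L,
                             minPeptideProbability = 0.90,
                             minProteinProbability = 0.99) {
    new("ValidationPolicy",
        minUniquePeptides = as.integer(minUniquePeptides),
        minPeptideProbability = minPeptideProbability,
        minProteinProbability = minProteinProbability)
}

setClass("ValidationPolicy",
         representation(minUniquePeptides = "integer",
                        minPeptideProbability = "numeric",
                        minProteinProbability = "numeric"))

setValidity("ValidationPolicy", function(object) {
    if (length(object@minUniquePeptides) != 1L ||
        is.na(object@minUniquePeptides) || object@minUniquePeptides < 1L)
        return("'minUniquePeptides' must be a single integer >= 1")
    for (s in c("minPeptideProbability", "minProteinProbability")) {
        v <- slot(object, s)
        if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
            return(sprintf("'%s' must be a single value in [0,1]", s))
    }
    TRUE
})

setMethod("show", "ValidationPolicy", function(object) {
    cat("ValidationPolicy:\n")
    cat(sprintf("  unique peptides >= %d (each at probability >= %.2f)\n",
                object@minUniquePeptides, object@minPeptideProbability))
    cat(sprintf("  protein probability >= %.2f\n",
                object@minProteinProbability))
})

## ---------------------------------------------------------------------------
## GroundTruth
## ---------------------------------------------------------------------------

#' Ground truth for the synthetic-data generator
#'
#' Describes the known composition of a simulated study: per-sample
#' relative protein abundances (each summing to 1), protein class labels
#' (extracellular / cell_surface / other), the decoy contamination rate
#' among accepted identifications, the number of independent ECM
#' isolations (replicates) per sample, and the total spectrum count per
#' replicate.  Downstream stages are validated by recovering these
#' quantities from simulated identification reports.
#'
#' @param compositions named list of named numeric vectors; one vector per
#'   sample, mapping protein symbols to relative abundances summing to 1.
#' @param classLabels named character vector over all proteins, values in
#'   \code{c("extracellular", "cell_surface", "other")}.
#' @param decoyRate expected fraction of decoys among accepted records,
#'   in [0, 0.5).
#' @param nReplicates independent isolations per sample (default 2).
#' @param totalSpectra total MS/MS spectra per replicate.
#' @param noiseProbabilityFraction fraction of true-protein records given a
#'   sub-threshold protein probability (simulated marginal identifications).
#' @param noisePeptideFraction fraction of true-protein records given a
#'   single unique peptide.
#' @param species named character vector mapping sample ids to
#'   \code{"human"} or \code{"mouse"}; defaults to human for all samples.
#' @param seed integer seed driving all randomness.
#'
#' @return A \code{GroundTruth} object.
#'
#' @examples
#' gt <- GroundTruth(
#'   compositions = list(s1 = c(A = 0.6, B = 0.4)),
#'   classLabels = c(A = "extracellular", B = "other"),
#'   totalSpectra = 1000, seed = 1)
#' gt
#'
#' @aliases GroundTruth-class
#' @exportClass GroundTruth
#' @export
GroundTruth <- function(compositions,
                        classLabels,
                        decoyRate = 0.001,
                        nReplicates = 2L,
                        totalSpectra = 10000L,
                        noiseProbabilityFraction = 0.02,
                        noisePeptideFraction = 0.02,
                        species = NULL,
                        seed = 1L) {
    if (is.null(species))
        species <- structure(rep("human", length(compositions)),
                             names = names(compositions))
    new("GroundTruth",
        compositions = compositions,
        classLabels = classLabels,
        decoyRate = decoyRate,
        nReplicates = as.integer(nReplicates),
        totalSpectra = as.integer(totalSpectra),
        noiseProbabilityFraction = noiseProbabilityFraction,
        noisePeptideFraction = noisePeptideFraction,
        species = species,
        seed = as.integer(seed))
}

setClass("GroundTruth",
         representation(compositions = "list",
                        classLabels = "character",
                        decoyRate = "numeric",
                        nReplicates = "integer",
                        totalSpectra = "integer",
                        noiseProbabilityFraction = "numeric",
                        noisePeptideFraction = "numeric",
                        species = "character",
                        seed = "integer"))

setValidity("GroundTruth", function(object) {
    if (length(object@compositions) < 1L || is.null(names(object@compositions)))
        return("'compositions' must be a named list with >= 1 sample")
    for (s in names(object@compositions)) {
        comp <- object@compositions[[s]]
        if (is.null(names(comp)) || any(comp < 0))
            return(sprintf("composition of sample '%s' must be named and non-negative", s))
        if (abs(sum(comp) - 1) > 1e-8)
            return(sprintf("composition of sample '%s' must sum to 1", s))
    }
    if (object@decoyRate < 0 || object@decoyRate >= 0.5)
        return("'decoyRate' must lie in [0, 0.5)")
    prots <- unique(unlist(lapply(object@compositions, names)))
    if (!all(prots %in% names(object@classLabels)))
        return("every protein in a composition needs a class label")
    if (!all(object@classLabels %in% c("extracellular", "cell_surface", "other")))
        return("class labels must be extracellular, cell_surface or other")
    if (object@nReplicates < 1L)
        return("'nReplicates' must be >= 1")
    if (!all(names(object@compositions) %in% names(object@species)))
        return("every sample needs a species entry")
    if (!all(object@species %in% c("human", "mouse")))
        return("species must be 'human' or 'mouse'")
    TRUE
})

setMethod("show", "GroundTruth", function(object) {
    cat(sprintf("GroundTruth: %d samples x %d replicates, %d spectra/replicate\n",
                length(object@compositions), object@nReplicates,
                object@totalSpectra))
    cat(sprintf("  proteins: %d; decoy rate %.4f; seed %d\n",
                length(unique(unlist(lapply(object@compositions, names)))),
                object@decoyRate, object@seed))
})

## ---------------------------------------------------------------------------
## ClusterSet
## ---------------------------------------------------------------------------

#' Hierarchical clustering result with extracted clusters
#'
#' Wraps the agglomerative merge tree built from uncentered Pearson
#' distances (1 - r_u) together with the clusters extracted at a
#' similarity threshold: the maximal subtrees whose root merge similarity
#' is at least \code{threshold} (default 0.5).  Proteins that join the
#' tree only below the threshold are reported as unclustered singletons.
#'
#' @slot tree the \code{hclust} merge tree (heights are 1 - similarity).
#' @slot clusters named list of character vectors (>= 2 proteins each).
#' @slot singletons character vector of unclustered proteins.
#' @slot threshold similarity threshold used for extraction.
#' @slot leafOrder proteins in dendrogram leaf order.
#' @slot dropped proteins removed before clustering (zero-norm profiles).
#'
#' @aliases ClusterSet-class clusters
#' @export clusters
#' @exportClass ClusterSet
setClass("ClusterSet",
         representation(tree = "hclust",
                        clusters = "list",
                        singletons = "character",
                        threshold = "numeric",
                        leafOrder = "character",
                        dropped = "character"))

setValidity("ClusterSet", function(object) {
    members <- unlist(object@clusters, use.names = FALSE)
    if (anyDuplicated(members))
        return("clusters must be disjoint")
    if (length(intersect(members, object@singletons)) > 0L)
        return("a protein cannot be both clustered and a singleton")
    if (!setequal(c(members, object@singletons), object@leafOrder))
        return("clusters plus singletons must partition the clustered proteins")
    TRUE
})

setGeneric("clusters", function(x, ...) standardGeneric("clusters"))

#' @describeIn ClusterSet the extracted clusters (list of protein vectors).
#' @param x,object a \code{ClusterSet}.
#' @param ... ignored.
#' @export
setMethod("clusters", "ClusterSet", function(x, ...) x@clusters)

setMethod("show", "ClusterSet", function(object) {
    sizes <- lengths(object@clusters)
    cat(sprintf("ClusterSet: %d proteins, %d clusters (r >= %.2f), %d singletons\n",
                length(object@leafOrder), length(object@clusters),
                object@threshold, length(object@singletons)))
    if (length(sizes))
        cat("  cluster sizes:", paste(sizes, collapse = ", "), "\n")
    if (length(object@dropped))
        cat("  dropped (zero-norm):",
            paste(object@dropped, collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## InteractionNetwork
## ---------------------------------------------------------------------------

#' Undirected protein-protein interaction network with topology metrics
#'
#' A simple undirected graph over protein symbols (no self-loops, no
#' duplicate edges) with per-edge source provenance, plus per-node degree
#' and local clustering coefficient and a global network density.  Metrics
#' are filled in by \code{\link{induceAndMeasure}}.
#'
#' @slot graph the \code{igraph} object.
#' @slot nodeMetrics data.frame with columns \code{symbol}, \code{degree},
#'   \code{clusteringCoefficient}, ordered by the hub ranking (descending
#'   degree, ties by symbol).
#' @slot density global density 2E/(N(N-1)); \code{NA} until measured.
#' @slot includeIsolates whether isolated nodes count toward N in the
#'   density denominator.
#' @slot droppedSelfLoops number of self-loop rows discarded on merge.
#'
#' @aliases InteractionNetwork-class
#' @exportClass InteractionNetwork
setClass("InteractionNetwork",
         representation(graph = "igraph",
                        nodeMetrics = "data.frame",
                        density = "numeric",
                        includeIsolates = "logical",
                        droppedSelfLoops = "integer"))

setValidity("InteractionNetwork", function(object) {
    g <- object@graph
    if (igraph::any_loop(g))
        return("self-loops are not allowed")
    if (igraph::any_multiple(g))
        return("duplicate undirected edges are not allowed")
    if (igraph::is_directed(g))
        return("graph must be undirected")
    cc <- object@nodeMetrics$clusteringCoefficient
    if (length(cc) && any(cc < 0 | cc > 1, na.rm = TRUE))
        return("clustering coefficients must lie in [0,1]")
    if (!is.na(object@density) && length(object@density) == 1L &&
        (object@density < 0 || object@density > 1))
        return("density must lie in [0,1]")
    TRUE
})

setMethod("show", "InteractionNetwork", function(object) {
    g <- object@graph
    cat(sprintf("InteractionNetwork: %d nodes, %d edges\n",
                igraph::vcount(g), igraph::ecount(g)))
    if (!is.na(object@density))
        cat(sprintf("  density: %.4f (%s isolates)\n", object@density,
                    if (object@includeIsolates) "including" else "excluding"))
    if (nrow(object@nodeMetrics))
        cat("  top hubs:",
            paste(utils::head(object@nodeMetrics$symbol, 5L), collapse = ", "),
            "\n")
})

## ---------------------------------------------------------------------------
## OverlapReport
## ---------------------------------------------------------------------------

#' Multi-set overlap cardinalities
#'
#' Exclusive-region cardinalities for up to five protein sets (the numbers
#' printed inside an area-proportional Euler diagram) plus the symmetric
#' pairwise shared-count matrix.
#'
#' @slot sets named list of character vectors.
#' @slot regionCardinalities named integer vector; names are
#'   \code{"&"}-joined subsets of set names, values the number of proteins
#'   lying in exactly that subset.
#' @slot pairwiseShared symmetric integer matrix of pairwise intersections.
#'
#' @aliases OverlapReport-class
#' @exportClass OverlapReport
setClass("OverlapReport",
         representation(sets = "list",
                        regionCardinalities = "integer",
                        pairwiseShared = "matrix"))

setValidity("OverlapReport", function(object) {
    if (sum(object@regionCardinalities) !=
        length(unique(unlist(object@sets, use.names = FALSE))))
        return("region cardinalities must sum to the size of the union")
    ps <- object@pairwiseShared
    if (!isTRUE(all.equal(ps, t(ps))))
        return("pairwise shared matrix must be symmetric")
    TRUE
})

setMethod("show", "OverlapReport", function(object) {
    cat(sprintf("OverlapReport: %d sets, union of %d proteins\n",
                length(object@sets), sum(object@regionCardinalities)))
    nz <- object@regionCardinalities[object@regionCardinalities > 0L]
    for (nm in names(nz))
        cat(sprintf("  [%s] %d\n", nm, nz[[nm]]))
})

## ---------------------------------------------------------------------------
## ComparisonReport
## ---------------------------------------------------------------------------

#' Supportive-versus-unsupportive differential comparison
#'
#' Partitions proteins by detection pattern between a supportive and an
#' unsupportive sample group: proteins unique to either group, proteins
#' detected in both but enriched beyond a fold threshold in the supportive
#' group, and a deterministic candidate ranking (unique before enriched,
#' then by descending abundance/fold, then interactome degree, then
#' symbol).
#'
#' @slot supportive,unsupportive sample id vectors.
#' @slot uniqueToSupportive,uniqueToUnsupportive protein symbol vectors.
#' @slot enriched data.frame (protein, foldChange) with all folds strictly
#'   above \code{foldThreshold}.
#' @slot foldThreshold the strict fold-change cutoff (default 2).
#' @slot folds data.frame of per-protein fold status for all candidates.
#' @slot ranking data.frame of ranked candidates.
#'
#' @aliases ComparisonReport-class
#' @exportClass ComparisonReport
setClass("ComparisonReport",
         representation(supportive = "character",
                        unsupportive = "character",
                        uniqueToSupportive = "character",
                        uniqueToUnsupportive = "character",
                        enriched = "data.frame",
                        foldThreshold = "numeric",
                        folds = "data.frame",
                        ranking = "data.frame"))

setValidity("ComparisonReport", function(object) {
    if (length(intersect(object@uniqueToSupportive,
                         object@uniqueToUnsupportive)) > 0L)
        return("unique sets must be disjoint")
    if (nrow(object@enriched)) {
        if (length(intersect(object@enriched$protein,
                             c(object@uniqueToSupportive,
                               object@uniqueToUnsupportive))) > 0L)
            return("enriched and unique sets must be disjoint")
        if (any(object@enriched$foldChange <= object@foldThreshold))
            return("all enriched folds must exceed the threshold")
    }
    TRUE
})

setMethod("show", "ComparisonReport", function(object) {
    cat("ComparisonReport:\n")
    cat("  supportive:", paste(object@supportive, collapse = ", "), "\n")
    cat("  unsupportive:", paste(object@unsupportive, collapse = ", "), "\n")
    cat(sprintf("  unique to supportive: %d; unique to unsupportive: %d\n",
                length(object@uniqueToSupportive),
                length(object@uniqueToUnsupportive)))
    cat(sprintf("  enriched (> %.1f-fold) in supportive: %d\n",
                object@foldThreshold, nrow(object@enriched)))
})
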