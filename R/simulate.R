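## Seeded synthetic-data generator with known ground truth.  Emulates the
## sampling structure behind spectral-count quantification: per replicate,
## spectrum counts are drawn multinomially from the sample's relative
## composition over a fixed total spectrum budget (two independent ECM
## isolations by default), decoy identifications are appended at a known
## expected rate, and a configurable fraction of records receive
## sub-threshold probabilities or single peptides so that identification
## filtering has real work to do.

#' Build a study-shaped ground truth
#'
#' Constructs a two-condition ground truth resembling a
#' supportive-versus-unsupportive ECM comparison: a shared protein core,
#' proteins unique to the supportive sample, and a set of planted fold
#' changes between the two samples.  About half of the proteins are
#' labelled extracellular or cell surface (the enrichment typical of ECM
#' preparations); the most abundant extracellular protein (a fibronectin
#' analog, \code{ECM001}) is the designated interactome hub.
#'
#' @param nProteins total distinct proteins (default 100).
#' @param nUnique proteins present only in the supportive sample
#'   (default 8).
#' @param plantedFolds named numeric vector of supportive/unsupportive
#'   fold changes planted on shared proteins (defaults to folds of 24, 7,
#'   2.8 and 2.2 on the four most abundant shared extracellular
#'   proteins).
#' @param totalSpectra spectra per replicate (default 10000, a typical
#'   single-run LC-MS/MS budget).
#' @param decoyRate expected decoy fraction among accepted records
#'   (default 0.001, i.e. a 0.1\% protein FDR).
#' @param nReplicates independent isolations per sample (default 2).
#' @param seed integer seed.
#' @param ... further arguments (noise fractions, species) passed to
#'   \code{\link{GroundTruth}}.
#' @return A \code{\linkS4class{GroundTruth}} with samples
#'   \code{supportive} and \code{unsupportive}.
#'
#' @examples
#' truth <- studyGroundTruth(seed = 7)
#' truth
#'
#' @export
studyGroundTruth <- function(nProteins = 100L, nUnique = 8L,
                             plantedFolds = c(ECM001 = 24, ECM002 = 7,
                                              ECM003 = 2.8, ECM004 = 2.2),
                             totalSpectra = 10000L, decoyRate = 0.001,
                             nReplicates = 2L, seed = 1L, ...) {
    stopifnot(nProteins >= nUnique + length(plantedFolds) + 10L)
    proteins <- sprintf("ECM%03d", seq_len(nProteins))
    ## class labels: ~40% extracellular, ~16% cell surface, rest other
    nEx <- ceiling(0.40 * nProteins)
    nCs <- ceiling(0.16 * nProteins)
    cls <- c(rep("extracellular", nEx), rep("cell_surface", nCs),
             rep("other", nProteins - nEx - nCs))
    names(cls) <- proteins
    uniqueProts <- proteins[seq_len(nUnique) + length(plantedFolds)]
    shared <- setdiff(proteins, uniqueProts)

    ## base abundances: geometric-like decay, high dynamic range
    base <- 2^(-(seq_len(nProteins) - 1L) / 8)
    names(base) <- proteins
    supp <- base / sum(base)
    ## Plant fold changes directly in composition (normalized-count) space:
    ## targeted proteins get u = s / fold, unique proteins u = 0, and the
    ## remaining shared proteins absorb the freed mass with a common factor
    ## so the unsupportive composition still sums to 1.  Planted proteins
    ## then have exactly the stated normalized fold change.
    unsupp <- supp
    unsupp[uniqueProts] <- 0
    unsupp[names(plantedFolds)] <- supp[names(plantedFolds)] / plantedFolds
    others <- setdiff(shared, names(plantedFolds))
    cFac <- (1 - sum(unsupp[names(plantedFolds)])) / sum(supp[others])
    unsupp[others] <- supp[others] * cFac
    GroundTruth(
        compositions = list(supportive = supp,
                            unsupportive = unsupp),
        classLabels = cls,
        decoyRate = decoyRate,
        nReplicates = nReplicates,
        totalSpectra = totalSpectra,
        seed = seed, ...)
}

#' Simulate identification reports from a ground truth
#'
#' For every sample and replicate, spectrum counts are drawn from a
#' multinomial over the sample composition with the replicate's total
#' spectrum budget; proteins drawing zero spectra are absent from that
#' replicate's report.  True proteins receive protein probabilities of at
#' least 0.99 and at least two unique peptides, except for configurable
#' noise fractions given sub-threshold probability or a single peptide.
#' Decoy records are appended so that the expected decoy fraction among
#' threshold-passing records equals \code{decoyRate}.  Output is fully
#' reproducible from the ground truth's seed.
#'
#' @param truth a \code{\linkS4class{GroundTruth}}.
#' @return data.frame of identification records in the report dialect.
#'
#' @examples
#' truth <- GroundTruth(compositions = list(s1 = c(A = 1)),
#'                      classLabels = c(A = "extracellular"),
#'                      totalSpectra = 100, seed = 1)
#' simulateReports(truth)
#'
#' @export
simulateReports <- function(truth) {
    stopifnot(is(truth, "GroundTruth"))
    if (truth@totalSpectra <= 0L)
        stop("'totalSpectra' must be positive")
    set.seed(truth@seed)
    out <- list()
    for (s in names(truth@compositions)) {
        comp <- truth@compositions[[s]]
        comp <- comp[comp > 0]
        for (r in seq_len(truth@nReplicates)) {
            counts <- as.vector(stats::rmultinom(1L, truth@totalSpectra,
                                                 comp))
            names(counts) <- names(comp)
            counts <- counts[counts > 0L]
            n <- length(counts)
            prob <- stats::runif(n, 0.99, 1)
            pept <- 2L + stats::rpois(n, 2)
            ## noise: marginal identifications that must be filtered out
            lowProb <- stats::runif(n) < truth@noiseProbabilityFraction
            prob[lowProb] <- stats::runif(sum(lowProb), 0.50, 0.95)
            onePept <- stats::runif(n) < truth@noisePeptideFraction
            pept[onePept] <- 1L
            rec <- data.frame(
                sample_id = s,
                replicate_id = paste0("rep", r),
                accession = paste0("ACC_", names(counts)),
                gene_symbol = names(counts),
                species = unname(truth@species[s]),
                n_unique_peptides = pept,
                protein_probability = prob,
                spectrum_count = unname(counts),
                is_decoy = FALSE,
                stringsAsFactors = FALSE)
            nAcceptable <- sum(!lowProb & !onePept)
            nDecoys <- stats::rbinom(1L, nAcceptable, truth@decoyRate)
            if (nDecoys > 0L) {
                dn <- sprintf("DECOY_%s_r%d_%03d", s, r, seq_len(nDecoys))
                rec <- rbind(rec, data.frame(
                    sample_id = s,
                    replicate_id = paste0("rep", r),
                    accession = dn,
                    gene_symbol = dn,
                    species = unname(truth@species[s]),
                    n_unique_peptides = 2L,
                    protein_probability = stats::runif(nDecoys, 0.99, 1),
                    spectrum_count = sample(3L, nDecoys, replace = TRUE),
                    is_decoy = TRUE,
                    stringsAsFactors = FALSE))
            }
            out[[length(out) + 1L]] <- rec
        }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Simulate annotations, ontology, interactomes and an ortholog map
#'
#' Generates class-consistent resources for a ground truth: extracellular
#' proteins are annotated with GO:0005576 or GO:0005615 and cell-surface
#' proteins with GO:0005886 or GO:0009986 (plus a shared
#' biological-process term per class, so cluster enrichment has signal);
#' \dQuote{other} proteins receive unrelated intracellular terms.  The
#' interactome is grown by preferential attachment over all proteins and
#' split across three source tags; the designated hub is guaranteed the
#' strictly largest degree.  Mouse-style aliases of every symbol are
#' emitted into the ortholog map.
#'
#' @param truth a \code{\linkS4class{GroundTruth}}.
#' @param hub symbol of the designated hub protein; defaults to the most
#'   abundant protein of the first sample.
#' @return list with elements \code{annotations}, \code{ontology},
#'   \code{edgeLists} (list of three data.frames), \code{orthologMap},
#'   \code{hub}.
#' @export
simulateResources <- function(truth, hub = NULL) {
    stopifnot(is(truth, "GroundTruth"))
    set.seed(truth@seed + 1L)
    proteins <- names(truth@classLabels)
    cls <- truth@classLabels
    if (is.null(hub)) {
        comp <- truth@compositions[[1L]]
        hub <- names(comp)[which.max(comp)]
    }

    ccTerm <- character(length(proteins))
    ccTerm[cls == "extracellular"] <-
        sample(c("GO:0005576", "GO:0005615"),
               sum(cls == "extracellular"), replace = TRUE)
    ccTerm[cls == "cell_surface"] <-
        sample(c("GO:0005886", "GO:0009986"),
               sum(cls == "cell_surface"), replace = TRUE)
    ccTerm[cls == "other"] <-
        sample(c("GO:0005634", "GO:0005739", "GO:0005829"),
               sum(cls == "other"), replace = TRUE)
    bpTerm <- c(extracellular = "GO:0030198",  # ECM organization
                cell_surface = "GO:0007155",   # cell adhesion
                other = "GO:0006412")[cls]     # translation
    annotations <- data.frame(
        symbol = rep(proteins, 2L),
        term = c(ccTerm, unname(bpTerm)),
        evidence = "SIM",
        stringsAsFactors = FALSE)

    ontology <- data.frame(
        term = c("GO:0005575", "GO:0005576", "GO:0005615", "GO:0071944",
                 "GO:0005886", "GO:0009986", "GO:0005634", "GO:0005739",
                 "GO:0005829", "GO:0008150", "GO:0007155", "GO:0030198",
                 "GO:0006412"),
        parent = c("", "GO:0005575", "GO:0005576", "GO:0005575",
                   "GO:0071944", "GO:0071944", "GO:0005575", "GO:0005575",
                   "GO:0005575", "", "GO:0008150", "GO:0008150",
                   "GO:0008150"),
        name = c("cellular_component", "extracellular region",
                 "extracellular space", "cell periphery", "plasma membrane",
                 "cell surface", "nucleus", "mitochondrion", "cytosol",
                 "biological_process", "cell adhesion",
                 "extracellular matrix organization", "translation"),
        stringsAsFactors = FALSE)

    ## preferential attachment with the hub seeded first
    ord <- c(hub, sample(setdiff(proteins, hub)))
    g <- igraph::sample_pa(length(ord), power = 1, m = 2, directed = FALSE)
    igraph::V(g)$name <- ord
    ## guarantee the hub is the strict top-degree node
    repeat {
        deg <- igraph::degree(g)
        top <- max(deg[names(deg) != hub])
        if (deg[hub] > top)
            break
        cand <- setdiff(igraph::V(g)$name,
                        c(hub, igraph::neighbors(g, hub)$name))
        if (!length(cand))
            break
        g <- igraph::add_edges(g, c(hub, sample(cand, 1L)))
    }
    el <- igraph::as_edgelist(g)
    src <- sample(c("pina", "matrixdb", "adhesome"), nrow(el),
                  replace = TRUE)
    edgeLists <- lapply(c("pina", "matrixdb", "adhesome"), function(tag) {
        keep <- src == tag
        data.frame(a = el[keep, 1L], b = el[keep, 2L], source = tag,
                   stringsAsFactors = FALSE)
    })
    names(edgeLists) <- c("pina", "matrixdb", "adhesome")

    orthologMap <- data.frame(
        mouse = paste0(substr(proteins, 1L, 1L),
                       tolower(substring(proteins, 2L))),
        human = proteins,
        stringsAsFactors = FALSE)

    list(annotations = annotations, ontology = ontology,
         edgeLists = edgeLists, orthologMap = orthologMap, hub = hub)
}
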