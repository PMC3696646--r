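## Packaged fixture: the published comparison table of extracellular
## proteins detected in HUES1 ECM versus feeder-cell ECMs, as printed
## (mean normalized spectrum counts, % total spectra x 10^3; ND encoded
## as empty cells).  Seven collagen rows not detected in HUES1 ECM are
## listed for reference and flagged notInReference.

#' Load the packaged HUES1-versus-feeder ECM abundance table
#'
#' Returns the published abundance comparison of extracellular proteins
#' detected in hESC (HUES1) ECM and in six feeder-cell ECMs (CD1 MEFs at
#' passages 4 and 9, MF1xCD1 MEFs at passages 4 and 9, primary and
#' immortalized human placental stromal fibroblasts).  Values are mean
#' normalized spectrum counts over two independent ECM isolations, in
#' units of \% total spectra x 10^3; \dQuote{ND} cells are loaded as
#' not-detected with value 0.  Collagen rows listed for reference only
#' (not detected in HUES1 ECM) carry \code{notInReference = TRUE} in the
#' row metadata.
#'
#' @return An \code{\linkS4class{AbundanceMatrix}} with 42 proteins and 7
#'   samples (\code{CD1_P4}, \code{CD1_P9}, \code{MF1xCD1_P4},
#'   \code{MF1xCD1_P9}, \code{hPSF}, \code{ihPSF}, \code{HUES1}).
#'
#' @examples
#' tab <- loadTable1()
#' abundance(tab)["FN1", "ihPSF"]       # 57.2
#' sum(detected(tab)[, "HUES1"])        # 35 proteins detected in HUES1 ECM
#'
#' @export
loadTable1 <- function() {
    path <- system.file("extdata", "table1_hues1_ecm.tsv",
                        package = "ecmProfiler", mustWork = TRUE)
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            colClasses = "character", check.names = FALSE)
    samples <- c("CD1_P4", "CD1_P9", "MF1xCD1_P4", "MF1xCD1_P9",
                 "hPSF", "ihPSF", "HUES1")
    vals <- as.matrix(df[, samples])
    de <- nzchar(vals) & !is.na(vals)
    num <- matrix(0, nrow(vals), ncol(vals),
                  dimnames = list(df$gene_symbol, samples))
    num[de] <- as.numeric(vals[de])
    dimnames(de) <- dimnames(num)
    rd <- S4Vectors::DataFrame(
        proteinName = df$protein_name,
        notInReference = df$not_in_HUES1 == "TRUE",
        row.names = df$gene_symbol)
    AbundanceMatrix(num, detected = de, rowData = rd)
}

#' Load the synthetic GO annotations mirroring the packaged table
#'
#' A constructed annotation table assigning each protein of
#' \code{\link{loadTable1}} one extracellular or cell-surface Gene
#' Ontology term (plus a cell-adhesion biological-process term for two
#' adhesion proteins).  The assignments are synthetic: they mirror the
#' published extracellular/cell-surface classification of the table's
#' rows but are not a curated GOA extract.
#'
#' @return data.frame with columns \code{symbol}, \code{term},
#'   \code{evidence}.
#' @export
loadTable1Annotations <- function() {
    readAnnotations(system.file("extdata", "table1_annotations_synthetic.tsv",
                                package = "ecmProfiler", mustWork = TRUE))
}

#' Load the small packaged GO ontology subset
#'
#' A hand-built acyclic parent table covering the cellular-component
#' terms used for extracellular/cell-surface classification and two
#' biological-process terms used in examples.
#'
#' @return data.frame with columns \code{term}, \code{parent}, \code{name}.
#' @export
loadOntologySubset <- function() {
    readOntologyTable(system.file("extdata", "go_subset_ontology.tsv",
                                  package = "ecmProfiler", mustWork = TRUE))
}
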