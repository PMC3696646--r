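## Readers and writers for the pipeline's file dialects.  All dialects are
## strict tab-separated text with fixed headers; no column guessing.

.REPORT_COLUMNS <- c("sample_id", "replicate_id", "accession", "gene_symbol",
                     "species", "n_unique_peptides", "protein_probability",
                     "spectrum_count", "is_decoy")

#' Read a protein identification report
#'
#' Reads one tab-separated identification report, one row per protein
#' observation in one sample replicate.  The header must be exactly
#' \code{sample_id, replicate_id, accession, gene_symbol, species,
#' n_unique_peptides, protein_probability, spectrum_count, is_decoy}.
#' \code{n_unique_peptides} counts unique peptides that already passed the
#' peptide-probability validation upstream.
#'
#' @param path path to a TSV file.
#'
#' @return A data.frame of typed identification records, in file order.
#'   Errors name the offending column or 1-based file line.
#'
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' r <- data.frame(sample_id = "s1", replicate_id = "r1", accession = "P1",
#'                 gene_symbol = "FN1", species = "human",
#'                 n_unique_peptides = 12L, protein_probability = 1,
#'                 spectrum_count = 40L, is_decoy = FALSE)
#' writeIdentificationReport(r, f)
#' readIdentificationReport(f)
#'
#' @export
readIdentificationReport <- function(path) {
    if (!file.exists(path))
        stop("identification report not found: ", path)
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            colClasses = "character", check.names = FALSE,
                            quote = "", comment.char = "")
    missing <- setdiff(.REPORT_COLUMNS, names(df))
    extra <- setdiff(names(df), .REPORT_COLUMNS)
    if (length(missing))
        stop("identification report is missing column(s): ",
             paste(missing, collapse = ", "))
    if (length(extra))
        stop("identification report has unexpected column(s): ",
             paste(extra, collapse = ", "))
    df <- df[, .REPORT_COLUMNS]
    n <- nrow(df)
    line <- seq_len(n) + 1L   # header is line 1

    .numeric_col <- function(col, integer = FALSE) {
        v <- suppressWarnings(as.numeric(df[[col]]))
        bad <- which(is.na(v))
        if (length(bad))
            stop(sprintf("non-numeric '%s' at line %d", col, line[bad[1L]]))
        if (integer) {
            if (any(v != round(v) | v < 0))
                stop(sprintf("'%s' must be a non-negative integer (line %d)",
                             col, line[which(v != round(v) | v < 0)[1L]]))
            v <- as.integer(v)
        }
        v
    }

    df$n_unique_peptides <- .numeric_col("n_unique_peptides", integer = TRUE)
    df$spectrum_count <- .numeric_col("spectrum_count", integer = TRUE)
    df$protein_probability <- .numeric_col("protein_probability")
    bad <- which(df$protein_probability < 0 | df$protein_probability > 1)
    if (length(bad))
        stop(sprintf("protein_probability outside [0,1] at line %d",
                     line[bad[1L]]))
    bad <- which(!df$species %in% c("human", "mouse"))
    if (length(bad))
        stop(sprintf("species must be 'human' or 'mouse' (line %d)",
                     line[bad[1L]]))
    dec <- toupper(trimws(df$is_decoy))
    bad <- which(!dec %in% c("TRUE", "FALSE"))
    if (length(bad))
        stop(sprintf("is_decoy must be TRUE or FALSE (line %d)", line[bad[1L]]))
    df$is_decoy <- dec == "TRUE"

    key <- paste(df$sample_id, df$replicate_id, df$accession, sep = "\r")
    if (anyDuplicated(key)) {
        d <- which(duplicated(key))[1L]
        stop(sprintf(paste0("duplicated (sample_id, replicate_id, accession) ",
                            "at line %d: (%s, %s, %s)"),
                     line[d], df$sample_id[d], df$replicate_id[d],
                     df$accession[d]))
    }
    rownames(df) <- NULL
    df
}

#' Write a protein identification report
#'
#' @param records a data.frame of identification records (dialect columns).
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeIdentificationReport <- function(records, path) {
    missing <- setdiff(.REPORT_COLUMNS, names(records))
    if (length(missing))
        stop("records are missing column(s): ", paste(missing, collapse = ", "))
    utils::write.table(records[, .REPORT_COLUMNS], path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

.read_id_table <- function(path, what) {
    if (!file.exists(path))
        stop(what, " file not found: ", path)
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            colClasses = "character", check.names = FALSE,
                            quote = "", comment.char = "")
    df[] <- lapply(df, trimws)
    df
}

#' Read an interaction edge list
#'
#' Tab-separated file with two identifier columns (\code{a}, \code{b}) and
#' an optional \code{source} column.  Identifiers are whitespace-trimmed
#' with case preserved.  Both orientations of an undirected edge may be
#' present; collapsing them is the job of \code{\link{mergeInteractomes}}.
#'
#' @param path path to a TSV edge list.
#' @param source optional source tag applied when the file carries no
#'   \code{source} column (defaults to the file name).
#' @return data.frame with columns \code{a}, \code{b}, \code{source}.
#' @export
readEdgeList <- function(path, source = NULL) {
    df <- .read_id_table(path, "edge list")
    if (ncol(df) < 2L)
        stop("edge list needs two identifier columns")
    out <- data.frame(a = df[[1L]], b = df[[2L]],
                      stringsAsFactors = FALSE)
    out$source <- if ("source" %in% names(df)) df[["source"]]
                  else if (!is.null(source)) source
                  else basename(path)
    if (any(!nzchar(out$a) | !nzchar(out$b)))
        stop("edge list contains blank identifiers")
    out
}

#' Read a mouse-to-human ortholog map
#'
#' Two identifier columns, mouse symbol then human symbol.  Rows mapping a
#' symbol to itself and rows with blank identifiers are rejected.
#'
#' @param path path to a TSV file.
#' @return data.frame with columns \code{mouse}, \code{human}.
#' @export
readOrthologMap <- function(path) {
    df <- .read_id_table(path, "ortholog map")
    if (ncol(df) < 2L)
        stop("ortholog map needs two identifier columns")
    out <- data.frame(mouse = df[[1L]], human = df[[2L]],
                      stringsAsFactors = FALSE)
    if (any(!nzchar(out$mouse) | !nzchar(out$human)))
        stop("ortholog map contains blank identifiers")
    self <- which(out$mouse == out$human)
    if (length(self))
        stop(sprintf("self-referential ortholog row: '%s' -> '%s'",
                     out$mouse[self[1L]], out$human[self[1L]]))
    out
}

#' Read a GO annotation table
#'
#' Two or three tab-separated columns: protein symbol, GO term id, and an
#' optional evidence code.
#'
#' @param path path to a TSV file.
#' @return data.frame with columns \code{symbol}, \code{term} and, when
#'   present, \code{evidence}.
#' @export
readAnnotations <- function(path) {
    df <- .read_id_table(path, "annotation")
    if (ncol(df) < 2L)
        stop("annotation table needs at least two columns (symbol, term)")
    out <- data.frame(symbol = df[[1L]], term = df[[2L]],
                      stringsAsFactors = FALSE)
    if (ncol(df) >= 3L)
        out$evidence <- df[[3L]]
    if (any(!nzchar(out$symbol) | !nzchar(out$term)))
        stop("annotation table contains blank identifiers")
    out
}

#' Read an ontology parent table
#'
#' Lightweight ontology representation: one row per is_a/part_of edge with
#' columns \code{term}, \code{parent} (empty for roots) and optional
#' \code{name}.  The parent graph must be acyclic.
#'
#' @param path path to a TSV file.
#' @return data.frame with columns \code{term}, \code{parent}, \code{name}.
#' @export
readOntologyTable <- function(path) {
    df <- .read_id_table(path, "ontology")
    if (ncol(df) < 2L)
        stop("ontology table needs columns term and parent")
    out <- data.frame(term = df[[1L]], parent = df[[2L]],
                      stringsAsFactors = FALSE)
    out$name <- if (ncol(df) >= 3L) df[[3L]] else NA_character_
    if (any(!nzchar(out$term)))
        stop("ontology table contains blank term ids")
    if (!isOntologyAcyclic(out))
        stop("ontology parent graph contains a cycle")
    out
}

#' Check that an ontology parent graph is acyclic
#'
#' Kahn-style topological elimination over the term -> parent edges.
#'
#' @param ontology data.frame with columns \code{term}, \code{parent}.
#' @return \code{TRUE} when acyclic, \code{FALSE} otherwise.
#' @export
isOntologyAcyclic <- function(ontology) {
    edges <- ontology[nzchar(ontology$parent) & !is.na(ontology$parent),
                      c("term", "parent")]
    if (!nrow(edges))
        return(TRUE)
    nodes <- unique(c(edges$term, edges$parent))
    repeat {
        ## nodes with no outgoing edge (no parent left) can be eliminated
        sinks <- setdiff(nodes, unique(edges$term))
        if (!length(sinks))
            break
        nodes <- setdiff(nodes, sinks)
        edges <- edges[!(edges$parent %in% sinks) | (edges$term %in% nodes), ]
        edges <- edges[edges$term %in% nodes & edges$parent %in% nodes, ]
        if (!length(nodes) || !nrow(edges))
            break
    }
    length(nodes) == 0L || nrow(edges) == 0L
}

#' Export an abundance matrix as CSV
#'
#' Writes mean normalized spectrum counts with non-detected cells left
#' empty (the printed tables' \dQuote{ND} convention).
#'
#' @param x an \code{\linkS4class{AbundanceMatrix}}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeAbundanceCSV <- function(x, path) {
    stopifnot(is(x, "AbundanceMatrix"))
    ab <- abundance(x)
    de <- detected(x)
    chr <- matrix("", nrow(ab), ncol(ab), dimnames = dimnames(ab))
    chr[de] <- format(ab[de], trim = TRUE, scientific = FALSE, digits = 7)
    out <- data.frame(gene_symbol = rownames(ab), chr, check.names = FALSE,
                      stringsAsFactors = FALSE)
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read an abundance matrix exported by \code{writeAbundanceCSV}
#'
#' @param path CSV path; first column \code{gene_symbol}, remaining columns
#'   samples, empty cells meaning not detected.
#' @return An \code{\linkS4class{AbundanceMatrix}}.
#' @export
readAbundanceCSV <- function(path) {
    if (!file.exists(path))
        stop("abundance CSV not found: ", path)
    df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
    if (names(df)[1L] != "gene_symbol")
        stop("abundance CSV must start with a gene_symbol column")
    syms <- df[[1L]]
    vals <- as.matrix(df[, -1L, drop = FALSE])
    de <- nzchar(vals) & !is.na(vals)
    num <- matrix(0, nrow(vals), ncol(vals),
                  dimnames = list(syms, colnames(vals)))
    num[de] <- as.numeric(vals[de])
    AbundanceMatrix(num, detected = de)
}
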