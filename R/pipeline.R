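## End-to-end orchestration: validate -> quantify -> classify -> overlap
## -> cluster/enrich -> network -> compare, with a manifest recording the
## seed, a config hash, per-stage record counts and every file written.

.pipelineDefaults <- function() {
    list(reports = NULL,          # path(s) to identification report TSVs
         matrix = NULL,           # "table1" or abundance CSV path
         annotations = NULL,      # path or data.frame
         ontology = NULL,         # path or data.frame
         propagate = FALSE,
         edgeLists = NULL,        # list of paths or data.frames
         orthologMap = NULL,      # path or data.frame
         policy = list(),         # ValidationPolicy arguments
         linkage = "average",
         clusterThreshold = 0.5,
         alpha = 0.05,
         backgroundMode = "classified",  # or "all"
         includeIsolates = FALSE,
         eulerSets = NULL,        # sample ids for overlap cardinalities
         overlapReference = NULL,
         overlapOthers = NULL,
         supportive = NULL,
         unsupportive = NULL,
         foldThreshold = 2,
         groupRule = "all",
         seed = 1L)
}

.configHash <- function(config) {
    f <- tempfile()
    on.exit(unlink(f))
    ## canonical serialization: sorted keys, JSON text
    keys <- sort(names(config))
    writeLines(jsonlite::toJSON(config[keys], auto_unbox = TRUE,
                                digits = NA, null = "null",
                                force = TRUE), f)
    unname(tools::md5sum(f))
}

.asTable <- function(x, reader) {
    if (is.null(x) || is.data.frame(x)) x else reader(x)
}

#' Run the full comparative ECM proteomics pipeline
#'
#' Executes the analysis stages in order on either raw identification
#' reports (validate, quantify) or a pre-normalized abundance matrix
#' (\emph{matrix-entry} mode, e.g. the packaged published table via
#' \code{matrix = "table1"}), followed by classification, overlap
#' statistics, profile clustering with per-cluster GO enrichment,
#' interaction network topology, and the supportive-versus-unsupportive
#' comparison.  Every output file is written under \code{outDir} and
#' listed in \code{manifest.json} together with the seed, a hash of the
#' configuration and per-stage record counts; a fixed config and seed
#' reproduce byte-identical numeric outputs.
#'
#' @param config named list overriding the defaults (see
#'   \code{ecmProfiler:::.pipelineDefaults()}); unknown keys are an
#'   error.  Either \code{reports} (identification report TSV paths) or
#'   \code{matrix} (\code{"table1"} or an abundance CSV path) must be
#'   supplied.
#' @param outDir output directory (created if needed).
#' @return The manifest, invisibly, as a list.
#'
#' @examples
#' \donttest{
#' out <- tempfile()
#' manifest <- runPipeline(list(matrix = "table1",
#'                              supportive = "ihPSF",
#'                              unsupportive = "hPSF"), out)
#' manifest$stages$compare
#' }
#'
#' @export
runPipeline <- function(config = list(), outDir) {
    defaults <- .pipelineDefaults()
    unknown <- setdiff(names(config), names(defaults))
    if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg <- utils::modifyList(defaults, config)
    if (is.null(cfg$reports) && is.null(cfg$matrix))
        stop("config needs either 'reports' or 'matrix'")
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    set.seed(cfg$seed)
    files <- character(0)
    stages <- list()
    emit <- function(name) { files <<- c(files, name); file.path(outDir, name) }
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop(sprintf("stage '%s': %s", name, conditionMessage(e)),
                 call. = FALSE))
    }

    ## -- validate + quantify, or matrix entry ------------------------------
    if (!is.null(cfg$matrix)) {
        mat <- stage("load_matrix", {
            if (identical(cfg$matrix, "table1")) loadTable1()
            else readAbundanceCSV(cfg$matrix)
        })
        stages$load_matrix <- list(proteins = nrow(mat),
                                   samples = ncol(mat))
        if (identical(cfg$matrix, "table1") && is.null(cfg$annotations))
            cfg$annotations <- loadTable1Annotations()
    } else {
        paths <- cfg$reports
        records <- stage("read_reports", {
            do.call(rbind, lapply(paths, readIdentificationReport))
        })
        val <- stage("validate", {
            policy <- do.call(ValidationPolicy, cfg$policy)
            acceptIdentifications(records, policy)
        })
        utils::write.table(val$rejected, emit("rejections.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        fdr <- stage("validate", estimateProteinFdr(val$accepted))
        jsonlite::write_json(list(fdr_percent = fdr,
                                  accepted = nrow(val$accepted),
                                  rejected = nrow(val$rejected)),
                             emit("fdr.json"), auto_unbox = TRUE, digits = NA)
        stages$validate <- list(accepted = nrow(val$accepted),
                                rejected = nrow(val$rejected),
                                fdr_percent = fdr)
        mat <- stage("quantify", {
            targets <- val$accepted[!val$accepted$is_decoy, , drop = FALSE]
            buildAbundanceMatrix(targets)
        })
        stages$quantify <- list(proteins = nrow(mat), samples = ncol(mat))
    }
    writeAbundanceCSV(mat, emit("abundance.csv"))

    ## -- classify ----------------------------------------------------------
    annotations <- .asTable(cfg$annotations, readAnnotations)
    ontology <- .asTable(cfg$ontology, readOntologyTable)
    classes <- NULL
    if (!is.null(annotations)) {
        cl <- stage("classify",
            classifyProteins(rownames(mat), annotations, ontology,
                             propagate = isTRUE(cfg$propagate)))
        classes <- structure(cl$cls, names = cl$symbol)
        utils::write.table(cl[, c("symbol", "cls")],
                           emit("classification.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        stages$classify <- as.list(table(cl$cls))
    }

    ## -- overlap -----------------------------------------------------------
    overlap <- list()
    de <- detected(mat)
    keepRows <- if (is.null(classes)) rownames(mat)
                else names(classes)[classes %in% c("extracellular",
                                                   "cell_surface")]
    eulerSamples <- cfg$eulerSets
    if (is.null(eulerSamples) && ncol(mat) <= 5L)
        eulerSamples <- colnames(mat)
    if (!is.null(eulerSamples)) {
        sets <- lapply(eulerSamples, function(s)
            intersect(rownames(de)[de[, s]], keepRows))
        names(sets) <- eulerSamples
        ov <- stage("overlap", eulerCardinalities(sets))
        overlap$region_cardinalities <- as.list(ov@regionCardinalities)
    }
    if (!is.null(cfg$overlapReference)) {
        sh <- stage("overlap",
            sharedWithReference(mat, cfg$overlapReference,
                                cfg$overlapOthers, classes = classes))
        sh$counts <- as.list(sh$counts)      # keep sample names in JSON
        sh$percent <- as.list(sh$percent)
        overlap$shared_with_reference <- sh
    }
    if (length(overlap)) {
        jsonlite::write_json(overlap, emit("overlap.json"),
                             auto_unbox = TRUE, digits = NA)
        stages$overlap <- list(computed = names(overlap))
    }

    ## -- cluster + enrich --------------------------------------------------
    cs <- stage("cluster",
        clusterProteins(mat, linkage = cfg$linkage,
                        threshold = cfg$clusterThreshold))
    assign <- data.frame(
        protein = c(unlist(clusters(cs), use.names = FALSE), cs@singletons),
        cluster = c(rep(names(clusters(cs)), lengths(clusters(cs))),
                    rep("singleton", length(cs@singletons))),
        stringsAsFactors = FALSE)
    utils::write.table(assign[order(match(assign$protein, cs@leafOrder)), ],
                       emit("clusters.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    stages$cluster <- list(clusters = length(clusters(cs)),
                           singletons = length(cs@singletons))
    if (!is.null(annotations)) {
        bg <- if (identical(cfg$backgroundMode, "classified") &&
                  !is.null(classes))
            intersect(cs@leafOrder, names(classes)[classes != "other"])
        else cs@leafOrder
        annBg <- annotations[annotations$symbol %in% bg, , drop = FALSE]
        enr <- stage("enrich", {
            clBg <- lapply(clusters(cs), function(p) intersect(p, bg))
            clBg <- clBg[lengths(clBg) >= 2L]
            res <- lapply(names(clBg), function(id) {
                r <- enrichCluster(clBg[[id]], annBg, bg,
                                   alpha = cfg$alpha)
                if (nrow(r)) cbind(cluster = id, r) else NULL
            })
            res <- res[!vapply(res, is.null, logical(1))]
            if (length(res))
                do.call(rbind, c(res, list(make.row.names = FALSE)))
            else data.frame()
        })
        utils::write.table(enr, emit("enrichment.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        stages$enrich <- list(tested = nrow(enr),
                              significant = if (nrow(enr))
                                  sum(enr$significant) else 0L)
    }

    ## -- network -----------------------------------------------------------
    degrees <- NULL
    if (!is.null(cfg$edgeLists)) {
        nets <- stage("network", {
            els <- lapply(cfg$edgeLists, .asTable, reader = readEdgeList)
            merged <- mergeInteractomes(els)
            hits <- keepRows
            if (!is.null(cfg$orthologMap)) {
                om <- .asTable(cfg$orthologMap, readOrthologMap)
                mouse <- hits[hits %in% om$mouse]
                if (length(mouse))
                    hits <- union(setdiff(hits, mouse),
                                  mapOrthologs(mouse, om)$mapped)
            }
            induceAndMeasure(merged, hits,
                             includeIsolates = isTRUE(cfg$includeIsolates))
        })
        utils::write.table(nets@nodeMetrics, emit("network_nodes.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        writeEdgeList(nets, emit("network_edges.tsv"))
        degrees <- structure(as.numeric(nets@nodeMetrics$degree),
                             names = nets@nodeMetrics$symbol)
        stages$network <- list(nodes = igraph::vcount(nets@graph),
                               edges = igraph::ecount(nets@graph),
                               density = nets@density)
    }

    ## -- compare -----------------------------------------------------------
    if (!is.null(cfg$supportive) && !is.null(cfg$unsupportive)) {
        cmp <- stage("compare",
            differentialReport(mat, cfg$supportive, cfg$unsupportive,
                               classes = classes,
                               foldThreshold = cfg$foldThreshold,
                               groupRule = cfg$groupRule,
                               degrees = degrees))
        jsonlite::write_json(comparisonAsList(cmp), emit("comparison.json"),
                             auto_unbox = TRUE, digits = NA)
        stages$compare <- list(
            unique_to_supportive = length(cmp@uniqueToSupportive),
            unique_to_unsupportive = length(cmp@uniqueToUnsupportive),
            enriched = nrow(cmp@enriched))
    }

    ## -- manifest ----------------------------------------------------------
    manifest <- list(seed = cfg$seed,
                     configHash = .configHash(cfg[!vapply(cfg, is.object,
                                                          logical(1))]),
                     stages = stages,
                     files = files)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    invisible(manifest)
}
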