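# End-to-end pipeline: (simulate | load) -> optional rarefaction ->
# Hill diversity -> beta-partition -> null model -> Bray-Curtis /
# dispersion -> diversity-function correlations -> consolidated report.

#' Run the full assembly-analysis pipeline
#'
#' Orchestrates every stage on either a pair of input files (count table
#' + sample metadata TSV) or a synthetic experiment — exactly one of the
#' two must be supplied. All stage outputs are written to `outputDir` as
#' TSV, plus a JSON run report with provenance, file manifest and a
#' per-treatment summary. Identical configuration and seed give
#' byte-identical stage tables; any stage failure aborts the run with a
#' stage-named error.
#'
#' @param countsFile,metadataFile input TSV paths (see
#'   [readCountTable()], [readSampleMetadata()]); both or neither.
#' @param simulation a [SimulationConfig-class], mutually exclusive with
#'   the input files.
#' @param outputDir output directory, created if needed.
#' @param rarefactionDepth optional even depth to subsample every sample
#'   to before analysis (`NULL` = use the table as given).
#' @param q Hill orders, subset of `c(0, 1, 2)`.
#' @param nIter null-model randomizations per treatment.
#' @param fdrRate FDR for the correlation family (default 0.10).
#' @param transform Bray-Curtis transform, `"sqrt"` or `"none"`.
#' @param day restrict diversity/null-model/dispersion stages to one
#'   sampling day (`NULL` = all samples).
#' @param seed master seed for every random stage.
#' @param verbose log stage progress to stderr.
#' @return the run report, invisibly (a list mirroring `report.json`).
#' @export
runPipeline <- function(countsFile = NULL, metadataFile = NULL,
                        simulation = NULL, outputDir,
                        rarefactionDepth = NULL, q = c(0, 1, 2),
                        nIter = 10000L, fdrRate = 0.10,
                        transform = c("sqrt", "none"), day = NULL,
                        seed = 1L, verbose = TRUE) {
    transform <- match.arg(transform)
    stopifnot(all(q %in% c(0, 1, 2)), nIter >= 2)
    haveFiles <- !is.null(countsFile) || !is.null(metadataFile)
    if (haveFiles && (is.null(countsFile) || is.null(metadataFile)))
        stop("countsFile and metadataFile must be given together",
             call. = FALSE)
    if (haveFiles == !is.null(simulation))
        stop("supply exactly one of (countsFile + metadataFile) or ",
             "simulation", call. = FALSE)
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    note <- function(...) if (verbose) message("[betadev] ", ...)
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("stage '", name, "': ", conditionMessage(e),
                 call. = FALSE))
    }
    manifest <- character()
    emit <- function(name, writer) {
        path <- file.path(outputDir, name)
        writer(path)
        manifest[[name]] <<- path
        path
    }

    note("input stage")
    x <- stage("input", {
        if (haveFiles) {
            communityExperiment(readCountTable(countsFile),
                                readSampleMetadata(metadataFile))
        } else {
            ce <- generateExperiment(simulation)
            emit("counts.tsv", function(p) writeCountTable(ce, p))
            ce
        }
    })
    cd <- SummarizedExperiment::colData(x)
    emit("metadata.tsv", function(p)
        writeSampleMetadata(data.frame(sample_id = rownames(cd),
                                       as.data.frame(cd)), p))

    if (!is.null(rarefactionDepth)) {
        note("rarefaction stage (depth ", rarefactionDepth, ")")
        x <- stage("rarefy", rarefy(x, rarefactionDepth,
                                    seed = .substreamSeed(seed, "rarefy")))
        emit("counts_rarefied.tsv", function(p) writeCountTable(x, p))
    }

    note("diversity stage")
    diversity <- stage("diversity", hillProfile(x, q = q))
    emit("diversity.tsv", function(p)
        write.table(diversity, p, sep = "\t", quote = FALSE,
                    row.names = FALSE))
    betas <- stage("beta_partition", betaPartitionTable(x, q = q,
                                                        day = day))
    emit("beta_partition.tsv", function(p)
        write.table(betas, p, sep = "\t", quote = FALSE,
                    row.names = FALSE))

    note("null model stage (", nIter, " iterations)")
    nm <- stage("null_model",
                as.data.frame(runNullModel(x, q = q, nIter = nIter,
                                           seed = seed, day = day)))
    emit("null_model.tsv", function(p)
        write.table(nm, p, sep = "\t", quote = FALSE, row.names = FALSE))

    note("dissimilarity stage")
    bc <- stage("dissimilarity", brayCurtisMatrix(x, transform = transform))
    emit("bray_curtis.tsv", function(p)
        write.table(data.frame(sample_id = rownames(bc), bc,
                               check.names = FALSE),
                    p, sep = "\t", quote = FALSE, row.names = FALSE))
    disp <- stage("dispersion", withinTreatmentDispersion(bc, x))
    emit("dispersion.tsv", function(p)
        write.table(disp, p, sep = "\t", quote = FALSE,
                    row.names = FALSE))

    correlations <- NULL
    if ("function_value" %in% colnames(cd) &&
        !all(is.na(cd$function_value))) {
        note("correlation stage (FDR ", fdrRate, ")")
        correlations <- stage("correlations",
            diversityFunctionCorrelations(x, q = intersect(q, c(1, 2)),
                                          rate = fdrRate))
        emit("correlations.tsv", function(p)
            write.table(correlations, p, sep = "\t", quote = FALSE,
                        row.names = FALSE))
    }

    note("summary stage")
    summaryTab <- stage("summary",
                        .treatmentSummary(diversity, cd, nm, disp, q))
    emit("summary.tsv", function(p)
        write.table(summaryTab, p, sep = "\t", quote = FALSE,
                    row.names = FALSE))

    report <- list(
        package = "betadev",
        version = as.character(packageVersion("betadev")),
        timestamp = format(Sys.time(), tz = "UTC",
                           format = "%Y-%m-%dT%H:%M:%SZ"),
        seed = seed,
        config = list(
            input = if (haveFiles) list(counts = countsFile,
                                        metadata = metadataFile)
                    else "simulated",
            simulation = if (!haveFiles) .configAsList(simulation),
            rarefaction_depth = rarefactionDepth, q = q, n_iter = nIter,
            fdr_rate = fdrRate, transform = transform, day = day),
        manifest = as.list(manifest),
        summary = summaryTab)
    writeReport(report, file.path(outputDir, "report.json"))
    note("done; report at ", file.path(outputDir, "report.json"))
    invisible(report)
}

.treatmentSummary <- function(diversity, cd, nm, disp, q) {
    tr <- as.character(cd$treatment)[match(diversity$sample_id,
                                           rownames(cd))]
    rows <- list()
    for (t in unique(as.character(cd$treatment))) for (qq in q) {
        D <- diversity$D[tr == t & diversity$q == qq]
        sel <- nm$treatment == t & nm$q == qq
        rows[[paste(t, qq)]] <- data.frame(
            treatment = t, q = qq,
            hill_mean = mean(D), hill_sd = if (length(D) > 1) sd(D) else NA,
            n_samples = length(D),
            beta_obs = if (any(sel)) nm$beta_obs[sel] else NA,
            ses = if (any(sel)) nm$ses[sel] else NA,
            si = if (any(sel)) nm$si[sel] else NA,
            dispersion_mean = if (t %in% disp$treatment)
                disp$mean[disp$treatment == t] else NA)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

.configAsList <- function(config) {
    if (is.null(config)) return(NULL)
    sn <- methods::slotNames(config)
    out <- lapply(sn, function(s) slot(config, s))
    names(out) <- sn
    out
}

#' Write a run report as JSON
#'
#' @param report list as produced by [runPipeline()].
#' @param path output path.
#' @export
writeReport <- function(report, path) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' Flat key-value YAML mirroring [runPipeline()]'s arguments; keys under
#' `simulation:` mirror [simulationConfig()]'s arguments. The returned
#' list can be spliced into [runPipeline()] with `do.call()`.
#'
#' @param path YAML file path.
#' @return named list of `runPipeline` arguments.
#' @export
readPipelineConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    if (!is.null(cfg$simulation))
        cfg$simulation <- do.call(simulationConfig, cfg$simulation)
    cfg
}
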