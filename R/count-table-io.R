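# Reading, writing and transforming OTU count tables and their sample
# metadata. The on-disk convention is the plain OTU-table TSV: UTF-8,
# tab-separated, first column OTU identifiers, remaining columns one per
# sample, integer read counts, no quoting.

#' Read an OTU count table from TSV
#'
#' @param path path to a tab-separated table; the first header cell names
#'   the OTU-id column, the remaining header cells are sample ids, body
#'   cells are integer read counts.
#' @param strict if `TRUE` (default) non-integer cells are an error; if
#'   `FALSE` they are rounded with a warning.
#' @param transpose set `TRUE` when the file stores samples in rows; the
#'   orientation is never guessed.
#' @return integer count matrix (OTUs in rows, samples in columns), row
#'   and column order as in the file.
#' @seealso [writeCountTable()], [communityExperiment()]
#' @export
readCountTable <- function(path, strict = TRUE, transpose = FALSE) {
    if (!file.exists(path))
        stop("count table not found: ", path, call. = FALSE)
    raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                      colClasses = "character", quote = "")
    if (ncol(raw) < 1L)
        stop("count table has no columns: ", path, call. = FALSE)
    ids <- raw[[1L]]
    if (anyDuplicated(ids))
        stop("duplicated OTU id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "),
             call. = FALSE)
    samples <- colnames(raw)[-1L]
    if (anyDuplicated(samples))
        stop("duplicated sample id(s): ",
             paste(unique(samples[duplicated(samples)]), collapse = ", "),
             call. = FALSE)
    body <- as.matrix(raw[, -1L, drop = FALSE])
    num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
    bad <- which(is.na(num) | num < 0, arr.ind = TRUE)
    if (nrow(bad)) {
        i <- bad[1L, 1L]; j <- bad[1L, 2L]
        stop(sprintf(
            "invalid count '%s' at OTU '%s', sample '%s' (%s)",
            body[i, j], ids[i], samples[j],
            if (is.na(num[i, j])) "not numeric" else "negative"),
            call. = FALSE)
    }
    frac <- which(num != round(num), arr.ind = TRUE)
    if (nrow(frac)) {
        i <- frac[1L, 1L]; j <- frac[1L, 2L]
        if (strict)
            stop(sprintf(
                "non-integer count '%s' at OTU '%s', sample '%s'",
                body[i, j], ids[i], samples[j]), call. = FALSE)
        warning("non-integer counts rounded to nearest integer")
        num <- round(num)
    }
    dimnames(num) <- list(ids, samples)
    storage.mode(num) <- "integer"
    if (transpose) num <- t(num)
    .assertCountMatrix(num)
}

#' Write an OTU count table to TSV
#'
#' Inverse of [readCountTable()]: integer tables round-trip
#' bit-identically.
#'
#' @param counts integer count matrix or [CommunityExperiment-class].
#' @param path output path.
#' @param idColumn header name for the OTU-id column.
#' @export
writeCountTable <- function(counts, path, idColumn = "otu_id") {
    counts <- .asCounts(counts)
    .assertCountMatrix(counts)
    ids <- rownames(counts)
    if (is.null(ids)) ids <- character(nrow(counts))
    df <- data.frame(ids, counts, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df)[1L] <- idColumn
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8")
    invisible(path)
}

#' Read sample design metadata from TSV
#'
#' @param path TSV with required columns `sample_id`, `treatment`,
#'   `replicate`, `day`; extra columns are preserved.
#' @return `data.frame` with one row per sample.
#' @export
readSampleMetadata <- function(path) {
    if (!file.exists(path))
        stop("metadata file not found: ", path, call. = FALSE)
    md <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                     quote = "", stringsAsFactors = FALSE)
    need <- c("sample_id", "treatment", "replicate", "day")
    miss <- setdiff(need, colnames(md))
    if (length(miss))
        stop("metadata lacks required column(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
    if (anyDuplicated(md$sample_id))
        stop("duplicated sample_id: ",
             paste(unique(md$sample_id[duplicated(md$sample_id)]),
                   collapse = ", "), call. = FALSE)
    key <- paste(md$treatment, md$replicate, md$day, sep = "\r")
    if (anyDuplicated(key))
        stop("duplicated (treatment, replicate, day) triple", call. = FALSE)
    md$day <- as.integer(md$day)
    md
}

#' Write sample metadata to TSV
#'
#' @param metadata `data.frame` as returned by [readSampleMetadata()].
#' @param path output path.
#' @export
writeSampleMetadata <- function(metadata, path) {
    write.table(metadata, path, sep = "\t", quote = FALSE,
                row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

#' Rarefy samples to an even read depth
#'
#' Random subsampling without replacement (multivariate hypergeometric
#' per sample) to a common depth, mirroring the subsampling of sequencing
#' reads to even depth before analysis. Samples whose total is below
#' `depth` abort the call: silently dropping replicates would corrupt the
#' design.
#'
#' @param x count matrix or [CommunityExperiment-class].
#' @param depth target reads per sample; every column sum must be >=
#'   `depth`.
#' @param seed integer seed; the draw is deterministic given it.
#' @return object of the same kind as `x`, every sample summing to
#'   `depth`.
#' @export
rarefy <- function(x, depth, seed = 1L) {
    counts <- .asCounts(x)
    .assertCountMatrix(counts)
    depth <- as.integer(depth)
    if (depth < 1L) stop("depth must be positive", call. = FALSE)
    tot <- colSums(counts)
    low <- which(tot < depth)
    if (length(low))
        stop("sample(s) below requested depth ", depth, ": ",
             paste(colnames(counts)[low], collapse = ", "), call. = FALSE)
    out <- .withSeed(seed, C_rarefy(counts, depth))
    dimnames(out) <- dimnames(counts)
    if (is(x, "SummarizedExperiment")) {
        SummarizedExperiment::assay(x, "counts") <- out
        x
    } else out
}

#' Convert counts to relative abundances
#'
#' @param x count matrix or [CommunityExperiment-class]; every sample
#'   total must be positive.
#' @return numeric matrix whose columns each sum to 1.
#' @export
relativeAbundance <- function(x) {
    counts <- .asCounts(x)
    tot <- colSums(counts)
    zero <- which(tot == 0)
    if (length(zero))
        stop("sample(s) with zero total count: ",
             paste(colnames(counts)[zero], collapse = ", "), call. = FALSE)
    sweep(counts, 2L, tot, "/")
}

#' Entrywise square-root transform
#'
#' Applied to relative abundances before Bray-Curtis to damp the
#' influence of dominant OTUs.
#'
#' @param x non-negative matrix (counts or proportions).
#' @return matrix of entrywise square roots.
#' @export
sqrtTransform <- function(x) {
    x <- .asCounts(x)
    if (any(x < 0)) stop("negative entries", call. = FALSE)
    sqrt(x)
}

#' Partition an experiment into per-treatment replicate blocks
#'
#' @param x [CommunityExperiment-class].
#' @param day restrict to samples of one day, or `NULL` for all.
#' @return named list of [TreatmentBlock-class], one per treatment level
#'   present, replicate columns ordered by replicate id; together the
#'   blocks partition the selected samples.
#' @export
splitByTreatment <- function(x, day = NULL) {
    stopifnot(is(x, "CommunityExperiment"))
    cd <- SummarizedExperiment::colData(x)
    keep <- if (is.null(day)) rep(TRUE, ncol(x)) else cd$day == day
    if (!any(keep))
        stop("no samples on day ", day, call. = FALSE)
    counts <- SummarizedExperiment::assay(x, "counts")[, keep, drop = FALSE]
    cd <- cd[keep, , drop = FALSE]
    treatments <- unique(as.character(cd$treatment))
    out <- lapply(treatments, function(tr) {
        sel <- which(cd$treatment == tr)
        sel <- sel[order(as.character(cd$replicate[sel]))]
        treatmentBlock(tr, counts[, sel, drop = FALSE])
    })
    names(out) <- treatments
    out
}
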