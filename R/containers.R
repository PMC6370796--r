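#' Construct a CommunityExperiment
#'
#' Bundles an OTU-by-sample integer count matrix with its sample design
#' metadata into a validated [CommunityExperiment-class]. Metadata rows
#' are matched to count columns by sample identifier; every sample in the
#' count table must be described.
#'
#' @param counts integer matrix, OTUs in rows (named), samples in columns
#'   (named).
#' @param metadata `data.frame` or [S4Vectors::DataFrame-class] with
#'   columns `sample_id`, `treatment`, `replicate`, `day` (extra columns,
#'   e.g. an ecosystem-function readout, are preserved).
#' @return a `CommunityExperiment`
#' @examples
#' counts <- matrix(c(5L, 3L, 2L, 4L), 2,
#'                  dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' md <- data.frame(sample_id = c("s1", "s2"), treatment = "L0",
#'                  replicate = c("R1", "R2"), day = 35)
#' communityExperiment(counts, md)
#' @export
communityExperiment <- function(counts, metadata) {
    .assertCountMatrix(counts)
    metadata <- as.data.frame(metadata)
    need <- c("sample_id", "treatment", "replicate", "day")
    miss <- setdiff(need, colnames(metadata))
    if (length(miss))
        stop("metadata lacks required column(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
    if (anyDuplicated(metadata$sample_id))
        stop("duplicated sample_id in metadata", call. = FALSE)
    absent <- setdiff(colnames(counts), metadata$sample_id)
    if (length(absent))
        stop("sample(s) missing from metadata: ",
             paste(absent, collapse = ", "), call. = FALSE)
    metadata <- metadata[match(colnames(counts), metadata$sample_id), ,
                         drop = FALSE]
    cd <- S4Vectors::DataFrame(metadata[setdiff(colnames(metadata),
                                                "sample_id")],
                               row.names = metadata$sample_id)
    storage.mode(counts) <- "integer"
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), colData = cd)
    new("CommunityExperiment", se)
}

#' Construct a TreatmentBlock
#'
#' @param treatment single treatment label.
#' @param counts integer OTU-by-replicate matrix; replicate identifiers
#'   may be given as `replicateIds` or as column names.
#' @param replicateIds optional replicate labels, one per column.
#' @return a validated [TreatmentBlock-class]
#' @examples
#' treatmentBlock("L0", matrix(c(2L, 0L, 0L, 2L), 2,
#'                dimnames = list(c("g1", "g2"), c("R1", "R2"))))
#' @export
treatmentBlock <- function(treatment, counts, replicateIds = NULL) {
    if (!is.matrix(counts))
        counts <- as.matrix(counts)
    if (!is.null(replicateIds)) colnames(counts) <- replicateIds
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0("R", seq_len(ncol(counts)))
    if (is.null(rownames(counts)))
        rownames(counts) <- paste0("OTU", seq_len(nrow(counts)))
    storage.mode(counts) <- "integer"
    new("TreatmentBlock", treatment = as.character(treatment),
        counts = counts)
}

#' @rdname TreatmentBlock-class
#' @export
setMethod("treatmentLabel", "TreatmentBlock", function(x) x@treatment)

#' @rdname TreatmentBlock-class
#' @export
setMethod("replicateIds", "TreatmentBlock", function(x) colnames(x@counts))

#' @rdname TreatmentBlock-class
#' @export
setMethod("blockCounts", "TreatmentBlock", function(x) x@counts)

setMethod("show", "TreatmentBlock", function(object) {
    cat("TreatmentBlock '", object@treatment, "': ",
        nrow(object@counts), " OTUs x ", ncol(object@counts),
        " replicates\n", sep = "")
    cat("  reads per replicate: ",
        paste(colSums(object@counts), collapse = ", "), "\n", sep = "")
})

setMethod("show", "Metacommunity", function(object) {
    cat("Metacommunity of", length(object@otuIds), "OTUs;",
        "most abundant:", signif(object@abundance[1L], 3), "\n")
})

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig:", object@nTreatments, "treatments x",
        object@nReplicates, "replicates,", object@nOtus, "OTUs, depth",
        object@depth, "\n")
    cat("  filterStrengths:",
        paste(object@filterStrengths, collapse = " "), "\n")
    cat("  dispersions (phi):",
        paste(object@dispersions, collapse = " "), "\n")
    cat("  seed:", object@seed, "\n")
})
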