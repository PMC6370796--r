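#' @importFrom methods new validObject is setClass setValidity setMethod
#'   setGeneric show callNextMethod slot as
#' @importFrom stats rnorm rmultinom rgamma runif rlnorm sd cor pt p.adjust
#' @importFrom utils read.delim write.table packageVersion
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame metadata
#' @useDynLib betadev, .registration = TRUE
NULL

.checkCountMatrix <- function(counts) {
    msg <- character()
    if (!is.matrix(counts) || !is.numeric(counts))
        return("'counts' must be a numeric matrix")
    if (anyNA(counts))
        msg <- c(msg, "counts contain NA")
    else {
        if (any(counts < 0))
            msg <- c(msg, "counts contain negative values")
        if (any(counts != round(counts)))
            msg <- c(msg, "counts contain non-integer values")
    }
    if (nrow(counts) > 0 &&
        (is.null(rownames(counts)) || anyDuplicated(rownames(counts))))
        msg <- c(msg, "OTU identifiers (rownames) must be present and unique")
    if (ncol(counts) > 0 &&
        (is.null(colnames(counts)) || anyDuplicated(colnames(counts))))
        msg <- c(msg, "sample identifiers (colnames) must be present and unique")
    msg
}

#' Container for a replicated community profiling experiment
#'
#' `CommunityExperiment` extends
#' [SummarizedExperiment::SummarizedExperiment-class] with a validity
#' contract tailored to replicated OTU count data: a single integer
#' `counts` assay (OTUs in rows, samples in columns, all entries
#' non-negative integers) and column metadata carrying the experimental
#' design columns `treatment`, `replicate` and `day`, with unique sample
#' identifiers and unique (treatment, replicate, day) triples.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment-class]; no
#'   additional slots are introduced.
#' @seealso [communityExperiment()] for construction,
#'   [splitByTreatment()] for decomposition into [TreatmentBlock-class]
#'   objects.
#' @export
setClass("CommunityExperiment", contains = "SummarizedExperiment")

setValidity("CommunityExperiment", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("assay 'counts' is required")
    counts <- SummarizedExperiment::assay(object, "counts")
    msg <- c(msg, .checkCountMatrix(counts))
    cd <- SummarizedExperiment::colData(object)
    need <- c("treatment", "replicate", "day")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        msg <- c(msg, paste0("colData lacks required column(s): ",
                             paste(miss, collapse = ", ")))
    else {
        key <- paste(cd$treatment, cd$replicate, cd$day, sep = "\r")
        if (anyDuplicated(key))
            msg <- c(msg, "(treatment, replicate, day) triples must be unique")
    }
    if (length(msg)) msg else TRUE
})

#' Replicate samples of one treatment level
#'
#' A `TreatmentBlock` holds the OTU-by-replicate count sub-matrix of all
#' replicate samples belonging to one treatment level. It is the unit on
#' which the beta-partition and the individual-based null model operate:
#' its column sums are the per-replicate read totals and its row sums the
#' per-OTU totals, both of which the null model holds fixed.
#'
#' @slot treatment single character label of the treatment level.
#' @slot counts integer matrix, OTUs in rows (named), replicates in
#'   columns (named); all entries non-negative, every column sum positive.
#' @seealso [treatmentBlock()], [betaPartition()], [drawNullTable()]
#' @export
setClass("TreatmentBlock",
         representation(treatment = "character", counts = "matrix"))

setValidity("TreatmentBlock", function(object) {
    msg <- character()
    if (length(object@treatment) != 1L || is.na(object@treatment))
        msg <- c(msg, "'treatment' must be a single label")
    msg <- c(msg, .checkCountMatrix(object@counts))
    if (ncol(object@counts) < 1L)
        msg <- c(msg, "a block needs at least one replicate")
    else if (!length(.checkCountMatrix(object@counts)) &&
             any(colSums(object@counts) <= 0))
        msg <- c(msg, "every replicate must contain at least one read")
    if (length(msg)) msg else TRUE
})

#' Regional species pool for the community simulator
#'
#' A `Metacommunity` is the simulator's regional pool: per-OTU relative
#' abundances (a lognormal-type rank abundance distribution, sorted
#' non-increasing) and a one-dimensional niche trait per OTU on \[0, 1\].
#' Treatment-level expected profiles are produced by Gaussian niche
#' filtering of this pool ([applyTreatmentFilter()]).
#'
#' @slot otuIds character, unique OTU labels.
#' @slot abundance numeric, relative abundances summing to 1, sorted
#'   non-increasing.
#' @slot trait numeric in \[0, 1\], one niche optimum per OTU.
#' @seealso [generateMetacommunity()]
#' @export
setClass("Metacommunity",
         representation(otuIds = "character", abundance = "numeric",
                        trait = "numeric"))

setValidity("Metacommunity", function(object) {
    msg <- character()
    n <- length(object@otuIds)
    if (n < 1L) msg <- c(msg, "at least one OTU is required")
    if (anyDuplicated(object@otuIds)) msg <- c(msg, "otuIds must be unique")
    if (length(object@abundance) != n || length(object@trait) != n)
        msg <- c(msg, "abundance and trait must have one entry per OTU")
    else {
        if (abs(sum(object@abundance) - 1) > 1e-12)
            msg <- c(msg, "abundances must sum to 1")
        if (any(object@abundance < 0))
            msg <- c(msg, "abundances must be non-negative")
        if (is.unsorted(rev(object@abundance)))
            msg <- c(msg, "abundances must be sorted non-increasing")
        if (any(object@trait < 0 | object@trait > 1))
            msg <- c(msg, "traits must lie in [0, 1]")
    }
    if (length(msg)) msg else TRUE
})

#' Parameterization of a synthetic disturbance experiment
#'
#' Full description of one simulated replicated disturbance experiment:
#' the metacommunity (size and lognormal spread), the per-treatment
#' niche-filter positions and strengths, the per-treatment
#' replicate-to-replicate dispersion regime, sequencing depth, replicate
#' counts and the master seed. Dispersion `phi` spans under-dispersed
#' (quasi-deterministic, `phi < 1`) through multinomial (`phi = 1`) to
#' over-dispersed, drift-like (`phi > 1`) sampling.
#'
#' @slot nOtus integer, number of genus-level OTUs in the pool.
#' @slot lognormalSigma non-negative spread of the lognormal rank
#'   abundance distribution (0 gives a perfectly even pool).
#' @slot nTreatments,nReplicates integers; `nReplicates >= 2` is needed
#'   for null-model-ready output.
#' @slot depth reads per sample (every sample column sums to this).
#' @slot environmentPositions numeric in \[0, 1\], one per treatment.
#' @slot nicheWidth positive Gaussian niche width (trait units).
#' @slot filterStrengths non-negative filtering exponents, one per
#'   treatment (0 = neutral, large = strict species sorting).
#' @slot dispersions non-negative dispersion `phi`, one per treatment.
#' @slot seed integer master seed; all randomness derives from it.
#' @slot nSeedReplicates integer, number of day-0 "seed" inoculum
#'   samples drawn from the unfiltered pool at `phi = 1` (0 = none).
#' @slot functionSlope,functionNoiseSd parameters of the optional
#'   emulated ecosystem-function readout
#'   `f = slope * 2D(profile) + N(0, noise)`; `functionSlope = NA`
#'   disables it.
#' @seealso [simulationConfig()], [idhPreset()], [generateExperiment()]
#' @export
setClass("SimulationConfig",
         representation(nOtus = "integer", lognormalSigma = "numeric",
                        nTreatments = "integer", nReplicates = "integer",
                        depth = "integer", environmentPositions = "numeric",
                        nicheWidth = "numeric", filterStrengths = "numeric",
                        dispersions = "numeric", seed = "integer",
                        nSeedReplicates = "integer",
                        functionSlope = "numeric",
                        functionNoiseSd = "numeric"))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    k <- object@nTreatments
    if (object@nOtus < 1L) msg <- c(msg, "nOtus must be >= 1")
    if (object@lognormalSigma < 0) msg <- c(msg, "lognormalSigma must be >= 0")
    if (k < 1L) msg <- c(msg, "nTreatments must be >= 1")
    if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
    if (object@depth < 1L) msg <- c(msg, "depth must be positive")
    for (s in c("environmentPositions", "filterStrengths", "dispersions"))
        if (length(slot(object, s)) != k)
            msg <- c(msg, sprintf("%s must have one entry per treatment", s))
    if (object@nicheWidth <= 0) msg <- c(msg, "nicheWidth must be > 0")
    if (length(object@filterStrengths) == k && any(object@filterStrengths < 0))
        msg <- c(msg, "filterStrengths must be >= 0")
    if (length(object@dispersions) == k && any(object@dispersions < 0))
        msg <- c(msg, "dispersions must be >= 0")
    if (object@nSeedReplicates < 0L)
        msg <- c(msg, "nSeedReplicates must be >= 0")
    if (length(msg)) msg else TRUE
})
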