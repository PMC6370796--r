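#' @rdname TreatmentBlock-class
#' @param object,x a `TreatmentBlock`
#' @export
setGeneric("treatmentLabel", function(x) standardGeneric("treatmentLabel"))

#' @rdname TreatmentBlock-class
#' @export
setGeneric("replicateIds", function(x) standardGeneric("replicateIds"))

#' @rdname TreatmentBlock-class
#' @export
setGeneric("blockCounts", function(x) standardGeneric("blockCounts"))

#' Mean replicate alpha diversity of a treatment block
#'
#' Arithmetic mean of the per-replicate Hill numbers of order `q`
#' (replicates weighted equally; with rarefied, equal-depth replicates
#' abundance weighting would be identical).
#'
#' @param x a [TreatmentBlock-class]
#' @param q Hill order, one of 0, 1, 2
#' @return mean effective number of OTUs across replicates
#' @seealso [gammaDiversity()], [betaPartition()]
#' @export
setGeneric("alphaDiversity", function(x, q) standardGeneric("alphaDiversity"))

#' Gamma diversity of a treatment block
#'
#' Hill number of order `q` of the pooled block: per-OTU counts are
#' summed over replicates and renormalized, so gamma is determined by the
#' row margins alone — exactly the quantity the individual-based null
#' model holds constant.
#'
#' @inheritParams alphaDiversity
#' @return effective number of OTUs of the pooled community
#' @export
setGeneric("gammaDiversity", function(x, q) standardGeneric("gammaDiversity"))

#' Multiplicative beta-partition of a treatment block
#'
#' Computes `beta = 1 - alphabar / gamma`, the among-replicate share of
#' the treatment's diversity: 0 when all replicates have identical
#' relative abundances, approaching `1 - 1/n` when `n` replicates are
#' compositionally disjoint (q = 0).
#'
#' @inheritParams alphaDiversity
#' @return one-row `data.frame` with columns `treatment`, `q`,
#'   `alpha_mean`, `gamma`, `beta`
#' @export
setGeneric("betaPartition", function(x, q) standardGeneric("betaPartition"))
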