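# Hill-number alpha diversity and the multiplicative beta-partition.
# Hill numbers express diversity as an effective number of equally
# abundant OTUs: q = 0 richness, q = 1 exp(Shannon entropy), q = 2
# inverse Simpson concentration; lower orders weight rare OTUs more.

.hillOne <- function(p, q) {
    if (q == 0) return(sum(p > 0))
    if (q == 1) {
        pos <- p[p > 0]                       # 0 * log 0 == 0 by limit
        return(exp(-sum(pos * log(pos))))
    }
    1 / sum(p^2)
}

#' Hill number of a relative-abundance vector
#'
#' @param p proportions summing to 1 (entries >= 0).
#' @param q diversity order, one of 0, 1, 2.
#' @return effective number of OTUs (>= 1 for any non-degenerate `p`).
#' @examples
#' hillNumber(c(0.8, 0.2), 1)   # 1.6494
#' hillNumber(c(0.8, 0.2), 2)   # 1.4706
#' @export
hillNumber <- function(p, q) {
    if (!is.numeric(p) || any(p < 0))
        stop("p must be non-negative", call. = FALSE)
    if (abs(sum(p) - 1) > 1e-8)
        stop("p must sum to 1 (got ", format(sum(p)), ")", call. = FALSE)
    if (!q %in% c(0, 1, 2))
        stop("q must be 0, 1 or 2", call. = FALSE)
    .hillOne(p, q)
}

#' Per-sample Hill diversity profile
#'
#' Computes Hill numbers on normalized, non-transformed relative
#' abundances for each sample.
#'
#' @param x count matrix or [CommunityExperiment-class].
#' @param q vector of orders, subset of `c(0, 1, 2)`.
#' @return long `data.frame` with columns `sample_id`, `q`, `D`.
#' @export
hillProfile <- function(x, q = c(0, 1, 2)) {
    stopifnot(all(q %in% c(0, 1, 2)))
    p <- relativeAbundance(x)
    out <- expand.grid(sample_id = colnames(p), q = q,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    out$D <- mapply(function(s, qq) .hillOne(p[, s], qq),
                    out$sample_id, out$q)
    out <- out[order(match(out$sample_id, colnames(p)), out$q), ]
    rownames(out) <- NULL
    out
}

#' @rdname alphaDiversity
#' @export
setMethod("alphaDiversity", "TreatmentBlock", function(x, q) {
    stopifnot(q %in% c(0, 1, 2))
    p <- relativeAbundance(x@counts)
    mean(vapply(seq_len(ncol(p)), function(j) .hillOne(p[, j], q),
                numeric(1)))
})

#' @rdname gammaDiversity
#' @export
setMethod("gammaDiversity", "TreatmentBlock", function(x, q) {
    stopifnot(q %in% c(0, 1, 2))
    pooled <- rowSums(x@counts)
    if (sum(pooled) == 0) stop("all-zero block", call. = FALSE)
    .hillOne(pooled / sum(pooled), q)
})

#' @rdname betaPartition
#' @export
setMethod("betaPartition", "TreatmentBlock", function(x, q) {
    a <- alphaDiversity(x, q)
    g <- gammaDiversity(x, q)
    data.frame(treatment = x@treatment, q = q, alpha_mean = a, gamma = g,
               beta = 1 - a / g)
})

#' Beta-partition table for a whole experiment
#'
#' Convenience wrapper applying [betaPartition()] to every treatment
#' block of an experiment for every requested order.
#'
#' @param x [CommunityExperiment-class].
#' @param q vector of orders, subset of `c(0, 1, 2)`.
#' @param day restrict to one sampling day, or `NULL` for all.
#' @return `data.frame` with one row per (treatment, q).
#' @export
betaPartitionTable <- function(x, q = c(0, 1, 2), day = NULL) {
    blocks <- splitByTreatment(x, day = day)
    do.call(rbind, unlist(lapply(blocks, function(b)
        lapply(q, function(qq) betaPartition(b, qq))), recursive = FALSE))
}
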