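# Bray-Curtis dissimilarity, within-treatment dispersion summaries,
# Spearman correlations and Benjamini-Hochberg FDR adjustment.

#' Bray-Curtis dissimilarity matrix
#'
#' Computes `BC(x, y) = 1 - 2 sum(min(x, y)) / (sum(x) + sum(y))` between
#' all sample pairs, on relative abundances, optionally square-root
#' transformed first (the convention for community-structure
#' comparisons). Distances are delegated to [vegan::vegdist()].
#'
#' @param x count matrix or [CommunityExperiment-class]; all sample
#'   totals must be positive.
#' @param transform `"sqrt"` (default) or `"none"`, applied after
#'   normalization.
#' @return symmetric numeric matrix in \[0, 1\] with zero diagonal and
#'   sample ids as dimnames.
#' @export
brayCurtisMatrix <- function(x, transform = c("sqrt", "none")) {
    transform <- match.arg(transform)
    p <- relativeAbundance(x)
    if (transform == "sqrt") p <- sqrt(p)
    d <- as.matrix(vegan::vegdist(t(p), method = "bray"))
    d[abs(d) < 1e-15] <- 0
    diag(d) <- 0
    (d + t(d)) / 2
}

#' Within-treatment dissimilarity summary
#'
#' Mean and standard deviation of all pairwise dissimilarities among the
#' replicates of each treatment — the scalar summary of replicate
#' divergence (dispersion) under identical handling.
#'
#' @param d symmetric dissimilarity matrix (e.g. from
#'   [brayCurtisMatrix()]) with sample ids as dimnames, or a `dist`.
#' @param metadata `data.frame` with columns `sample_id` and `treatment`
#'   (e.g. from [readSampleMetadata()]), or a
#'   [CommunityExperiment-class] whose colData is used.
#' @return `data.frame` with columns `treatment`, `mean`, `sd`,
#'   `n_pairs`; treatments with fewer than 2 samples are skipped with a
#'   warning.
#' @export
withinTreatmentDispersion <- function(d, metadata) {
    d <- as.matrix(d)
    if (is(metadata, "CommunityExperiment")) {
        cd <- SummarizedExperiment::colData(metadata)
        metadata <- data.frame(sample_id = rownames(cd),
                               treatment = as.character(cd$treatment))
    }
    ids <- rownames(d)
    tr <- metadata$treatment[match(ids, metadata$sample_id)]
    if (anyNA(tr))
        stop("sample(s) missing from metadata: ",
             paste(ids[is.na(tr)], collapse = ", "), call. = FALSE)
    out <- lapply(unique(tr), function(t) {
        sel <- which(tr == t)
        if (length(sel) < 2L) {
            warning("treatment '", t, "' has < 2 samples; skipped")
            return(NULL)
        }
        vals <- d[sel, sel][upper.tri(diag(length(sel)))]
        data.frame(treatment = t, mean = mean(vals),
                   sd = if (length(vals) > 1) sd(vals) else 0,
                   n_pairs = length(vals))
    })
    do.call(rbind, out)
}

# all permutations of 1..n as a matrix (rows); used for the exact
# permutation distribution of rho at small n
.permutations <- function(n) {
    if (n == 1L) return(matrix(1L, 1L, 1L))
    sub <- .permutations(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(i) {
        rest <- seq_len(n)[-i]
        cbind(i, matrix(rest[sub], nrow(sub)))
    }))
}

#' Spearman rank correlation with small-sample exact p-value
#'
#' Rank correlation with average ranks for ties. The two-sided p-value
#' comes from the full permutation distribution when `n <= 9` (all `n!`
#' pairings enumerated) and from the t approximation otherwise.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param label optional name for the pair being tested.
#' @return one-row `data.frame` with columns `pair`, `rho`, `p_value`,
#'   `n`; `rho` is `NA` (with a warning) when either vector is constant.
#' @export
spearmanCorrelation <- function(x, y, label = "") {
    if (length(x) != length(y))
        stop("x and y must have the same length", call. = FALSE)
    n <- length(x)
    if (n < 3L) stop("need at least 3 observations", call. = FALSE)
    if (anyNA(x) || anyNA(y)) {
        keep <- !(is.na(x) | is.na(y))
        x <- x[keep]; y <- y[keep]; n <- length(x)
        if (n < 3L) stop("fewer than 3 complete observations", call. = FALSE)
    }
    rx <- rank(x); ry <- rank(y)
    if (sd(rx) == 0 || sd(ry) == 0) {
        warning("constant vector: rho undefined")
        return(data.frame(pair = label, rho = NA_real_,
                          p_value = NA_real_, n = n))
    }
    rho <- cor(rx, ry)
    if (n <= 9L) {
        perms <- .permutations(n)
        # under permutation of the pairing only sum(rx_perm * ry) varies
        stat <- matrix(rx[perms], nrow(perms)) %*% ry
        obs <- sum(rx * ry)
        center <- n * mean(rx) * mean(ry)
        p <- mean(abs(stat - center) >= abs(obs - center) - 1e-9)
    } else {
        tval <- rho * sqrt((n - 2) / (1 - rho^2))
        p <- 2 * pt(-abs(tval), df = n - 2)
    }
    data.frame(pair = label, rho = rho, p_value = min(1, p), n = n)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values ([stats::p.adjust()] method `"BH"`) with
#' rejection flags at the requested false discovery rate.
#'
#' @param p p-values in \[0, 1\].
#' @param rate target FDR (default 0.10).
#' @return `data.frame` with columns `p_value`, `p_adjusted`,
#'   `significant`.
#' @export
bhFdrAdjust <- function(p, rate = 0.10) {
    if (any(p < 0 | p > 1, na.rm = TRUE))
        stop("p-values must lie in [0, 1]", call. = FALSE)
    adj <- p.adjust(p, method = "BH")
    data.frame(p_value = p, p_adjusted = adj,
               significant = !is.na(adj) & adj <= rate)
}

#' Diversity-function correlation screen
#'
#' Spearman correlations between per-sample Hill diversities (one test
#' per order in `q`) and an ecosystem-function readout, BH-adjusted as
#' one family.
#'
#' @param x [CommunityExperiment-class] whose colData carries the
#'   function readout.
#' @param functionColumn colData column holding the per-sample function
#'   value.
#' @param q Hill orders to test (default 1 and 2, the robust compound
#'   orders).
#' @param rate target FDR for the family.
#' @return `data.frame` with one row per order: `pair`, `rho`,
#'   `p_value`, `p_adjusted`, `significant`, `n`.
#' @export
diversityFunctionCorrelations <- function(x, functionColumn =
                                              "function_value",
                                          q = c(1, 2), rate = 0.10) {
    cd <- SummarizedExperiment::colData(x)
    if (!functionColumn %in% colnames(cd))
        stop("colData lacks column '", functionColumn, "'", call. = FALSE)
    f <- cd[[functionColumn]]
    prof <- hillProfile(x, q = q)
    rows <- do.call(rbind, lapply(q, function(qq) {
        D <- prof$D[prof$q == qq]
        spearmanCorrelation(D, f, label = sprintf("D%g_vs_%s", qq,
                                                  functionColumn))
    }))
    adj <- bhFdrAdjust(rows$p_value, rate = rate)
    cbind(rows[c("pair", "rho", "p_value")],
          adj[c("p_adjusted", "significant")], n = rows$n)
}
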