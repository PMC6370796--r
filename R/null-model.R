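# Individual-based null model of community assembly. Every read of a
# treatment block is randomly relocated among the block's replicate
# samples while the per-replicate read totals, the per-OTU totals, and
# therefore the pooled (gamma) diversity stay fixed. The induced
# distribution over tables is the multivariate hypergeometric (Fisher)
# distribution on fixed-margin contingency tables; it is sampled with a
# sequential hypergeometric allocation (Patefield-equivalent, compiled)
# rather than by literally permuting millions of read labels.

#' Draw one fixed-margin null table
#'
#' A single randomized table with exactly the observed block's row sums
#' (per-OTU read totals) and column sums (per-replicate read totals),
#' distributed as a uniform permutation of individual read labels.
#'
#' @param block a [TreatmentBlock-class] (>= 2 replicates for a
#'   non-degenerate randomization; 1 replicate returns the input with a
#'   warning since only one table exists).
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return integer matrix with the block's dimnames and margins.
#' @seealso [nullBetaDistribution()], [enumerateNullExact()]
#' @export
drawNullTable <- function(block, seed = NULL) {
    stopifnot(is(block, "TreatmentBlock"))
    counts <- block@counts
    if (ncol(counts) < 2L) {
        warning("single replicate: only one fixed-margin table exists")
        return(counts)
    }
    out <- .withSeed(seed, C_null_table(as.integer(rowSums(counts)),
                                        as.integer(colSums(counts))))
    dimnames(out) <- dimnames(counts)
    out
}

# Multivariate hypergeometric log-mass of a fixed-margin table
# (Fisher's exact distribution).
.logTableProb <- function(tab) {
    sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
        lgamma(sum(tab) + 1) - sum(lgamma(tab + 1))
}

#' Exact null distribution of beta by enumeration
#'
#' Enumerates every contingency table with the block's margins, weights
#' each by its multivariate hypergeometric probability, and returns the
#' exact distribution of `beta = 1 - alphabar/gamma`. Serves as the
#' independent oracle for the Monte-Carlo sampler; guarded to small
#' blocks.
#'
#' @param block a [TreatmentBlock-class].
#' @param q Hill order, one of 0, 1, 2.
#' @param maxTables enumeration guard; exceeded only when the block total
#'   is above 20 reads.
#' @return list with `support` (`data.frame` of distinct `beta` values
#'   and probabilities), `mean`, `sd` (population standard deviation) and
#'   `n_tables`.
#' @export
enumerateNullExact <- function(block, q, maxTables = 1e5) {
    stopifnot(is(block, "TreatmentBlock"), q %in% c(0, 1, 2))
    counts <- block@counts
    rowT <- rowSums(counts)
    colT <- colSums(counts)
    total <- sum(rowT)
    guardFree <- total <= 20
    acc <- new.env(parent = emptyenv())
    acc$beta <- numeric(); acc$logp <- numeric(); acc$n <- 0L
    nr <- nrow(counts); nc <- ncol(counts)
    tab <- matrix(0L, nr, nc)

    fillRow <- function(i, remCol) {
        # enumerate compositions of rowT[i] into nc cells bounded by remCol
        enumComp <- function(j, left, row) {
            if (j == nc) {
                if (left > remCol[nc]) return()
                row[nc] <- left
                tab[i, ] <<- row
                if (i == nr) {
                    acc$n <- acc$n + 1L
                    if (!guardFree && acc$n > maxTables)
                        stop("enumeration guard exceeded (", maxTables,
                             " tables)", call. = FALSE)
                    acc$beta[acc$n] <- .betaOfTable(tab, colT, rowT, total, q)
                    acc$logp[acc$n] <- .logTableProb(tab)
                } else fillRow(i + 1L, remCol - row)
                return()
            }
            for (v in 0:min(left, remCol[j])) {
                row[j] <- v
                enumComp(j + 1L, left - v, row)
            }
        }
        enumComp(1L, rowT[i], integer(nc))
    }
    fillRow(1L, colT)

    prob <- exp(acc$logp)
    beta <- round(acc$beta, 12)
    support <- stats::aggregate(prob, list(beta = beta), sum)
    names(support)[2L] <- "prob"
    mu <- sum(acc$beta * prob)
    sdev <- sqrt(sum((acc$beta - mu)^2 * prob))
    list(support = support, mean = mu, sd = sdev, n_tables = acc$n)
}

# beta of a table given fixed margins (gamma depends on row margins only)
.betaOfTable <- function(tab, colT, rowT, total, q) {
    a <- mean(vapply(seq_along(colT),
                     function(j) .hillOne(tab[, j] / colT[j], q),
                     numeric(1)))
    g <- .hillOne(rowT / total, q)
    1 - a / g
}

#' Monte-Carlo null distribution of beta
#'
#' Mean and sample standard deviation of `beta` over `nIter` independent
#' fixed-margin randomizations of the block, for each requested order.
#'
#' @param block a [TreatmentBlock-class] with >= 2 replicates.
#' @param q vector of orders, subset of `c(0, 1, 2)`; all orders reuse
#'   the same randomized tables.
#' @param nIter number of randomizations (>= 2); 10,000 is the
#'   conventional choice.
#' @param seed integer seed.
#' @param keepSamples attach the raw `beta` draws as attribute
#'   `"samples"` (an `nIter` x `length(q)` matrix).
#' @return `data.frame` with columns `q`, `null_mean`, `null_sd`.
#' @export
nullBetaDistribution <- function(block, q = c(0, 1, 2), nIter = 10000L,
                                 seed = 1L, keepSamples = FALSE) {
    stopifnot(is(block, "TreatmentBlock"), all(q %in% c(0, 1, 2)),
              nIter >= 2)
    if (ncol(block@counts) < 2L)
        stop("null distribution needs >= 2 replicates", call. = FALSE)
    betas <- .withSeed(seed,
        C_null_beta(block@counts, as.integer(q), as.integer(nIter)))
    out <- data.frame(q = q,
                      null_mean = colMeans(betas),
                      null_sd = apply(betas, 2L, sd))
    if (keepSamples) attr(out, "samples") <- betas
    out
}

#' Standardized effect size of beta-diversity
#'
#' `SES = (beta_obs - mean(beta_null)) / sd(beta_null)`. Magnitude
#' measures deviation from random assembly; values near zero indicate
#' stochastic-dominated assembly, negative values replicates more similar
#' than expected (deterministic convergence), positive values more
#' divergent.
#'
#' @param betaObs observed beta.
#' @param nullMean,nullSd moments of the null distribution.
#' @return SES, or `NA` when `nullSd` is 0 (undefined, not "at
#'   expectation").
#' @export
computeSES <- function(betaObs, nullMean, nullSd) {
    stopifnot(all(nullSd >= 0))
    ifelse(nullSd > 0, (betaObs - nullMean) / nullSd, NA_real_)
}

#' Stochastic intensity
#'
#' `SI = (beta_obs - mean(beta_null)) / beta_obs`, the null deviation
#' normalized by the observed beta.
#'
#' @inheritParams computeSES
#' @return SI, or `NA` when `betaObs` is 0.
#' @export
computeSI <- function(betaObs, nullMean) {
    ifelse(betaObs != 0, (betaObs - nullMean) / betaObs, NA_real_)
}

#' Run the null model over a whole experiment
#'
#' For every treatment level (optionally restricted to one sampling day)
#' and every order `q`, computes the observed beta-partition, the
#' Monte-Carlo null distribution under individual-based fixed-margin
#' randomization, and the derived SES and SI. Per-treatment randomization
#' streams are derived from the master seed, so results do not depend on
#' treatment processing order.
#'
#' @param x [CommunityExperiment-class].
#' @param q vector of orders, subset of `c(0, 1, 2)`.
#' @param nIter randomizations per treatment (default 10,000).
#' @param seed master integer seed.
#' @param day restrict to one sampling day, or `NULL` for all samples.
#' @return [S4Vectors::DataFrame-class] with one row per (treatment, q):
#'   `treatment`, `q`, `beta_obs`, `null_mean`, `null_sd`, `ses`, `si`,
#'   `n_iter`, `seed`. Treatments with a single replicate are skipped
#'   with a warning.
#' @export
runNullModel <- function(x, q = c(0, 1, 2), nIter = 10000L, seed = 1L,
                         day = NULL) {
    blocks <- splitByTreatment(x, day = day)
    single <- vapply(blocks, function(b) ncol(b@counts) < 2L, logical(1))
    if (any(single)) {
        warning("skipping treatment(s) with a single replicate: ",
                paste(names(blocks)[single], collapse = ", "))
        blocks <- blocks[!single]
    }
    rows <- lapply(blocks, function(b) {
        subSeed <- .substreamSeed(seed, "nullmodel", b@treatment)
        nd <- nullBetaDistribution(b, q = q, nIter = nIter, seed = subSeed)
        obs <- vapply(q, function(qq) betaPartition(b, qq)$beta, numeric(1))
        data.frame(treatment = b@treatment, q = q, beta_obs = obs,
                   null_mean = nd$null_mean, null_sd = nd$null_sd,
                   ses = computeSES(obs, nd$null_mean, nd$null_sd),
                   si = computeSI(obs, nd$null_mean),
                   n_iter = as.integer(nIter), seed = as.integer(seed))
    })
    res <- S4Vectors::DataFrame(do.call(rbind, rows))
    rownames(res) <- NULL
    res
}
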