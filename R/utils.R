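# Internal helpers: seeded evaluation, substream derivation, integer
# apportionment.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG state is untouched. `seed = NULL` uses the current stream.
.withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

# Derive a reproducible substream seed from a master seed and a tuple of
# indices (LCG-style hash, kept below 2^31 - 1 so set.seed() accepts it).
# Makes per-treatment / per-sample randomness independent of processing
# order.
.substreamSeed <- function(seed, ...) {
    h <- (abs(as.double(seed)) + 1) %% 2147483647
    for (k in c(...)) {
        v <- if (is.character(k)) sum(utf8ToInt(k) * seq_along(utf8ToInt(k)))
             else as.double(k)
        h <- (h * 48271 + v + 1) %% 2147483647
    }
    as.integer(h)
}

# Largest-remainder apportionment of non-negative weights `x` to integers
# summing to `total`; ties on the fractional part go to the lowest index.
.largestRemainder <- function(x, total) {
    stopifnot(all(x >= 0), total >= 0)
    if (sum(x) == 0) {
        out <- integer(length(x))
        out[1L] <- total
        return(out)
    }
    target <- x / sum(x) * total
    base <- floor(target)
    short <- total - sum(base)
    if (short > 0) {
        pick <- order(-(target - base), seq_along(x))[seq_len(short)]
        base[pick] <- base[pick] + 1
    }
    as.integer(base)
}

.assertCountMatrix <- function(counts, what = "counts") {
    msg <- .checkCountMatrix(counts)
    if (length(msg))
        stop(what, ": ", paste(msg, collapse = "; "), call. = FALSE)
    invisible(counts)
}

# Coerce the counts assay out of matrix-or-CommunityExperiment inputs.
.asCounts <- function(x) {
    if (is(x, "SummarizedExperiment"))
        x <- SummarizedExperiment::assay(x, "counts")
    if (!is.matrix(x))
        stop("expected a count matrix or a CommunityExperiment",
             call. = FALSE)
    x
}
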