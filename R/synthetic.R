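# Synthetic generator for replicated disturbance experiments: a
# lognormal metacommunity, Gaussian niche filtering whose strength varies
# along the treatment gradient, and replicate sampling whose dispersion
# spans quasi-deterministic through multinomial to drift-like regimes.

#' Construct a SimulationConfig
#'
#' @param nOtus number of OTUs in the metacommunity pool.
#' @param lognormalSigma lognormal spread of the rank abundance
#'   distribution (0 = perfectly even pool).
#' @param nTreatments,nReplicates design dimensions.
#' @param depth reads per sample.
#' @param environmentPositions per-treatment environmental position on
#'   the \[0, 1\] trait axis; default evenly spaced.
#' @param nicheWidth Gaussian niche width (trait units).
#' @param filterStrengths per-treatment niche-filter exponent (0 =
#'   neutral).
#' @param dispersions per-treatment dispersion `phi` (< 1
#'   under-dispersed, 1 multinomial, > 1 over-dispersed).
#' @param seed master seed.
#' @param nSeedReplicates number of day-0 inoculum samples (0 = none).
#' @param functionSlope,functionNoiseSd emulated ecosystem-function link
#'   `f = slope * 2D(profile) + N(0, noise)`; slope `NA` disables it.
#' @return a validated [SimulationConfig-class]
#' @seealso [idhPreset()], [generateExperiment()]
#' @export
simulationConfig <- function(nOtus = 300L, lognormalSigma = 1.5,
                             nTreatments = 8L, nReplicates = 3L,
                             depth = 50000L,
                             environmentPositions = NULL,
                             nicheWidth = 0.25,
                             filterStrengths = rep(1, nTreatments),
                             dispersions = rep(1, nTreatments),
                             seed = 1L, nSeedReplicates = 0L,
                             functionSlope = NA_real_,
                             functionNoiseSd = 0) {
    k <- as.integer(nTreatments)
    if (is.null(environmentPositions))
        environmentPositions <- if (k == 1L) 0.5 else
            (seq_len(k) - 1) / (k - 1)
    new("SimulationConfig", nOtus = as.integer(nOtus),
        lognormalSigma = lognormalSigma, nTreatments = k,
        nReplicates = as.integer(nReplicates), depth = as.integer(depth),
        environmentPositions = environmentPositions,
        nicheWidth = nicheWidth,
        filterStrengths = as.numeric(filterStrengths),
        dispersions = as.numeric(dispersions), seed = as.integer(seed),
        nSeedReplicates = as.integer(nSeedReplicates),
        functionSlope = functionSlope,
        functionNoiseSd = functionNoiseSd)
}

#' Disturbance-gradient preset
#'
#' A 8-treatment x 3-replicate configuration encoding the qualitative
#' expectation that the extreme ends of a disturbance-frequency gradient
#' are strongly niche-filtered and under-dispersed (deterministic
#' convergence of replicates) while intermediate treatments are weakly
#' filtered and near-multinomial (drift-like divergence): filter
#' strengths 4, 2, 1, 0.5, 0.5, 1, 2, 4 and dispersions 0.2, 0.8, 1, 1,
#' 1, 1, 0.8, 0.2 across evenly spaced environments, 300 OTUs, lognormal
#' sigma 1.5, 50,000 reads per sample. These constants are generator
#' defaults for emulation, not estimates of any real system.
#'
#' @param seed master seed.
#' @param depth reads per sample.
#' @param nOtus pool size.
#' @param nSeedReplicates day-0 inoculum samples (default 0).
#' @return a [SimulationConfig-class]
#' @export
idhPreset <- function(seed = 1L, depth = 50000L, nOtus = 300L,
                      nSeedReplicates = 0L) {
    simulationConfig(nOtus = nOtus, lognormalSigma = 1.5,
                     nTreatments = 8L, nReplicates = 3L, depth = depth,
                     nicheWidth = 0.25,
                     filterStrengths = c(4, 2, 1, 0.5, 0.5, 1, 2, 4),
                     dispersions = c(0.2, 0.8, 1, 1, 1, 1, 0.8, 0.2),
                     seed = seed, nSeedReplicates = nSeedReplicates,
                     functionSlope = 1, functionNoiseSd = 2)
}

#' Generate a metacommunity pool
#'
#' Relative abundances are normalized lognormal draws (sorted
#' non-increasing, the classic rank-abundance shape of community
#' surveys); niche traits are independent uniforms on \[0, 1\].
#'
#' @param nOtus pool size (>= 1).
#' @param lognormalSigma lognormal sd on the log scale; 0 gives an even
#'   pool.
#' @param seed integer seed.
#' @return a [Metacommunity-class]
#' @export
generateMetacommunity <- function(nOtus, lognormalSigma, seed = 1L) {
    nOtus <- as.integer(nOtus)
    if (nOtus < 1L) stop("nOtus must be >= 1", call. = FALSE)
    if (lognormalSigma < 0)
        stop("lognormalSigma must be >= 0", call. = FALSE)
    .withSeed(seed, {
        ab <- rlnorm(nOtus, meanlog = 0, sdlog = lognormalSigma)
        ab <- sort(ab / sum(ab), decreasing = TRUE)
        tr <- runif(nOtus)
        new("Metacommunity",
            otuIds = sprintf("OTU%04d", seq_len(nOtus)),
            abundance = ab, trait = tr)
    })
}

#' Apply a niche filter to the metacommunity
#'
#' Species sorting along the trait axis: each OTU's pool abundance is
#' multiplied by a Gaussian fitness weight
#' `w = exp(-(trait - environment)^2 / (2 nicheWidth^2))` raised to the
#' filter-strength exponent, then renormalized. Strength 0 returns the
#' pool unchanged (neutral); large strengths concentrate the community
#' on the OTUs whose traits best match the environment.
#'
#' @param meta a [Metacommunity-class].
#' @param environment environmental position in \[0, 1\].
#' @param nicheWidth positive Gaussian width.
#' @param filterStrength non-negative exponent.
#' @return named proportion vector summing to 1.
#' @export
applyTreatmentFilter <- function(meta, environment, nicheWidth,
                                 filterStrength) {
    stopifnot(is(meta, "Metacommunity"))
    if (nicheWidth <= 0) stop("nicheWidth must be > 0", call. = FALSE)
    if (filterStrength < 0)
        stop("filterStrength must be >= 0", call. = FALSE)
    # log space: w^F underflows for strong filters long before the
    # renormalized profile is degenerate
    logw <- -(meta@trait - environment)^2 / (2 * nicheWidth^2)
    lp <- log(meta@abundance) + filterStrength * logw
    lp <- lp - max(lp)
    p <- exp(lp)
    p <- p / sum(p)
    names(p) <- meta@otuIds
    p
}

#' Draw one replicate's read counts at a given dispersion
#'
#' Samples `depth` reads from an expected profile under a tunable
#' replicate-to-replicate dispersion `phi`:
#' * `phi = 1`: a single multinomial draw;
#' * `phi > 1`: Dirichlet-multinomial with concentration
#'   `depth / (phi - 1)`, so the count variance is about `phi` times the
#'   multinomial variance at large depth (drift-like divergence);
#' * `0 <= phi < 1`: largest-remainder rounding of the blend
#'   `(1 - phi) * depth * profile + phi * multinomial draw`, a monotone
#'   variance knob that is exactly deterministic at `phi = 0`.
#'
#' Counts always sum exactly to `depth`.
#'
#' @param profile proportion vector summing to 1.
#' @param depth positive number of reads.
#' @param dispersion `phi >= 0`.
#' @param seed optional integer seed (`NULL` uses the current stream).
#' @return integer count vector summing to `depth`.
#' @export
drawReplicateCounts <- function(profile, depth, dispersion = 1,
                                seed = NULL) {
    if (abs(sum(profile) - 1) > 1e-8)
        stop("profile must sum to 1", call. = FALSE)
    if (any(profile < 0)) stop("profile must be non-negative", call. = FALSE)
    depth <- as.integer(depth)
    if (depth < 1L) stop("depth must be positive", call. = FALSE)
    if (dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
    out <- .withSeed(seed, {
        if (dispersion == 0) {
            .largestRemainder(profile, depth)
        } else if (dispersion < 1) {
            m <- rmultinom(1L, depth, profile)[, 1L]
            .largestRemainder((1 - dispersion) * depth * profile +
                                  dispersion * m, depth)
        } else if (dispersion == 1) {
            rmultinom(1L, depth, profile)[, 1L]
        } else {
            conc <- depth / (dispersion - 1)
            g <- rgamma(length(profile), shape = conc * profile, rate = 1)
            if (sum(g) == 0) g <- profile      # degenerate gamma draw
            rmultinom(1L, depth, g / sum(g))[, 1L]
        }
    })
    out <- as.integer(out)
    names(out) <- names(profile)
    out
}

#' Generate a full synthetic disturbance experiment
#'
#' Builds the metacommunity, derives each treatment's expected profile
#' by niche filtering, and draws every replicate at the treatment's
#' dispersion, at a common read depth. Treatments are labelled
#' `T0 ... T(k-1)` at day 35; optional inoculum ("seed") samples are
#' multinomial draws from the unfiltered pool at day 0. When the
#' function link is enabled, each sample gets
#' `function_value = slope * 2D(generating profile) + N(0, noise)` in
#' its colData. Every random draw comes from a substream hashed from the
#' master seed and the sample's (treatment, replicate) indices, so
#' output is reproducible and order-independent.
#'
#' @param config a [SimulationConfig-class].
#' @return a [CommunityExperiment-class]; the per-treatment expected
#'   profiles are attached as `metadata(x)$profiles` and the pool as
#'   `metadata(x)$metacommunity`.
#' @export
generateExperiment <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    meta <- generateMetacommunity(config@nOtus, config@lognormalSigma,
                                  seed = .substreamSeed(config@seed,
                                                        "metacommunity"))
    k <- config@nTreatments
    profiles <- lapply(seq_len(k), function(t)
        applyTreatmentFilter(meta, config@environmentPositions[t],
                             config@nicheWidth,
                             config@filterStrengths[t]))
    names(profiles) <- paste0("T", seq_len(k) - 1L)

    cols <- list(); mdRows <- list()
    hasFun <- !is.na(config@functionSlope)
    addSample <- function(id, tr, rep, day, profile, phi, sub) {
        counts <- drawReplicateCounts(profile, config@depth, phi,
                                      seed = sub)
        cols[[id]] <<- counts
        f <- if (hasFun)
            config@functionSlope * .hillOne(profile, 2) +
                .withSeed(.substreamSeed(sub, "fun"),
                          rnorm(1L, 0, config@functionNoiseSd))
        else NA_real_
        mdRows[[id]] <<- data.frame(sample_id = id, treatment = tr,
                                    replicate = rep, day = day,
                                    function_value = f)
    }
    for (t in seq_len(k)) for (r in seq_len(config@nReplicates)) {
        tr <- paste0("T", t - 1L)
        addSample(sprintf("%s_R%d", tr, r), tr, paste0("R", r), 35L,
                  profiles[[t]], config@dispersions[t],
                  .substreamSeed(config@seed, t, r))
    }
    if (config@nSeedReplicates > 0L) {
        pool <- meta@abundance
        names(pool) <- meta@otuIds
        for (r in seq_len(config@nSeedReplicates))
            addSample(sprintf("seed_R%d", r), "seed", paste0("R", r), 0L,
                      pool, 1, .substreamSeed(config@seed, 0L, r))
    }
    counts <- do.call(cbind, cols)
    rownames(counts) <- meta@otuIds
    md <- do.call(rbind, mdRows)
    if (!hasFun) md$function_value <- NULL
    x <- communityExperiment(counts, md)
    S4Vectors::metadata(x) <- list(metacommunity = meta,
                                   profiles = profiles,
                                   config = config)
    x
}
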