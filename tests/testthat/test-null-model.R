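# Individual-based fixed-margin null model: sampler, enumeration oracle,
# SES / SI, experiment-level driver.

test_that("every null draw preserves both margins exactly", {
    set.seed(21)
    for (i in 1:40) {
        b <- randomBlock(nOtu = sample(3:15, 1), nRep = sample(2:4, 1))
        m <- blockCounts(b)
        for (j in 1:10) {
            t <- drawNullTable(b)
            expect_identical(rowSums(t), rowSums(m))
            expect_identical(colSums(t), colSums(m))
        }
    }
})

test_that("single-replicate blocks admit only the observed table", {
    single <- treatmentBlock("s", matrix(c(3L, 1L), 2,
                             dimnames = list(c("a", "b"), "R1")))
    expect_warning(t <- drawNullTable(single), "single replicate")
    expect_identical(t, blockCounts(single))
    ex <- enumerateNullExact(single, 0)
    expect_equal(ex$support$beta, 0)
    expect_equal(ex$support$prob, 1)
    expect_equal(ex$sd, 0)
})

test_that("enumeration oracle reproduces the exact 2x2 distribution", {
    ex <- enumerateNullExact(blockShared(), 0)
    expect_equal(ex$n_tables, 3L)
    expect_equal(ex$support$beta, c(0, 0.5))
    expect_equal(ex$support$prob, c(2 / 3, 1 / 3), tolerance = 1e-12)
    expect_equal(sum(ex$support$prob), 1, tolerance = 1e-12)
    expect_equal(ex$mean, 1 / 6, tolerance = 1e-12)
    expect_equal(ex$sd, sqrt(1 / 18), tolerance = 1e-12)
    expect_equal(ex$sd, 0.23570, tolerance = 1e-5)
    # same margins, same distribution, regardless of the observed table
    ex2 <- enumerateNullExact(blockDisjoint(), 0)
    expect_equal(ex2$support, ex$support, tolerance = 1e-12)
    expect_error(
        enumerateNullExact(randomBlock(nOtu = 30, nRep = 4, lambda = 50),
                           0, maxTables = 100),
        "guard")
})

test_that("Monte-Carlo moments converge to the enumerated ones", {
    # margins (2,2)/(2,2), q = 0: mean 1/6, sd sqrt(1/18)
    nd <- nullBetaDistribution(blockShared(), q = 0, nIter = 10000,
                               seed = 101, keepSamples = TRUE)
    se <- sqrt(1 / 18) / sqrt(10000)
    expect_lt(abs(nd$null_mean - 1 / 6), 3 * se)
    expect_lt(abs(nd$null_sd - sqrt(1 / 18)), 3 * se)
    # a richer block, all q, against its own enumeration
    b <- treatmentBlock("t", matrix(c(2L, 1L, 0L, 1L, 2L, 1L), 3,
                        dimnames = list(c("a", "b", "c"), c("R1", "R2"))))
    nd <- nullBetaDistribution(b, q = 0:2, nIter = 10000, seed = 7,
                               keepSamples = TRUE)
    for (k in 1:3) {
        ex <- enumerateNullExact(b, (0:2)[k])
        se <- ex$sd / sqrt(10000)
        expect_lt(abs(nd$null_mean[k] - ex$mean), 3 * se + 1e-12)
        expect_lt(abs(nd$null_sd[k] - ex$sd), 3 * se + 1e-12)
    }
})

test_that("sampler matches Patefield r2dtable cell frequencies", {
    # margins (2,2)/(2,2): P(top-left = 1) = 4/6 exactly
    b <- blockShared()
    mine <- mean(vapply(1:10000, function(i)
        drawNullTable(b)[1, 1] == 1L, logical(1)))
    ref <- mean(vapply(stats::r2dtable(10000, c(2, 2), c(2, 2)),
                       function(t) t[1, 1] == 1L, logical(1)))
    se <- sqrt(2 / 3 * 1 / 3 / 10000)
    expect_lt(abs(mine - 2 / 3), 3 * se)
    expect_lt(abs(mine - ref), 4 * se)
    # larger margins: cell means agree with r*c/N between both samplers
    set.seed(3)
    m <- matrix(rpois(12, 20) + 1L, 4, 3,
                dimnames = list(paste0("g", 1:4), paste0("R", 1:3)))
    bb <- treatmentBlock("t", m)
    mu_mine <- Reduce(`+`, lapply(1:2000, function(i)
        drawNullTable(bb))) / 2000
    mu_ref <- Reduce(`+`, stats::r2dtable(2000, rowSums(m),
                                          colSums(m))) / 2000
    mu_theory <- outer(rowSums(m), colSums(m)) / sum(m)
    expect_lt(max(abs(mu_mine - mu_theory)), 0.5)
    expect_lt(max(abs(mu_mine - mu_ref)), 0.7)
})

test_that("null draws are deterministic given a seed", {
    b <- randomBlock(nOtu = 6, nRep = 3)
    expect_identical(drawNullTable(b, seed = 9), drawNullTable(b, seed = 9))
    expect_identical(nullBetaDistribution(b, nIter = 500, seed = 4),
                     nullBetaDistribution(b, nIter = 500, seed = 4))
})

test_that("SES and SI follow their definitions with undefined markers", {
    expect_equal(computeSES(0.5, 1 / 6, sqrt(1 / 18)), sqrt(2),
                 tolerance = 1e-12)
    expect_equal(computeSES(0, 1 / 6, sqrt(1 / 18)), -sqrt(2) / 2,
                 tolerance = 1e-12)
    expect_equal(computeSES(0.3, 0.3, 0.1), 0)
    expect_true(is.na(computeSES(0.3, 0.2, 0)))
    expect_equal(computeSI(0.5, 1 / 6), 2 / 3, tolerance = 1e-12)
    expect_true(is.na(computeSI(0, 0.2)))
    expect_equal(computeSI(0.4, 0.4), 0)
    # SI increases with SES at fixed beta_obs > 0
    means <- seq(0, 0.4, by = 0.05)
    ses <- computeSES(0.5, means, 0.1)
    si <- computeSI(0.5, means)
    expect_true(all(diff(si[order(ses)]) > 0))
})

test_that("runNullModel covers every (treatment, q) and respects seeds", {
    x <- tinyExperiment(nTreat = 4, nRep = 3, nOtu = 25, depth = 600,
                        nSeed = 2)
    res <- runNullModel(x, q = 0:2, nIter = 300, seed = 5)
    expect_equal(nrow(res), 5 * 3)          # 4 treatments + seed group
    expect_setequal(unique(res$treatment), c(paste0("T", 0:3), "seed"))
    expect_equal(sum(res$treatment == "seed"), 3L)  # n = 2 supported
    expect_true(all(res$null_sd >= 0))
    # identical reruns; and per-treatment results invariant under
    # sample-column reordering (independent substreams per treatment)
    res2 <- runNullModel(x, q = 0:2, nIter = 300, seed = 5)
    expect_identical(as.data.frame(res), as.data.frame(res2))
    xs <- x[, rev(seq_len(ncol(x)))]
    res3 <- runNullModel(xs, q = 0:2, nIter = 300, seed = 5)
    ord <- order(res$treatment, res$q)
    ord3 <- order(res3$treatment, res3$q)
    expect_equal(as.data.frame(res)[ord, ], as.data.frame(res3)[ord3, ],
                 ignore_attr = TRUE)
})

test_that("treatments with one replicate are skipped with a warning", {
    x <- tinyExperiment(nTreat = 2, nRep = 3, nOtu = 10, depth = 300)
    xdrop <- x[, -c(4, 5)]                  # leave T1 with one replicate
    expect_warning(res <- runNullModel(xdrop, q = 0, nIter = 100, seed = 1),
                   "single replicate.*T1")
    expect_setequal(unique(res$treatment), "T0")
})
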