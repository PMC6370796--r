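# OTU-table / metadata IO, rarefaction and basic transforms.

test_that("count table TSV round-trips bit-identically and validates", {
    counts <- matrix(1L, 2, 2,
                     dimnames = list(c("g1", "g2"), c("s1", "s2")))
    path <- withr::local_tempfile(fileext = ".tsv")
    writeCountTable(counts, path)
    back <- readCountTable(path)
    expect_identical(back, counts)
    expect_equal(colSums(back), c(s1 = 2, s2 = 2))
    # header lists sample ids in order; one line per OTU plus header
    lines <- readLines(path)
    expect_identical(lines[1], "otu_id\ts1\ts2")
    expect_length(lines, nrow(counts) + 1L)

    big <- matrix(rpois(50 * 6, 3), 50, 6,
                  dimnames = list(sprintf("g%02d", 1:50),
                                  sprintf("s%d", 1:6)))
    storage.mode(big) <- "integer"
    writeCountTable(big, path)
    expect_length(readLines(path), 51L)
    expect_identical(readCountTable(path), big)

    # 0-OTU degenerate table: header-only file, reads back empty
    empty <- matrix(integer(), 0, 2,
                    dimnames = list(character(), c("s1", "s2")))
    writeCountTable(empty, path)
    expect_length(readLines(path), 1L)
    expect_identical(dim(readCountTable(path)), c(0L, 2L))
})

test_that("malformed count tables are rejected with cell-level messages", {
    path <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("otu\ts1\ts2", "g1\t1\t3.7", "g2\t2\t0"), path)
    expect_error(readCountTable(path, strict = TRUE),
                 "non-integer count '3.7'.*OTU 'g1'.*sample 's2'")
    expect_warning(r <- readCountTable(path, strict = FALSE), "rounded")
    expect_identical(r["g1", "s2"], 4L)

    writeLines(c("otu\ts1", "g1\t-2"), path)
    expect_error(readCountTable(path), "negative")
    writeLines(c("otu\ts1", "g1\tfoo"), path)
    expect_error(readCountTable(path), "not numeric")
    writeLines(c("otu\ts1", "g1\t1", "g1\t2"), path)
    expect_error(readCountTable(path), "duplicated OTU")
    expect_error(readCountTable(file.path(tempdir(), "nope.tsv")),
                 "not found")
})

test_that("sample metadata reader enforces the design contract", {
    path <- withr::local_tempfile(fileext = ".tsv")
    md <- expand.grid(replicate = paste0("R", 1:3),
                      treatment = paste0("L", 0:7),
                      stringsAsFactors = FALSE)
    md$day <- 35L
    md$sample_id <- paste(md$treatment, md$replicate, sep = "_")
    writeSampleMetadata(md, path)
    got <- readSampleMetadata(path)
    expect_equal(nrow(got), 24L)
    expect_equal(unname(table(got$treatment)), rep(3L, 8L),
                 ignore_attr = TRUE)

    seedmd <- data.frame(sample_id = c("seed_R1", "seed_R2"),
                         treatment = "seed", replicate = c("R1", "R2"),
                         day = 0L)
    writeSampleMetadata(seedmd, path)
    got <- readSampleMetadata(path)
    expect_equal(sum(got$treatment == "seed"), 2L)

    writeSampleMetadata(rbind(seedmd, seedmd[1, ]), path)
    expect_error(readSampleMetadata(path), "duplicated sample_id")
    writeSampleMetadata(seedmd[c("sample_id", "treatment", "day")], path)
    expect_error(readSampleMetadata(path), "replicate")
})

test_that("rarefaction is exact, bounded and hypergeometric", {
    m <- matrix(c(5L, 3L, 2L), 3, 1,
                dimnames = list(c("a", "b", "c"), "s"))
    expect_identical(rarefy(m, 10, seed = 1)[, 1], m[, 1])  # depth = total
    m2 <- matrix(c(100L, 0L), 2, 1, dimnames = list(c("a", "b"), "s"))
    expect_identical(unname(rarefy(m2, 10, seed = 1)[, 1]), c(10L, 0L))
    expect_error(rarefy(m2, 200, seed = 1), "below requested depth.*s")

    # property: column sums hit depth exactly, no cell exceeds its input
    for (s in 1:25) {
        mm <- matrix(rpois(40, 8), 10, 4,
                     dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
        storage.mode(mm) <- "integer"
        depth <- min(colSums(mm))
        r <- rarefy(mm, depth, seed = s)
        expect_true(all(colSums(r) == depth))
        expect_true(all(r <= mm))
    }

    # [50, 50] at depth 20: mean of first cell ~ hypergeometric mean 10
    m3 <- matrix(c(50L, 50L), 2, 1, dimnames = list(c("a", "b"), "s"))
    draws <- vapply(1:10000, function(s) rarefy(m3, 20, seed = s)[1, 1],
                    integer(1))
    se <- sqrt(20 * 0.25 * (100 - 20) / (100 - 1) / 10000)
    expect_lt(abs(mean(draws) - 10), 3 * se)
})

test_that("relative abundance and sqrt transform behave", {
    m <- matrix(c(2L, 2L, 4L, 1L), 2, 2,
                dimnames = list(c("a", "b"), c("s1", "s2")))
    p <- relativeAbundance(m)
    expect_equal(unname(p), cbind(c(0.5, 0.5), c(0.8, 0.2)))
    expect_true(all(abs(colSums(p) - 1) < 1e-12))
    z <- matrix(0L, 2, 1, dimnames = list(c("a", "b"), "s"))
    expect_error(relativeAbundance(z), "zero total")
    expect_equal(sqrtTransform(matrix(c(4, 9, 0, 1), 2)),
                 matrix(c(2, 3, 0, 1), 2))
    expect_error(sqrtTransform(matrix(-1, 1)), "negative")
})

test_that("splitByTreatment partitions samples into ordered blocks", {
    x <- tinyExperiment(nTreat = 4, nRep = 3, nSeed = 2)
    blocks <- splitByTreatment(x, day = 35)
    expect_length(blocks, 4L)
    expect_true(all(vapply(blocks, function(b) ncol(blockCounts(b)),
                           integer(1)) == 3L))
    seedBlock <- splitByTreatment(x, day = 0)
    expect_length(seedBlock, 1L)
    expect_equal(ncol(blockCounts(seedBlock$seed)), 2L)
    # the blocks partition the full sample set: nothing lost, nothing twice
    all_ids <- unlist(lapply(splitByTreatment(x), function(b)
        paste(treatmentLabel(b), replicateIds(b))))
    expect_equal(length(all_ids), ncol(x))
    expect_false(anyDuplicated(all_ids) > 0)
    # replicate columns come back ordered by replicate id
    expect_identical(replicateIds(blocks$T0), paste0("T0_R", 1:3))
})

test_that("experiments reject samples missing from metadata", {
    counts <- matrix(1L, 2, 2,
                     dimnames = list(c("g1", "g2"), c("s1", "s2")))
    md <- data.frame(sample_id = "s1", treatment = "L0",
                     replicate = "R1", day = 35L)
    expect_error(communityExperiment(counts, md), "missing from metadata.*s2")
})
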