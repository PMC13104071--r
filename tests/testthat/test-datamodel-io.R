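test_that("TSV round-trip is lossless for counts, ids and lineages", {
  tab <- community_table(matrix(c(5L, 0L, 2L, 1L, 3L, 4L), nrow = 3,
                                dimnames = list(c("x", "y", "z"),
                                                c("a", "b"))),
                         lineages = c("d__B|s__x", "d__B|s__y", "d__B|s__z"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_community_table(tab, path)
  back <- read_community_table(path, drop_zero_taxa = FALSE)
  expect_identical(back$counts, tab$counts)
  expect_identical(unname(back$lineages), unname(tab$lineages))
})

test_that("malformed tables are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon_id\ts1\ts1", "x\t1\t2"), path)
  expect_error(read_community_table(path), "s1")
  expect_error(community_table(matrix(1:4, 2,
                                      dimnames = list(c("a", "a"),
                                                      c("s1", "s2")))),
               "duplicate taxon")
  expect_error(community_table(matrix(c(-1, 2, 3, 4), 2,
                                      dimnames = list(c("a", "b"),
                                                      c("s1", "s2")))),
               "non-negative")
})

test_that("rarefaction conserves totals, is reproducible, errors on deficit", {
  tab <- dm_table(n_taxa = 20, n_samples = 6, reads = 800, seed = 3)
  r1 <- rarefy(tab, 500, seed = 11)
  expect_true(all(colSums(r1$counts) == 500))
  r2 <- rarefy(tab, 500, seed = 11)
  expect_identical(r1$counts, r2$counts)
  expect_error(rarefy(tab, 10^6, seed = 1), "exceeds")
  # depth == column sums leaves the table unchanged (up to zero-drop)
  even <- community_table(matrix(c(3L, 7L, 5L, 5L), 2,
                                 dimnames = list(c("a", "b"),
                                                 c("s1", "s2"))))
  expect_identical(rarefy(even, 10, seed = 1)$counts, even$counts)
})

test_that("rarefaction is unbiased: mean across seeds matches proportions", {
  counts <- matrix(c(60L, 30L, 10L), ncol = 1,
                   dimnames = list(c("a", "b", "c"), "s1"))
  tab <- community_table(counts)
  depth <- 40
  draws <- vapply(seq_len(250), function(s)
    rarefy(tab, depth, seed = s, drop_zero = FALSE)$counts[, 1],
    numeric(3))
  expected <- depth * counts[, 1] / sum(counts)   # hypergeometric mean
  se <- sqrt(depth * (counts[, 1] / 100) * (1 - counts[, 1] / 100) *
               (100 - depth) / 99) / sqrt(250)
  expect_true(all(abs(rowMeans(draws) - expected) < 3 * se + 1e-9))
})

test_that("relative abundance normalises columns and is idempotent", {
  tab <- community_table(matrix(c(2L, 2L, 0L), ncol = 1,
                                dimnames = list(c("a", "b", "c"), "s1")))
  rel <- relative_abundance(tab)
  expect_equal(unname(rel[, 1]), c(0.5, 0.5, 0))
  expect_equal(relative_abundance(rel), rel)
  big <- dm_table(seed = 5)
  expect_equal(unname(colSums(relative_abundance(big))),
               rep(1, n_samples(big)))
  zero <- matrix(c(1L, 0L), 2, dimnames = list(c("a", "b"), "s1"))
  zero <- cbind(zero, s2 = c(0L, 0L))
  expect_error(relative_abundance(community_table(zero)), "all-zero")
})

test_that("mean-abundance filter is inclusive at the threshold", {
  # taxon b sits exactly at mean relative abundance 0.01
  counts <- matrix(c(990L, 10L, 990L, 10L), 2,
                   dimnames = list(c("a", "b"), c("s1", "s2")))
  tab <- community_table(counts)
  kept <- filter_taxa_by_mean_abundance(tab, 0.01)
  expect_true("b" %in% taxon_ids(kept))
  expect_identical(filter_taxa_by_mean_abundance(tab, 0)$counts, tab$counts)
  strict <- filter_taxa_by_mean_abundance(tab, 0.010001)
  expect_false("b" %in% taxon_ids(strict))
})

test_that("sample frame validation enforces layer consistency", {
  frame <- data.frame(sample_id = c("a", "b"), site = 1,
                      depth_m = c(0.5, 1.5),
                      main_layer = c("active", "permafrost"),
                      sub_layer = c("TAL", "TPL"))
  expect_silent(validate_sample_frame(frame))
  bad <- frame
  bad$sub_layer[2] <- "SAL"      # SAL inside permafrost is inconsistent
  expect_error(validate_sample_frame(bad), "mismatch")
  dup <- frame
  dup$sample_id <- c("a", "a")
  expect_error(validate_sample_frame(dup), "duplicate")
})
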