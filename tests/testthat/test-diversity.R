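test_that("richness and Shannon match hand values", {
  tab <- community_table(matrix(c(5L, 0L, 2L, 0L, 0L, 0L, 4L, 4L, 4L, 0L),
                                nrow = 5,
                                dimnames = list(paste0("t", 1:5),
                                                c("s1", "s2"))))
  expect_equal(unname(richness(tab)), c(2, 3))
  one <- community_table(matrix(7L, 1, 1, dimnames = list("t", "s")))
  expect_equal(unname(shannon(one)), 0)
  uni <- community_table(matrix(rep(3L, 4), 4, 1,
                                dimnames = list(paste0("t", 1:4), "s")))
  expect_equal(unname(shannon(uni)), log(4))
  hand <- community_table(matrix(c(2L, 1L, 1L), 3, 1,
                                 dimnames = list(paste0("t", 1:3), "s")))
  # -sum(p log p) for p = (0.5, 0.25, 0.25)
  expect_equal(unname(shannon(hand)),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)))
})

test_that("rarefaction cannot increase richness", {
  for (s in 1:10) {
    tab <- dm_table(n_taxa = 25, n_samples = 5, reads = 600,
                    conc = 20, seed = s)
    r <- rarefy(tab, 300, seed = s, drop_zero = FALSE)
    expect_true(all(richness(r) <= richness(tab)))
  }
})

test_that("Bray-Curtis matches the formula and its limits", {
  m <- matrix(c(1L, 1L, 0L, 0L, 1L, 1L), 3,
              dimnames = list(paste0("t", 1:3), c("x", "y")))
  bc <- bray_curtis_matrix(community_table(m))
  expect_equal(bc["x", "y"], 0.5)       # sum|x-y| / sum(x+y) = 2/4
  same <- community_table(cbind(m, z = m[, "x"]))
  expect_equal(bray_curtis_matrix(same)["x", "z"], 0)
  disj <- community_table(matrix(c(3L, 0L, 0L, 5L), 2,
                                 dimnames = list(c("a", "b"),
                                                 c("s1", "s2"))))
  expect_equal(bray_curtis_matrix(disj)["s1", "s2"], 1)
})

test_that("PCoA reproduces Euclidean-embeddable distances", {
  d <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  d["a", "b"] <- d["b", "a"] <- 3
  d["a", "c"] <- d["c", "a"] <- 4
  d["b", "c"] <- d["c", "b"] <- 5
  res <- pcoa(d)
  rec <- as.matrix(dist(res$coordinates))
  expect_lt(max(abs(rec - d)), 1e-8)
  expect_true(all(diff(res$eigenvalues) <= 1e-10))
  expect_true(all(res$proportion_explained >= 0 &
                    res$proportion_explained <= 1))
  # identical samples land on coincident coordinates
  dd <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  co <- pcoa(dd)$coordinates
  expect_lt(max(abs(co["a", ] - co["b", ])), 1e-10)
})

test_that("PERMANOVA is label-order invariant and saturates on separation", {
  tab <- dm_table(n_taxa = 10, n_samples = 12, seed = 4)
  bc <- bray_curtis_matrix(tab)
  g <- rep(c("A", "B"), each = 6)
  r1 <- permanova(bc, g, n_perm = 99, seed = 7)
  perm <- c(7:12, 1:6)
  r2 <- permanova(bc[perm, perm], g[perm], n_perm = 99, seed = 7)
  expect_equal(r1$pseudo_F, r2$pseudo_F)
  # two far-separated blocks: p hits its resolution floor
  m <- matrix(0L, 4, 12, dimnames = list(paste0("t", 1:4),
                                         paste0("s", 1:12)))
  m[1:2, 1:6] <- 100L
  m[3:4, 7:12] <- 100L
  sep <- permanova(bray_curtis_matrix(community_table(m)), g,
                   n_perm = 199, seed = 1)
  expect_equal(sep$p_value, 1 / 200)
  expect_error(permanova(bc, c("A", rep("B", 11)), seed = 1),
               "at least 2 samples")
})

test_that("group dispersion reflects within-group spread", {
  m <- matrix(0L, 4, 8, dimnames = list(paste0("t", 1:4), paste0("s", 1:8)))
  m[, 1:4] <- c(50L, 50L, 0L, 0L)                 # tight group
  set.seed(1)
  m[, 5:8] <- rmultinom(4, 100, c(.25, .25, .25, .25))  # loose group
  bc <- bray_curtis_matrix(community_table(m))
  g <- rep(c("tight", "loose"), each = 4)
  disp <- suppressWarnings(group_dispersion(bc, g))
  expect_true(all(disp[1:4] < 1e-10))
  expect_gt(mean(disp[5:8]), mean(disp[1:4]))
})

test_that("distance decay recovers an exact linear relationship", {
  env <- 1:10
  e <- as.matrix(dist(env))
  sim <- 1 - 0.05 * e
  res <- distance_decay(sim, e, n_perm = 99, seed = 2)
  expect_equal(res$slope, -0.05, tolerance = 1e-10)
  expect_equal(res$p_value, 1 / 100)
  expect_error(distance_decay(sim, e * 0, seed = 1), "constant")
})
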