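test_that("depth alignment merges the smallest adjacent gap first", {
  tab4 <- dm_table(n_taxa = 6, n_samples = 4, seed = 1)
  tab3 <- dm_table(n_taxa = 6, n_samples = 3, seed = 2)
  al <- align_samples_by_depth(list(a = tab4, b = tab3),
                               list(a = c(1, 2, 10, 11), b = c(1, 5, 9)))
  expect_equal(n_samples(al$tables$a), 3)
  expect_equal(al$depths$a, c(1.5, 10, 11))   # 1 and 2 merged
  expect_identical(al$tables$b$counts, tab3$counts)  # already at target
  expect_false(is.unsorted(al$depths$a))
  tab2 <- dm_table(n_taxa = 6, n_samples = 2, seed = 3)
  expect_error(align_samples_by_depth(list(a = tab2), list(a = c(1, 2))),
               "fewer than 3")
})

test_that("thresholding is strict and empty networks are legal", {
  rho <- diag(3)
  rho[1, 2] <- rho[2, 1] <- 0.35      # exactly at the bound: excluded
  rho[1, 3] <- rho[3, 1] <- 0.5
  dimnames(rho) <- list(letters[1:3], letters[1:3])
  p <- matrix(0.01, 3, 3)
  net <- build_network(rho, p, r_min = 0.35)
  expect_equal(nrow(net$edges), 1)
  expect_setequal(c(net$edges$from, net$edges$to), c("a", "c"))
  none <- build_network(rho, p, r_min = 0.9)
  expect_equal(igraph::ecount(none$graph), 0)
  expect_equal(topology(none)$density, 0)
  full <- build_network(rho + 0.6 - diag(0.6, 3), NULL, r_min = 0.35)
  expect_equal(topology(full)$density, 1)
})

test_that("topology matches hand computations", {
  tri <- matrix(0.9, 3, 3) - diag(0.9, 3) + diag(3)
  dimnames(tri) <- list(letters[1:3], letters[1:3])
  t_tri <- topology(build_network(tri, NULL, r_min = 0.5))
  expect_equal(t_tri$density, 1)
  expect_equal(t_tri$transitivity, 1)
  expect_equal(t_tri$linkage_density, 2)
  star <- diag(4)
  star[1, 2:4] <- star[2:4, 1] <- 0.9
  dimnames(star) <- list(letters[1:4], letters[1:4])
  t_star <- topology(build_network(star, NULL, r_min = 0.5))
  expect_equal(t_star$transitivity, 0)
  expect_equal(t_star$mean_degree, 1.5)
})

test_that("natural connectivity matches closed forms and the trace route", {
  expect_equal(natural_connectivity(matrix(0, 5, 5)), 0)
  k3 <- matrix(1, 3, 3) - diag(3)
  expect_equal(natural_connectivity(k3),
               log((exp(2) + 2 * exp(-1)) / 3))
  k4 <- matrix(1, 4, 4) - diag(4)
  expect_gt(natural_connectivity(k4), natural_connectivity(k3))
  for (s in 1:10) {
    g <- withr::with_seed(s, igraph::sample_gnp(25, 0.15))
    A <- as.matrix(igraph::as_adjacency_matrix(g))
    via_trace <- log(mean(diag(as.matrix(Matrix::expm(A)))))
    expect_equal(natural_connectivity(A), via_trace, tolerance = 1e-8)
  }
})

test_that("robustness curve starts intact, ends at zero, declines", {
  g <- withr::with_seed(3, igraph::sample_gnp(30, 0.2))
  rc <- robustness_curve(g, fractions = c(0, 0.25, 0.5, 0.75, 1),
                         n_rep = 30, seed = 4)
  expect_equal(rc$nc[1], natural_connectivity(g))
  expect_equal(rc$nc[5], 0)
  expect_true(all(diff(rc$nc) <= 1e-9))
  expect_equal(rc$nc_normalized[1], 1)
})

test_that("leave-one-out scores are symmetric for duplicated samples", {
  tab <- dm_table(n_taxa = 12, n_samples = 24, seed = 5)
  dup <- community_table(cbind(tab$counts,
                               s_dup = tab$counts[, 24]),
                         tab$lineages)
  ssn <- single_sample_networks(dup, taxon_ids(tab)[1:8], seed = 6)
  expect_equal(ssn$scores[, 24], ssn$scores[, 25],
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("a planted sample-specific dependence is detected", {
  tab <- dm_table(n_taxa = 15, n_samples = 60, seed = 9)
  m <- tab$counts
  m[1, 7] <- m[2, 7] <- as.integer(m[1, 7] * 8 + 2000)
  planted <- community_table(m)
  ssn <- single_sample_networks(planted, rownames(m), seed = 10)
  pair <- ssn$scores["t01|t02", ]
  expect_true(all(abs(pair[7]) > abs(pair[-7])))
})

test_that("homogeneous samples give homogeneous interaction counts", {
  tab <- dm_table(n_taxa = 15, n_samples = 60, seed = 9)
  ssn <- single_sample_networks(tab, taxon_ids(tab), r_min = 0.35,
                                seed = 11)
  ec <- ssn$edge_counts
  expect_true(all(abs(ec - median(ec)) <=
                    3 * max(mad(ec, constant = 1), 1)))
})

test_that("core edge analytics count blocks and paths correctly", {
  rho <- diag(4)
  rho[1, 2] <- rho[2, 1] <- 0.9    # core-core within P1
  rho[2, 3] <- rho[3, 2] <- 0.8    # core(P1)-core(P2)
  rho[3, 4] <- rho[4, 3] <- 0.9    # core-other
  dimnames(rho) <- list(letters[1:4], letters[1:4])
  ann <- data.frame(taxon = letters[1:4],
                    phylum = c("P1", "P1", "P2", "P2"),
                    core = c(TRUE, TRUE, TRUE, FALSE))
  net <- build_network(rho, NULL, r_min = 0.35, annotations = ann)
  res <- core_edge_analytics(net)
  bc <- setNames(res$block_counts$edges, res$block_counts$block)
  expect_equal(unname(bc["core:P1-P1"]), 1)
  expect_equal(unname(bc["core:P1-P2"]), 1)
  expect_equal(unname(bc["core-other"]), 1)
  # core subgraph is the path a-b-c: mean shortest path (1+1+2)/3
  expect_equal(res$core_path_length, 4 / 3)
  # no annotations at all -> flagged empty result
  bare <- build_network(rho, NULL, r_min = 0.35)
  expect_match(core_edge_analytics(bare)$flag, "no core")
})
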