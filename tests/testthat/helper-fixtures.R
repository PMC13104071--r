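# Shared fixtures: everything is generated in code at test time.

# tiny deterministic table
toy_table <- function() {
  community_table(matrix(c(2L, 8L, 4L, 6L, 6L, 4L),
                         nrow = 2,
                         dimnames = list(c("tA", "tB"),
                                         c("s1", "s2", "s3"))))
}

# Dirichlet-multinomial table around a fixed composition: compositional,
# overdispersed, i.i.d. samples — the "one regime" null fixture.
dm_table <- function(n_taxa = 15, n_samples = 40, reads = 5000,
                     conc = 300, seed = 1) {
  withr::with_seed(seed, {
    base <- rgamma(n_taxa, 2)
    base <- base / sum(base)
    m <- vapply(seq_len(n_samples), function(j) {
      g <- rgamma(n_taxa, base * conc)
      as.integer(rmultinom(1, reads, g / sum(g)))
    }, integer(n_taxa))
    dimnames(m) <- list(sprintf("t%02d", seq_len(n_taxa)),
                        sprintf("s%02d", seq_len(n_samples)))
    community_table(m)
  })
}

# log-normal basis counts with one planted log-scale correlation
planted_table <- function(n_samples = 200, n_taxa = 50, rho = 0.8,
                          reads = 20000, seed = 1) {
  withr::with_seed(seed, {
    z <- rnorm(n_samples)
    L <- matrix(rnorm(n_samples * n_taxa), n_samples, n_taxa)
    if (!is.null(rho)) {
      L[, 1] <- sqrt(rho) * z + sqrt(1 - rho) * rnorm(n_samples)
      L[, 2] <- sqrt(rho) * z + sqrt(1 - rho) * rnorm(n_samples)
    }
    B <- exp(L + 4)
    fr <- B / rowSums(B)
    m <- t(vapply(seq_len(n_samples), function(i)
      as.integer(rmultinom(1, reads, fr[i, ])), integer(n_taxa)))
    m <- t(m)
    dimnames(m) <- list(sprintf("t%02d", seq_len(n_taxa)),
                        sprintf("s%03d", seq_len(n_samples)))
    community_table(m)
  })
}

# small simulated permafrost dataset for pipeline-level tests
small_sim_config <- function(seed = 1, ...) {
  simulation_config(n_sites = 3, depths_per_site = 10,
                    species_pool_size = 60, reads_per_sample = 1500,
                    seed = seed, ...)
}
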