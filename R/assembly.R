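#' Null communities preserving richness and totals
#'
#' Draws randomized communities for a group of samples: each null sample
#' keeps the observed sample's richness, taxa are drawn (without
#' replacement) with probability proportional to their occurrence frequency
#' in the group pool, and the sample's total count is re-allocated among
#' the drawn taxa in proportion to their pooled abundance. The default
#' allocation draws the total as individuals (multinomial over the pooled
#' proportions), so null replicates carry the sampling variance a random
#' assembly would; \code{allocation = "proportional"} instead assigns
#' expected counts deterministically (largest-remainder rounding). Totals
#' are exact either way.
#'
#' @param table community_table restricted to the group's samples
#' @param n_null number of randomizations (>= 2)
#' @param seed integer seed
#' @param allocation "multinomial" (default) or "proportional"
#' @return list of count matrices, one per randomization
#' @export
null_communities <- function(table, n_null = 200, seed = 1L,
                             allocation = c("multinomial", "proportional")) {
  allocation <- match.arg(allocation)
  stopifnot(inherits(table, "community_table"))
  if (n_null < 2) stop("n_null must be >= 2")
  m <- table$counts
  if (ncol(m) < 2) stop("need at least 2 samples in the group")
  freq <- rowMeans(m > 0)               # pool occurrence frequency
  pool_ab <- rowSums(m)                 # pool abundance for allocation
  present <- freq > 0
  rich <- colSums(m > 0)
  totals <- colSums(m)
  idx_present <- which(present)
  with_seed(seed, {
    lapply(seq_len(n_null), function(k) {
      out <- matrix(0L, nrow(m), ncol(m), dimnames = dimnames(m))
      for (j in seq_len(ncol(m))) {
        r <- min(rich[j], length(idx_present))
        if (r == 0) next
        drawn <- sample(idx_present, r, prob = freq[idx_present])
        out[drawn, j] <- if (allocation == "multinomial")
          as.integer(rmultinom(1, totals[j], pool_ab[drawn]))
        else allocate_integer(pool_ab[drawn], totals[j])
      }
      out
    })
  })
}

#' Null-model stochasticity ratio
#'
#' For every within-group sample pair, the observed Bray-Curtis similarity
#' (1 - BC) is compared with its expectation over null communities. When
#' observed similarity >= null expectation (a selection-like regime) the
#' pair's ratio is E[similarity] / observed similarity; otherwise it is
#' E[dissimilarity] / observed dissimilarity. Both forms lie in [0, 1]
#' (clamped); the group value is their mean. Values above 0.5 indicate
#' assembly dominated by stochastic processes, below 0.5 by deterministic
#' processes.
#'
#' @param table community_table (one group of samples)
#' @param n_null number of null communities (default 200)
#' @param seed integer seed
#' @param allocation passed to \code{\link{null_communities}}
#' @return list of class \code{stochasticity_result}: \code{ratio} (group
#'   mean), \code{pair_ratios}, \code{raw_ratios} (unclamped audit copy),
#'   \code{n_null}, \code{seed}
#' @export
stochasticity_ratio <- function(table, n_null = 200, seed = 1L,
                                allocation = "multinomial") {
  stopifnot(inherits(table, "community_table"))
  obs_sim <- 1 - bray_curtis_matrix(table)
  nulls <- null_communities(table, n_null = n_null, seed = seed,
                            allocation = allocation)
  null_sims <- vapply(nulls, function(nm) 1 - bray_curtis_matrix(nm),
                      matrix(0, ncol(table$counts), ncol(table$counts)))
  exp_sim <- apply(null_sims, c(1, 2), mean)
  o <- vec_pairs(obs_sim); e <- vec_pairs(exp_sim)
  raw <- ifelse(o >= e,
                ifelse(o > 0, e / o, 1),
                (1 - e) / (1 - o))
  # observed similarity 0 with nonzero null expectation: maximal stochasticity
  if (any(o == 0 & e > 0))
    warning("pair(s) with zero observed similarity: ratio set to 1")
  ratio <- pmin(pmax(raw, 0), 1)
  structure(list(ratio = mean(ratio), pair_ratios = ratio, raw_ratios = raw,
                 n_null = n_null, seed = seed),
            class = "stochasticity_result")
}

#' @export
print.stochasticity_result <- function(x, ...) {
  cat("stochasticity ratio:", round(x$ratio, 4),
      "(", length(x$pair_ratios), "pairs,", x$n_null, "nulls )\n")
  cat("  regime:", if (x$ratio > 0.5) "more stochastic (> 0.5)"
      else "more deterministic (< 0.5)", "\n")
  invisible(x)
}

#' Levins niche overlap, community mean
#'
#' Resource states are the samples; each taxon's utilisation distribution is
#' its proportional abundance across samples. The directed overlap
#' O_jk = sum_i p_ij p_ik / sum_i p_ij^2 is symmetrised as
#' (O_jk + O_kj)/2 and averaged over all taxon pairs.
#'
#' @param table community_table
#' @return list: \code{mean_overlap}, \code{pairwise} (symmetric matrix)
#' @export
niche_overlap <- function(table) {
  m <- table$counts
  keep <- rowSums(m) > 0
  if (!all(keep)) {
    warning("excluding ", sum(!keep), " all-zero taxa")
    m <- m[keep, , drop = FALSE]
  }
  p <- m / rowSums(m)                    # per-taxon utilisation profile
  cross <- p %*% t(p)                    # sum_i p_ij p_ik
  selfsq <- diag(cross)                  # sum_i p_ij^2
  directed <- cross / selfsq             # O[j, k] = cross / selfsq_j
  sym <- (directed + t(directed)) / 2
  diag(sym) <- NA
  list(mean_overlap = mean(sym, na.rm = TRUE), pairwise = sym)
}

#' Modified Mantel test with four-candidate model selection
#'
#' Fits the four models Y~X, Y~ln(X), ln(Y)~X, ln(Y)~ln(X) to vectorized
#' pairwise distances of community composition (Y) against pairwise
#' Euclidean distances of one environmental variable (X), picks the model
#' with maximal |r|, and assesses significance by sample-label permutation
#' of the environmental variable. Before any log, a variable with zero or
#' negative values is shifted by its minimum and surviving zeros replaced by
#' 0.05 x the minimum positive value (ln(0.05) = -3.00 on the natural-log
#' scale).
#'
#' @param comm_dist community distance matrix
#' @param env per-sample numeric variable, aligned with comm_dist
#' @param n_perm permutations (default 999)
#' @param seed integer seed
#' @param perm_refit re-run the four-model selection inside each permutation
#'   (default TRUE; keeps the null p-value uniform). FALSE keeps the chosen
#'   transformation fixed across permutations.
#' @return list of class \code{mantel_model_fit}: \code{model}, \code{r},
#'   \code{p_value}, \code{candidates} (r per model), \code{audit}
#'   (shift/zero-replacement record)
#' @export
modified_mantel <- function(comm_dist, env, n_perm = 999, seed = 1L,
                            perm_refit = TRUE) {
  d <- as.matrix(comm_dist)
  stopifnot(length(env) == nrow(d))
  if (sd(env) == 0) stop("environmental variable is constant")
  y <- vec_pairs(d)
  xmat <- as.matrix(dist(env))

  best_of_four <- function(yv, xv) {
    ty <- safe_log_transform(yv); tx <- safe_log_transform(xv)
    cand <- c("Y~X" = cor(xv, yv),
              "Y~ln(X)" = cor(tx$values, yv),
              "ln(Y)~X" = cor(xv, ty$values),
              "ln(Y)~ln(X)" = cor(tx$values, ty$values))
    # ties (within numerical noise) go to the earlier = simpler model
    best_i <- which(abs(cand) >= max(abs(cand)) - 1e-10)[1]
    list(cand = cand, best = names(cand)[best_i],
         r = cand[best_i], ty = ty, tx = tx)
  }
  obs <- best_of_four(y, vec_pairs(xmat))
  n <- nrow(d)
  score_perm <- function(p) {
    xv <- vec_pairs(xmat[p, p])
    if (perm_refit) {
      max(abs(best_of_four(y, xv)$cand))
    } else {
      yv <- if (startsWith(obs$best, "ln(Y)")) obs$ty$values else y
      xv2 <- if (endsWith(obs$best, "ln(X)")) safe_log_transform(xv)$values else xv
      abs(cor(xv2, yv))
    }
  }
  hits <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      score_perm(sample.int(n)) >= abs(obs$r) - 1e-12
    }, logical(1)))
  })
  structure(list(model = obs$best, r = unname(obs$r),
                 p_value = (1 + hits) / (1 + n_perm),
                 candidates = obs$cand,
                 audit = list(x = obs$tx[c("shifted", "zero_replacement")],
                              y = obs$ty[c("shifted", "zero_replacement")])),
            class = "mantel_model_fit")
}

# Shift-then-replace log transform: subtract the minimum when zeros or
# negatives are present, then replace residual zeros with 0.05 x the
# minimum positive value before taking the natural log.
safe_log_transform <- function(v) {
  shifted <- FALSE
  if (any(v <= 0)) {
    v <- v - min(v)
    shifted <- TRUE
  }
  zr <- NA_real_
  if (any(v == 0)) {
    minpos <- min(v[v > 0])
    zr <- 0.05 * minpos
    v[v == 0] <- zr
  }
  list(values = log(v), shifted = shifted, zero_replacement = zr)
}
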