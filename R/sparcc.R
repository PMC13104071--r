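#' SparCC compositional correlations
#'
#' Estimates basis (log-scale) correlations between taxa from compositional
#' count data by the log-ratio variance procedure: with fractions f,
#' T_ij = var(ln(f_i / f_j)) across samples is averaged over \code{n_inner}
#' Dirichlet resamples of each sample's composition (posterior under
#' counts + pseudocount); basis log-variances omega_i^2 are solved from the
#' linear system obtained by summing T over included partners; then
#' rho_ij = (omega_i^2 + omega_j^2 - T_ij) / (2 omega_i omega_j), clipped
#' to [-1, 1]. The most correlated pair above \code{exclusion_threshold} is
#' iteratively excluded from the sums and the system re-solved, up to
#' \code{n_iterations} rounds, to reduce the bias strong pairs induce.
#'
#' @param table community_table or counts matrix (taxa x samples)
#' @param n_iterations exclusion rounds (default 10)
#' @param exclusion_threshold |rho| above which the strongest pair is
#'   excluded (default 0.1)
#' @param n_inner Dirichlet resamples per sample (default 20); 0 uses the
#'   posterior-mean fractions (counts + pseudocount, column-normalised)
#'   once, making the estimate deterministic — used by the leave-one-out
#'   single-sample machinery where resampling noise would be amplified
#' @param pseudocount added to counts before resampling (default 1)
#' @param seed integer seed
#' @return symmetric correlation matrix with unit diagonal
#' @export
sparcc_correlations <- function(table, n_iterations = 10,
                                exclusion_threshold = 0.1,
                                n_inner = 20, pseudocount = 1, seed = 1L) {
  m <- if (inherits(table, "community_table")) table$counts else as.matrix(table)
  D <- nrow(m); n <- ncol(m)
  if (D < 4) stop("SparCC needs at least 4 taxa (system underdetermined)")
  if (n < 10) stop("SparCC needs at least 10 samples")

  # Averaged log-ratio variance matrix over Dirichlet resamples:
  # T_ij = var(L_i) + var(L_j) - 2 cov(L_i, L_j) with L = log fractions.
  lrv <- function(fr) {
    L <- log(fr)
    C <- stats::cov(t(L))
    v <- diag(C)
    outer(v, rep(1, D)) + outer(rep(1, D), v) - 2 * C
  }
  Tm <- if (n_inner == 0) {
    f <- m + pseudocount
    lrv(sweep(f, 2, colSums(f), "/"))
  } else {
    with_seed(seed, {
      acc <- matrix(0, D, D)
      for (r in seq_len(n_inner)) {
        g <- matrix(rgamma(D * n, shape = as.numeric(m) + pseudocount,
                           rate = 1), D, n)
        acc <- acc + lrv(sweep(g, 2, colSums(g), "/"))
      }
      acc / n_inner
    })
  }

  include <- matrix(TRUE, D, D); diag(include) <- FALSE
  solve_basis <- function() {
    A <- include * 1
    M <- A + diag(rowSums(A))
    t_i <- rowSums(Tm * A)
    w <- tryCatch(solve(M, t_i), error = function(e) rep(mean(Tm) / 2, D))
    w[w <= 0] <- min(w[w > 0], na.rm = TRUE)
    w
  }
  rho_from <- function(w) {
    denom <- 2 * sqrt(outer(w, w))
    r <- (outer(w, rep(1, D)) + outer(rep(1, D), w) - Tm) / denom
    r <- pmin(pmax(r, -1), 1)
    diag(r) <- 1
    r
  }
  w <- solve_basis()
  rho <- rho_from(w)
  excl_count <- integer(D)
  for (it in seq_len(n_iterations)) {
    cand <- abs(rho) * include
    # never strip a taxon below 3 remaining partners
    cand[excl_count >= D - 3, ] <- 0
    cand[, excl_count >= D - 3] <- 0
    top <- which(cand == max(cand), arr.ind = TRUE)[1, ]
    if (max(cand) <= exclusion_threshold) break
    include[top[1], top[2]] <- include[top[2], top[1]] <- FALSE
    excl_count[top] <- excl_count[top] + 1L
    w <- solve_basis()
    rho <- rho_from(w)
  }
  dimnames(rho) <- list(rownames(m), rownames(m))
  rho
}

#' Permutation p-values for SparCC correlations
#'
#' Two-sided pseudo p per pair: each taxon's counts are shuffled across
#' samples independently (breaking all associations while keeping marginal
#' distributions), SparCC is recomputed, and
#' p_ij = (1 + #\{|rho_perm| >= |rho_obs|\}) / (1 + n_boot).
#'
#' @param table community_table or counts matrix
#' @param rho_obs observed correlation matrix from
#'   \code{\link{sparcc_correlations}}
#' @param n_boot permutations (>= 19 to resolve p = 0.05)
#' @param seed integer seed
#' @param ... passed on to \code{sparcc_correlations}
#' @return symmetric p-value matrix (diagonal NA)
#' @export
sparcc_pvalues <- function(table, rho_obs, n_boot = 99, seed = 1L, ...) {
  m <- if (inherits(table, "community_table")) table$counts else as.matrix(table)
  if (n_boot < 19) stop("n_boot must be >= 19 to resolve p < 0.05")
  D <- nrow(m); n <- ncol(m)
  hits <- matrix(0, D, D)
  perm_seeds <- with_seed(seed, sample.int(2^31 - 2, n_boot))
  for (b in seq_len(n_boot)) {
    mp <- with_seed(perm_seeds[b], {
      t(apply(m, 1, sample))
    })
    rownames(mp) <- rownames(m)
    rp <- sparcc_correlations(mp, seed = perm_seeds[b], ...)
    hits <- hits + (abs(rp) >= abs(rho_obs) - 1e-12)
  }
  p <- (1 + hits) / (1 + n_boot)
  diag(p) <- NA
  dimnames(p) <- dimnames(rho_obs)
  p
}
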