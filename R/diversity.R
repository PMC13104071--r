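#' Per-sample richness
#'
#' Number of taxa with a positive count in each sample.
#'
#' @param table community_table
#' @return named integer vector
#' @export
richness <- function(table) {
  stopifnot(inherits(table, "community_table"))
  colSums(table$counts > 0)
}

#' Per-sample Shannon index (natural log)
#'
#' H = -sum p ln p over taxa with positive proportion p.
#'
#' @param table community_table
#' @return named numeric vector, H >= 0
#' @export
shannon <- function(table) {
  rel <- relative_abundance(table)
  apply(rel, 2, function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  })
}

#' Bray-Curtis dissimilarity matrix
#'
#' BC(x, y) = sum|x - y| / sum(x + y) over taxa; symmetric, zero diagonal,
#' entries in [0, 1]. Computed on the table as given (the pipeline passes
#' rarefied counts).
#'
#' @param table community_table or taxa x sample matrix
#' @return symmetric matrix with sample ids as dimnames
#' @export
bray_curtis_matrix <- function(table) {
  m <- if (inherits(table, "community_table")) table$counts else as.matrix(table)
  if (ncol(m) < 2) stop("need at least 2 samples")
  if (any(colSums(m) == 0))
    stop("all-zero sample(s) make Bray-Curtis undefined: ",
         paste(colnames(m)[colSums(m) == 0], collapse = ", "))
  d <- as.matrix(vegan::vegdist(t(m), method = "bray"))
  dimnames(d) <- list(colnames(m), colnames(m))
  d
}

#' Principal coordinates analysis
#'
#' Classical scaling of the double-centred -D^2/2 matrix. Negative
#' eigenvalues are retained in \code{eigenvalues} but excluded from the
#' \code{proportion_explained} denominator (sum of positive eigenvalues).
#'
#' @param dist symmetric distance matrix
#' @param k number of axes to keep (default: all positive-eigenvalue axes)
#' @return list of class \code{pcoa_result}: \code{coordinates}
#'   (samples x axes), \code{eigenvalues} (descending),
#'   \code{proportion_explained}
#' @export
pcoa <- function(dist, k = NULL) {
  d <- as.matrix(dist)
  n <- nrow(d)
  cs <- suppressWarnings(cmdscale(d, k = n - 1, eig = TRUE, add = FALSE))
  eig <- cs$eig
  pos <- sum(eig > 1e-10)
  if (is.null(k)) k <- max(pos, 1L)
  k <- min(k, max(pos, 1L))
  coords <- cs$points[, seq_len(k), drop = FALSE]
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCo", seq_len(k))
  prop <- if (pos > 0) pmax(eig, 0) / sum(eig[eig > 0]) else rep(0, length(eig))
  structure(list(coordinates = coords,
                 eigenvalues = eig,
                 proportion_explained = prop[seq_len(k)]),
            class = "pcoa_result")
}

#' PERMANOVA on a distance matrix
#'
#' Partitions the among/within sum of squares of a distance matrix by a
#' grouping factor; the p-value is (1 + #{F_perm >= F_obs}) / (1 + n_perm)
#' from free label permutation. Wraps \code{vegan::adonis2}.
#'
#' @param dist symmetric distance matrix
#' @param groups factor-like vector, one label per sample
#' @param n_perm number of permutations (default 999)
#' @param seed integer seed
#' @return list of class \code{permanova_result}: \code{pseudo_F},
#'   \code{R2}, \code{p_value}, \code{n_permutations}
#' @export
permanova <- function(dist, groups, n_perm = 999, seed = 1L) {
  d <- as.matrix(dist)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 samples")
  fit <- with_seed(seed, {
    vegan::adonis2(stats::as.dist(d) ~ g,
                   data = data.frame(g = groups),
                   permutations = n_perm)
  })
  structure(list(pseudo_F = fit$F[1], R2 = fit$R2[1],
                 p_value = fit$`Pr(>F)`[1], n_permutations = n_perm),
            class = "permanova_result")
}

#' Distance of each sample to its group centroid
#'
#' Beta-dispersion: centroids are computed in principal-coordinate space
#' with the standard real/imaginary-axis handling. Wraps
#' \code{vegan::betadisper}.
#'
#' @param dist symmetric distance matrix
#' @param groups labels
#' @return named numeric vector of distances (>= 0); singleton groups get
#'   distance 0 with a warning
#' @export
group_dispersion <- function(dist, groups) {
  groups <- as.factor(groups)
  if (any(table(groups) < 2))
    warning("singleton group(s): their centroid distance is 0")
  bd <- vegan::betadisper(stats::as.dist(as.matrix(dist)), groups)
  setNames(as.numeric(bd$distances), rownames(as.matrix(dist)))
}

#' Distance-decay of community similarity
#'
#' Least-squares slope of pairwise community similarity (1 - Bray-Curtis)
#' against pairwise environmental (or spatial) distance, with Mantel-style
#' significance: sample labels of the predictor matrix are permuted and the
#' regression recomputed.
#'
#' @param similarity similarity matrix (e.g. 1 - Bray-Curtis)
#' @param env_dist predictor distance matrix (z-standardise environmental
#'   variables before taking Euclidean distances)
#' @param n_perm permutations (default 999)
#' @param seed integer seed
#' @return list: \code{slope}, \code{intercept}, \code{r} (Pearson over
#'   pairs), \code{p_value}, \code{n_pairs}
#' @export
distance_decay <- function(similarity, env_dist, n_perm = 999, seed = 1L) {
  s <- as.matrix(similarity); e <- as.matrix(env_dist)
  stopifnot(identical(dim(s), dim(e)))
  y <- vec_pairs(s); x <- vec_pairs(e)
  if (sd(x) == 0) stop("environmental distances are constant")
  fit <- lm(y ~ x)
  r_obs <- cor(x, y)
  n <- nrow(e)
  hits <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      abs(cor(vec_pairs(e[p, p]), y)) >= abs(r_obs) - 1e-12
    }, logical(1)))
  })
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r = r_obs, p_value = (1 + hits) / (1 + n_perm), n_pairs = length(y))
}
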