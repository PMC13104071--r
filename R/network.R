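#' Equalise group sample counts by averaging adjacent depths
#'
#' Network comparisons across layers or sites require equal sample counts.
#' Within each larger group the two adjacent-depth samples with the
#' smallest depth gap are repeatedly averaged (counts = rounded mean,
#' depth = mean depth) until every group matches the smallest group's size.
#'
#' @param tables named list of community_table, one per group
#' @param depths named list of numeric depth vectors aligned with each
#'   table's samples
#' @return list with \code{tables} (aligned), \code{depths}
#' @export
align_samples_by_depth <- function(tables, depths) {
  stopifnot(length(tables) == length(depths))
  target <- min(vapply(tables, n_samples, integer(1)))
  if (target < 3) stop("smallest group has fewer than 3 samples")
  out_t <- tables; out_d <- depths
  for (g in seq_along(tables)) {
    m <- tables[[g]]$counts
    d <- depths[[g]]
    ord <- order(d)
    m <- m[, ord, drop = FALSE]; d <- d[ord]
    while (ncol(m) > target) {
      gaps <- diff(d)
      i <- which.min(gaps)
      merged <- as.integer(round((m[, i] + m[, i + 1]) / 2))
      id <- paste0(colnames(m)[i], "+", colnames(m)[i + 1])
      m <- cbind(m[, seq_len(i) - 1, drop = FALSE],
                 matrix(merged, ncol = 1, dimnames = list(rownames(m), id)),
                 m[, -seq_len(i + 1), drop = FALSE])
      d <- c(d[seq_len(i) - 1], mean(d[i:(i + 1)]), d[-seq_len(i + 1)])
    }
    out_t[[g]] <- community_table(m, tables[[g]]$lineages)
    out_d[[g]] <- d
  }
  list(tables = out_t, depths = out_d)
}

#' Build a thresholded correlation network
#'
#' Keeps taxon pairs with |rho| > r_min and p < p_max. Isolated nodes are
#' dropped; the pre/post node counts are recorded. Conventional presets:
#' r_min = 0.35 for layer-level networks, 0.65 for site-level networks,
#' both with p_max = 0.05.
#'
#' @param rho correlation matrix
#' @param p p-value matrix (optional; NULL keeps every |rho| > r_min edge)
#' @param r_min correlation threshold (strict >)
#' @param p_max significance threshold (strict <)
#' @param annotations optional data.frame with columns \code{taxon},
#'   \code{phylum}, \code{core} (logical)
#' @return object of class \code{correlation_network}: \code{graph}
#'   (igraph, edge attributes rho/p/sign), \code{edges} (data.frame),
#'   \code{thresholds}, \code{n_nodes_before}
#' @export
build_network <- function(rho, p = NULL, r_min = 0.35, p_max = 0.05,
                          annotations = NULL) {
  D <- nrow(rho)
  ids <- rownames(rho)
  if (is.null(ids)) ids <- paste0("t", seq_len(D))
  keep <- abs(rho) > r_min
  if (!is.null(p)) keep <- keep & (p < p_max)
  keep[upper.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]],
                      rho = rho[idx],
                      p = if (is.null(p)) NA_real_ else p[idx],
                      sign = ifelse(rho[idx] > 0, 1L, -1L),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
  if (!is.null(annotations)) {
    i <- match(igraph::V(g)$name, annotations$taxon)
    igraph::V(g)$phylum <- annotations$phylum[i]
    igraph::V(g)$core <- annotations$core[i]
  }
  structure(list(graph = g, edges = edges,
                 thresholds = c(r_min = r_min, p_max = p_max),
                 n_nodes_before = D),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  cat("correlation_network:", igraph::vcount(x$graph), "nodes,",
      igraph::ecount(x$graph), "edges (|rho| >", x$thresholds["r_min"],
      ", p <", x$thresholds["p_max"], ")\n")
  invisible(x)
}

#' Network topology summary
#'
#' Density 2E/(N(N-1)), transitivity (global clustering), modularity from
#' deterministic greedy modularity maximisation on the unweighted graph,
#' mean degree, mean eigenvector centrality on the largest component,
#' linkage density (2E/N, i.e. degree per node) and the proportion of
#' positive edges. An edgeless network reports zeros with
#' \code{degenerate = TRUE}.
#'
#' @param network correlation_network (or bare igraph)
#' @return list of class \code{topology_summary}
#' @export
topology <- function(network) {
  g <- if (inherits(network, "correlation_network")) network$graph else network
  N <- igraph::vcount(g); E <- igraph::ecount(g)
  if (E == 0) {
    return(structure(list(n_nodes = N, n_edges = 0, density = 0,
                          transitivity = 0, modularity = 0, mean_degree = 0,
                          mean_eigen_centrality = 0, linkage_density = 0,
                          proportion_positive = NA_real_, degenerate = TRUE),
                     class = "topology_summary"))
  }
  trans <- igraph::transitivity(g, type = "global")
  if (is.nan(trans)) trans <- 0
  comm <- igraph::cluster_fast_greedy(igraph::simplify(g))
  comp <- igraph::components(g)
  big <- igraph::induced_subgraph(g, which(comp$membership ==
                                             which.max(comp$csize)))
  eig <- igraph::eigen_centrality(big)$vector
  prop_pos <- if (!is.null(igraph::E(g)$sign))
    mean(igraph::E(g)$sign > 0) else NA_real_
  structure(list(n_nodes = N, n_edges = E,
                 density = 2 * E / (N * (N - 1)),
                 transitivity = trans,
                 modularity = igraph::modularity(comm),
                 mean_degree = mean(igraph::degree(g)),
                 mean_eigen_centrality = mean(eig),
                 linkage_density = 2 * E / N,
                 proportion_positive = prop_pos,
                 degenerate = FALSE),
            class = "topology_summary")
}

#' Natural connectivity
#'
#' NC = ln((1/N) sum_i exp(lambda_i)) over the eigenvalues lambda of the
#' unweighted adjacency matrix: the log of the average closed-walk
#' generating function, a spectral measure of route redundancy. Edgeless
#' graphs give exactly 0.
#'
#' @param network correlation_network, igraph, or 0/1 adjacency matrix
#' @return numeric NC
#' @export
natural_connectivity <- function(network) {
  A <- if (inherits(network, "correlation_network")) {
    as.matrix(igraph::as_adjacency_matrix(network$graph))
  } else if (inherits(network, "igraph")) {
    as.matrix(igraph::as_adjacency_matrix(network))
  } else as.matrix(network)
  if (nrow(A) == 0) stop("empty graph: natural connectivity undefined")
  A <- (A != 0) * 1
  lambda <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  # log-sum-exp for numerical stability on large spectra
  mx <- max(lambda)
  mx + log(mean(exp(lambda - mx)))
}

#' Edge-removal robustness curve
#'
#' For each removal fraction f, round(f * E) edges are deleted uniformly at
#' random and natural connectivity recomputed; the mean over \code{n_rep}
#' replicates is reported, together with the curve normalised by NC(0).
#' Slower decline of NC under the same removal fraction indicates a more
#' robust (stabler) network.
#'
#' @param network correlation_network or igraph
#' @param fractions removal fractions in [0, 1]
#' @param n_rep replicates per fraction (default 50)
#' @param seed integer seed
#' @return data.frame of class \code{robustness_curve}: fraction,
#'   mean natural connectivity \code{nc}, \code{nc_normalized}
#' @export
robustness_curve <- function(network, fractions = seq(0, 0.8, by = 0.1),
                             n_rep = 50, seed = 1L) {
  g <- if (inherits(network, "correlation_network")) network$graph else network
  E <- igraph::ecount(g)
  if (E == 0) stop("edgeless network: nothing to attack")
  stopifnot(all(fractions >= 0), all(fractions <= 1))
  nc0 <- natural_connectivity(g)
  mean_nc <- with_seed(seed, {
    vapply(fractions, function(f) {
      k <- round(f * E)
      if (k == 0) return(nc0)
      mean(vapply(seq_len(n_rep), function(r) {
        gg <- igraph::delete_edges(g, sample.int(E, k))
        natural_connectivity(gg)
      }, numeric(1)))
    }, numeric(1))
  })
  out <- data.frame(fraction = fractions, nc = mean_nc,
                    nc_normalized = if (nc0 > 0) mean_nc / nc0 else NA_real_)
  class(out) <- c("robustness_curve", class(out))
  attr(out, "n_rep") <- n_rep
  attr(out, "seed") <- seed
  out
}

#' Per-sample core-taxa interaction via leave-one-out SparCC
#'
#' Sample-specific association scores by linear leave-one-out perturbation:
#' for sample s, score(i,j; s) = N * rho_all(i,j) - (N - 1) *
#' rho_without_s(i,j), computed with SparCC on the core-taxa submatrix.
#' The per-sample interaction is the count of core-core pairs with
#' |score| > r_min; it proxies how strongly that sample expresses the
#' core-taxon co-occurrence structure.
#'
#' @param table community_table (all samples)
#' @param core_ids taxon ids of the core set
#' @param r_min score threshold (default 0.35)
#' @param seed integer seed
#' @param n_inner passed to \code{sparcc_correlations}; the default 0
#'   (posterior-mean fractions) keeps the leave-one-out pseudovalues free
#'   of resampling noise, which the N-fold amplification would otherwise
#'   magnify
#' @param ... further arguments to \code{sparcc_correlations}
#' @return list: \code{edge_counts} (named per-sample integer),
#'   \code{scores} (pairs x samples matrix)
#' @export
single_sample_networks <- function(table, core_ids, r_min = 0.35,
                                   seed = 1L, n_inner = 0, ...) {
  stopifnot(inherits(table, "community_table"))
  if (n_samples(table) < 10) stop("need at least 10 samples")
  missing <- setdiff(core_ids, taxon_ids(table))
  if (length(missing)) stop("core ids absent from table: ",
                            paste(missing, collapse = ", "))
  sub <- subset_table(table, taxa = core_ids)
  N <- n_samples(sub)
  rho_all <- sparcc_correlations(sub, seed = seed, n_inner = n_inner, ...)
  pair_idx <- which(lower.tri(rho_all), arr.ind = TRUE)
  scores <- vapply(seq_len(N), function(s) {
    loo <- subset_table(sub, samples = -s)
    rho_s <- sparcc_correlations(loo, seed = seed, n_inner = n_inner, ...)
    N * rho_all[pair_idx] - (N - 1) * rho_s[pair_idx]
  }, numeric(nrow(pair_idx)))
  rownames(scores) <- paste(rownames(rho_all)[pair_idx[, 2]],
                            rownames(rho_all)[pair_idx[, 1]], sep = "|")
  colnames(scores) <- sample_ids(sub)
  list(edge_counts = colSums(abs(scores) > r_min),
       scores = scores)
}

#' Core/other edge analytics
#'
#' Edge counts over (core phylum x core phylum), core x other and
#' other x other blocks, plus mean shortest path length and mean edge
#' betweenness on the core-induced subgraph (unreachable pairs excluded and
#' counted).
#'
#' @param network correlation_network whose graph carries \code{core} and
#'   \code{phylum} vertex annotations (see \code{\link{build_network}})
#' @return list: \code{block_counts} (data.frame), \code{core_path_length},
#'   \code{core_edge_betweenness}, \code{unreachable_pairs}, \code{flag}
#' @export
core_edge_analytics <- function(network) {
  g <- network$graph
  core <- igraph::V(g)$core
  phylum <- igraph::V(g)$phylum
  if (is.null(core) || !any(core, na.rm = TRUE)) {
    return(list(block_counts = data.frame(), core_path_length = NA_real_,
                core_edge_betweenness = NA_real_, unreachable_pairs = NA,
                flag = "no core nodes in network"))
  }
  core[is.na(core)] <- FALSE
  el <- igraph::as_edgelist(g)
  i <- match(el[, 1], igraph::V(g)$name)
  j <- match(el[, 2], igraph::V(g)$name)
  block_of <- function(a, b) {
    if (core[a] && core[b])
      paste0("core:", paste(sort(c(phylum[a], phylum[b])), collapse = "-"))
    else if (core[a] || core[b]) "core-other"
    else "other-other"
  }
  blocks <- mapply(block_of, i, j)
  bc <- as.data.frame(table(block = blocks), stringsAsFactors = FALSE)
  names(bc)[2] <- "edges"

  sub <- igraph::induced_subgraph(g, which(core))
  if (igraph::ecount(sub) == 0) {
    return(list(block_counts = bc, core_path_length = NA_real_,
                core_edge_betweenness = NA_real_, unreachable_pairs = NA,
                flag = "all core nodes isolated"))
  }
  sp <- igraph::distances(sub)
  v <- sp[upper.tri(sp)]
  unreachable <- sum(!is.finite(v))
  list(block_counts = bc,
       core_path_length = mean(v[is.finite(v)]),
       core_edge_betweenness = mean(igraph::edge_betweenness(sub)),
       unreachable_pairs = unreachable,
       flag = NA_character_)
}
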