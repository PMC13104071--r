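#' Identify core taxa by abundance rank and occupancy
#'
#' Core taxa are the intersection of (i) the top \code{top_fraction} of
#' taxa ranked by mean relative abundance and (ii) taxa occurring in more
#' than \code{min_occupancy} of all samples (strict >). Ties at the rank
#' cutoff are broken deterministically by taxon id.
#'
#' @param table community_table
#' @param top_fraction abundance-rank cutoff (default 0.05, i.e. top 5\%)
#' @param min_occupancy occupancy cutoff, exceeded strictly (default 0.70)
#' @return object of class \code{core_taxa_set}: \code{taxa},
#'   \code{mean_rel_abundance}, \code{occupancy}, \code{top_fraction},
#'   \code{min_occupancy}
#' @export
identify_core_taxa <- function(table, top_fraction = 0.05,
                               min_occupancy = 0.70) {
  stopifnot(inherits(table, "community_table"))
  rel <- relative_abundance(table)
  mra <- rowMeans(rel)
  occ <- occupancy(table)
  k <- ceiling(top_fraction * n_taxa(table))
  ord <- order(-mra, taxon_ids(table))      # deterministic tie-break by id
  top_ids <- taxon_ids(table)[ord][seq_len(k)]
  core <- intersect(top_ids, taxon_ids(table)[occ > min_occupancy])
  if (length(core) == 0) warning("no taxa satisfy both core criteria")
  core <- sort(core)
  structure(list(taxa = core,
                 mean_rel_abundance = mra[core],
                 occupancy = occ[core],
                 top_fraction = top_fraction,
                 min_occupancy = min_occupancy),
            class = "core_taxa_set")
}

#' @export
print.core_taxa_set <- function(x, ...) {
  cat("core_taxa_set:", length(x$taxa), "taxa (top",
      paste0(100 * x$top_fraction, "%"), "abundance, occupancy >",
      paste0(100 * x$min_occupancy, "%"), ")\n")
  invisible(x)
}

#' AVD community stability
#'
#' Average variation degree: within each group, each taxon i has mean mu_i
#' and sd sigma_i of relative abundance over the group's samples; a
#' sample's AVD is the mean of |x_is - mu_i| / sigma_i over the taxa with
#' sigma_i > 0. Stability is 1 - standardised AVD; by default the
#' standardisation is min-max over all samples in the analysis set, so
#' stability lies in [0, 1] and is a strictly decreasing function of AVD.
#' Computed on relative abundances so read-depth differences do not read
#' as instability.
#'
#' @param table community_table
#' @param groups per-sample group labels (mu/sigma reference); defaults to
#'   one group
#' @param standardize "minmax" (default) or "zscore"
#' @return object of class \code{stability_profile}: data-frame-like list
#'   with \code{sample_id}, \code{avd}, \code{stability}, \code{group},
#'   plus \code{standardize} and \code{flag}
#' @export
avd_stability <- function(table, groups = NULL,
                          standardize = c("minmax", "zscore")) {
  stopifnot(inherits(table, "community_table"))
  standardize <- match.arg(standardize)
  n <- n_samples(table)
  if (is.null(groups)) groups <- rep("all", n)
  stopifnot(length(groups) == n)
  if (any(table(groups) < 3)) stop("each group needs at least 3 samples")
  rel <- relative_abundance(table)
  avd <- numeric(n)
  names(avd) <- sample_ids(table)
  flag <- NA_character_
  for (g in unique(groups)) {
    cols <- which(groups == g)
    sub <- rel[, cols, drop = FALSE]
    mu <- rowMeans(sub)
    sigma <- apply(sub, 1, sd)
    ok <- sigma > 0
    if (!any(ok)) {
      avd[cols] <- 0
      flag <- "group with identical samples: AVD 0, stability 1"
      next
    }
    dev <- abs(sub[ok, , drop = FALSE] - mu[ok]) / sigma[ok]
    avd[cols] <- colMeans(dev)
  }
  if (diff(range(avd)) == 0) {
    stability <- rep(1, n)
    if (is.na(flag)) flag <- "constant AVD across samples: stability 1"
  } else if (standardize == "minmax") {
    stability <- 1 - (avd - min(avd)) / (max(avd) - min(avd))
  } else {
    stability <- 1 - (avd - mean(avd)) / sd(avd)
  }
  structure(list(sample_id = sample_ids(table), avd = avd,
                 stability = setNames(stability, sample_ids(table)),
                 group = groups, standardize = standardize, flag = flag),
            class = "stability_profile")
}

#' @export
print.stability_profile <- function(x, ...) {
  cat("stability_profile:", length(x$avd), "samples;",
      "AVD range", paste(round(range(x$avd), 3), collapse = "-"),
      "| standardization:", x$standardize, "\n")
  if (!is.na(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' Correlation surface between stability and candidate drivers
#'
#' Spearman correlations of per-sample stability against each predictor,
#' within each stratum, with Benjamini-Hochberg adjustment across the
#' predictors of each stratum. Constant predictors are skipped with a flag.
#'
#' @param profile stability_profile
#' @param predictors data.frame of per-sample predictors (rows aligned with
#'   the profile's samples)
#' @param strata optional per-sample stratum labels (default: one stratum)
#' @return data.frame: stratum, predictor, rho, p, p_adj, flag
#' @export
stability_drivers <- function(profile, predictors, strata = NULL) {
  stopifnot(inherits(profile, "stability_profile"),
            nrow(predictors) == length(profile$stability))
  if (is.null(strata)) strata <- rep("all", nrow(predictors))
  out <- list()
  for (s in unique(strata)) {
    rows <- strata == s
    y <- profile$stability[rows]
    res <- lapply(names(predictors), function(v) {
      x <- predictors[[v]][rows]
      if (sd(x, na.rm = TRUE) == 0 || sd(y) == 0)
        return(data.frame(stratum = s, predictor = v, rho = NA_real_,
                          p = NA_real_, flag = "constant"))
      ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
      data.frame(stratum = s, predictor = v, rho = unname(ct$estimate),
                 p = ct$p.value, flag = NA_character_)
    })
    res <- do.call(rbind, res)
    res$p_adj <- p.adjust(res$p, method = "BH")
    out[[s]] <- res
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
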