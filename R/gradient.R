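#' Permafrost degradation index (PDI)
#'
#' First principal component of z-standardised active-layer thickness (ALT)
#' and mean annual ground temperature (MAGT) across sites, oriented so that
#' corr(PDI, ALT) > 0: larger PDI = more degraded.
#'
#' @param site_table data.frame with columns \code{site}, \code{ALT},
#'   \code{MAGT} (one row per site)
#' @return object of class \code{degradation_index}: \code{pdi} (named per
#'   site), \code{loadings}, \code{variance_explained}, \code{flipped}
#' @export
compute_pdi <- function(site_table) {
  stopifnot(all(c("site", "ALT", "MAGT") %in% names(site_table)),
            nrow(site_table) >= 3)
  if (sd(site_table$ALT) == 0 || sd(site_table$MAGT) == 0)
    stop("ALT and MAGT must both be non-constant")
  X <- scale(site_table[, c("ALT", "MAGT")])
  pc <- prcomp(X, center = FALSE, scale. = FALSE)
  score <- pc$x[, 1]
  flipped <- cor(score, site_table$ALT) < 0
  if (flipped) {
    score <- -score
    pc$rotation[, 1] <- -pc$rotation[, 1]
  }
  structure(list(pdi = setNames(score, site_table$site),
                 loadings = pc$rotation[, 1],
                 variance_explained = pc$sdev[1]^2 / sum(pc$sdev^2),
                 flipped = flipped),
            class = "degradation_index")
}

#' @export
print.degradation_index <- function(x, ...) {
  cat("degradation_index (PC1 of ALT + MAGT,",
      sprintf("%.1f%% variance):\n", 100 * x$variance_explained))
  print(round(x$pdi, 3))
  invisible(x)
}

#' Species trend analysis along an ordinal gradient
#'
#' Filters taxa by mean relative abundance (default 0.01\%), computes the
#' Spearman correlation of each taxon's relative abundance with the
#' gradient, ranks by |r| and returns the strongest responders with
#' BH-adjusted p-values.
#'
#' @param table community_table
#' @param gradient per-sample ordinal/continuous gradient
#' @param min_mean_rel abundance filter (default 1e-4 = 0.01\%)
#' @param top_n rows returned (default 20)
#' @return data.frame: taxon, r, p, p_adj, rank
#' @export
species_trends <- function(table, gradient, min_mean_rel = 1e-4,
                           top_n = 20) {
  stopifnot(length(gradient) == n_samples(table))
  if (length(unique(gradient)) < 3) stop("gradient needs at least 3 levels")
  tab <- filter_taxa_by_mean_abundance(table, min_mean_rel)
  if (n_taxa(tab) == 0) {
    out <- data.frame(taxon = character(), r = numeric(), p = numeric(),
                      p_adj = numeric(), rank = integer())
    attr(out, "flag") <- "no taxa pass the abundance filter"
    return(out)
  }
  rel <- relative_abundance(tab)
  res <- t(apply(rel, 1, function(x) {
    ct <- suppressWarnings(cor.test(x, gradient, method = "spearman",
                                    exact = FALSE))
    c(r = unname(ct$estimate), p = ct$p.value)
  }))
  out <- data.frame(taxon = rownames(res), r = res[, "r"], p = res[, "p"],
                    row.names = NULL)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out <- out[order(-abs(out$r), out$taxon), ]
  out$rank <- seq_len(nrow(out))
  head(out, top_n)
}

#' Kruskal-Wallis group comparison with BH correction and letters
#'
#' Omnibus Kruskal-Wallis test, pairwise Wilcoxon rank-sum tests with
#' Benjamini-Hochberg adjustment, and a compact letter display: groups
#' sharing a letter are not significantly different at \code{alpha}.
#' Letters come from a greedy insert-absorb pass over groups in a
#' deterministic (label-sorted) order.
#'
#' @param values per-sample numeric metric
#' @param groups per-sample labels
#' @param alpha significance level for the letters (default 0.05)
#' @return list: \code{kruskal_p}, \code{pairwise} (data.frame with
#'   adjusted p), \code{letters} (named character), \code{excluded}
#' @export
compare_groups <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  tab <- table(groups)
  excluded <- names(tab)[tab < 2]
  if (length(excluded)) {
    keep <- !(groups %in% excluded)
    values <- values[keep]; groups <- groups[keep]
  }
  lev <- sort(unique(groups))
  if (length(lev) < 2) stop("need at least 2 groups with n >= 2")
  kp <- kruskal.test(values, factor(groups))$p.value
  pw <- suppressWarnings(
    pairwise.wilcox.test(values, factor(groups), p.adjust.method = "BH",
                         exact = FALSE))
  pm <- pw$p.value
  get_p <- function(a, b) {
    p <- NA_real_
    if (a %in% rownames(pm) && b %in% colnames(pm)) p <- pm[a, b]
    if (is.na(p) && b %in% rownames(pm) && a %in% colnames(pm)) p <- pm[b, a]
    p
  }
  pairs <- t(combn(lev, 2))
  pairwise <- data.frame(group1 = pairs[, 1], group2 = pairs[, 2],
                         p_adj = mapply(get_p, pairs[, 1], pairs[, 2]))
  distinct <- function(a, b) {
    p <- get_p(a, b)
    !is.na(p) && p < alpha
  }
  # greedy insert-absorb letter assignment
  sets <- list()
  for (g in lev) {
    placed <- FALSE
    for (k in seq_along(sets)) {
      if (!any(vapply(sets[[k]], distinct, logical(1), b = g))) {
        sets[[k]] <- c(sets[[k]], g)
        placed <- TRUE
      }
    }
    if (!placed) sets[[length(sets) + 1]] <- g
  }
  letters_out <- setNames(rep("", length(lev)), lev)
  for (k in seq_along(sets))
    for (g in sets[[k]])
      letters_out[g] <- paste0(letters_out[g], letters[k])
  list(kruskal_p = kp, pairwise = pairwise, letters = letters_out,
       excluded = excluded)
}

#' Percent change of POCD along an ordered gradient
#'
#' 100 * (next - previous) / previous for each consecutive pair of ordered
#' group means.
#'
#' @param ordered_group_means numeric vector, ordered (e.g. S1..S5 means)
#' @return numeric vector of per-step percent changes, named "a->b"
#' @export
pocd_percent_change <- function(ordered_group_means) {
  x <- ordered_group_means
  if (length(x) < 2) stop("need at least 2 ordered groups")
  if (any(x[-length(x)] <= 0)) stop("previous-group mean must be > 0")
  pc <- 100 * diff(x) / x[-length(x)]
  nm <- names(x)
  if (!is.null(nm)) names(pc) <- paste(nm[-length(nm)], nm[-1], sep = "->")
  pc
}

#' Stratum-adjusted association between stability and POCD
#'
#' Least-squares regression of POCD on community stability with the
#' stratum (site or sub-layer) entering as fixed-effect indicators; the
#' reported effect is the stability coefficient and its p-value comes from
#' permuting stability within strata. Strata with a single sample are
#' merged into the nearest (label-adjacent) level with a flag.
#'
#' @param profile stability_profile
#' @param frame sample frame carrying \code{POCD} (rows aligned with the
#'   profile's samples)
#' @param stratum per-sample stratum labels
#' @param n_perm permutations (default 999)
#' @param seed integer seed
#' @return list: \code{coefficient}, \code{partial_r}, \code{p_value},
#'   \code{n_permutations}, \code{flag}
#' @export
stability_pocd_association <- function(profile, frame, stratum,
                                       n_perm = 999, seed = 1L) {
  stopifnot(inherits(profile, "stability_profile"),
            "POCD" %in% names(frame),
            nrow(frame) == length(profile$stability))
  s <- profile$stability
  y <- frame$POCD
  stratum <- as.character(stratum)
  flag <- NA_character_
  tab <- table(stratum)
  if (any(tab < 2)) {
    singles <- names(tab)[tab < 2]
    lev <- sort(names(tab)[tab >= 2])
    for (sg in singles) {
      near <- lev[which.min(abs(match(sg, sort(names(tab))) -
                                  match(lev, sort(names(tab)))))]
      stratum[stratum == sg] <- near
    }
    flag <- paste("singleton strata merged:", paste(singles, collapse = ", "))
  }
  f <- factor(stratum)
  fit <- if (nlevels(f) > 1) lm(y ~ s + f) else lm(y ~ s)
  beta <- unname(coef(fit)["s"])
  # partial correlation: residualise both sides on the stratum indicators
  ry <- if (nlevels(f) > 1) residuals(lm(y ~ f)) else y - mean(y)
  rs <- if (nlevels(f) > 1) residuals(lm(s ~ f)) else s - mean(s)
  pr <- if (sd(rs) == 0) NA_real_ else cor(ry, rs)
  hits <- with_seed(seed, {
    idx_by_stratum <- split(seq_along(s), f)
    sum(vapply(seq_len(n_perm), function(i) {
      sp <- s
      for (ix in idx_by_stratum) sp[ix] <- sp[sample(ix, length(ix))]
      fitp <- if (nlevels(f) > 1) lm(y ~ sp + f) else lm(y ~ sp)
      abs(coef(fitp)["sp"]) >= abs(beta) - 1e-12
    }, logical(1)))
  })
  list(coefficient = beta, partial_r = pr,
       p_value = (1 + hits) / (1 + n_perm),
       n_permutations = n_perm, flag = flag)
}
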