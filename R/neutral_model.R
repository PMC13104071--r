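#' Fit the Sloan neutral community model
#'
#' Predicts each taxon's occupancy (fraction of samples where it is
#' detected) from its mean relative abundance p via the beta approximation
#' to neutral drift with immigration:
#' occupancy(p) = 1 - pbeta(d, Nm * p, Nm * (1 - p)), where d is the
#' detection limit (1 / mean reads per sample) and Nm the product of
#' metacommunity size and migration rate. Nm is estimated by unweighted
#' nonlinear least squares on the unbinned per-taxon points
#' (\code{minpack.lm::nlsLM}); the migration rate is m = Nm / N with
#' N the mean reads per sample.
#'
#' @param table community_table
#' @param detection_limit optional override of d (default 1 / mean column
#'   sum)
#' @return object of class \code{ncm_fit}: \code{Nm}, \code{m}, \code{R2},
#'   \code{detection_limit}, \code{points} (data.frame: taxon, p, observed
#'   and predicted occupancy), \code{N}
#' @export
fit_neutral_model <- function(table, detection_limit = NULL) {
  stopifnot(inherits(table, "community_table"))
  if (n_taxa(table) < 20) stop("need at least 20 taxa to fit the neutral model")
  N <- mean(colSums(table$counts))
  d <- if (is.null(detection_limit)) 1 / N else detection_limit
  rel <- relative_abundance(table)
  p <- rowMeans(rel)
  occ <- occupancy(table)
  keep <- p > 0
  p <- p[keep]; occ <- occ[keep]
  if (all(occ == 0) || all(occ == 1))
    stop("degenerate occupancies (all 0 or all 1): nothing to fit")
  dat <- data.frame(p = p, occ = occ)
  start <- list(Nm = max(10, 1 / d / 10))
  fit <- tryCatch(
    minpack.lm::nlsLM(occ ~ 1 - pbeta(d, Nm * p, Nm * (1 - p)),
                      data = dat, start = start,
                      lower = 1e-3, upper = 1e9,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("neutral model fit failed to converge: ",
                             conditionMessage(e)))
  Nm <- unname(coef(fit)["Nm"])
  pred <- 1 - pbeta(d, Nm * p, Nm * (1 - p))
  sse <- sum((occ - pred)^2)
  sst <- sum((occ - mean(occ))^2)
  m <- Nm / N
  if (m > 1) warning("estimated migration rate m exceeds 1")
  structure(list(Nm = Nm, m = m, R2 = 1 - sse / sst,
                 detection_limit = d, N = N,
                 points = data.frame(taxon = names(p), p = p,
                                     observed = occ, predicted = pred,
                                     row.names = NULL)),
            class = "ncm_fit")
}

#' Predicted occupancy from a fitted neutral model
#'
#' @param object ncm_fit
#' @param newdata optional numeric vector of mean relative abundances
#' @param ... unused
#' @export
predict.ncm_fit <- function(object, newdata = NULL, ...) {
  p <- if (is.null(newdata)) object$points$p else newdata
  1 - pbeta(object$detection_limit, object$Nm * p, object$Nm * (1 - p))
}

#' @export
coef.ncm_fit <- function(object, ...) {
  c(Nm = object$Nm, m = object$m)
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat("Sloan neutral community model fit\n")
  cat(sprintf("  Nm = %.1f  m = %.4g  R2 = %.3f  (d = %.3g, %d taxa)\n",
              x$Nm, x$m, x$R2, x$detection_limit, nrow(x$points)))
  invisible(x)
}

#' Occupancy-abundance plot of a neutral model fit
#'
#' @param x ncm_fit
#' @param ... passed to plot()
#' @export
plot.ncm_fit <- function(x, ...) {
  o <- order(x$points$p)
  plot(x$points$p[o], x$points$observed[o], log = "x",
       xlab = "mean relative abundance", ylab = "occupancy",
       pch = 16, col = "grey40", ...)
  graphics::lines(x$points$p[o], x$points$predicted[o], col = "red3", lwd = 2)
  invisible(x)
}

#' Simulate occupancy data from the Sloan neutral model
#'
#' Per-sample relative abundances of each taxon are drawn from
#' Beta(Nm p, Nm (1 - p)) and a taxon is detected where its abundance
#' exceeds the detection limit. Used as the generative counterpart of
#' \code{\link{fit_neutral_model}} in parameter-recovery tests.
#'
#' @param Nm true Nm
#' @param n_taxa,n_samples dimensions
#' @param reads reads per sample (sets d = 1/reads)
#' @param seed integer seed
#' @return community_table of 0/1-scaled counts thresholded at d (counts =
#'   rounded reads * abundance)
#' @export
simulate_neutral_occupancy <- function(Nm, n_taxa = 300, n_samples = 100,
                                       reads = 20000, seed = 1L) {
  with_seed(seed, {
    # log-normal regional abundances, normalised
    p <- rlnorm(n_taxa, -2, 1.5)
    p <- p / sum(p)
    counts <- vapply(seq_len(n_samples), function(j) {
      x <- stats::rbeta(n_taxa, Nm * p, Nm * (1 - p))
      # floor ties detection (count >= 1) exactly to abundance >= 1/reads
      as.integer(floor(x * reads))
    }, integer(n_taxa))
    rownames(counts) <- sprintf("sp%04d", seq_len(n_taxa))
    colnames(counts) <- sprintf("s%03d", seq_len(n_samples))
    community_table(counts[rowSums(counts) > 0, , drop = FALSE])
  })
}
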