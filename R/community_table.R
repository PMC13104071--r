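#' Construct a community table
#'
#' A community table holds non-negative integer counts of taxa (rows) by
#' samples (columns) together with one taxonomic lineage string per taxon.
#' It is the universal input of the pipeline: rarefaction, diversity,
#' assembly inference, networks and stability all start from one.
#'
#' @param counts numeric matrix, taxa x samples, non-negative integers.
#'   Row names are taxon ids, column names sample ids (both required unless
#'   supplied explicitly).
#' @param lineages character vector of rank-labelled lineage strings, one per
#'   taxon; defaults to "unclassified" for every taxon.
#' @param taxon_ids,sample_ids optional explicit ids overriding dimnames.
#'
#' @return an object of class \code{community_table}: a list with elements
#'   \code{counts} (integer matrix with dimnames), \code{lineages} (named
#'   character vector).
#' @export
community_table <- function(counts, lineages = NULL,
                            taxon_ids = NULL, sample_ids = NULL) {
  counts <- as.matrix(counts)
  if (!is.null(taxon_ids)) rownames(counts) <- taxon_ids
  if (!is.null(sample_ids)) colnames(counts) <- sample_ids
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry taxon ids (rownames) and sample ids (colnames)")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate taxon ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (!is.numeric(counts) || anyNA(counts))
    stop("counts must be numeric and free of NA")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (max(abs(counts - round(counts))) > 1e-8)
    stop("counts must be integers")
  storage.mode(counts) <- "integer"
  if (is.null(lineages)) lineages <- rep("unclassified", nrow(counts))
  if (length(lineages) != nrow(counts))
    stop("need one lineage per taxon")
  names(lineages) <- rownames(counts)
  structure(list(counts = counts, lineages = as.character(lineages)),
            class = "community_table")
}

#' @export
print.community_table <- function(x, ...) {
  cat("community_table:", nrow(x$counts), "taxa x", ncol(x$counts), "samples\n")
  cat("  total reads:", sum(as.numeric(x$counts)),
      "| per-sample range:", paste(range(colSums(x$counts)), collapse = "-"), "\n")
  invisible(x)
}

#' @export
dim.community_table <- function(x) dim(x$counts)

n_taxa <- function(table) nrow(table$counts)
n_samples <- function(table) ncol(table$counts)
taxon_ids <- function(table) rownames(table$counts)
sample_ids <- function(table) colnames(table$counts)

#' Subset a community table
#'
#' @param x community_table
#' @param taxa,samples indices, logical masks or ids
#' @param drop_zero drop taxa whose counts become all zero
#' @param ... unused
#' @export
subset_table <- function(x, taxa = NULL, samples = NULL, drop_zero = FALSE, ...) {
  stopifnot(inherits(x, "community_table"))
  counts <- x$counts
  lineages <- x$lineages
  if (!is.null(taxa)) {
    counts <- counts[taxa, , drop = FALSE]
    lineages <- lineages[rownames(counts)]
  }
  if (!is.null(samples)) counts <- counts[, samples, drop = FALSE]
  if (drop_zero) {
    keep <- rowSums(counts) > 0
    counts <- counts[keep, , drop = FALSE]
    lineages <- lineages[keep]
  }
  community_table(counts, lineages)
}

#' Convert counts to per-sample relative abundances
#'
#' Each column is divided by its sum so columns sum to one; zeros are
#' preserved. Applying the transform to an already-proportional matrix leaves
#' it unchanged.
#'
#' @param table community_table or a numeric taxa x sample matrix
#' @return numeric matrix of proportions with the same dimnames
#' @export
relative_abundance <- function(table) {
  m <- if (inherits(table, "community_table")) table$counts else as.matrix(table)
  cs <- colSums(m)
  if (any(cs <= 0))
    stop("all-zero sample(s): ", paste(colnames(m)[cs <= 0], collapse = ", "))
  sweep(m, 2, cs, "/")
}

#' Rarefy a community table to even depth
#'
#' Subsamples each sample's reads without replacement down to \code{depth},
#' so every column sums exactly to \code{depth}. Reproducible under a fixed
#' seed.
#'
#' @param table community_table
#' @param depth target reads per sample; defaults to the minimum column sum
#'   (the usual even-depth choice)
#' @param seed integer seed
#' @param drop_zero drop taxa that become all-zero after subsampling
#' @return rarefied community_table
#' @export
rarefy <- function(table, depth = min(colSums(table$counts)), seed,
                   drop_zero = TRUE) {
  stopifnot(inherits(table, "community_table"))
  if (missing(seed)) stop("seed is required for reproducible rarefaction")
  cs <- colSums(table$counts)
  if (any(cs < depth))
    stop("rarefaction depth ", depth, " exceeds reads in sample(s): ",
         paste(colnames(table$counts)[cs < depth], collapse = ", "))
  out <- with_seed(seed, {
    apply(table$counts, 2, function(col) {
      # draw `depth` reads without replacement from the sample's read pool
      reads <- rep.int(seq_along(col), col)
      kept <- reads[sample.int(length(reads), depth)]
      tabulate(kept, nbins = length(col))
    })
  })
  dimnames(out) <- dimnames(table$counts)
  res <- community_table(out, table$lineages)
  if (drop_zero) res <- subset_table(res, drop_zero = TRUE)
  res
}

#' Filter taxa by mean relative abundance
#'
#' Retains taxa whose mean (across samples) relative abundance is at least
#' \code{min_mean_rel}. The comparison is inclusive: a taxon sitting exactly
#' at the threshold is kept. The conventional noise filter for species-level
#' profiles is 0.01\% (\code{min_mean_rel = 1e-4}).
#'
#' @param table community_table
#' @param min_mean_rel fraction in [0, 1)
#' @return filtered community_table (taxon order preserved)
#' @export
filter_taxa_by_mean_abundance <- function(table, min_mean_rel = 1e-4) {
  stopifnot(inherits(table, "community_table"),
            min_mean_rel >= 0, min_mean_rel < 1)
  rel <- relative_abundance(table)
  keep <- rowMeans(rel) >= min_mean_rel
  if (!any(keep)) warning("no taxa pass the mean-abundance filter")
  subset_table(table, taxa = keep)
}

#' Per-taxon occupancy (occurrence frequency)
#'
#' @param table community_table
#' @return named numeric vector, fraction of samples where each taxon occurs
#' @export
occupancy <- function(table) {
  rowMeans(table$counts > 0)
}
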