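#' Read a taxa-by-sample community table
#'
#' TSV layout: first column taxon id, optional \code{lineage} column, one
#' column per sample. BIOM 2.1 files are read through the \pkg{biomformat}
#' package when it is installed.
#'
#' @param path file path
#' @param format "tsv" or "biom"
#' @param drop_zero_taxa drop all-zero taxa on read (reported via message)
#' @return community_table
#' @export
read_community_table <- function(path, format = c("tsv", "biom"),
                                 drop_zero_taxa = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM requires the 'biomformat' package")
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    tab <- community_table(round(m))
  } else {
    header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
    dups <- unique(header[duplicated(header)])
    if (length(dups))
      stop("duplicated sample header(s): ", paste(dups, collapse = ", "))
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (anyDuplicated(df[[1]]))
      stop("duplicated taxon id(s): ",
           paste(unique(df[[1]][duplicated(df[[1]])]), collapse = ", "))
    lineages <- NULL
    if ("lineage" %in% names(df)) {
      lineages <- df[["lineage"]]
      df[["lineage"]] <- NULL
    }
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric counts in ", path)
    if (any(m < 0)) stop("negative counts in ", path)
    rownames(m) <- df[[1]]
    tab <- community_table(round(m), lineages)
  }
  if (drop_zero_taxa) {
    n0 <- sum(rowSums(tab$counts) == 0)
    if (n0 > 0) {
      message("dropping ", n0, " all-zero taxa")
      tab <- subset_table(tab, drop_zero = TRUE)
    }
  }
  tab
}

#' Write a community table as TSV
#'
#' Inverse of \code{\link{read_community_table}}; round-trips counts, taxon
#' ids and lineages losslessly.
#'
#' @param table community_table
#' @param path output path
#' @export
write_community_table <- function(table, path) {
  stopifnot(inherits(table, "community_table"))
  df <- data.frame(taxon_id = taxon_ids(table),
                   lineage = table$lineages,
                   table$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample metadata keyed by sample_id
#'
#' @param path TSV path with a \code{sample_id} column
#' @return data.frame (a "sample frame")
#' @export
read_sample_frame <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_sample_frame(df)
}

#' Write per-sample metadata as TSV
#' @param frame sample frame (data.frame)
#' @param path output path
#' @export
write_sample_frame <- function(frame, path) {
  write.table(frame, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a sample frame
#'
#' Checks the per-sample metadata contract: unique sample ids, strictly
#' increasing depth within each site, and sub-layer labels consistent with
#' the main-layer split (TAL/SAL active; TPL/SPL permafrost; FFL straddles
#' the thaw front and carries an explicit per-sample main-layer flag).
#'
#' @param frame data.frame with at least \code{sample_id}; when positional
#'   columns (\code{site}, \code{depth_m}, \code{main_layer},
#'   \code{sub_layer}) are present they are checked.
#' @return the validated data.frame, invisibly classed \code{sample_frame}
#' @export
validate_sample_frame <- function(frame) {
  stopifnot(is.data.frame(frame))
  if (!"sample_id" %in% names(frame)) stop("sample frame needs a sample_id column")
  if (anyDuplicated(frame$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(frame$sample_id[duplicated(frame$sample_id)]), collapse = ", "))
  if (all(c("site", "depth_m") %in% names(frame))) {
    if (any(frame$depth_m <= 0)) stop("depth_m must be > 0")
    bad <- vapply(split(frame$depth_m, frame$site),
                  function(d) is.unsorted(d, strictly = TRUE), logical(1))
    if (any(bad))
      stop("depth_m not strictly increasing within site(s): ",
           paste(names(bad)[bad], collapse = ", "))
  }
  if (all(c("main_layer", "sub_layer") %in% names(frame))) {
    ok <- (frame$sub_layer %in% c("TAL", "SAL") & frame$main_layer == "active") |
      (frame$sub_layer %in% c("TPL", "SPL") & frame$main_layer == "permafrost") |
      frame$sub_layer == "FFL"
    if (!all(ok))
      stop("sub_layer/main_layer mismatch for: ",
           paste(frame$sample_id[!ok], collapse = ", "))
  }
  class(frame) <- unique(c("sample_frame", class(frame)))
  invisible(frame)
}

# Align a community table's sample columns with a sample frame's rows.
align_table_frame <- function(table, frame) {
  common <- intersect(sample_ids(table), frame$sample_id)
  if (length(common) < 2) stop("fewer than 2 samples shared by table and frame")
  table <- subset_table(table, samples = common)
  frame <- frame[match(common, frame$sample_id), , drop = FALSE]
  list(table = table, frame = frame)
}
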