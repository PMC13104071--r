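#' Build a pipeline configuration
#'
#' One configuration drives the whole analysis chain
#' (simulate/load -> rarefy -> diversity -> assembly -> networks ->
#' stability -> gradient). Every stochastic stage's seed is derived from
#' the master seed, and the config round-trips to YAML losslessly.
#'
#' @param input NULL to simulate, or list(table=, metadata=) of file paths
#' @param simulation named list of \code{\link{simulation_config}}
#'   overrides used when \code{input} is NULL
#' @param rarefaction list(policy = "min" or "fixed", depth = integer)
#' @param grouping list naming metadata columns: \code{main}, \code{sub},
#'   \code{site}
#' @param assembly list(n_null = ...)
#' @param network list(enabled =, r_min =, p_max =, n_inner =, n_boot =,
#'   max_taxa = )
#' @param seed master seed
#' @param outdir output directory
#' @return classed \code{pipeline_config} list
#' @export
pipeline_config <- function(input = NULL,
                            simulation = list(),
                            rarefaction = list(policy = "min", depth = NULL),
                            grouping = list(main = "main_layer",
                                            sub = "sub_layer",
                                            site = "site"),
                            assembly = list(n_null = 100),
                            network = list(enabled = TRUE, r_min = 0.35,
                                           p_max = 0.05, n_inner = 10,
                                           n_boot = 49, max_taxa = 60),
                            seed = 1L,
                            outdir = tempfile("permacomm_run_")) {
  cfg <- list(input = input, simulation = simulation,
              rarefaction = modifyList(list(policy = "min", depth = NULL),
                                       rarefaction),
              grouping = modifyList(list(main = "main_layer",
                                         sub = "sub_layer", site = "site"),
                                    grouping),
              assembly = modifyList(list(n_null = 100), assembly),
              network = modifyList(list(enabled = TRUE, r_min = 0.35,
                                        p_max = 0.05, n_inner = 10,
                                        n_boot = 49, max_taxa = 60),
                                   network),
              seed = as.integer(seed), outdir = outdir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file
#' @return pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param config pipeline_config to write
#' @export
write_pipeline_config <- function(config, path) {
  cfg <- unclass(config)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes all stages in dependency order, writes every result as TSV
#' under \code{config$outdir}, and records a manifest (config snapshot,
#' package version, per-output checksum, collected warnings). When a
#' manifest from a previous run is present, stages whose outputs still
#' match their recorded checksums are skipped; corrupted or missing
#' outputs trigger re-execution of that stage.
#'
#' @param config \code{\link{pipeline_config}}
#' @return the run manifest (list), invisibly; written as manifest.json
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character()
  note <- function(...) warnings_log <<- c(warnings_log, paste0(...))

  prev <- NULL
  manifest_path <- file.path(config$outdir, "manifest.json")
  if (file.exists(manifest_path))
    prev <- tryCatch(jsonlite::read_json(manifest_path, simplifyVector = TRUE),
                     error = function(e) NULL)
  checksums <- list()
  fresh <- function(files) {
    !is.null(prev) && all(files %in% names(prev$checksums)) &&
      all(file.exists(file.path(config$outdir, files))) &&
      all(vapply(files, function(f)
        identical(unname(tools::md5sum(file.path(config$outdir, f))),
                  prev$checksums[[f]]), logical(1)))
  }
  record <- function(files) {
    for (f in files)
      checksums[[f]] <<- unname(tools::md5sum(file.path(config$outdir, f)))
  }
  out <- function(f) file.path(config$outdir, f)
  tsv <- function(df, f) {
    write.table(df, out(f), sep = "\t", quote = FALSE, row.names = FALSE)
    f
  }

  ## -- stage: input -------------------------------------------------------
  truth <- NULL
  if (is.null(config$input)) {
    sim_cfg <- do.call(simulation_config,
                       modifyList(config$simulation, list(seed = config$seed)))
    ds <- simulate_dataset(sim_cfg)
    table <- ds$table; frame <- ds$frame; truth <- ds$truth
    tsv(data.frame(key = c("m_true", "alpha_active", "alpha_permafrost",
                           "pocd_stability_slope"),
                   value = c(truth$m_true, truth$alpha_active,
                             truth$alpha_permafrost,
                             truth$pocd_stability_slope)),
        "truth.tsv")
    write_community_table(table, out("table.tsv"))
    write_sample_frame(frame, out("metadata.tsv"))
    record(c("truth.tsv", "table.tsv", "metadata.tsv"))
  } else {
    table <- read_community_table(config$input$table)
    frame <- read_sample_frame(config$input$metadata)
  }
  # validate grouping columns before any compute
  for (col in unlist(config$grouping))
    if (!col %in% names(frame))
      stop("grouping column '", col, "' not found in metadata")
  al <- align_table_frame(table, frame)
  table <- al$table; frame <- al$frame

  ## -- stage: rarefaction -------------------------------------------------
  depth <- if (identical(config$rarefaction$policy, "fixed"))
    config$rarefaction$depth else min(colSums(table$counts))
  table <- rarefy(table, depth, seed = derive_seed(config$seed, "rarefy"))

  ## -- stage: diversity ---------------------------------------------------
  if (!fresh("alpha_diversity.tsv")) {
    alpha <- data.frame(sample_id = sample_ids(table),
                        richness = richness(table),
                        shannon = shannon(table))
    record(tsv(alpha, "alpha_diversity.tsv"))
  }
  bc <- bray_curtis_matrix(table)
  main <- frame[[config$grouping$main]]
  pn <- permanova(bc, main, seed = derive_seed(config$seed, "permanova"))
  record(tsv(data.frame(test = "main_layer", pseudo_F = pn$pseudo_F,
                        R2 = pn$R2, p = pn$p_value),
             "permanova.tsv"))

  ## -- stage: assembly ----------------------------------------------------
  if (!fresh("stochasticity.tsv")) {
    st <- lapply(unique(main), function(g) {
      sub <- subset_table(table, samples = main == g, drop_zero = TRUE)
      r <- stochasticity_ratio(sub, n_null = config$assembly$n_null,
                               seed = derive_seed(config$seed,
                                                  paste0("null_", g)))
      data.frame(group = g, ratio = r$ratio, n_pairs = length(r$pair_ratios))
    })
    record(tsv(do.call(rbind, st), "stochasticity.tsv"))
  }
  ncm <- tryCatch(fit_neutral_model(table), error = function(e) {
    note("neutral model: ", conditionMessage(e)); NULL
  })
  if (!is.null(ncm))
    record(tsv(data.frame(Nm = ncm$Nm, m = ncm$m, R2 = ncm$R2,
                          detection_limit = ncm$detection_limit),
               "ncm.tsv"))

  ## -- stage: stability & core taxa --------------------------------------
  core <- identify_core_taxa(table)
  record(tsv(data.frame(taxon = core$taxa,
                        mean_rel_abundance = core$mean_rel_abundance,
                        occupancy = core$occupancy),
             "core_taxa.tsv"))
  stab <- avd_stability(table, groups = main)
  if (!is.na(stab$flag)) note("avd: ", stab$flag)
  record(tsv(data.frame(sample_id = stab$sample_id, avd = stab$avd,
                        stability = stab$stability, group = stab$group),
             "stability.tsv"))

  ## -- stage: networks ----------------------------------------------------
  if (isTRUE(config$network$enabled)) {
    ftab <- filter_taxa_by_mean_abundance(table, 1e-4)
    if (n_taxa(ftab) > config$network$max_taxa) {
      keep <- order(-rowMeans(relative_abundance(ftab)))[
        seq_len(config$network$max_taxa)]
      ftab <- subset_table(ftab, taxa = sort(keep))
    }
    rho <- sparcc_correlations(ftab, n_inner = config$network$n_inner,
                               seed = derive_seed(config$seed, "sparcc"))
    pm <- sparcc_pvalues(ftab, rho, n_boot = config$network$n_boot,
                         n_inner = config$network$n_inner,
                         seed = derive_seed(config$seed, "sparcc_p"))
    net <- build_network(rho, pm, r_min = config$network$r_min,
                         p_max = config$network$p_max)
    record(tsv(net$edges, "network_edges.tsv"))
    top <- topology(net)
    record(tsv(data.frame(metric = names(unclass(top)),
                          value = vapply(unclass(top), function(v)
                            as.character(v)[1], character(1))),
               "topology.tsv"))
  }

  ## -- stage: gradient & carbon ------------------------------------------
  site_tab <- unique(frame[, c("site", "ALT", "MAGT")])
  if (nrow(site_tab) >= 3) {
    pdi <- compute_pdi(site_tab)
    record(tsv(data.frame(site = names(pdi$pdi), pdi = pdi$pdi),
               "pdi.tsv"))
  }
  trends <- species_trends(table, frame$depth_m)
  record(tsv(trends, "species_trends.tsv"))
  if ("POCD" %in% names(frame)) {
    means <- tapply(frame$POCD, frame[[config$grouping$site]], mean)
    means <- means[order(as.numeric(names(means)))]
    pc <- pocd_percent_change(means)
    record(tsv(data.frame(step = names(pc), percent_change = pc),
               "pocd_change.tsv"))
    assoc <- stability_pocd_association(
      stab, frame, frame[[config$grouping$site]],
      seed = derive_seed(config$seed, "assoc"))
    if (!is.na(assoc$flag)) note("association: ", assoc$flag)
    record(tsv(data.frame(coefficient = assoc$coefficient,
                          partial_r = assoc$partial_r, p = assoc$p_value),
               "stability_pocd.tsv"))
  }

  manifest <- list(config = unclass(config),
                   version = as.character(packageVersion("permacomm")),
                   checksums = checksums,
                   warnings = warnings_log,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
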