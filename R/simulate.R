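#' Configuration for the synthetic permafrost-profile generator
#'
#' The generator emulates the sampling design the pipeline targets: five
#' cores (sites) of 25 depth-resolved samples down to 15 m, split into an
#' active layer and a permafrost layer with a frozen-fringe transition,
#' depth-decaying environmental covariates, a site-level degradation
#' gradient (active-layer thickness and mean annual ground temperature both
#' increase with site index), a species pool with a tunable mix of
#' environmental filtering and neutral drift, high-occupancy core taxa, and
#' an organic-carbon-density (POCD) variable with a tunable (default
#' negative) dependence on community stability.
#'
#' @param n_sites number of cores (default 5)
#' @param depths_per_site samples per core (default 25, down to 15 m)
#' @param species_pool_size metacommunity richness (default 300)
#' @param reads_per_sample sequencing depth per sample (default 20000)
#' @param alpha_active,alpha_permafrost selection strength in [0,1] per main
#'   layer: 0 = pure neutral drift, 1 = pure environmental filtering.
#'   Defaults (0.6 active, 0.25 permafrost) mirror the expectation that
#'   seasonal thaw drives niche selection near the surface while the frozen
#'   column drifts.
#' @param sigma_niche niche breadth on the standardised depth-environment
#'   axis (default 0.15)
#' @param m_true immigration (migration) rate of the drift process,
#'   in (0, 1] (default 0.1)
#' @param core_fraction fraction of the pool designated core taxa
#'   (default 0.05)
#' @param theta Dirichlet-multinomial concentration adding technical
#'   overdispersion on top of the drift component (default 20000, roughly
#'   doubling multinomial variance at the default read depth; smaller =
#'   noisier)
#' @param pocd_stability_slope dependence of POCD on latent community
#'   stability (default -1: stabler communities hold less carbon)
#' @param pocd_noise_sd sd of POCD measurement noise (default 0.5)
#' @param env_noise_sd sd of covariate noise, as a fraction of each
#'   covariate's dynamic range (default 0.05)
#' @param seed master seed; all stage streams derive from it
#' @return a \code{simulation_config} list
#' @export
simulation_config <- function(n_sites = 5L,
                              depths_per_site = 25L,
                              species_pool_size = 300L,
                              reads_per_sample = 20000L,
                              alpha_active = 0.6,
                              alpha_permafrost = 0.25,
                              sigma_niche = 0.15,
                              m_true = 0.1,
                              core_fraction = 0.05,
                              theta = 20000,
                              pocd_stability_slope = -1,
                              pocd_noise_sd = 0.5,
                              env_noise_sd = 0.05,
                              seed = 1L) {
  cfg <- list(n_sites = as.integer(n_sites),
              depths_per_site = as.integer(depths_per_site),
              species_pool_size = as.integer(species_pool_size),
              reads_per_sample = as.integer(reads_per_sample),
              alpha_active = alpha_active,
              alpha_permafrost = alpha_permafrost,
              sigma_niche = sigma_niche,
              m_true = m_true,
              core_fraction = core_fraction,
              theta = theta,
              pocd_stability_slope = pocd_stability_slope,
              pocd_noise_sd = pocd_noise_sd,
              env_noise_sd = env_noise_sd,
              seed = as.integer(seed))
  stopifnot(cfg$n_sites >= 1, cfg$depths_per_site >= 3,
            cfg$species_pool_size >= 10, cfg$reads_per_sample >= 100,
            cfg$alpha_active >= 0, cfg$alpha_active <= 1,
            cfg$alpha_permafrost >= 0, cfg$alpha_permafrost <= 1,
            cfg$sigma_niche > 0, cfg$m_true > 0, cfg$m_true <= 1,
            cfg$core_fraction > 0, cfg$core_fraction < 1, cfg$theta > 0)
  class(cfg) <- "simulation_config"
  cfg
}

# Fixed depth grid (m): denser near the surface, as core sampling is.
depth_grid <- function(n) {
  top <- seq(0.1, 5.9, length.out = ceiling(n * 0.6))
  deep <- seq(6.5, 15, length.out = n - length(top))
  c(top, deep)
}

#' Generate per-sample metadata for a synthetic profile set
#'
#' Covariates follow the field's depth structure: temperature (Tp), water
#' content (PWC), organic matter (POM) and total nitrogen (TN) decline with
#' depth; pH rises; Eh drifts down slowly. Active-layer thickness (ALT) and
#' mean annual ground temperature (MAGT) increase with site index so the
#' degradation ordering is S1 < ... < Sn. Layer labels derive from each
#' site's ALT with a +/-0.2 m frozen fringe around the thaw front;
#' fringe samples carry an explicit main-layer flag.
#'
#' @param config \code{\link{simulation_config}}
#' @return sample frame (data.frame) with positional, layer and covariate
#'   columns (POCD is attached later by \code{\link{attach_pocd}})
#' @export
generate_metadata <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(derive_seed(config$seed, "metadata"), {
    depths <- depth_grid(config$depths_per_site)
    rows <- lapply(seq_len(config$n_sites), function(s) {
      alt <- 1.0 + 0.9 * (s - 1)            # m, thickens with degradation
      magt <- -2.6 + 0.45 * (s - 1)         # deg C, warms with degradation
      d <- depths
      nz <- function(range) rnorm(length(d), 0, config$env_noise_sd * range)
      tp <- 3 - 0.45 * d + 0.25 * (s - 1) + nz(6)
      pwc <- 30 * exp(-0.12 * d) - 1.2 * (s - 1) + nz(25)
      pom <- 6 * exp(-0.18 * d) - 0.25 * (s - 1) + nz(6)
      tn <- 0.45 * exp(-0.15 * d) - 0.015 * (s - 1) + nz(0.4)
      ph <- 7.1 + 0.075 * d + nz(1.2)
      eh <- 320 - 6 * d + nz(90)
      sub <- ifelse(d <= 0.5, "TAL",
             ifelse(d < alt - 0.2, "SAL",
             ifelse(d <= alt + 0.2, "FFL",
             ifelse(d <= 12, "TPL", "SPL"))))
      main <- ifelse(d <= alt, "active", "permafrost")
      data.frame(sample_id = sprintf("S%d_D%02d", s, seq_along(d)),
                 site = s, depth_m = d,
                 main_layer = main, sub_layer = sub,
                 Tp = tp, PWC = pmax(pwc, 0.5), pH = ph, Eh = eh,
                 POM = pmax(pom, 0.05), TN = pmax(tn, 0.005),
                 ALT = alt, MAGT = magt,
                 stringsAsFactors = FALSE)
    })
    frame <- do.call(rbind, rows)
    validate_sample_frame(frame)
    frame
  })
}

#' Generate a synthetic community table over a sample frame
#'
#' Each sample's expected composition is the mixture
#' \code{alpha * w(E) + (1 - alpha) * pi_neutral}: \code{w(E)} is a Gaussian
#' niche response around species-specific optima on the standardised
#' depth-environment axis (breadth \code{sigma_niche}); \code{pi_neutral}
#' is drawn, independently per sample, from the stationary law of
#' Wright-Fisher drift with immigration \code{m_true} from a fixed
#' log-normal metacommunity: Dirichlet with concentration
#' \code{Nm = m_true * reads_per_sample} (the local community is sized by
#' the sequencing depth), which is exactly the local community model the
#' neutral-fit module estimates, so \code{m_true} is recoverable ground
#' truth. Designated
#' core taxa receive uniformly high metacommunity weight so their occupancy
#' stays at or above 70\% by construction. Counts are drawn
#' Dirichlet-multinomial with concentration \code{theta}.
#'
#' @param config \code{\link{simulation_config}}
#' @param frame output of \code{\link{generate_metadata}}
#' @return list: \code{table} (community_table), \code{truth} (core ids,
#'   per-layer alpha, m_true, metacommunity weights)
#' @export
generate_community <- function(config, frame) {
  stopifnot(inherits(config, "simulation_config"), is.data.frame(frame))
  with_seed(derive_seed(config$seed, "community"), {
    S <- config$species_pool_size
    n_core <- max(1L, round(config$core_fraction * S))
    ids <- sprintf("sp%03d", seq_len(S))
    core_ids <- ids[seq_len(n_core)]

    # log-normal metacommunity; core taxa boosted to uniformly high weight
    meta <- rlnorm(S, meanlog = 0, sdlog = 1.3)
    meta[seq_len(n_core)] <- quantile(meta, 0.97) * runif(n_core, 0.8, 1.2)
    meta <- meta / sum(meta)

    env <- (frame$depth_m - min(frame$depth_m)) /
      diff(range(frame$depth_m))               # scalar axis in [0,1]
    opt <- runif(S)                             # species optima on the axis
    # stationary Wright-Fisher-with-immigration concentration
    Nm <- config$m_true * config$reads_per_sample

    alpha_s <- ifelse(frame$main_layer == "active",
                      config$alpha_active, config$alpha_permafrost)

    counts <- matrix(0L, S, nrow(frame),
                     dimnames = list(ids, frame$sample_id))
    for (j in seq_len(nrow(frame))) {
      w <- meta * exp(-(env[j] - opt)^2 / (2 * config$sigma_niche^2))
      if (sum(w) == 0) w <- meta
      w <- w / sum(w)
      gx <- rgamma(S, shape = Nm * meta, rate = 1)
      x <- if (sum(gx) > 0) gx / sum(gx) else meta
      mu <- alpha_s[j] * w + (1 - alpha_s[j]) * x
      # Dirichlet-multinomial draw
      g <- rgamma(S, shape = mu * config$theta, rate = 1)
      if (sum(g) == 0) g <- mu
      counts[, j] <- as.numeric(rmultinom(1, config$reads_per_sample,
                                          g / sum(g)))
    }
    lineages <- paste0("d__Bacteria|s__", ids)
    list(table = community_table(counts, lineages),
         truth = list(core_ids = core_ids,
                      niche_optima = setNames(opt, ids),
                      alpha_active = config$alpha_active,
                      alpha_permafrost = config$alpha_permafrost,
                      m_true = config$m_true,
                      metacommunity = setNames(meta, ids)))
  })
}

#' Attach a POCD column driven by a latent stability variable
#'
#' POCD = depth-decaying baseline + slope * latent + Gaussian noise. The
#' slope is recorded as ground truth so downstream association tests can be
#' scored against it.
#'
#' @param frame sample frame
#' @param stability_driver per-sample latent (same order as frame rows)
#' @param slope real; default from config is -1
#' @param noise_sd Gaussian noise sd
#' @param seed integer seed
#' @return frame with a \code{POCD} column and attribute
#'   \code{pocd_truth} = list(slope, noise_sd)
#' @export
attach_pocd <- function(frame, stability_driver, slope = -1,
                        noise_sd = 0.5, seed = 1L) {
  stopifnot(length(stability_driver) == nrow(frame))
  with_seed(derive_seed(seed, "pocd"), {
    # steep decline through the near-surface organic horizon, near-constant
    # storage below: the canonical permafrost organic-carbon depth profile
    baseline <- 2 + 6 * exp(-frame$depth_m / 0.4)
    frame$POCD <- baseline + slope * stability_driver +
      rnorm(nrow(frame), 0, noise_sd)
    attr(frame, "pocd_truth") <- list(slope = slope, noise_sd = noise_sd)
    frame
  })
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper: metadata, community, and POCD driven by the latent
#' community stability (1 - standardised AVD of the noise-free mixture is
#' approximated by the realised AVD stability of the sampled table, computed
#' per main layer).
#'
#' @param config \code{\link{simulation_config}}
#' @return list with \code{table}, \code{frame}, \code{truth}
#' @export
simulate_dataset <- function(config = simulation_config()) {
  frame <- generate_metadata(config)
  com <- generate_community(config, frame)
  stab <- avd_stability(com$table, groups = frame$main_layer)
  frame <- attach_pocd(frame, stab$stability,
                       slope = config$pocd_stability_slope,
                       noise_sd = config$pocd_noise_sd,
                       seed = config$seed)
  truth <- c(com$truth,
             list(pocd_stability_slope = config$pocd_stability_slope))
  list(table = com$table, frame = frame, truth = truth)
}
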