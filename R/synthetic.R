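#' Parametric species reflectance template
#'
#' A compact generative model of a vegetation reflectance-factor spectrum:
#' a visible baseline with a Gaussian green peak at 550 nm, a logistic red
#' edge rising to a NIR plateau, and a SWIR decline with water-absorption
#' dips at 1450 and 1940 nm scaled by a moisture parameter. The defaults
#' per functional type encode the qualitative contrasts of peatland
#' vegetation: vascular plants have a stronger green peak and steeper red
#' edge than mosses; litter (dead material) rises monotonically through
#' VIS-NIR and keeps a high SWIR level (low moisture). All numeric values
#' are synthetic — chosen for realism of shape, not measured.
#'
#' @param functional_type `"vascular"`, `"moss"` or `"litter"`.
#' @param vis_base Visible baseline RF.
#' @param green_peak_amp Amplitude of the 550-nm green peak.
#' @param red_edge_inflection_nm,red_edge_width_nm Logistic red-edge
#'   inflection and width (nm).
#' @param nir_plateau NIR plateau RF.
#' @param swir_slope Linear SWIR decline per nm beyond 1300 nm (fraction of
#'   the local level per 1200 nm).
#' @param moisture Water content in [0, 1] scaling the absorption dips.
#' @param bumps Optional list of species-specific pigmentation/structure
#'   features, each `c(center_nm, width_nm, amplitude)`: Gaussian bumps
#'   (amplitude may be negative) added to the base curve. These mimic the
#'   pigment and tissue absorption detail that distinguishes species with
#'   otherwise similar broadband shape, and keep the endmember matrix
#'   realistically conditioned.
#' @return List of class `"species_spectral_params"`.
#' @export
species_spectral_params <- function(functional_type = c("vascular", "moss", "litter"),
                                    vis_base = 0.05, green_peak_amp = 0.06,
                                    red_edge_inflection_nm = 715,
                                    red_edge_width_nm = 30,
                                    nir_plateau = 0.48, swir_slope = 0.25,
                                    moisture = 0.6, bumps = list()) {
  functional_type <- match.arg(functional_type)
  stopifnot(vis_base > 0, green_peak_amp >= 0, red_edge_width_nm > 0,
            nir_plateau > vis_base, moisture >= 0, moisture <= 1,
            all(vapply(bumps, length, integer(1)) == 3L))
  structure(list(functional_type = functional_type, vis_base = vis_base,
                 green_peak_amp = green_peak_amp,
                 red_edge_inflection_nm = red_edge_inflection_nm,
                 red_edge_width_nm = red_edge_width_nm,
                 nir_plateau = nir_plateau, swir_slope = swir_slope,
                 moisture = moisture, bumps = bumps),
            class = "species_spectral_params")
}

#' Evaluate a species reflectance template
#'
#' @param params A [species_spectral_params()].
#' @param wavelength_nm Wavelength grid (nm).
#' @return Numeric RF vector; errors if any value falls outside (0, 1).
#' @export
synth_rf <- function(params, wavelength_nm = 350:2500) {
  wl <- wavelength_nm
  rise <- stats::plogis((wl - params$red_edge_inflection_nm) /
                          params$red_edge_width_nm)
  green <- params$green_peak_amp * exp(-0.5 * ((wl - 550) / 25)^2)
  base <- params$vis_base + green * (1 - rise) +
    (params$nir_plateau - params$vis_base) * rise
  for (b in params$bumps) {
    base <- base + b[3] * exp(-0.5 * ((wl - b[1]) / b[2])^2)
  }
  dip <- params$moisture *
    (0.45 * exp(-0.5 * ((wl - 1450) / 45)^2) +
     0.60 * exp(-0.5 * ((wl - 1940) / 80)^2) +
     0.35 * exp(-0.5 * ((wl - 2500) / 220)^2)) +
    params$swir_slope * pmax(0, wl - 1300) / 1200
  rf <- base * pmax(0.03, 1 - dip)
  if (any(rf <= 0) || any(rf >= 1)) {
    stop("generation error: parameters produce rf outside (0, 1)", call. = FALSE)
  }
  rf
}

#' Default species templates per trophic level
#'
#' One [species_spectral_params()] per endmember species of each trophic
#' level ([peatland_endmember_species()]). Within each level, every species
#' gets slightly different plateau/edge parameters so the endmember matrix
#' is well-conditioned.
#'
#' @param trophic_level `"minerotrophic"` or `"ombrotrophic"`.
#' @return Named list of parameter sets.
#' @export
default_species_params <- function(trophic_level = c("minerotrophic",
                                                     "ombrotrophic")) {
  trophic_level <- match.arg(trophic_level)
  sp <- species_spectral_params
  litter <- sp("litter", vis_base = 0.10, green_peak_amp = 0,
               red_edge_inflection_nm = 660, red_edge_width_nm = 150,
               nir_plateau = 0.44, swir_slope = 0.10, moisture = 0.18,
               bumps = list(c(2050, 150, 0.020)))
  if (trophic_level == "minerotrophic") {
    list(
      "Comarum palustre" = sp("vascular", 0.045, 0.075, 712, 28, 0.46, 0.25, 0.55,
                              bumps = list(c(680, 40, -0.012), c(1680, 80, 0.015))),
      "Filipendula ulmaria" = sp("vascular", 0.050, 0.080, 718, 26, 0.52, 0.25, 0.50,
                                 bumps = list(c(620, 50, 0.010), c(2200, 100, 0.020))),
      "Litter" = litter,
      "Menyanthes trifoliata" = sp("vascular", 0.050, 0.070, 715, 30, 0.49, 0.22, 0.60,
                                   bumps = list(c(720, 30, 0.015), c(1600, 120, -0.015))),
      "Sphagnum angustifolium" = sp("moss", 0.045, 0.018, 705, 55, 0.36, 0.30, 0.85,
                                    bumps = list(c(640, 45, 0.012), c(2100, 150, 0.020))),
      "Sphagnum fallax" = sp("moss", 0.050, 0.020, 700, 60, 0.33, 0.30, 0.80,
                             bumps = list(c(600, 60, -0.010), c(1750, 90, 0.018)))
    )
  } else {
    list(
      "Calluna vulgaris" = sp("vascular", 0.060, 0.045, 710, 40, 0.42, 0.15, 0.35,
                              bumps = list(c(670, 50, -0.015), c(2250, 120, 0.020))),
      "Litter" = litter,
      "Rubus chamaemorus" = sp("vascular", 0.048, 0.075, 716, 27, 0.50, 0.25, 0.55,
                               bumps = list(c(710, 35, 0.012), c(1650, 100, -0.012))),
      "Sphagnum cuspidatum" = sp("moss", 0.042, 0.016, 700, 62, 0.30, 0.34, 0.95,
                                 bumps = list(c(610, 50, 0.015), c(1700, 120, 0.025))),
      "Sphagnum fuscum" = sp("moss", 0.058, 0.022, 710, 50, 0.40, 0.24, 0.55,
                             bumps = list(c(650, 70, 0.020), c(2150, 130, -0.020))),
      "Sphagnum rubellum" = sp("moss", 0.052, 0.018, 704, 56, 0.35, 0.30, 0.78,
                               bumps = list(c(660, 35, -0.018), c(1620, 90, 0.020)))
    )
  }
}

#' Synthetic study configuration
#'
#' Defaults define the standard simulated study: 60 plots per trophic
#' level, the six endmember species of each level, Dirichlet cover draws
#' whose concentrations mirror the relative mean covers of the twelve
#' endmember species (total concentration 3 for minerotrophic, 4 for the
#' more even ombrotrophic level), additive spectral noise of 0.002 RF,
#' 5% per-plot-per-species brightness variability, and a 100-point
#' point-intercept grid.
#'
#' @param seed Master integer seed; all stage seeds are derived from it.
#' @param n_plots Named vector: plots per trophic level.
#' @param species_params Named list of per-level species template lists.
#' @param dirichlet_alpha Named list of per-level Dirichlet concentration
#'   vectors (names = species).
#' @param noise_sd Additive spectral noise standard deviation (RF units).
#' @param brightness_cv Log-scale standard deviation of the per
#'   plot-species multiplicative brightness factor.
#' @param shade_fraction Fraction of the plot signal absorbed by an
#'   unmodelled dark component (scales every mixture down).
#' @param grid_points Point-intercept grid size.
#' @param endmember_replicates Replicate spectra measured per species.
#' @param endmember_noise_sd Additive noise on replicate endmember spectra.
#' @param zero_threshold_pct Cover draws below this are set to zero and the
#'   rest renormalized (creates realistic absent species).
#' @return List of class `"simulation_config"`.
#' @export
simulation_config <- function(seed = 1,
                              n_plots = c(minerotrophic = 60, ombrotrophic = 60),
                              species_params = list(
                                minerotrophic = default_species_params("minerotrophic"),
                                ombrotrophic = default_species_params("ombrotrophic")),
                              dirichlet_alpha = NULL,
                              noise_sd = 0.002, brightness_cv = 0.05,
                              shade_fraction = 0, grid_points = 100,
                              endmember_replicates = 3,
                              endmember_noise_sd = 0.002,
                              zero_threshold_pct = 0.5) {
  if (is.null(dirichlet_alpha)) {
    ## concentrations proportional to the relative abundance structure of
    ## the two levels; litter dominant, a couple of rare species per level
    dirichlet_alpha <- list(
      minerotrophic = c("Comarum palustre" = 0.09, "Filipendula ulmaria" = 0.14,
                        "Litter" = 1.38, "Menyanthes trifoliata" = 0.32,
                        "Sphagnum angustifolium" = 0.28, "Sphagnum fallax" = 0.79),
      ombrotrophic = c("Calluna vulgaris" = 0.83, "Litter" = 1.89,
                       "Rubus chamaemorus" = 0.05, "Sphagnum cuspidatum" = 0.14,
                       "Sphagnum fuscum" = 0.51, "Sphagnum rubellum" = 0.60)
    )
  }
  stopifnot(all(unlist(dirichlet_alpha) > 0), noise_sd >= 0,
            brightness_cv >= 0, shade_fraction >= 0, shade_fraction < 1,
            grid_points >= 1, seed == round(seed))
  for (lev in names(species_params)) {
    if (!setequal(names(species_params[[lev]]), names(dirichlet_alpha[[lev]]))) {
      stop("config error: species_params and dirichlet_alpha disagree for ",
           lev, call. = FALSE)
    }
  }
  structure(list(seed = as.integer(seed), n_plots = n_plots,
                 species_params = species_params,
                 dirichlet_alpha = dirichlet_alpha, noise_sd = noise_sd,
                 brightness_cv = brightness_cv, shade_fraction = shade_fraction,
                 grid_points = grid_points,
                 endmember_replicates = endmember_replicates,
                 endmember_noise_sd = endmember_noise_sd,
                 zero_threshold_pct = zero_threshold_pct),
            class = "simulation_config")
}

## stage-specific derived seeds, kept well below 2^31
stage_seed <- function(seed, stage) {
  offsets <- c(endmembers = 101L, communities = 211L, spectra = 307L,
               grid = 401L)
  (as.integer(seed) %% 1000000L) * 1000L + offsets[[stage]]
}

#' Generate a replicate endmember spectral library
#'
#' For each species, draws `n_replicates` spectra on the full 350-2500 nm
#' 1-nm grid: the species template with small multiplicative parameter
#' jitter per replicate plus additive instrument noise. Deterministic
#' given `seed`.
#'
#' @param params Named list of [species_spectral_params()].
#' @param seed Integer seed.
#' @param trophic_level Label stored in the metadata.
#' @param n_replicates Spectra per species.
#' @param noise_sd Additive noise sd (RF).
#' @return A `spectral_library` with `role = "endmember"`.
#' @export
gen_endmember_library <- function(params, seed = 1,
                                  trophic_level = NA_character_,
                                  n_replicates = 3, noise_sd = 0.002) {
  stopifnot(length(params) >= 1L, !is.null(names(params)))
  set.seed(seed)
  wl <- 350:2500
  cols <- list(); meta <- list()
  for (s in names(params)) {
    p <- params[[s]]
    for (r in seq_len(n_replicates)) {
      pj <- p
      pj$vis_base <- p$vis_base * exp(stats::rnorm(1, 0, 0.03))
      pj$nir_plateau <- max(pj$vis_base * 1.5,
                            p$nir_plateau * exp(stats::rnorm(1, 0, 0.03)))
      pj$green_peak_amp <- p$green_peak_amp * exp(stats::rnorm(1, 0, 0.05))
      rf <- synth_rf(pj, wl) + stats::rnorm(length(wl), 0, noise_sd)
      rf <- pmin(pmax(rf, 1e-6), 1 - 1e-6)
      id <- sprintf("%s_rep%d", gsub(" ", "_", s), r)
      cols[[id]] <- rf
      meta[[id]] <- data.frame(
        sample_id = id, role = "endmember", species = s,
        plot_id = NA_character_, trophic_level = trophic_level,
        quantity = switch(p$functional_type, vascular = "DHRF", "CCRF"),
        stringsAsFactors = FALSE)
    }
  }
  spectral_library(wl, do.call(cbind, cols), do.call(rbind, meta))
}

#' Generate plot communities from Dirichlet cover draws
#'
#' Per plot, covers are drawn Dirichlet(alpha) x 100; draws below
#' `zero_threshold_pct` are zeroed (the species is absent from the plot)
#' and the remainder renormalized to 100.
#'
#' @param cfg A [simulation_config()].
#' @param trophic_level Which level to generate.
#' @return Long-format community data frame (`plot_id`, `trophic_level`,
#'   `species`, `cover_pct`), positive covers only.
#' @export
gen_communities <- function(cfg, trophic_level = c("minerotrophic",
                                                   "ombrotrophic")) {
  trophic_level <- match.arg(trophic_level)
  alpha <- cfg$dirichlet_alpha[[trophic_level]]
  n <- cfg$n_plots[[trophic_level]]
  set.seed(stage_seed(cfg$seed, "communities") +
             ifelse(trophic_level == "minerotrophic", 0L, 1L))
  prefix <- if (trophic_level == "minerotrophic") "M" else "O"
  out <- lapply(seq_len(n), function(i) {
    g <- stats::rgamma(length(alpha), shape = alpha)
    cover <- 100 * g / sum(g)
    cover[cover < cfg$zero_threshold_pct] <- 0
    if (sum(cover) == 0) cover[which.max(g)] <- 100
    cover <- 100 * cover / sum(cover)
    keep <- cover > 0
    data.frame(plot_id = sprintf("%s%02d", prefix, i),
               trophic_level = trophic_level,
               species = names(alpha)[keep], cover_pct = cover[keep],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Generate mixed plot spectra from communities and endmembers
#'
#' The linear mixing model the unmixing analysis assumes:
#' \eqn{y(\lambda) = (1 - \mathrm{shade}) \sum_s (f_s / 100)\, b_{ps}\,
#' E_s(\lambda) + \varepsilon(\lambda)} with per plot-species brightness
#' factors \eqn{b_{ps} \sim \mathrm{LogNormal}(0, \mathrm{brightness\_cv})}
#' and iid Gaussian noise. Negative values are clamped at 0 and counted
#' (attribute `n_clamped`, with a warning).
#'
#' @param communities Long-format community table.
#' @param endmembers A `spectral_library` of replicate endmember spectra
#'   (species means are used as the mixing basis).
#' @param cfg A [simulation_config()].
#' @param seed Integer seed (default derived from `cfg$seed`).
#' @return A `spectral_library` of plot spectra (`role = "plot"`,
#'   `quantity = "HCRF"`) on the endmember grid.
#' @export
gen_plot_spectra <- function(communities, endmembers, cfg,
                             seed = stage_seed(cfg$seed, "spectra")) {
  em_mean <- average_species_spectra(endmembers)
  missing <- setdiff(unique(communities$species),
                     em_mean$metadata$species)
  if (length(missing) > 0L) {
    stop("missing endmember for species: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  set.seed(seed)
  wl <- em_mean$wavelength_nm
  plot_ids <- unique(communities$plot_id)
  n_clamped <- 0L
  cols <- vapply(plot_ids, function(pid) {
    d <- communities[communities$plot_id == pid, , drop = FALSE]
    b <- exp(stats::rnorm(nrow(d), 0, cfg$brightness_cv))
    E <- em_mean$rf[, match(d$species, em_mean$metadata$species), drop = FALSE]
    y <- drop(E %*% (d$cover_pct / 100 * b)) * (1 - cfg$shade_fraction) +
      stats::rnorm(length(wl), 0, cfg$noise_sd)
    n_clamped <<- n_clamped + sum(y < 0)
    pmax(y, 0)
  }, numeric(length(wl)))
  if (n_clamped > 0L) {
    warning(n_clamped, " negative simulated rf value(s) clamped at 0",
            call. = FALSE)
  }
  colnames(cols) <- plot_ids
  level <- communities$trophic_level[match(plot_ids, communities$plot_id)]
  meta <- data.frame(sample_id = plot_ids, role = "plot",
                     species = NA_character_, plot_id = plot_ids,
                     trophic_level = level, quantity = "HCRF",
                     stringsAsFactors = FALSE)
  out <- spectral_library(wl, cols, meta)
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Generate a point-intercept grid observation for one plot
#'
#' Labels are drawn iid from the plot's cover distribution, one per grid
#' cell, emulating a field observer recording the species at each cell
#' centre.
#'
#' @param community Community rows for a single plot.
#' @param grid_points Number of grid cells (default 100).
#' @param seed Integer seed.
#' @return Character vector of `grid_points` species labels.
#' @export
gen_grid_observation <- function(community, grid_points = 100, seed = 1) {
  stopifnot(length(unique(community$plot_id)) == 1L, nrow(community) >= 1L)
  set.seed(seed)
  sample(community$species, grid_points, replace = TRUE,
         prob = community$cover_pct / sum(community$cover_pct))
}

#' Generate a complete synthetic study
#'
#' Produces, for each trophic level: a replicate endmember library on the
#' full 350-2500 nm grid, plot communities, mixed plot spectra, grid
#' observations and true diversity records — everything the pipeline
#' consumes, fully determined by `cfg$seed`.
#'
#' @param cfg A [simulation_config()].
#' @return List of class `"synthetic_study"` with one entry per trophic
#'   level (`endmembers`, `plots`, `communities`, `grid_observations`,
#'   `diversity`) plus `config`.
#' @export
gen_study <- function(cfg = simulation_config()) {
  levels <- names(cfg$n_plots)
  out <- stats::setNames(lapply(seq_along(levels), function(i) {
    lev <- levels[i]
    em <- gen_endmember_library(cfg$species_params[[lev]],
                                seed = stage_seed(cfg$seed, "endmembers") + i,
                                trophic_level = lev,
                                n_replicates = cfg$endmember_replicates,
                                noise_sd = cfg$endmember_noise_sd)
    comm <- gen_communities(cfg, lev)
    plots <- gen_plot_spectra(comm, em, cfg,
                              seed = stage_seed(cfg$seed, "spectra") + i)
    plot_ids <- unique(comm$plot_id)
    grid_obs <- stats::setNames(lapply(seq_along(plot_ids), function(j) {
      gen_grid_observation(comm[comm$plot_id == plot_ids[j], , drop = FALSE],
                           grid_points = cfg$grid_points,
                           seed = stage_seed(cfg$seed, "grid") + i * 1000L + j)
    }), plot_ids)
    list(endmembers = em, plots = plots, communities = comm,
         grid_observations = grid_obs,
         diversity = diversity_indices(comm))
  }), levels)
  structure(c(out, list(config = cfg)), class = "synthetic_study")
}

#' Write the small committed synthetic fixture
#'
#' A 12-plot (6 + 6), fully seeded miniature study used by the test suite:
#' communities, true diversity, and the harmonized plot spectra resampled
#' to the ten synthetic bands (the full-grid objects are regenerated in
#' code rather than stored). Regenerating with the recorded seed
#' reproduces the files byte for byte.
#'
#' @param dir Output directory.
#' @param seed Integer seed (the committed copy uses 42).
#' @return Invisibly, the paths written.
#' @export
write_study_fixture <- function(dir, seed = 42) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- simulation_config(seed = seed,
                           n_plots = c(minerotrophic = 6, ombrotrophic = 6))
  study <- gen_study(cfg)
  comm <- rbind(study$minerotrophic$communities, study$ombrotrophic$communities)
  div <- rbind(study$minerotrophic$diversity, study$ombrotrophic$diversity)
  plots <- align_to_common_grid(list(harmonize(study$minerotrophic$plots),
                                     harmonize(study$ombrotrophic$plots)))
  bands <- resample_to_bands(plots, gaussian_band_set())

  paths <- file.path(dir, c("synthetic_study_communities.csv",
                            "synthetic_study_diversity.csv",
                            "synthetic_study_plot_bands.csv",
                            "synthetic_study_plot_bands_metadata.csv"))
  utils::write.csv(comm, paths[1], row.names = FALSE)
  utils::write.csv(div, paths[2], row.names = FALSE)
  write_spectral_library(bands, paths[3], paths[4])
  invisible(paths)
}
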