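test_that("endmember generation is deterministic and encodes the functional-type contrasts", {
  params <- default_species_params("minerotrophic")
  lib1 <- gen_endmember_library(params, seed = 3)
  lib2 <- gen_endmember_library(params, seed = 3)
  expect_identical(lib1$rf, lib2$rf)
  expect_identical(lib1$wavelength_nm, as.numeric(350:2500))
  expect_true(all(lib1$rf > 0 & lib1$rf < 1))

  # vascular mean rf in the green (530-570 nm) strictly above moss
  avg <- average_species_spectra(lib1)
  green <- avg$wavelength_nm >= 530 & avg$wavelength_nm <= 570
  type_of <- vapply(avg$metadata$species, function(s) params[[s]]$functional_type,
                    character(1))
  green_mean <- colMeans(avg$rf[green, , drop = FALSE])
  expect_gt(min(green_mean[type_of == "vascular"]),
            max(green_mean[type_of == "moss"]))

  # litter template monotone through VIS-NIR: rf(700) > rf(550) > rf(450)
  litter <- synth_rf(params$Litter, 350:2500)
  wl <- 350:2500
  expect_gt(litter[wl == 700], litter[wl == 550])
  expect_gt(litter[wl == 550], litter[wl == 450])

  # template parameters outside the valid range error
  bad <- species_spectral_params("vascular", vis_base = 0.9,
                                 green_peak_amp = 0.2, nir_plateau = 0.95,
                                 swir_slope = 0, moisture = 0)
  expect_error(synth_rf(bad), "generation error")
})

test_that("generated communities satisfy the cover invariants and respond to concentration", {
  cfg <- simulation_config(seed = 23)
  comm <- gen_communities(cfg, "minerotrophic")
  sums <- tapply(comm$cover_pct, comm$plot_id, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  expect_true(all(comm$cover_pct > 0))
  expect_equal(length(unique(comm$plot_id)), 60)

  # concentrated Dirichlet -> near-uniform covers, Shannon near ln 6
  alpha_hi <- list(
    minerotrophic = setNames(rep(100, 6),
                             peatland_endmember_species("minerotrophic")),
    ombrotrophic = setNames(rep(100, 6),
                            peatland_endmember_species("ombrotrophic")))
  cfg_hi <- simulation_config(seed = 23, dirichlet_alpha = alpha_hi)
  div_hi <- diversity_indices(gen_communities(cfg_hi, "minerotrophic"))
  expect_gt(mean(div_hi$shannon), log(6) - 0.05)

  # sparse Dirichlet -> mean richness well below the species pool
  alpha_lo <- lapply(alpha_hi, function(a) a * 0 + 0.3)
  cfg_lo <- simulation_config(seed = 23, dirichlet_alpha = alpha_lo)
  div_lo <- diversity_indices(gen_communities(cfg_lo, "minerotrophic"))
  expect_lt(mean(div_lo$richness), 6)
  expect_lt(mean(div_lo$richness), mean(div_hi$richness))
})

test_that("plot spectra are exact mixtures at zero noise and unbiased under noise", {
  cfg0 <- simulation_config(seed = 29, noise_sd = 0, brightness_cv = 0,
                            n_plots = c(minerotrophic = 8, ombrotrophic = 2))
  st0 <- gen_study(cfg0)
  lev <- st0$minerotrophic
  em_mean <- average_species_spectra(lev$endmembers)
  comm <- lev$communities
  # noiseless spectra equal the exact linear mixture
  for (pid in unique(comm$plot_id)[1:4]) {
    d <- comm[comm$plot_id == pid, ]
    E <- em_mean$rf[, match(d$species, em_mean$metadata$species), drop = FALSE]
    expect_equal(unname(lev$plots$rf[, pid]),
                 unname(drop(E %*% (d$cover_pct / 100))), tolerance = 1e-12)
  }
  # and unmixing recovers the covers exactly
  ph <- harmonize(lev$plots)
  eh <- harmonize(lev$endmembers, average_species = TRUE)
  ems <- endmember_set(eh, species = sort(unique(comm$species)))
  res <- unmix(ph, ems, comm)
  expect_lt(max(abs(res$pairs$cover_pred_pct - res$pairs$cover_obs_pct)), 1e-6)

  # single-species plot without noise equals its endmember
  one <- data.frame(plot_id = "solo", trophic_level = "minerotrophic",
                    species = "Litter", cover_pct = 100)
  solo <- gen_plot_spectra(one, lev$endmembers, cfg0)
  expect_equal(unname(solo$rf[, 1]),
               unname(em_mean$rf[, match("Litter", em_mean$metadata$species)]),
               tolerance = 1e-12)

  # ensemble mean over noisy replicates within 3 SE of the exact mixture
  cfg_n <- simulation_config(seed = 31, noise_sd = 0.004, brightness_cv = 0)
  n_rep <- 400
  reps <- vapply(seq_len(n_rep), function(i) {
    gen_plot_spectra(one, lev$endmembers, cfg_n, seed = 40000 + i)$rf[, 1]
  }, numeric(length(lev$plots$wavelength_nm)))
  truth <- em_mean$rf[, match("Litter", em_mean$metadata$species)]
  se <- 0.004 / sqrt(n_rep)
  expect_true(all(abs(rowMeans(reps) - truth) <= 4 * se))
})

test_that("grid observations follow the cover distribution", {
  one_sp <- data.frame(plot_id = "p", trophic_level = "omb",
                       species = "Litter", cover_pct = 100)
  expect_equal(gen_grid_observation(one_sp, 100, seed = 1),
               rep("Litter", 100))

  two <- data.frame(plot_id = "p", trophic_level = "omb",
                    species = c("A", "B"), cover_pct = c(50, 50))
  counts <- vapply(1:2000, function(s) {
    sum(gen_grid_observation(two, 100, seed = s) == "A")
  }, numeric(1))
  # Binomial(100, 0.5) moments
  expect_equal(mean(counts), 50, tolerance = 0.5)
  expect_equal(sd(counts), 5, tolerance = 0.5)
})

test_that("a full study is deterministic, passes its invariants, and runs end to end", {
  cfg <- simulation_config(seed = 37,
                           n_plots = c(minerotrophic = 12, ombrotrophic = 12))
  st1 <- gen_study(cfg)
  st2 <- gen_study(cfg)
  expect_identical(st1$minerotrophic$plots$rf, st2$minerotrophic$plots$rf)
  expect_identical(st1$ombrotrophic$communities, st2$ombrotrophic$communities)
  expect_identical(st1$minerotrophic$grid_observations,
                   st2$minerotrophic$grid_observations)

  for (lev in c("minerotrophic", "ombrotrophic")) {
    s <- st1[[lev]]
    expect_true(all(s$plots$rf >= 0))
    sums <- tapply(s$communities$cover_pct, s$communities$plot_id, sum)
    expect_true(all(abs(sums - 100) < 1e-9))
    expect_true(all(lengths(s$grid_observations) == cfg$grid_points))
    # smoke: harmonize -> unmix -> diversity -> PLS without error
    ph <- harmonize(s$plots)
    eh <- harmonize(s$endmembers, average_species = TRUE)
    ems <- endmember_set(eh, species = select_endmembers(s$communities),
                         trophic_level = lev)
    res <- unmix(ph, ems, s$communities)
    expect_gt(sum(!res$pairs$dropped), 0)
    div <- diversity_indices(s$communities)
    expect_true(all(div$shannon >= 0 & div$simpson >= 0 & div$simpson < 1))
    X <- t(ph$rf)
    ev <- evaluate_diversity_model(X, div$shannon[match(rownames(X), div$plot_id)],
                                   seed = 37)
    expect_true(is.finite(ev$metrics$r2))
  }
})

test_that("the committed fixture regenerates byte-identically from its seed", {
  dir <- tempfile("fixture_")
  paths <- write_study_fixture(dir, seed = 42)
  for (p in paths) {
    committed <- system.file("extdata", basename(p), package = "peatspec")
    expect_true(nzchar(committed))
    expect_identical(readLines(p), readLines(committed))
  }
})

test_that("increasing noise monotonically degrades unmixing accuracy", {
  med_r2 <- vapply(c(0.002, 0.02, 0.06), function(ns) {
    cfg <- simulation_config(seed = 43, noise_sd = ns,
                             n_plots = c(minerotrophic = 30, ombrotrophic = 2))
    st <- suppressWarnings(gen_study(cfg))  # high noise clamps some rf at 0
    lev <- st$minerotrophic
    ph <- suppressWarnings(harmonize(lev$plots))
    eh <- harmonize(lev$endmembers, average_species = TRUE)
    ems <- endmember_set(eh, species = select_endmembers(lev$communities))
    met <- unmix_metrics(unmix(ph, ems, lev$communities))
    median(met$r2, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(med_r2) < 0))
})
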