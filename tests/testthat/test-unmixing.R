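test_that("endmember selection applies the AND exclusion rule", {
  mk <- function(species, plots, covers) {
    data.frame(plot_id = plots, trophic_level = "minerotrophic",
               species = species, cover_pct = covers)
  }
  comm <- rbind(
    mk("rare_sparse", paste0("p", 1:4), c(3, 2, 1, 3)),     # 4 plots, max 3%
    mk("common_sparse", paste0("p", 1:6), rep(2, 6)),       # 6 plots, max 2%
    mk("rare_dense", paste0("p", 1:2), c(40, 10)),          # 2 plots, max 40%
    mk("Litter", paste0("p", 1:10), rep(30, 10)))
  sel <- select_endmembers(comm)
  expect_false("rare_sparse" %in% sel)       # fails both clauses -> excluded
  expect_true("common_sparse" %in% sel)      # fails only the cover clause
  expect_true("rare_dense" %in% sel)         # fails only the occupancy clause
  expect_true("Litter" %in% sel)

  # mean-cover variant is stricter here: rare_dense mean = 25 still kept,
  # but a species with one big and many tiny covers can flip
  flip <- rbind(comm, mk("flip", paste0("p", 1:3), c(12, 1, 1)))
  expect_true("flip" %in% select_endmembers(flip, cover_stat = "max"))
  expect_false("flip" %in% select_endmembers(flip, cover_stat = "mean"))

  expect_error(select_endmembers(comm[0, ]), "no communities")

  # canonical endmember lists hold six species per level
  sets <- peatland_endmember_species()
  expect_equal(lengths(sets), c(minerotrophic = 6L, ombrotrophic = 6L))
  expect_true(all(vapply(sets, function(s) "Litter" %in% s, logical(1))))
})

test_that("NNLS solves exact mixtures, truncates at zero, and matches oracles", {
  fix <- exact_mixture_fixture(seed = 2)
  # exact nonnegative combination recovered
  y <- drop(fix$E %*% c(0.3, 0.7, 0))
  sol <- nnls_solve(fix$E, y)
  expect_equal(unname(sol$coef), c(0.3, 0.7, 0), tolerance = 1e-8)

  # coordinate-wise truncation at the bound
  E <- cbind(c(1, 0), c(0, 1))
  sol2 <- nnls_solve(E, c(1, -0.5))
  expect_equal(unname(sol2$coef), c(1, 0), tolerance = 1e-12)

  # random 5-endmember problems vs exhaustive active-set enumeration and
  # an independent library implementation
  set.seed(123)
  for (i in 1:25) {
    E5 <- matrix(runif(50 * 5, 0, 1), 50, 5)
    y5 <- runif(50, -0.2, 1)
    got <- nnls_solve(E5, y5)
    obj <- sum((y5 - E5 %*% got$coef)^2)
    oracle <- nnls_enumerate(E5, y5)
    expect_lte(obj, oracle$objective + 1e-6)
    expect_equal(obj, oracle$objective, tolerance = 1e-6)
    ref <- pracma::lsqnonneg(E5, y5)
    expect_equal(unname(got$coef), unname(ref$x), tolerance = 1e-6)

    # KKT conditions: zero gradient on the support, nonnegative elsewhere
    grad <- drop(crossprod(E5, E5 %*% got$coef - y5))
    expect_true(all(abs(grad[got$coef > 1e-8]) <= 1e-6))
    expect_true(all(grad[got$coef <= 1e-8] >= -1e-6))

    # optimal objective beats random feasible points
    for (j in 1:5) {
      a_rand <- runif(5, 0, 2)
      expect_lte(obj, sum((y5 - E5 %*% a_rand)^2) + 1e-12)
    }
  }

  # scale equivariance
  got1 <- nnls_solve(fix$E, fix$Y[, 1])
  got3 <- nnls_solve(fix$E, 3 * fix$Y[, 1])
  expect_equal(unname(got3$coef), 3 * unname(got1$coef), tolerance = 1e-8)

  expect_error(nnls_solve(fix$E, numeric(0)), "zero-length")
  expect_error(nnls_solve(fix$E, fix$Y[1:10, 1]), "grid error")
})

test_that("normalization and zero-removal follow the observed-zero rule", {
  raw <- data.frame(plot_id = rep(c("p1", "p2"), each = 3),
                    species = rep(c("A", "B", "C"), 2),
                    a_raw = c(0.2, 0.3, 0.5, 0, 0, 0),
                    residual_norm = rep(c(0.01, 0.02), each = 3))
  comm <- data.frame(plot_id = c("p1", "p1"), trophic_level = "x",
                     species = c("B", "C"), cover_pct = c(40, 60))
  res <- normalize_and_filter(raw, comm)
  p1 <- res$pairs[res$pairs$plot_id == "p1", ]
  expect_equal(p1$a_norm, c(0.2, 0.3, 0.5))
  expect_equal(sum(p1$a_norm), 1)
  # species A observed 0 -> dropped; evaluation pairs are (40, 30), (60, 50)
  expect_true(p1$dropped[p1$species == "A"])
  kept <- p1[!p1$dropped, ]
  expect_equal(kept$cover_obs_pct, c(40, 60))
  expect_equal(kept$cover_pred_pct, c(30, 50))
  # all-zero coefficients: plot flagged degenerate and fully dropped
  expect_true(res$plots$degenerate[res$plots$plot_id == "p2"])
  expect_true(all(res$pairs$dropped[res$pairs$plot_id == "p2"]))

  # simple normalization case
  raw2 <- data.frame(plot_id = "q", species = c("A", "B"), a_raw = c(2, 2))
  res2 <- normalize_and_filter(raw2, data.frame(plot_id = "q",
                                                species = c("A", "B"),
                                                cover_pct = c(50, 50)))
  expect_equal(res2$pairs$a_norm, c(0.5, 0.5))

  # predicted-zero variant drops on the prediction side instead
  res3 <- normalize_and_filter(raw, comm, drop_on = "predicted")
  expect_false(res3$pairs$dropped[res3$pairs$plot_id == "p1" &
                                    res3$pairs$species == "A"])
})

test_that("noiseless exact mixtures are recovered exactly through the full unmix path", {
  fix <- exact_mixture_fixture(seed = 5, n_plots = 10, noise_sd = 0)
  ids <- sprintf("p%02d", seq_len(nrow(fix$covers)))
  colnames(fix$Y) <- ids
  plots <- spectral_library(fix$wl, fix$Y, data.frame(
    sample_id = ids, role = "plot", plot_id = ids,
    trophic_level = "minerotrophic", quantity = "HCRF"))
  em_lib <- spectral_library(fix$wl, fix$E, data.frame(
    sample_id = colnames(fix$E), role = "endmember",
    species = colnames(fix$E), quantity = "DHRF"))
  ems <- endmember_set(em_lib, trophic_level = "minerotrophic")
  comm <- do.call(rbind, lapply(seq_along(ids), function(i) {
    data.frame(plot_id = ids[i], trophic_level = "minerotrophic",
               species = colnames(fix$E), cover_pct = fix$covers[i, ])
  }))
  res <- unmix(plots, ems, comm)
  ev <- res$pairs
  expect_lt(max(abs(ev$cover_pred_pct - ev$cover_obs_pct)), 1e-6)

  # scale equivariance of normalized abundances: brightening a plot
  # changes a_raw but not a_norm
  bright <- plots; bright$rf <- 2 * plots$rf
  res2 <- unmix(bright, ems, comm)
  expect_equal(res2$pairs$a_raw, 2 * res$pairs$a_raw, tolerance = 1e-7)
  expect_equal(res2$pairs$a_norm, res$pairs$a_norm, tolerance = 1e-8)

  # grid mismatch caught
  shifted <- em_lib; shifted$wavelength_nm <- em_lib$wavelength_nm + 1
  expect_error(unmix(plots, endmember_set(shifted), comm), "grid error")
})

test_that("unmixing under noise keeps cover errors small; 10-band input does no better than hyperspectral", {
  # simulated study at the default noise settings, one trophic level
  cfg <- simulation_config(seed = 11,
                           n_plots = c(minerotrophic = 50, ombrotrophic = 2))
  st <- gen_study(cfg)
  lev <- st$minerotrophic
  plots_h <- harmonize(lev$plots)
  em_h <- harmonize(lev$endmembers, average_species = TRUE)
  ems <- endmember_set(em_h, species = select_endmembers(lev$communities),
                       trophic_level = "minerotrophic")
  res_hs <- unmix(plots_h, ems, lev$communities)
  ev <- res_hs$pairs[!res_hs$pairs$dropped, ]
  med_err_hs <- median(abs(ev$cover_pred_pct - ev$cover_obs_pct))
  expect_lt(med_err_hs, 5)  # percentage points

  bs <- gaussian_band_set()
  ems_ms <- endmember_set(resample_to_bands(em_h, bs), species = ems$species,
                          trophic_level = "minerotrophic")
  res_ms <- unmix(resample_to_bands(plots_h, bs), ems_ms, lev$communities)
  ev_ms <- res_ms$pairs[!res_ms$pairs$dropped, ]
  med_err_ms <- median(abs(ev_ms$cover_pred_pct - ev_ms$cover_obs_pct))
  expect_gte(med_err_ms, med_err_hs)
})
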