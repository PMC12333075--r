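#' Prediction accuracy metrics
#'
#' The three metrics used throughout the pipeline, with the standard
#' definitions: `r2 = 1 - SSres/SStot` (can be negative for a model worse
#' than the observed mean), `rmse = sqrt(mean((o - p)^2))` and
#' `bias = mean(p - o)` (positive bias means over-prediction).
#'
#' @param observed Numeric vector of observed values.
#' @param predicted Numeric vector of predictions, same length.
#' @return One-row data frame with `n`, `r2`, `rmse`, `bias`. If the
#'   observed values have zero variance, `r2` is `NA` with a warning
#'   (rmse and bias are still returned).
#' @export
fit_metrics <- function(observed, predicted) {
  observed <- as.numeric(observed)
  predicted <- as.numeric(predicted)
  n <- length(observed)
  if (n == 0L || n != length(predicted)) {
    stop("observed and predicted must be equal, nonzero length", call. = FALSE)
  }
  err <- observed - predicted
  sstot <- sum((observed - mean(observed))^2)
  r2 <- if (sstot > 0) 1 - sum(err^2) / sstot else {
    warning("zero variance in observed values: r2 undefined", call. = FALSE)
    NA_real_
  }
  data.frame(n = n, r2 = r2, rmse = sqrt(mean(err^2)), bias = mean(-err))
}

#' Per-wavelength R-squared profile for one species
#'
#' At each retained wavelength, the reflectance factor across plots is
#' regressed on the species' fractional cover by simple linear regression;
#' the profile reports the squared Pearson correlation (hence in [0, 1])
#' per wavelength, and its maximum with the wavelength where it occurs.
#'
#' @param plots A `spectral_library` of plot spectra.
#' @param communities Long-format community table covering the plots.
#' @param species Species name.
#' @param plots_subset `"all"` (default): use every plot, with cover 0
#'   where the species is absent; `"occupied"`: only plots where the
#'   species occurs.
#' @return List of class `"wavelength_r2_profile"`: `species`, `profile`
#'   (data frame `wavelength_nm`, `r2`), `best_r2`, `best_wavelength_nm`,
#'   `n_plots`.
#' @export
wavelength_r2_profile <- function(plots, communities, species,
                                  plots_subset = c("all", "occupied")) {
  plots_subset <- match.arg(plots_subset)
  stopifnot(inherits(plots, "spectral_library"))
  meta <- plots$metadata
  is_plot <- if ("role" %in% names(meta)) {
    !is.na(meta$role) & meta$role == "plot"
  } else rep(TRUE, nrow(meta))
  ids <- meta$sample_id[is_plot]
  plot_ids <- if ("plot_id" %in% names(meta)) {
    ifelse(is.na(meta$plot_id[is_plot]), ids, meta$plot_id[is_plot])
  } else ids

  sp <- communities[communities$species == species, , drop = FALSE]
  cover <- sp$cover_pct[match(plot_ids, sp$plot_id)]
  cover[is.na(cover)] <- 0

  keep <- if (plots_subset == "occupied") cover > 0 else rep(TRUE, length(cover))
  if (sum(keep) < 3L) {
    stop("need at least 3 plots for a regression profile", call. = FALSE)
  }
  cover <- cover[keep]
  if (stats::sd(cover) == 0) {
    stop("zero-variance cover for species '", species, "'", call. = FALSE)
  }

  rf <- plots$rf[, ids[keep], drop = FALSE]
  ## squared Pearson correlation of rf(lambda) with cover, vectorized over rows
  cc <- as.numeric(stats::cor(t(rf), cover))
  r2 <- cc^2
  r2[is.na(r2)] <- 0  # constant rf at a wavelength: no explainable variance

  best <- which.max(r2)
  structure(list(species = species,
                 profile = data.frame(wavelength_nm = plots$wavelength_nm, r2 = r2),
                 best_r2 = r2[best],
                 best_wavelength_nm = plots$wavelength_nm[best],
                 n_plots = sum(keep)),
            class = "wavelength_r2_profile")
}

#' @export
print.wavelength_r2_profile <- function(x, ...) {
  cat(sprintf("<wavelength_r2_profile> %s: best r2 = %.3f at %g nm (%d plots)\n",
              x$species, x$best_r2, x$best_wavelength_nm, x$n_plots))
  invisible(x)
}
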