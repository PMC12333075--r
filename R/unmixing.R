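#' Canonical endmember species per trophic level
#'
#' The six endmember species used by each trophic-level unmixing model:
#' the dominant vascular plants and Sphagnum mosses of each level, plus
#' litter (dead Carex), which occurs at both levels.
#'
#' @param trophic_level `"minerotrophic"`, `"ombrotrophic"`, or `"both"`.
#' @return Character vector of species names (or a named list for
#'   `"both"`).
#' @export
peatland_endmember_species <- function(trophic_level = c("both", "minerotrophic",
                                                         "ombrotrophic")) {
  trophic_level <- match.arg(trophic_level)
  sets <- list(
    minerotrophic = c("Comarum palustre", "Filipendula ulmaria", "Litter",
                      "Menyanthes trifoliata", "Sphagnum angustifolium",
                      "Sphagnum fallax"),
    ombrotrophic = c("Calluna vulgaris", "Litter", "Rubus chamaemorus",
                     "Sphagnum cuspidatum", "Sphagnum fuscum",
                     "Sphagnum rubellum")
  )
  if (trophic_level == "both") sets else sets[[trophic_level]]
}

#' Select endmember species by abundance in the plots
#'
#' A species is excluded only when it is both rare and sparse: present in
#' fewer than `min_plots` plots AND with cover below `min_cover_pct` in
#' every plot where it occurs. Litter counts as a species. Species failing
#' only one clause are retained.
#'
#' @param communities Long-format community table for one trophic level
#'   (`plot_id`, `species`, `cover_pct`).
#' @param min_plots Occupancy threshold (default 5 plots).
#' @param min_cover_pct Cover threshold in percent (default 5).
#' @param cover_stat How "coverage in these plots" is summarized over the
#'   occupied plots: `"max"` (default, inclusion-favouring) or `"mean"`.
#' @return Character vector of retained species, sorted.
#' @export
select_endmembers <- function(communities, min_plots = 5, min_cover_pct = 5,
                              cover_stat = c("max", "mean")) {
  cover_stat <- match.arg(cover_stat)
  if (is.null(communities) || nrow(communities) == 0L) {
    stop("no communities supplied", call. = FALSE)
  }
  stat_fun <- if (cover_stat == "max") max else mean
  occ <- communities[communities$cover_pct > 0, , drop = FALSE]
  keep <- vapply(split(occ, occ$species), function(d) {
    n_plots <- length(unique(d$plot_id))
    n_plots >= min_plots || stat_fun(d$cover_pct) >= min_cover_pct
  }, logical(1))
  sort(names(keep)[keep])
}

#' Build an endmember set from a spectral library
#'
#' Extracts the endmember spectra of the given species into the
#' wavelength-by-species matrix `E` used as the NNLS design matrix.
#'
#' @param lib A harmonized `spectral_library` containing one spectrum per
#'   species (see [average_species_spectra()]).
#' @param species Species to include, in column order. Default: all
#'   endmember species in `lib`.
#' @param trophic_level Optional label carried on the set.
#' @return An object of class `"endmember_set"`: list with `species`,
#'   `wavelength_nm`, `E` (matrix, one column per species) and
#'   `trophic_level`.
#' @export
endmember_set <- function(lib, species = NULL, trophic_level = NA_character_) {
  stopifnot(inherits(lib, "spectral_library"))
  meta <- lib$metadata
  em <- meta[!is.na(meta$role) & meta$role == "endmember", , drop = FALSE]
  if (is.null(species)) species <- em$species
  ids <- em$sample_id[match(species, em$species)]
  if (anyNA(ids)) {
    stop("missing endmember spectrum for species: ",
         paste(species[is.na(ids)], collapse = ", "), call. = FALSE)
  }
  E <- lib$rf[, ids, drop = FALSE]
  colnames(E) <- species
  if (any(colSums(abs(E)) == 0)) {
    stop("endmember with all-zero spectrum", call. = FALSE)
  }
  structure(list(species = species, wavelength_nm = lib$wavelength_nm,
                 E = E, trophic_level = trophic_level),
            class = "endmember_set")
}

#' @export
print.endmember_set <- function(x, ...) {
  cat(sprintf("<endmember_set> %s: %d species x %d wavelengths\n",
              x$trophic_level, length(x$species), nrow(x$E)))
  invisible(x)
}

#' Non-negative least squares (Lawson-Hanson active set)
#'
#' Solves \eqn{\min_{a \ge 0} \|E a - y\|_2} by the Lawson-Hanson
#' active-set algorithm. No intercept and no sum-to-one constraint: the
#' abundance normalization used in unmixing is applied afterwards (see
#' [normalize_and_filter()]).
#'
#' @param E Numeric design matrix (wavelengths x endmembers).
#' @param y Numeric response vector (the plot spectrum).
#' @param sum_to_one Add the sum-to-one abundance constraint inside the
#'   solver (fully constrained least squares, implemented as a heavily
#'   weighted pseudo-observation). Off by default.
#' @param tol Dual-feasibility tolerance; default scales with the problem.
#' @return List with `coef` (nonnegative vector, one per column of `E`),
#'   `fitted`, `residual` and `residual_norm`.
#' @export
nnls_solve <- function(E, y, sum_to_one = FALSE, tol = NULL) {
  E <- as.matrix(E)
  y <- as.numeric(y)
  if (length(y) == 0L) stop("zero-length spectrum", call. = FALSE)
  if (nrow(E) != length(y)) stop("grid error: nrow(E) != length(y)", call. = FALSE)
  E0 <- E; y0 <- y
  if (sum_to_one) {
    lam <- 1e4 * max(1, max(abs(E)))
    E <- rbind(E, rep(lam, ncol(E)))
    y <- c(y, lam)
  }
  n <- ncol(E)
  if (is.null(tol)) tol <- 1e-10 * max(1, max(abs(crossprod(E, y))))

  x <- numeric(n)
  passive <- logical(n)
  w <- drop(crossprod(E, y))
  outer_iter <- 0L
  while (any(!passive) && max(w[!passive]) > tol) {
    outer_iter <- outer_iter + 1L
    if (outer_iter > 30L * n) break  # safeguard; KKT checked by callers/tests
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      z <- numeric(n)
      fit <- qr(E[, passive, drop = FALSE])
      zp <- qr.coef(fit, y)
      zp[is.na(zp)] <- 0  # rank deficiency within the passive set
      z[passive] <- zp
      if (all(z[passive] > 0)) {
        x <- z
        break
      }
      hit <- passive & z <= 0
      alpha <- min(x[hit] / (x[hit] - z[hit]))
      x <- x + alpha * (z - x)
      passive <- passive & x > tol
      x[!passive] <- 0
      if (!any(passive)) break
    }
    w <- drop(crossprod(E, y - E %*% x))
  }

  fitted <- drop(E0 %*% x)
  res <- y0 - fitted
  list(coef = stats::setNames(x, colnames(E0)), fitted = fitted,
       residual = res, residual_norm = sqrt(sum(res^2)))
}

#' Normalize raw abundances and drop absent-species pairs
#'
#' Raw NNLS coefficients are normalized to sum to one per plot (plots whose
#' coefficients are all zero are flagged and excluded from evaluation).
#' Then (plot, species) pairs whose *observed* cover is zero are flagged as
#' dropped from the evaluation set; their predicted values are retained in
#' the table for inspection. Dropping predicted zeros instead is available
#' via `drop_on = "predicted"`.
#'
#' @param raw Data frame with columns `plot_id`, `species`, `a_raw`
#'   (nonnegative NNLS coefficients) and per-plot `residual_norm`.
#' @param communities Long-format observed community table.
#' @param drop_on `"observed"` (default) or `"predicted"`: which zeros
#'   define removal from the evaluation set.
#' @return An object of class `"unmix_result"`: list with `pairs` (data
#'   frame: `plot_id`, `species`, `a_raw`, `a_norm`, `cover_pred_pct`,
#'   `cover_obs_pct`, `dropped`), `plots` (data frame: `plot_id`,
#'   `residual_norm`, `degenerate`), and `drop_on`.
#' @export
normalize_and_filter <- function(raw, communities,
                                 drop_on = c("observed", "predicted")) {
  drop_on <- match.arg(drop_on)
  stopifnot(all(c("plot_id", "species", "a_raw") %in% names(raw)))

  parts <- lapply(split(raw, raw$plot_id), function(d) {
    tot <- sum(d$a_raw)
    d$a_norm <- if (tot > 0) d$a_raw / tot else NA_real_
    d
  })
  pairs <- do.call(rbind, parts)
  rownames(pairs) <- NULL
  pairs$cover_pred_pct <- 100 * pairs$a_norm

  obs_key <- paste(communities$plot_id, communities$species, sep = "\r")
  m <- match(paste(pairs$plot_id, pairs$species, sep = "\r"), obs_key)
  pairs$cover_obs_pct <- ifelse(is.na(m), 0, communities$cover_pct[m])

  plot_tot <- tapply(raw$a_raw, raw$plot_id, sum)
  plots <- data.frame(plot_id = names(plot_tot),
                      degenerate = as.numeric(plot_tot) <= 0,
                      stringsAsFactors = FALSE)
  if ("residual_norm" %in% names(raw)) {
    plots$residual_norm <- raw$residual_norm[match(plots$plot_id, raw$plot_id)]
  }

  zero <- if (drop_on == "observed") pairs$cover_obs_pct == 0 else
    pairs$cover_pred_pct == 0
  pairs$dropped <- zero | plots$degenerate[match(pairs$plot_id, plots$plot_id)]

  structure(list(pairs = pairs, plots = plots, drop_on = drop_on),
            class = "unmix_result")
}

#' @export
print.unmix_result <- function(x, ...) {
  cat(sprintf("<unmix_result> %d plots, %d (plot, species) pairs (%d in evaluation set)\n",
              nrow(x$plots), nrow(x$pairs), sum(!x$pairs$dropped)))
  invisible(x)
}

#' Unmix the plots of one trophic level
#'
#' Fits the NNLS mixture model plot by plot (plot spectrum as response,
#' endmember spectra as predictors), then normalizes the coefficients and
#' applies zero-removal. Works identically on hyperspectral (1427-point)
#' and band-simulated (10-point) input as long as plots and endmembers
#' share one grid.
#'
#' @param plots A `spectral_library` of plot spectra (role `"plot"`).
#' @param ems An [endmember_set()] on the same wavelength grid.
#' @param communities Observed long-format community table for the same
#'   plots.
#' @param ... Passed to [normalize_and_filter()] (e.g. `drop_on`) and
#'   [nnls_solve()] (`sum_to_one`).
#' @param sum_to_one See [nnls_solve()].
#' @return An `unmix_result` (abundances in percent alongside observed
#'   covers).
#' @export
unmix <- function(plots, ems, communities, sum_to_one = FALSE, ...) {
  stopifnot(inherits(plots, "spectral_library"), inherits(ems, "endmember_set"))
  if (length(plots$wavelength_nm) != length(ems$wavelength_nm) ||
      any(plots$wavelength_nm != ems$wavelength_nm)) {
    stop("grid error: plots and endmembers are on different wavelength grids",
         call. = FALSE)
  }
  meta <- plots$metadata
  is_plot <- if ("role" %in% names(meta)) {
    !is.na(meta$role) & meta$role == "plot"
  } else rep(TRUE, nrow(meta))
  ids <- meta$sample_id[is_plot]
  if (length(ids) == 0L) stop("no plot spectra in library", call. = FALSE)
  plot_ids <- if ("plot_id" %in% names(meta)) {
    ifelse(is.na(meta$plot_id[is_plot]), ids, meta$plot_id[is_plot])
  } else ids

  raw <- do.call(rbind, lapply(seq_along(ids), function(i) {
    sol <- nnls_solve(ems$E, plots$rf[, ids[i]], sum_to_one = sum_to_one)
    data.frame(plot_id = plot_ids[i], species = ems$species,
               a_raw = unname(sol$coef), residual_norm = sol$residual_norm,
               stringsAsFactors = FALSE)
  }))
  normalize_and_filter(raw, communities, ...)
}

#' Per-species accuracy of an unmixing result
#'
#' Computes R-squared, RMSE and bias of predicted vs observed cover for
#' each species over the evaluation pairs (non-dropped), in percent units.
#' Species with fewer than two evaluation pairs, or with constant observed
#' cover, get `NA` R-squared.
#'
#' @param result An `unmix_result`.
#' @param min_pairs Minimum evaluation pairs for a species row (default 2).
#' @return Data frame `species`, `n`, `r2`, `rmse`, `bias`.
#' @export
unmix_metrics <- function(result, min_pairs = 2L) {
  stopifnot(inherits(result, "unmix_result"))
  ev <- result$pairs[!result$pairs$dropped, , drop = FALSE]
  out <- do.call(rbind, lapply(split(ev, ev$species), function(d) {
    if (nrow(d) < min_pairs) {
      return(data.frame(species = d$species[1], n = nrow(d), r2 = NA_real_,
                        rmse = NA_real_, bias = NA_real_))
    }
    fm <- suppressWarnings(fit_metrics(d$cover_obs_pct, d$cover_pred_pct))
    cbind(data.frame(species = d$species[1]), fm)
  }))
  rownames(out) <- NULL
  out
}
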