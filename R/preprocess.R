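#' Segmented Savitzky-Golay smoothing configuration
#'
#' Field-spectrometer noise grows with wavelength, so the smoothing window
#' widens across the spectrum: 15 nm in 350-1000 nm, 39 nm in 1001-2000 nm
#' and 75 nm in 2001-2500 nm, all with a second-order polynomial. On the
#' 1-nm ASD grid the window in samples equals the window in nm.
#'
#' @param segments Data frame with columns `lower_nm`, `upper_nm`
#'   (closed interval, inclusive), `window_nm` (odd, > `polyorder`) and
#'   `polyorder`. Segments must not overlap.
#' @return An object of class `"smoothing_config"`.
#' @export
smoothing_config <- function(segments = data.frame(
                               lower_nm  = c(350, 1001, 2001),
                               upper_nm  = c(1000, 2000, 2500),
                               window_nm = c(15, 39, 75),
                               polyorder = c(2, 2, 2))) {
  segments <- as.data.frame(segments)
  needed <- c("lower_nm", "upper_nm", "window_nm", "polyorder")
  if (!all(needed %in% names(segments))) {
    stop("config error: segments need columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (any(segments$window_nm %% 2 != 1)) {
    stop("config error: window_nm must be odd", call. = FALSE)
  }
  if (any(segments$window_nm <= segments$polyorder)) {
    stop("config error: window_nm must exceed polyorder", call. = FALSE)
  }
  segments <- segments[order(segments$lower_nm), , drop = FALSE]
  if (nrow(segments) > 1L &&
      any(segments$lower_nm[-1] <= segments$upper_nm[-nrow(segments)])) {
    stop("config error: segments overlap", call. = FALSE)
  }
  structure(list(segments = segments), class = "smoothing_config")
}

#' Wavelength masking configuration
#'
#' Default removed ranges are the atmospheric water-absorption windows
#' 1330-1549, 1761-2024 and 2311-2500 nm plus the noisy 350-399 nm region,
#' leaving three analysis regions: 400-1329, 1550-1760 and 2025-2310 nm
#' (1427 points on a full 1-nm grid).
#'
#' @param removed_ranges_nm Two-column matrix (or data frame) of closed
#'   `[lower, upper]` intervals to drop, disjoint and sorted.
#' @return An object of class `"mask_config"`.
#' @export
mask_config <- function(removed_ranges_nm = cbind(
                          lower_nm = c(350, 1330, 1761, 2311),
                          upper_nm = c(399, 1549, 2024, 2500))) {
  m <- as.matrix(removed_ranges_nm)
  if (ncol(m) != 2L) stop("config error: intervals need 2 columns", call. = FALSE)
  colnames(m) <- c("lower_nm", "upper_nm")
  if (any(m[, 1] > m[, 2])) stop("config error: lower > upper", call. = FALSE)
  m <- m[order(m[, 1]), , drop = FALSE]
  if (nrow(m) > 1L && any(m[-1, 1] <= m[-nrow(m), 2])) {
    stop("config error: removed ranges overlap", call. = FALSE)
  }
  structure(list(removed_ranges_nm = m), class = "mask_config")
}

#' Savitzky-Golay smoothing, applied segment by segment
#'
#' Each configured wavelength segment is filtered independently with its
#' own window, so the different window widths never leak across segment
#' boundaries. Edges of each segment use the standard Savitzky-Golay
#' boundary treatment (polynomial fit over the terminal window), which
#' reproduces polynomials up to the configured order exactly everywhere in
#' the segment. Wavelengths outside every configured segment pass through
#' unchanged.
#'
#' @param lib A `spectral_library` on a 1-nm grid.
#' @param cfg A [smoothing_config()].
#' @return The smoothed library (same grid, same metadata).
#' @export
sg_smooth <- function(lib, cfg = smoothing_config()) {
  stopifnot(inherits(lib, "spectral_library"), inherits(cfg, "smoothing_config"))
  wl <- lib$wavelength_nm
  out <- lib$rf
  for (i in seq_len(nrow(cfg$segments))) {
    seg <- cfg$segments[i, ]
    idx <- which(wl >= seg$lower_nm & wl <= seg$upper_nm)
    if (length(idx) == 0L) next
    ## masked grids leave several contiguous 1-nm runs inside one segment;
    ## each run is filtered on its own
    runs <- split(idx, cumsum(c(1, diff(wl[idx]) != 1)))
    filt <- signal::sgolay(p = seg$polyorder, n = seg$window_nm)
    for (run in runs) {
      if (seg$window_nm > length(run)) {
        stop("config error: window (", seg$window_nm,
             ") exceeds contiguous segment length (", length(run), ")",
             call. = FALSE)
      }
      for (j in seq_len(ncol(out))) {
        out[run, j] <- signal::sgolayfilt(lib$rf[run, j], filt)
      }
    }
  }
  lib$rf <- out
  lib
}

#' Remove masked wavelength regions
#'
#' Drops every wavelength falling inside a removed range; retained rows are
#' passed through untouched (bit-identical rf values).
#'
#' @param lib A `spectral_library`.
#' @param cfg A [mask_config()].
#' @return The masked library.
#' @export
apply_mask <- function(lib, cfg = mask_config()) {
  stopifnot(inherits(lib, "spectral_library"), inherits(cfg, "mask_config"))
  wl <- lib$wavelength_nm
  drop <- rep(FALSE, length(wl))
  for (i in seq_len(nrow(cfg$removed_ranges_nm))) {
    drop <- drop | (wl >= cfg$removed_ranges_nm[i, 1] &
                    wl <= cfg$removed_ranges_nm[i, 2])
  }
  if (all(drop)) stop("empty spectrum: all wavelengths masked", call. = FALSE)
  lib$wavelength_nm <- wl[!drop]
  lib$rf <- lib$rf[!drop, , drop = FALSE]
  lib
}

#' Contiguous retained regions of a masked grid
#'
#' Utility describing the blocks of consecutive 1-nm wavelengths that
#' survive masking (e.g. the three analysis regions of the default mask).
#'
#' @param wavelength_nm Integer-nm wavelength vector (post-mask).
#' @return Data frame with `lower_nm`, `upper_nm`, `n_points` per block.
#' @export
retained_regions <- function(wavelength_nm) {
  stopifnot(length(wavelength_nm) >= 1L)
  brk <- c(0, which(diff(wavelength_nm) != 1), length(wavelength_nm))
  out <- do.call(rbind, lapply(seq_len(length(brk) - 1L), function(i) {
    block <- wavelength_nm[(brk[i] + 1L):brk[i + 1L]]
    data.frame(lower_nm = min(block), upper_nm = max(block),
               n_points = length(block))
  }))
  rownames(out) <- NULL
  out
}

#' Average replicate spectra into one spectrum per species
#'
#' Laboratory endmember spectra are measured on several leaves or samples
#' per species; the species endmember is their arithmetic per-wavelength
#' mean. Only rows with `role == "endmember"` are averaged; other samples
#' are passed through.
#'
#' @param lib A `spectral_library` whose metadata has a `species` column
#'   for endmember samples.
#' @return A library with one spectrum per species (sample_id = species
#'   name, role = "endmember"); non-endmember samples unchanged.
#' @export
average_species_spectra <- function(lib) {
  stopifnot(inherits(lib, "spectral_library"))
  meta <- lib$metadata
  is_em <- !is.na(meta$role) & meta$role == "endmember"
  if (!any(is_em)) stop("no endmember spectra to average", call. = FALSE)
  sp <- meta$species[is_em]
  if (anyNA(sp)) stop("metadata error: endmember sample without species", call. = FALSE)

  groups <- split(meta$sample_id[is_em], sp)
  mean_rf <- vapply(groups, function(ids) {
    rowMeans(lib$rf[, ids, drop = FALSE])
  }, numeric(length(lib$wavelength_nm)))
  mean_rf <- as.matrix(mean_rf)

  ## carry representative metadata (first replicate) per species
  first_ids <- vapply(groups, `[`, character(1), 1L)
  em_meta <- meta[match(first_ids, meta$sample_id), , drop = FALSE]
  em_meta$sample_id <- names(groups)
  em_meta$species <- names(groups)

  keep <- !is_em
  rf <- cbind(lib$rf[, keep, drop = FALSE], mean_rf)
  metadata <- rbind(meta[keep, , drop = FALSE], em_meta)
  spectral_library(lib$wavelength_nm, rf, metadata)
}

#' Harmonize a spectral library
#'
#' The harmonization pipeline: segmented Savitzky-Golay smoothing first,
#' then removal of the masked wavelength regions, optionally followed by
#' per-species averaging of replicate endmember spectra. The order matters:
#' smoothing sees the full grid (points later masked still inform the fit
#' near mask edges), which is the convention adopted throughout.
#'
#' @param lib A `spectral_library` on the full instrument grid.
#' @param smooth_cfg A [smoothing_config()].
#' @param mask_cfg A [mask_config()].
#' @param average_species Average replicate endmember spectra per species.
#' @return The harmonized library.
#' @export
harmonize <- function(lib, smooth_cfg = smoothing_config(),
                      mask_cfg = mask_config(), average_species = FALSE) {
  out <- sg_smooth(lib, smooth_cfg)
  out <- apply_mask(out, mask_cfg)
  if (average_species) out <- average_species_spectra(out)
  out
}
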