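#' Sentinel-2 band centres used in the pipeline
#'
#' The ten MSI bands retained for vegetation analysis: the 60-m atmospheric
#' bands B1 and B9 are excluded, and the cirrus band B10 cannot be
#' simulated at all because its support lies inside the masked
#' water-absorption region.
#'
#' @return Named numeric vector of band centres (nm), in band order.
#' @export
sentinel2_band_centers <- function() {
  c(B2 = 490, B3 = 560, B4 = 665, B5 = 705, B6 = 740,
    B7 = 783, B8 = 842, B8a = 865, B11 = 1610, B12 = 2190)
}

new_band_set <- function(bands) {
  nm <- vapply(bands, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("config error: duplicated band names", call. = FALSE)
  for (b in bands) {
    if (length(b$wavelength_nm) != length(b$weight) ||
        any(b$weight < 0) || sum(b$weight) <= 0) {
      stop("config error: band ", b$name,
           " needs nonnegative weights with positive total", call. = FALSE)
    }
  }
  structure(list(bands = stats::setNames(bands, nm)), class = "band_set")
}

#' @export
print.band_set <- function(x, ...) {
  cat(sprintf("<band_set> %d bands: %s\n", length(x$bands),
              paste(names(x$bands), collapse = ", ")))
  invisible(x)
}

#' Read multispectral band response functions from a table
#'
#' Parses the wide export layout of sensor spectral-response tables
#' (a `wavelength_nm` column plus one column per band, weights on an
#' integer-nm grid) and restricts to the requested band list.
#'
#' @param path CSV path.
#' @param bands Character vector of band column names to keep; defaults to
#'   the ten Sentinel-2 bands of [sentinel2_band_centers()].
#' @param centers Named numeric vector of band centres (nm) for the
#'   requested bands.
#' @return A `band_set`.
#' @export
read_srf <- function(path, bands = names(sentinel2_band_centers()),
                     centers = sentinel2_band_centers()) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"wavelength_nm" %in% names(tab)) {
    stop("format error: SRF table needs a 'wavelength_nm' column", call. = FALSE)
  }
  missing <- setdiff(bands, names(tab))
  if (length(missing) > 0L) {
    stop("config error: requested band(s) absent from SRF table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!all(bands %in% names(centers))) {
    stop("config error: no centre wavelength for some requested bands", call. = FALSE)
  }
  wl <- tab$wavelength_nm
  new_band_set(lapply(bands, function(b) {
    w <- tab[[b]]
    keep <- !is.na(w) & w > 0
    list(name = b, center_nm = unname(centers[b]),
         wavelength_nm = wl[keep], weight = w[keep])
  }))
}

#' Synthetic Gaussian band responses
#'
#' A self-contained stand-in for a sensor response table: Gaussian response
#' curves at the ten Sentinel-2 band centres with plausible bandwidths.
#' The weights are synthetic (not the ESA-published responses); a real
#' exported SRF table read with [read_srf()] is a drop-in replacement.
#'
#' @param centers Named numeric vector of band centres (nm).
#' @param fwhm_nm Named numeric vector of full-widths at half-maximum (nm),
#'   same names as `centers`.
#' @return A `band_set`.
#' @export
gaussian_band_set <- function(centers = sentinel2_band_centers(),
                              fwhm_nm = c(B2 = 65, B3 = 35, B4 = 30, B5 = 15,
                                          B6 = 15, B7 = 20, B8 = 105, B8a = 20,
                                          B11 = 90, B12 = 180)) {
  stopifnot(all(names(centers) %in% names(fwhm_nm)))
  new_band_set(lapply(names(centers), function(b) {
    mu <- centers[[b]]
    sd <- fwhm_nm[[b]] / (2 * sqrt(2 * log(2)))
    wl <- seq(round(mu - 3 * sd), round(mu + 3 * sd))
    list(name = b, center_nm = unname(mu), wavelength_nm = wl,
         weight = exp(-0.5 * ((wl - mu) / sd)^2))
  }))
}

#' Resample hyperspectral spectra to multispectral bands
#'
#' Each band value is the response-weighted mean of the reflectance factor
#' over the wavelengths of the band's support that are present in the
#' (possibly masked) input grid; the response is renormalized over that
#' unmasked support, so constants are preserved even at mask edges. A band
#' whose support is entirely masked cannot be simulated and raises an
#' error naming the band.
#'
#' @param lib A harmonized `spectral_library`.
#' @param bs A `band_set`.
#' @return A `spectral_library` on the band-centre grid with
#'   `quantity = "SIMULATED"`.
#' @export
resample_to_bands <- function(lib, bs) {
  stopifnot(inherits(lib, "spectral_library"), inherits(bs, "band_set"))
  vals <- vapply(bs$bands, function(b) {
    idx <- match(b$wavelength_nm, lib$wavelength_nm)
    keep <- !is.na(idx)
    if (!any(keep) || sum(b$weight[keep]) <= 0) {
      stop("band ", b$name, " could not be simulated: ",
           "response support entirely outside the retained wavelengths",
           call. = FALSE)
    }
    w <- b$weight[keep] / sum(b$weight[keep])
    drop(crossprod(w, lib$rf[idx[keep], , drop = FALSE]))
  }, numeric(ncol(lib$rf)))
  vals <- matrix(vals, nrow = length(bs$bands), ncol = ncol(lib$rf),
                 byrow = TRUE, dimnames = list(NULL, colnames(lib$rf)))

  centers <- vapply(bs$bands, `[[`, numeric(1), "center_nm")
  ord <- order(centers)
  meta <- lib$metadata
  meta$quantity <- "SIMULATED"
  out <- spectral_library(centers[ord], vals[ord, , drop = FALSE], meta)
  attr(out, "band_names") <- names(bs$bands)[ord]
  out
}
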