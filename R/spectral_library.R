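#' Construct a spectral library
#'
#' A spectral library holds reflectance-factor (RF) spectra for a set of
#' samples that share one wavelength grid, together with a per-sample
#' metadata table. It is the common currency of the whole pipeline: field
#' plot spectra, laboratory leaf spectra, species endmembers and simulated
#' multispectral bands all travel in this container.
#'
#' @param wavelength_nm Strictly increasing numeric vector of wavelengths in
#'   nanometres. Integer-valued grids are expected (the 1-nm grid of ASD
#'   field spectrometers); fractional grids are rejected unless
#'   `allow_fractional = TRUE`.
#' @param rf Numeric matrix of reflectance factors, one row per wavelength
#'   and one named column per sample. RF is unitless; values slightly above
#'   1 can occur for bright targets and are accepted with a warning (no
#'   clamping), as are small negative values from noisy dark targets.
#' @param metadata A data frame keyed by `sample_id`, one row per column of
#'   `rf`. Recognised columns: `sample_id`, `role` (`"endmember"` or
#'   `"plot"`), `species` (endmembers), `plot_id` (plots), `trophic_level`
#'   (`"minerotrophic"` or `"ombrotrophic"`), and `quantity` (one of
#'   `"HCRF"`, `"DHRF"`, `"CCRF"`, `"SIMULATED"`).
#' @param allow_fractional Accept non-integer wavelength grids.
#'
#' @return An object of class `"spectral_library"`: a list with elements
#'   `wavelength_nm`, `rf` and `metadata`.
#' @export
spectral_library <- function(wavelength_nm, rf, metadata,
                             allow_fractional = FALSE) {
  wavelength_nm <- as.numeric(wavelength_nm)
  rf <- as.matrix(rf)
  storage.mode(rf) <- "double"

  if (length(wavelength_nm) < 1L || nrow(rf) != length(wavelength_nm)) {
    stop("grid error: 'rf' must have one row per wavelength", call. = FALSE)
  }
  if (any(diff(wavelength_nm) <= 0)) {
    stop("grid error: wavelengths must be strictly increasing", call. = FALSE)
  }
  if (!allow_fractional && any(wavelength_nm != round(wavelength_nm))) {
    stop("grid error: non-integer wavelength grid (set allow_fractional = TRUE to accept)",
         call. = FALSE)
  }
  if (is.null(colnames(rf)) || anyNA(colnames(rf)) || any(colnames(rf) == "")) {
    stop("metadata error: every sample column must be named", call. = FALSE)
  }
  if (anyDuplicated(colnames(rf))) {
    stop("metadata error: duplicated sample_id in spectra", call. = FALSE)
  }
  if (anyNA(rf)) {
    stop("rf contains missing values; masked regions must be removed, not flagged NA",
         call. = FALSE)
  }

  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(metadata)) {
    stop("metadata error: metadata must contain a 'sample_id' column", call. = FALSE)
  }
  metadata$sample_id <- as.character(metadata$sample_id)
  if (anyDuplicated(metadata$sample_id)) {
    stop("metadata error: duplicated sample_id in metadata", call. = FALSE)
  }
  missing_meta <- setdiff(colnames(rf), metadata$sample_id)
  if (length(missing_meta) > 0L) {
    stop("metadata error: no metadata row for sample(s): ",
         paste(missing_meta, collapse = ", "), call. = FALSE)
  }
  ## keep metadata in spectra column order, drop unreferenced rows
  metadata <- metadata[match(colnames(rf), metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL

  if (any(rf < 0) || any(rf > 1.5)) {
    warning("rf values outside [0, 1.5] present; kept as-is (possible instrument issue)",
            call. = FALSE)
  }

  structure(
    list(wavelength_nm = wavelength_nm, rf = rf, metadata = metadata),
    class = "spectral_library"
  )
}

#' @export
print.spectral_library <- function(x, ...) {
  cat(sprintf("<spectral_library> %d samples x %d wavelengths (%g-%g nm)\n",
              ncol(x$rf), length(x$wavelength_nm),
              min(x$wavelength_nm), max(x$wavelength_nm)))
  roles <- table(x$metadata$role)
  if (length(roles) > 0L) {
    cat("  roles:", paste(sprintf("%s=%d", names(roles), roles), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of samples in a spectral library
#' @param lib A `spectral_library`.
#' @return Integer count of sample columns.
#' @export
n_samples <- function(lib) ncol(lib$rf)

#' Extract one spectrum from a library
#'
#' @param lib A `spectral_library`.
#' @param sample_id Name of the sample column.
#' @return A list with `wavelength_nm` and `rf` (numeric vector).
#' @export
get_spectrum <- function(lib, sample_id) {
  if (!sample_id %in% colnames(lib$rf)) {
    stop("unknown sample_id: ", sample_id, call. = FALSE)
  }
  list(wavelength_nm = lib$wavelength_nm, rf = lib$rf[, sample_id])
}

#' Read a spectral library from delimited text files
#'
#' Expects the plain-table dialect used throughout the package: a CSV whose
#' first column is `wavelength_nm` and whose remaining columns are samples,
#' plus a sidecar metadata CSV keyed by `sample_id`. Column order of the
#' spectra file is preserved.
#'
#' @param path Path to the spectra CSV.
#' @param metadata_path Path to the metadata CSV.
#' @inheritParams spectral_library
#' @return A validated [spectral_library()].
#' @export
read_spectral_library <- function(path, metadata_path, allow_fractional = FALSE) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) {
    stop("format error: spectra table needs a wavelength column plus >= 1 sample",
         call. = FALSE)
  }
  if (names(tab)[1] != "wavelength_nm") {
    stop("format error: first column must be named 'wavelength_nm'", call. = FALSE)
  }
  meta <- utils::read.csv(metadata_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  rf <- as.matrix(tab[, -1, drop = FALSE])
  spectral_library(tab[[1]], rf, meta, allow_fractional = allow_fractional)
}

#' Write a spectral library to delimited text files
#'
#' Round-trip safe: `read_spectral_library()` on the written files
#' reproduces wavelengths exactly and rf values to well below 1e-9.
#'
#' @param lib A `spectral_library`.
#' @param path Output path for the spectra CSV.
#' @param metadata_path Output path for the metadata CSV.
#' @return Invisibly, `lib`.
#' @export
write_spectral_library <- function(lib, path, metadata_path) {
  stopifnot(inherits(lib, "spectral_library"))
  if (n_samples(lib) == 0L) stop("nothing to write: empty library", call. = FALSE)
  tab <- data.frame(wavelength_nm = lib$wavelength_nm, check.names = FALSE)
  tab <- cbind(tab, as.data.frame(lib$rf, check.names = FALSE))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  utils::write.csv(lib$metadata, metadata_path, row.names = FALSE)
  invisible(lib)
}

#' Merge libraries onto their common wavelength grid
#'
#' Restricts every library to the intersection of the wavelength grids and
#' binds the samples into one library. By default no interpolation is done:
#' a wavelength survives only if present in every input grid. With
#' `interpolate = TRUE`, spectra are linearly interpolated onto the
#' intersection range of the grids (1-nm steps).
#'
#' Idempotent: aligning an already-aligned library is the identity.
#'
#' @param libs A list of `spectral_library` objects.
#' @param interpolate Linearly interpolate onto the shared 1-nm range
#'   instead of taking the exact grid intersection.
#' @return A single `spectral_library` on the common grid.
#' @export
align_to_common_grid <- function(libs, interpolate = FALSE) {
  stopifnot(is.list(libs), length(libs) >= 1L,
            all(vapply(libs, inherits, logical(1), "spectral_library")))
  if (length(libs) == 1L) return(libs[[1]])

  if (interpolate) {
    lo <- max(vapply(libs, function(l) min(l$wavelength_nm), numeric(1)))
    hi <- min(vapply(libs, function(l) max(l$wavelength_nm), numeric(1)))
    if (lo > hi) stop("grid error: empty wavelength intersection", call. = FALSE)
    grid <- seq(ceiling(lo), floor(hi), by = 1)
    mats <- lapply(libs, function(l) {
      apply(l$rf, 2, function(col) {
        stats::approx(l$wavelength_nm, col, xout = grid)$y
      })
    })
  } else {
    grid <- Reduce(intersect, lapply(libs, function(l) l$wavelength_nm))
    if (length(grid) == 0L) {
      stop("grid error: empty wavelength intersection", call. = FALSE)
    }
    grid <- sort(grid)
    mats <- lapply(libs, function(l) {
      l$rf[match(grid, l$wavelength_nm), , drop = FALSE]
    })
  }

  all_ids <- unlist(lapply(libs, function(l) colnames(l$rf)))
  if (anyDuplicated(all_ids)) {
    stop("metadata error: duplicated sample_id across libraries", call. = FALSE)
  }
  meta_cols <- Reduce(union, lapply(libs, function(l) names(l$metadata)))
  metas <- lapply(libs, function(l) {
    m <- l$metadata
    for (col in setdiff(meta_cols, names(m))) m[[col]] <- NA
    m[, meta_cols, drop = FALSE]
  })
  spectral_library(grid, do.call(cbind, mats), do.call(rbind, metas))
}
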