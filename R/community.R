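#' Point-intercept sampling grid
#'
#' Cell centres of the digital grid laid over a square vegetation plot:
#' a 1 m frame marked every 10 cm gives a 10 x 10 grid of 100 cells, each
#' observed at its centre.
#'
#' @param frame_m Side length of the square frame (m).
#' @param spacing_m Grid spacing (m); must divide `frame_m`.
#' @return Data frame of cell-centre coordinates `x_m`, `y_m`, one row per
#'   cell, `(i + 0.5) * spacing` along each axis.
#' @export
make_grid <- function(frame_m = 1, spacing_m = 0.1) {
  stopifnot(frame_m > 0, spacing_m > 0)
  k <- frame_m / spacing_m
  if (abs(k - round(k)) > 1e-9) {
    stop("config error: frame length must be divisible by spacing", call. = FALSE)
  }
  k <- round(k)
  centers <- (seq_len(k) - 0.5) * spacing_m
  out <- expand.grid(x_m = centers, y_m = centers, KEEP.OUT.ATTRS = FALSE)
  out[order(out$y_m, out$x_m), , drop = FALSE]
}

#' Fractional cover from point-intercept observations
#'
#' One species is recorded at the centre of each grid cell; the fractional
#' cover of a species is the percentage of cells where it was recorded, so
#' covers always partition the plot (sum to 100).
#'
#' @param labels Character vector of species identities, one per grid cell
#'   (length 100 for the default grid).
#' @param plot_id Plot identifier.
#' @param trophic_level `"minerotrophic"` or `"ombrotrophic"`.
#' @return A plot-community data frame: `plot_id`, `trophic_level`,
#'   `species`, `cover_pct`.
#' @export
estimate_cover <- function(labels, plot_id, trophic_level) {
  labels <- as.character(labels)
  if (length(labels) == 0L) stop("empty grid observation", call. = FALSE)
  counts <- table(labels)
  data.frame(plot_id = plot_id,
             trophic_level = trophic_level,
             species = names(counts),
             cover_pct = 100 * as.numeric(counts) / length(labels),
             row.names = NULL, stringsAsFactors = FALSE)
}

## cover vector (possibly with zeros) -> probability vector, with checks
cover_to_p <- function(cover) {
  cover <- as.numeric(cover)
  if (length(cover) == 0L || any(cover < 0)) {
    stop("covers must be nonnegative", call. = FALSE)
  }
  tot <- sum(cover)
  if (tot <= 0) stop("all-zero cover: diversity undefined", call. = FALSE)
  cover / tot
}

#' Shannon-Wiener diversity index
#'
#' \eqn{H = -\sum_{p_s > 0} p_s \ln p_s} with \eqn{p_s} the relative cover
#' of species \eqn{s}. Natural logarithm (nats) by default; `base` makes
#' the logarithm configurable.
#'
#' @param cover Numeric vector of species covers (any nonnegative scale;
#'   normalized internally). Zeros are allowed and contribute nothing.
#' @param base Logarithm base (default `exp(1)`).
#' @return Nonnegative scalar, at most `log(richness, base)`.
#' @export
shannon_index <- function(cover, base = exp(1)) {
  p <- cover_to_p(cover)
  h <- unname(vegan::diversity(p, index = "shannon"))
  if (base != exp(1)) h <- h / log(base)
  h
}

#' Simpson diversity index
#'
#' The complement form \eqn{D = 1 - \sum_s p_s^2}: the probability that two
#' random point intercepts hit different species. Ranges in
#' \eqn{[0, 1 - 1/\mathrm{richness}]}; 0 iff exactly one species present.
#'
#' @inheritParams shannon_index
#' @return Scalar in `[0, 1)`.
#' @export
simpson_index <- function(cover) {
  p <- cover_to_p(cover)
  unname(vegan::diversity(p, index = "simpson"))
}

#' Alpha-diversity per plot
#'
#' Computes the Shannon-Wiener and Simpson indices for every plot of a
#' long-format community table, using all species present in each plot.
#'
#' @param communities Data frame with columns `plot_id`, `species`,
#'   `cover_pct` (and optionally `trophic_level`, carried through).
#' @param base Logarithm base for the Shannon index.
#' @return Data frame `plot_id`, (`trophic_level`,) `richness`, `shannon`,
#'   `simpson`, one row per plot.
#' @export
diversity_indices <- function(communities, base = exp(1)) {
  stopifnot(all(c("plot_id", "species", "cover_pct") %in% names(communities)))
  has_level <- "trophic_level" %in% names(communities)
  out <- do.call(rbind, lapply(split(communities, communities$plot_id), function(d) {
    cov <- d$cover_pct
    data.frame(plot_id = d$plot_id[1],
               trophic_level = if (has_level) d$trophic_level[1] else NA,
               richness = sum(cov > 0),
               shannon = shannon_index(cov, base = base),
               simpson = simpson_index(cov),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (!has_level) out$trophic_level <- NULL
  out
}

#' Long community table -> plot x species cover matrix
#'
#' @param communities Long-format community data frame (`plot_id`,
#'   `species`, `cover_pct`).
#' @param species Optional species order for the columns; defaults to the
#'   sorted species present. Missing (plot, species) pairs are 0.
#' @return Numeric matrix, rows = plots, columns = species, entries in
#'   percent.
#' @export
community_matrix <- function(communities, species = NULL) {
  if (is.null(species)) species <- sort(unique(communities$species))
  plots <- unique(communities$plot_id)
  m <- matrix(0, nrow = length(plots), ncol = length(species),
              dimnames = list(as.character(plots), species))
  keep <- communities$species %in% species
  idx <- cbind(match(communities$plot_id[keep], plots),
               match(communities$species[keep], species))
  m[idx] <- communities$cover_pct[keep]
  m
}
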