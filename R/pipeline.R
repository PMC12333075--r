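#' Default pipeline configuration
#'
#' One nested list capturing every coupled threshold of the workflow
#' (smoothing windows, mask ranges, band list, unmixing thresholds,
#' diversity log base, PLS settings, simulation settings) so a run is
#' reproducible from its config alone. Can also be written as YAML and
#' loaded with [read_pipeline_config()].
#'
#' @param seed Master seed for the simulated study and the PLS split/folds.
#' @return Nested configuration list.
#' @export
pipeline_config <- function(seed = 1) {
  list(
    seed = as.integer(seed),
    simulate = list(enabled = TRUE),
    preprocess = list(average_species = TRUE),
    unmix = list(input_type = "hs", min_plots = 5, min_cover_pct = 5,
                 drop_on = "observed"),
    bands = list(synthetic = TRUE, srf_path = NULL),
    diversity = list(log_base = exp(1)),
    pls = list(k_folds = 10, max_components = 10, train_fraction = 0.7)
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys override the defaults of
#'   [pipeline_config()].
#' @return Nested configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- pipeline_config(seed = if (!is.null(user$seed)) user$seed else 1)
  for (section in names(user)) {
    if (is.list(user[[section]]) && is.list(cfg[[section]])) {
      for (k in names(user[[section]])) cfg[[section]][[k]] <- user[[section]][[k]]
    } else {
      cfg[[section]] <- user[[section]]
    }
  }
  cfg
}

validate_pipeline_config <- function(cfg) {
  if (!cfg$unmix$input_type %in% c("hs", "ms")) {
    stop("config error: unmix$input_type must be 'hs' or 'ms'", call. = FALSE)
  }
  if (cfg$unmix$input_type == "ms" &&
      !isTRUE(cfg$bands$synthetic) && is.null(cfg$bands$srf_path)) {
    stop("config error: input_type 'ms' needs bands$srf_path or bands$synthetic = TRUE",
         call. = FALSE)
  }
  if (!is.null(cfg$bands$srf_path) && !file.exists(cfg$bands$srf_path)) {
    stop("config error: SRF file not found: ", cfg$bands$srf_path, call. = FALSE)
  }
  invisible(cfg)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages on a simulated study: generate data, harmonize
#' plot and endmember spectra, optionally simulate multispectral bands,
#' unmix each trophic level, compute per-species accuracy, compute plot
#' diversity, and fit the diversity-from-spectra PLS models. All output
#' tables are written as CSV under `out_dir` together with a JSON run
#' manifest (config and package version); rerunning with the same config
#' reproduces every output byte for byte.
#'
#' @param cfg Configuration list from [pipeline_config()] or
#'   [read_pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @param quiet Suppress per-stage messages.
#' @return Invisibly, a list with the in-memory results per trophic level
#'   (`unmix`, `unmix_metrics`, `diversity`, `pls`) and `files` (paths
#'   written).
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = tempfile("peatspec_run_"),
                         quiet = FALSE) {
  validate_pipeline_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }

  say("stage simulate: generating synthetic study (seed ", cfg$seed, ")")
  sim_args <- list(seed = cfg$seed)
  if (!is.null(cfg$simulate$n_plots)) {
    sim_args$n_plots <- unlist(cfg$simulate$n_plots)
  }
  if (!is.null(cfg$simulate$noise_sd)) sim_args$noise_sd <- cfg$simulate$noise_sd
  study <- gen_study(do.call(simulation_config, sim_args))

  bs <- if (cfg$unmix$input_type == "ms") {
    if (!is.null(cfg$bands$srf_path)) read_srf(cfg$bands$srf_path)
    else gaussian_band_set()
  } else NULL

  results <- list()
  for (lev in setdiff(names(study), "config")) {
    say("stage harmonize: ", lev)
    plots_h <- harmonize(study[[lev]]$plots)
    em_h <- harmonize(study[[lev]]$endmembers,
                      average_species = isTRUE(cfg$preprocess$average_species))
    comm <- study[[lev]]$communities

    selected <- select_endmembers(comm, min_plots = cfg$unmix$min_plots,
                                  min_cover_pct = cfg$unmix$min_cover_pct)
    ems <- endmember_set(em_h, species = selected, trophic_level = lev)

    if (cfg$unmix$input_type == "ms") {
      say("stage bandsim: ", lev)
      plots_u <- resample_to_bands(plots_h, bs)
      em_b <- resample_to_bands(em_h, bs)
      ems <- endmember_set(em_b, species = selected, trophic_level = lev)
    } else {
      plots_u <- plots_h
    }

    say("stage unmix: ", lev)
    um <- unmix(plots_u, ems, comm, drop_on = cfg$unmix$drop_on)
    met <- unmix_metrics(um)
    emit(um$pairs, paste0("unmix_pairs_", lev, ".csv"))
    emit(met, paste0("unmix_metrics_", lev, ".csv"))

    say("stage diversity: ", lev)
    div <- diversity_indices(comm, base = cfg$diversity$log_base)
    emit(div, paste0("diversity_", lev, ".csv"))

    say("stage diversity-model: ", lev)
    X <- t(plots_h$rf)
    ord <- match(rownames(X), div$plot_id)
    pls <- lapply(c(shannon = "shannon", simpson = "simpson"), function(idx) {
      evaluate_diversity_model(X, div[[idx]][ord],
                               train_fraction = cfg$pls$train_fraction,
                               k_folds = cfg$pls$k_folds,
                               max_components = cfg$pls$max_components,
                               seed = cfg$seed)
    })
    pls_metrics <- do.call(rbind, lapply(names(pls), function(idx) {
      cbind(data.frame(index = idx, n_components = pls[[idx]]$n_components),
            pls[[idx]]$metrics)
    }))
    emit(pls_metrics, paste0("pls_metrics_", lev, ".csv"))

    results[[lev]] <- list(unmix = um, unmix_metrics = met, diversity = div,
                           pls = pls)
  }

  manifest <- list(package = "peatspec",
                   version = as.character(utils::packageVersion("peatspec")),
                   config = cfg, outputs = basename(files))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  results$files <- c(files, manifest_path)
  invisible(results)
}
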