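# Pipeline binding and plain-text I/O: photon streams and burst tables as
# CSV with JSON sidecars, fits as JSON, and a seeded multi-condition run
# with a hashed manifest.

#' Write a photon stream as CSV plus a JSON parameter sidecar
#'
#' @param stream A `photon_stream`.
#' @param path Output CSV path; a sidecar `<path>.json` echoing the
#'   acquisition settings and seed is written next to it.
#' @return Invisibly, the two paths written.
#' @export
write_photon_stream <- function(stream, path) {
  stopifnot(inherits(stream, "photon_stream"))
  ph <- stream$photons
  ph$truth_burst <- NULL
  utils::write.csv(ph, path, row.names = FALSE)
  sidecar <- paste0(path, ".json")
  meta <- unclass(stream$settings)
  meta$background_rate <- as.list(meta$background_rate)
  jsonlite::write_json(list(format = "fretpda_photon_stream",
                            format_version = 1L,
                            clock_rate = stream$clock_rate,
                            settings = meta),
                       sidecar, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(csv = path, json = sidecar))
}

#' Read a photon stream written by [write_photon_stream()]
#'
#' @param path CSV path (the `<path>.json` sidecar must be present).
#' @return A `photon_stream` (without simulation ground truth).
#' @export
read_photon_stream <- function(path) {
  ph <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(meta$format, "fretpda_photon_stream"))
    stop("not a fretpda photon stream sidecar")
  st <- meta$settings
  acq <- acquisition_settings(
    duration = st$duration,
    background_rate = unlist(st$background_rate),
    burst_rate = st$burst_rate, transit_time_mean = st$transit_time_mean,
    dex_fraction = st$dex_fraction, excitation_period = st$excitation_period,
    clock_rate = st$clock_rate, R0 = st$R0, gamma = st$gamma,
    alpha = st$alpha, delta = st$delta,
    bleach_fraction = st$bleach_fraction %||% 0,
    seed = st$seed)
  structure(list(photons = ph, clock_rate = meta$clock_rate,
                 settings = acq, truth = NULL),
            class = "photon_stream")
}

#' Write a burst-metrics table as CSV plus JSON metadata
#'
#' @param metrics A `burst_metrics` table.
#' @param path Output CSV path; filters, thresholds and background rates go
#'   to `<path>.json`.
#' @return Invisibly, the paths written.
#' @export
write_burst_table <- function(metrics, path) {
  utils::write.csv(as.data.frame(metrics), path, row.names = FALSE)
  meta <- list(format = "fretpda_burst_table", format_version = 1L,
               background_rate = as.list(attr(metrics, "background_rate")),
               filters = attr(metrics, "filters"),
               kde_tau_us = attr(metrics, "kde_tau_us"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(c(csv = path, json = paste0(path, ".json")))
}

#' Default pipeline configuration
#'
#' A scaled-down analogue of the full study: per condition a two-state
#' dual-labeled species (closed state 4.4 nm, open state 6.3 nm) at a given
#' closed-state occupancy, simulated, burst-processed, species-sorted and
#' PDA-fitted; plus one corrector dose-response series simulated from a
#' four-parameter logistic curve and refitted.
#'
#' @param master_seed Master integer seed; every stochastic stage derives
#'   its own seed from it.
#' @param out_dir Output directory.
#' @param conditions data.frame with columns `label` and `closed_fraction`.
#' @param duration Per-condition acquisition length (s).
#' @param dose Named list of the generating logistic parameters plus
#'   `concentrations`, `noise_sd`, `replicates`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(master_seed = 1, out_dir = tempfile("fretpda_run_"),
                            conditions = data.frame(
                              label = c("wildtype_POPC", "V232D_POPC"),
                              closed_fraction = c(0.684, 0.342)),
                            duration = 60,
                            dose = list(f_min = 0.24, f_max = 0.87,
                                        EC50 = 350, n = 0.91,
                                        concentrations = exp(seq(log(1),
                                                                 log(2000),
                                                                 length.out = 8)),
                                        noise_sd = 0.03, replicates = 3)) {
  structure(list(master_seed = master_seed, out_dir = out_dir,
                 conditions = conditions, duration = duration, dose = dose,
                 format_version = 1L),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The file may define any subset of the [pipeline_config()] fields
#' (`master_seed`, `out_dir`, `conditions` as a list of `label` /
#' `closed_fraction` pairs, `duration`, `dose`); missing fields take the
#' defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  defaults <- pipeline_config()
  if (!is.null(y$conditions)) {
    y$conditions <- do.call(rbind, lapply(y$conditions, function(cc) {
      data.frame(label = cc$label, closed_fraction = cc$closed_fraction,
                 stringsAsFactors = FALSE)
    }))
  }
  for (f in c("master_seed", "out_dir", "conditions", "duration", "dose")) {
    if (is.null(y[[f]])) y[[f]] <- defaults[[f]]
  }
  pipeline_config(master_seed = y$master_seed, out_dir = y$out_dir,
                  conditions = y$conditions, duration = y$duration,
                  dose = y$dose)
}

#' Run the full simulate -> bursts -> PDA -> dose-fit pipeline
#'
#' Executes every condition of the configuration, writes all artifacts
#' (stream CSVs, burst tables, fit JSONs) under `config$out_dir`, and
#' returns a manifest listing each artifact with its MD5 content hash and
#' the derived seed of each stochastic stage. Re-running with the same
#' configuration reproduces every stochastic stage bit-identically.
#'
#' @param config A [pipeline_config()].
#' @param write_streams Write the (large) photon-stream CSVs (default
#'   `FALSE`; burst tables and fits are always written).
#' @return Manifest list: per-condition folded fractions with errors and
#'   free energies, the dose-response fit, file paths and hashes.
#' @export
run_pipeline <- function(config, write_streams = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  conditions <- config$conditions
  results <- vector("list", nrow(conditions))
  if (nrow(conditions) == 0L) {
    warning("configuration has zero conditions")
  }
  for (i in seq_len(nrow(conditions))) {
    stage <- conditions$label[i]
    res <- tryCatch({
      cond_seed <- (config$master_seed * 131L + i * 977L) %% .Machine$integer.max
      sp <- species_spec(stage, "dual",
                         state_fractions = c(conditions$closed_fraction[i],
                                             1 - conditions$closed_fraction[i]),
                         distance_center = c(4.4, 6.3),
                         distance_width = c(0.3, 0.3))
      acq <- acquisition_settings(duration = config$duration, seed = cond_seed)
      stream <- simulate_photon_stream(sp, acq)
      bursts <- find_bursts(stream)
      metrics <- burst_metrics(stream, bursts)
      sel <- sort_species(metrics)
      hist <- build_fret_histogram(sel)
      model0 <- pda_state_model(c(0.5, 0.5), c(4.4, 6.3), 0.3,
                                R0 = acq$R0, gamma = acq$gamma,
                                alpha = acq$alpha)
      fit <- pda_fit(hist, model0, seed = cond_seed)
      ff <- fraction_folded(fit)
      bt_path <- file.path(config$out_dir, paste0(stage, "_bursts.csv"))
      files <- c(files, write_burst_table(sel, bt_path))
      if (write_streams) {
        st_path <- file.path(config$out_dir, paste0(stage, "_stream.csv"))
        files <- c(files, write_photon_stream(stream, st_path))
      }
      fit_path <- file.path(config$out_dir, paste0(stage, "_pda.json"))
      jsonlite::write_json(list(
        condition = stage, seed = cond_seed,
        fractions = fit$fractions, fractions_se = fit$fractions_se,
        distance_center_nm = fit$distance_center,
        distance_center_se_nm = fit$distance_center_se,
        distance_width_nm = fit$distance_width,
        reduced_chi2 = fit$reduced_chi2,
        f_F = unname(ff["f_F"]), f_F_se = unname(ff["se"]),
        dG_kJ_per_mol = unname(delta_g(ff["f_F"])),
        n_bursts = hist$n_bursts,
        error_definition = fit$meta$error_definition
      ), fit_path, auto_unbox = TRUE, digits = NA)
      files <- c(files, fit_path)
      list(condition = stage, seed = cond_seed, f_F = unname(ff["f_F"]),
           f_F_se = unname(ff["se"]),
           dG_kJ_per_mol = unname(delta_g(ff["f_F"])),
           n_bursts = hist$n_bursts, reduced_chi2 = fit$reduced_chi2)
    }, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
    results[[i]] <- res
  }

  dose_fit_out <- NULL
  if (!is.null(config$dose)) {
    d <- config$dose
    dose_seed <- (config$master_seed * 131L + 65537L) %% .Machine$integer.max
    tab <- simulate_dose_response(d[c("f_min", "f_max", "EC50", "n")],
                                  d$concentrations, d$noise_sd,
                                  d$replicates, seed = dose_seed)
    dose_path <- file.path(config$out_dir, "dose_response.csv")
    utils::write.csv(tab, dose_path, row.names = FALSE)
    fit <- fit_dose_response(tab)
    fit_path <- file.path(config$out_dir, "dose_fit.json")
    jsonlite::write_json(list(
      seed = dose_seed, par = as.list(fit$par), se = as.list(fit$se),
      dG_at_max_conc_kJ_per_mol =
        as.numeric(delta_g_at_saturation(fit, mode = "max_conc")),
      dG_at_f_max_kJ_per_mol =
        as.numeric(delta_g_at_saturation(fit, mode = "f_max"))
    ), fit_path, auto_unbox = TRUE, digits = NA)
    files <- c(files, dose_path, fit_path)
    dose_fit_out <- list(seed = dose_seed, par = fit$par, se = fit$se)
  }

  cfg_path <- file.path(config$out_dir, "config.json")
  jsonlite::write_json(list(master_seed = config$master_seed,
                            conditions = conditions,
                            duration = config$duration,
                            dose = config$dose,
                            format_version = config$format_version),
                       cfg_path, auto_unbox = TRUE, digits = NA)
  files <- c(files, cfg_path)
  hashes <- tools::md5sum(unname(files))
  manifest <- list(master_seed = config$master_seed,
                   out_dir = config$out_dir,
                   conditions = results,
                   dose_fit = dose_fit_out,
                   files = data.frame(path = unname(files),
                                      md5 = unname(hashes)))
  man_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA)
  manifest
}
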