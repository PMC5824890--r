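#' Read a station table
#'
#' Parses a delimited station file (see
#' `inst/extdata/station_columns.md` for the column dictionary): one
#' header row, `#` comment lines, empty fields as missing values.
#' `station_id`, `depth_m` and `sampling_year` are required; all other
#' columns are optional and carried through.
#'
#' @param path Path to a delimited text file.
#' @param delim Field delimiter (default comma).
#' @return A `station_table` tibble, validated (positive depths, unique
#'   station ids, non-negative sigmas).
#' @export
read_stations <- function(path, delim = ",") {
  df <- readr::read_delim(path, delim = delim, comment = "#",
                          show_col_types = FALSE, progress = FALSE,
                          trim_ws = TRUE)
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    stop("malformed station table at line ", probs$row[1] + 1, ": ",
         probs$expected[1], call. = FALSE)
  }
  validate_stations(df)
}

#' @rdname read_stations
#' @param stations A data frame to validate/coerce.
#' @export
validate_stations <- function(stations) {
  df <- tibble::as_tibble(stations)
  req <- c("station_id", "depth_m", "sampling_year")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    stop("station table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0) stop("station table has no data rows", call. = FALSE)
  if (anyDuplicated(df$station_id)) {
    stop("duplicate station_id values", call. = FALSE)
  }
  if (any(!is.finite(df$depth_m)) || any(df$depth_m <= 0)) {
    stop("depth_m must be positive for every station", call. = FALSE)
  }
  for (col in grep("_sd", names(df), value = TRUE)) {
    bad <- which(!is.na(df[[col]]) & df[[col]] < 0)
    if (length(bad) > 0) {
      stop("negative sigma in column ", col, " at row ", bad[1],
           call. = FALSE)
    }
  }
  class(df) <- c("station_table", class(tibble::tibble()))
  df
}

#' Write a station table
#'
#' Round-trips losslessly with [read_stations()].
#'
#' @param stations A `station_table` (or coercible data frame).
#' @param path Output path.
#' @export
write_stations <- function(stations, path) {
  readr::write_csv(tibble::as_tibble(stations), path, na = "")
  invisible(path)
}

#' Default run configuration
#'
#' The full set of pipeline settings with their defaults: endmember
#' priors, MCMC protocol, fine-fraction model (passthrough), number of
#' Monte-Carlo draws and weighting for the age-depth fit, pools to fit
#' (auto-detected from `loading_*` columns when `NULL`), and the base
#' seed from which all stage seeds derive.
#'
#' @param seed Base integer seed.
#' @return A `run_config` list.
#' @export
default_run_config <- function(seed = 1) {
  structure(list(
    seed = as.integer(seed),
    transport = list(n_draws = 10000, weights = "none"),
    mcmc = list(n_iterations = 1e6, burn_in = 1e4, thinning = 10,
                target_acceptance = 0.23),
    endmembers = NULL,        # NULL -> default_endmembers()
    fine_fraction = list(form = "passthrough", coefficients = numeric(),
                         depth_range = c(0, Inf)),
    calibration_curve = NULL,
    pools = NULL,             # NULL -> detect loading_* columns
    output_dir = NULL
  ), class = "run_config")
}

.config_keys <- c("seed", "transport", "mcmc", "endmembers",
                  "fine_fraction", "calibration_curve", "pools",
                  "output_dir")

#' Read and validate a run configuration file
#'
#' YAML key-value file; recognized top-level keys are `seed`,
#' `transport`, `mcmc`, `endmembers`, `fine_fraction`,
#' `calibration_curve`, `pools`, `output_dir`. Unknown keys are
#' rejected. Missing keys take the [default_run_config()] values.
#'
#' @param path Path to a YAML config file.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), .config_keys)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- default_run_config()
  for (k in names(raw)) {
    if (is.list(cfg[[k]]) && is.list(raw[[k]])) {
      sub_unknown <- setdiff(names(raw[[k]]), names(cfg[[k]]))
      if (k %in% c("transport", "mcmc", "fine_fraction") &&
          length(sub_unknown) > 0) {
        stop("unknown config key(s) under ", k, ": ",
             paste(sub_unknown, collapse = ", "), call. = FALSE)
      }
      cfg[[k]][names(raw[[k]])] <- raw[[k]]
    } else {
      cfg[[k]] <- raw[[k]]
    }
  }
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A `run_config` to validate.
#' @export
validate_run_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config") || is.list(cfg))
  cfg$seed <- as.integer(cfg$seed)
  stopifnot(length(cfg$seed) == 1L, !is.na(cfg$seed))
  with(cfg$mcmc, {
    stopifnot(burn_in < n_iterations, thinning >= 1,
              target_acceptance > 0, target_acceptance < 1)
  })
  stopifnot(cfg$transport$weights %in% c("none", "inverse_variance"),
            cfg$transport$n_draws >= 1000)
  if (!is.null(cfg$endmembers) && !inherits(cfg$endmembers,
                                            "endmember_set")) {
    em <- do.call(rbind.data.frame, cfg$endmembers)
    cfg$endmembers <- structure(
      tibble::as_tibble(em),
      tau_kyr = 0, sampling_year = C14_REFERENCE_YEAR,
      class = c("endmember_set", "tbl_df", "tbl", "data.frame"))
  }
  class(cfg) <- "run_config"
  cfg
}

#' Run the full cross-shelf pipeline
#'
#' Executes the analysis chain in order: the Monte-Carlo age-depth fit on
#' all stations with compound-specific ages; net transport times for
#' every station (from depth via the fitted slope); fine-fraction
#' correction and first-order decay fits for every pool with loading
#' columns; and dual-isotope source apportionment per station with the
#' active-layer endmember decayed by that station's transport time.
#' Stages whose inputs are absent are skipped with a notice. All stage
#' seeds derive from `config$seed`.
#'
#' @param stations A `station_table` (or a file path readable by
#'   [read_stations()]).
#' @param config A `run_config` (default [default_run_config()]).
#' @return A `shelfcarbon_results` list: `transport_model`,
#'   `transport_times` (tibble), `decay_fits` (named list),
#'   `apportionment` (tibble) and `manifest` (seeds, config hash,
#'   package version). If `config$output_dir` is set, result tables, fit
#'   summaries and the manifest are also written there.
#' @export
run_pipeline <- function(stations, config = default_run_config()) {
  if (is.character(stations)) stations <- read_stations(stations)
  stations <- validate_stations(stations)
  config <- validate_run_config(config)
  ems0 <- if (is.null(config$endmembers)) default_endmembers() else
    config$endmembers
  ffm <- fine_fraction_model(config$fine_fraction$form,
                             config$fine_fraction$coefficients,
                             config$fine_fraction$depth_range)
  if (ffm$form == "passthrough") {
    message("fine-fraction model: passthrough (no hydrodynamic-sorting ",
            "correction applied)")
  }

  dated <- !is.na(stations$csra_cal_age_kyr %||% rep(NA_real_,
                                                     nrow(stations)))
  if (sum(dated) < 3) {
    stop("pipeline needs at least 3 stations with compound-specific ages",
         call. = FALSE)
  }
  model <- fit_age_depth(stations$depth_m[dated],
                         stations$csra_cal_age_kyr[dated],
                         stations$csra_cal_age_sd_kyr[dated],
                         n_draws = config$transport$n_draws,
                         seed = config$seed,
                         weights = config$transport$weights,
                         station_id = stations$station_id[dated])
  tt <- transport_time_at_depth(model, stations$depth_m)
  transport_times <- tibble::tibble(
    station_id = stations$station_id,
    depth_m = stations$depth_m,
    tau_kyr = tt$tau_kyr,
    tau_sigma_kyr = tt$tau_sigma_kyr)

  # --- decay kinetics per pool ---
  pool_cols <- grep("^loading_(.*)(?<!_sd)$", names(stations), value = TRUE,
                    perl = TRUE)
  pools <- config$pools %||% sub("^loading_", "", pool_cols)
  decay_fits <- list()
  if (length(pools) == 0) {
    message("no pool loading columns found; decay stage skipped")
  }
  for (i in seq_along(pools)) {
    pn <- pools[i]
    lcol <- paste0("loading_", pn); scol <- paste0(lcol, "_sd")
    if (!all(c(lcol, scol) %in% names(stations))) {
      message("pool ", pn, " lacks loading columns; skipped")
      next
    }
    ok <- !is.na(stations[[lcol]]) & !is.na(stations[[scol]])
    corr <- vapply(which(ok), function(j) {
      predict_fine_fraction(ffm, stations$depth_m[j])
    }, numeric(1))
    series <- pool_series(pn,
                          transport_times$tau_kyr[ok],
                          transport_times$tau_sigma_kyr[ok],
                          stations[[lcol]][ok] * corr,
                          stations[[scol]][ok] * corr)
    mc <- mcmc_config(config$mcmc$n_iterations, config$mcmc$burn_in,
                      config$mcmc$thinning,
                      config$mcmc$target_acceptance,
                      seed = config$seed + 100L + i)
    decay_fits[[pn]] <- fit_decay(series, mc)
  }

  # --- source apportionment per station ---
  apportionment <- NULL
  has_iso <- all(c("d13c_toc", "d13c_toc_sd", "d14c_toc",
                   "d14c_toc_sd") %in% names(stations))
  if (!has_iso) {
    message("no bulk dual-isotope columns; apportionment stage skipped")
  } else {
    rows <- list()
    for (i in seq_len(nrow(stations))) {
      if (is.na(stations$d13c_toc[i]) || is.na(stations$d14c_toc[i])) next
      obs <- isotope_observation(stations$d13c_toc[i],
                                 stations$d13c_toc_sd[i],
                                 stations$d14c_toc[i],
                                 stations$d14c_toc_sd[i],
                                 stations$sampling_year[i])
      ems <- build_endmembers(ems0, tau_kyr = transport_times$tau_kyr[i],
                              sampling_year = stations$sampling_year[i])
      mc <- mcmc_config(config$mcmc$n_iterations, config$mcmc$burn_in,
                        config$mcmc$thinning,
                        config$mcmc$target_acceptance,
                        seed = config$seed + 200L + i)
      mix <- apportion_sample(obs, ems, mc)
      rows[[length(rows) + 1]] <- tibble::tibble(
        station_id = stations$station_id[i],
        f_AL = mix$fractions$mean[1], f_AL_sd = mix$fractions$sd[1],
        f_ICD = mix$fractions$mean[2], f_ICD_sd = mix$fractions$sd[2],
        f_marine = mix$fractions$mean[3],
        f_marine_sd = mix$fractions$sd[3],
        f_terr = mix$f_terr$value, f_terr_sd = mix$f_terr$sigma,
        acceptance_rate = mix$acceptance_rate, seed = mix$seed)
    }
    if (length(rows) > 0) apportionment <- dplyr::bind_rows(rows)
  }

  cfg_for_hash <- unclass(config)
  cfg_for_hash$output_dir <- NULL   # hash the science, not the destination
  manifest <- list(
    seed = config$seed,
    config_hash = rlang::hash(cfg_for_hash),
    package_version = as.character(utils::packageVersion("shelfcarbon")),
    n_stations = nrow(stations),
    stages = list(transport = TRUE, decay = length(decay_fits) > 0,
                  apportionment = !is.null(apportionment)))

  res <- structure(list(transport_model = model,
                        transport_times = transport_times,
                        decay_fits = decay_fits,
                        apportionment = apportionment,
                        manifest = manifest),
                   class = "shelfcarbon_results")
  if (!is.null(config$output_dir)) write_results(res, config$output_dir)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write pipeline results to a directory
#'
#' Emits `transport_times.csv`, `transport_model.json`,
#' `decay_fits.json`, `apportionment.csv` (when computed) and
#' `manifest.json`. Re-running with identical inputs and seeds
#' reproduces the files byte-identically.
#'
#' @param res A `shelfcarbon_results`.
#' @param dir Output directory (created if needed).
#' @export
write_results <- function(res, dir) {
  stopifnot(inherits(res, "shelfcarbon_results"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(res$transport_times, file.path(dir,
                                                  "transport_times.csv"))
  jsonlite::write_json(transport_model_summary(res$transport_model),
                       file.path(dir, "transport_model.json"),
                       auto_unbox = TRUE, digits = NA)
  if (length(res$decay_fits) > 0) {
    jsonlite::write_json(lapply(res$decay_fits, decay_fit_summary),
                         file.path(dir, "decay_fits.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(res$apportionment)) {
    readr::write_csv(res$apportionment, file.path(dir,
                                                  "apportionment.csv"))
  }
  jsonlite::write_json(res$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.shelfcarbon_results <- function(x, ...) {
  cat("shelfcarbon pipeline results (seed ", x$manifest$seed, ")\n",
      sep = "")
  print(x$transport_model)
  cat("Transport times for", nrow(x$transport_times), "stations\n")
  if (length(x$decay_fits) > 0) {
    for (f in x$decay_fits) {
      cat(sprintf("  %-16s k = %s kyr^-1, f_R = %s\n", f$pool_name,
                  format(f$k), format(f$f_r)))
    }
  }
  if (!is.null(x$apportionment)) {
    cat("Apportionment for", nrow(x$apportionment), "stations\n")
  }
  invisible(x)
}
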