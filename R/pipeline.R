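.known_config_keys <- c(
  "rates_csv", "habitat_csv", "baseline_grid_csv", "model_hist_grid_csv",
  "model_future_grid_csv", "out_dir", "seed", "rcp_label",
  "t_break_C", "cline_lat", "mass_g", "b0", "mass_exponent",
  "refuge_compare", "include_33",
  "res_t_min", "res_t_pref_min", "res_t_pref_max", "res_t_max")

#' Validate a pipeline run configuration
#'
#' A configuration is a named list (or a YAML file holding one) with any of
#' the keys: input paths (\code{rates_csv, habitat_csv, baseline_grid_csv,
#' model_hist_grid_csv, model_future_grid_csv}), \code{out_dir},
#' \code{seed}, \code{rcp_label} (metadata only), the [pibcm_config()]
#' fields and the RES envelope fields (\code{res_t_min} ...). Unknown keys
#' are rejected outright; referenced input paths must exist.
#'
#' @param config named list or path to a YAML file.
#' @return The validated config list (class \code{"run_config"}).
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop(sprintf("config file not found: %s", config), call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("'config' must be a list or a YAML path",
                             call. = FALSE)
  unknown <- setdiff(names(config), .known_config_keys)
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  for (k in intersect(names(config),
                      c("rates_csv", "habitat_csv", "baseline_grid_csv",
                        "model_hist_grid_csv", "model_future_grid_csv")))
    if (!file.exists(config[[k]]))
      stop(sprintf("config key '%s': file not found: %s", k, config[[k]]),
           call. = FALSE)
  structure(config, class = c("run_config", "list"))
}

.config_hash <- function(config) {
  f <- tempfile(fileext = ".yml")
  on.exit(unlink(f))
  yaml::write_yaml(config[order(names(config))], f)
  unname(tools::md5sum(f))
}

.cfg_pibcm <- function(config) {
  pibcm_config(
    t_break_C = config$t_break_C %||% 32,
    cline_lat = config$cline_lat %||% 40,
    mass_g = config$mass_g %||% 10,
    b0 = config$b0 %||% 14.47,
    mass_exponent = config$mass_exponent %||% 0.75,
    refuge_compare = config$refuge_compare %||% "contemporary",
    include_33 = config$include_33 %||% TRUE)
}

#' Run one stage of the habitat-projection pipeline
#'
#' Executes a named stage against the files in \code{config} and writes its
#' artifacts under \code{config$out_dir}:
#' \describe{
#'   \item{simulate}{generate a synthetic fixture bundle (acclimation
#'     rates, contemporary climatology, model pair, habitat map).}
#'   \item{fit-e}{Arrhenius fits per species/subpopulation from
#'     \code{rates_csv} to \code{fits.csv}.}
#'   \item{climatology}{extremes and SST range from
#'     \code{baseline_grid_csv} to \code{extremes.csv}.}
#'   \item{downscale}{delta-method downscaling of the model pair onto the
#'     baseline, to \code{downscaled.csv}.}
#'   \item{project}{the full chain: envelope E table, downscaling, cell
#'     states, habitat projection; writes \code{future_map.csv},
#'     \code{condition.csv}, \code{delta_map.csv} and a text report.}
#'   \item{res}{trapezoidal RES map of the (downscaled if a model pair is
#'     given, otherwise baseline) climatology, to \code{res_map.csv}.}
#' }
#' Every run writes \code{run_info.txt} with the package version, seed and
#' config hash.
#'
#' @param config a [run_config()] (or list / YAML path coercible to one).
#' @param command one of \code{"simulate"}, \code{"fit-e"},
#'   \code{"climatology"}, \code{"downscale"}, \code{"project"},
#'   \code{"res"}.
#' @param quiet suppress progress messages.
#' @return A list of the stage's main in-memory results, invisibly.
#' @export
run_pipeline <- function(config,
                         command = c("project", "simulate", "fit-e",
                                     "climatology", "downscale", "res"),
                         quiet = FALSE) {
  command <- match.arg(command)
  config <- run_config(config)
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()

  writeLines(c(
    sprintf("pibcm %s", as.character(utils::packageVersion("pibcm"))),
    sprintf("command: %s", command),
    sprintf("seed: %d", as.integer(seed)),
    sprintf("rcp_label: %s", config$rcp_label %||% ""),
    sprintf("config_hash: %s", .config_hash(unclass(config)))),
    file.path(out_dir, "run_info.txt"))

  result <- switch(command,
    "simulate" = {
      spec <- scenario_spec(seed = seed)
      say("simulate: generating scenario (seed %d)", seed)
      sc <- gen_coastal_sst(spec)
      clim <- monthly_climatology(sc$sst, sc$dates, sc$lat, sc$lon)
      clim_c <- coarsen(clim, as.integer(round(spec$grid_res /
                                                 spec$fine_res)))
      pair <- gen_model_pair(spec)
      acc <- gen_acclimation_data(seed = seed)
      utils::write.csv(acc, file.path(out_dir, "rates.csv"),
                       row.names = FALSE)
      write_grid_csv(clim_c, file.path(out_dir, "baseline.csv"))
      write_grid_csv(pair$hist, file.path(out_dir, "model_hist.csv"))
      write_grid_csv(pair$future, file.path(out_dir, "model_future.csv"))
      write_habitat_csv(sc$habitat, file.path(out_dir, "habitat.csv"))
      list(spec = spec, baseline = clim_c, pair = pair, habitat = sc$habitat)
    },
    "fit-e" = {
      d <- read_rate_csv(config$rates_csv)
      groups <- split(d, interaction(d$species, d$subpopulation,
                                     drop = TRUE))
      say("fit-e: %d dataset(s)", length(groups))
      fits <- lapply(groups, fit_arrhenius)
      write_fit_csv(fits, file.path(out_dir, "fits.csv"))
      list(fits = fits)
    },
    "climatology" = {
      clim <- read_grid_csv(config$baseline_grid_csv)
      ext <- extremes_and_range(clim)
      write_extremes_csv(ext, file.path(out_dir, "extremes.csv"))
      say("climatology: %d unmasked cells", sum(ext$mask))
      list(clim = clim, extremes = ext)
    },
    "downscale" = {
      base <- read_grid_csv(config$baseline_grid_csv)
      hist <- read_grid_csv(config$model_hist_grid_csv)
      fut <- read_grid_csv(config$model_future_grid_csv)
      down <- delta_downscale(hist, fut, base)
      write_grid_csv(down, file.path(out_dir, "downscaled.csv"))
      say("downscale: done on %d x %d grid",
          length(base$lat), length(base$lon))
      list(downscaled = down)
    },
    "project" = {
      cfg <- .cfg_pibcm(config)
      acc <- read_rate_csv(config$rates_csv)
      E_table <- build_envelope_E_table(acc, include_33 = cfg$include_33)
      base <- read_grid_csv(config$baseline_grid_csv)
      hist <- read_grid_csv(config$model_hist_grid_csv)
      fut <- read_grid_csv(config$model_future_grid_csv)
      down <- delta_downscale(hist, fut, base)
      habitat <- read_habitat_csv(config$habitat_csv)
      states <- cell_states(extremes_and_range(base),
                            extremes_and_range(down), E_table, cfg,
                            cells = habitat[c("lat", "lon")])
      proj <- project_habitat(habitat, states, cfg)
      write_habitat_csv(proj$future, file.path(out_dir, "future_map.csv"))
      utils::write.csv(
        data.frame(lat = proj$contemporary$lat, lon = proj$contemporary$lon,
                   condition = proj$condition,
                   dest_lat = ifelse(is.na(proj$destination), NA,
                                     proj$contemporary$lat[proj$destination]),
                   dest_lon = ifelse(is.na(proj$destination), NA,
                                     proj$contemporary$lon[proj$destination]),
                   overflow = proj$overflow, stranded = proj$stranded),
        file.path(out_dir, "condition.csv"), row.names = FALSE)
      delta <- probability_delta(proj$future, proj$contemporary)
      utils::write.csv(delta, file.path(out_dir, "delta_map.csv"),
                       row.names = FALSE)
      rep_path <- file.path(out_dir, "report.txt")
      sink(rep_path); print(proj); sink()
      say("project: %d cells, %d movers", proj$diagnostics$n_cells,
          proj$diagnostics$counts[["move_c3"]])
      list(projection = proj, E_table = E_table)
    },
    "res" = {
      env <- res_envelope(config$res_t_min %||% 5.63,
                          config$res_t_pref_min %||% 7.74,
                          config$res_t_pref_max %||% 21.97,
                          config$res_t_max %||% 27.05)
      clim <- if (!is.null(config$model_hist_grid_csv)) {
        delta_downscale(read_grid_csv(config$model_hist_grid_csv),
                        read_grid_csv(config$model_future_grid_csv),
                        read_grid_csv(config$baseline_grid_csv))
      } else read_grid_csv(config$baseline_grid_csv)
      map <- project_res_map(clim, env)
      write_habitat_csv(map, file.path(out_dir, "res_map.csv"))
      say("res: %d cells", nrow(map))
      list(res_map = map, envelope = env)
    })

  say("%s finished in %.2f s", command,
      as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(result)
}
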