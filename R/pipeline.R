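# End-to-end report: configuration, orchestration, CSV/JSON emission.

#' Run configuration
#'
#' Collects every tunable of the pipeline with full defaulting; unknown keys
#' are rejected so typos cannot silently fall back to defaults. All defaults
#' match the module-level defaults, and the whole resolved configuration is
#' echoed into the JSON summary for provenance.
#'
#' @param calendar path to the spawning calendar CSV (required for the
#'   synchrony/output stages).
#' @param nights optional monitoring-nights CSV path.
#' @param gametes optional gamete-record CSV path.
#' @param env optional hourly environmental CSV path.
#' @param out_dir directory for report files.
#' @param spawn_threshold,heavy_threshold spawn classification cuts.
#' @param weight_light `"auto"` or a fixed weight in (0, 1].
#' @param lunar_epoch reference new-moon date (enables lunar annotation).
#' @param synodic_days synodic month length.
#' @param participation_threshold main-spawning-period participation cut.
#' @param fragment_area_cm2,colony_area_cm2 output-scaling areas.
#' @param bin_width_um oocyte histogram bin width.
#' @param seed integer seed (recorded; the report itself is deterministic).
#' @return List of class `run_config`.
#' @export
run_config <- function(calendar = NULL, nights = NULL, gametes = NULL,
                       env = NULL, out_dir = tempfile("spawnsync-report-"),
                       spawn_threshold = 10, heavy_threshold = 200,
                       weight_light = "auto", lunar_epoch = NULL,
                       synodic_days = 29.530588,
                       participation_threshold = 0.30,
                       fragment_area_cm2 = 250, colony_area_cm2 = 10000,
                       bin_width_um = 25, seed = 1L) {
  cfg <- list(calendar = calendar, nights = nights, gametes = gametes,
              env = env, out_dir = out_dir,
              spawn_threshold = spawn_threshold,
              heavy_threshold = heavy_threshold,
              weight_light = weight_light, lunar_epoch = lunar_epoch,
              synodic_days = synodic_days,
              participation_threshold = participation_threshold,
              fragment_area_cm2 = fragment_area_cm2,
              colony_area_cm2 = colony_area_cm2,
              bin_width_um = bin_width_um, seed = as.integer(seed))
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose keys are the arguments of [run_config()];
#'   unknown keys are an error.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop_input("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  do.call(run_config, vals)
}

#' Run the full phenology report
#'
#' Strings the analysis stages together over the configured inputs and emits
#' (1) a per-species-per-year synchrony table (N, nights, D, light weight,
#' index), (2) cross-year season averages with fold ratio and percent
#' changes, (3) a reproductive-output table, (4) monthly oocyte size
#' histograms and stage frequencies, and (5) a predictor-ranking table —
#' each as CSV plus one JSON summary. Stages whose inputs are missing are
#' skipped with a warning; all values in the JSON are unrounded (rounding
#' happens only in rendered report strings).
#'
#' @param config a [run_config()] object (or path to a YAML config).
#' @return Invisibly, a list with the computed tables and the path of every
#'   file written.
#' @export
run_report <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$calendar)) stop_input("config needs a calendar path")
  if (!file.exists(config$calendar)) {
    stop_input("calendar file not found: %s", config$calendar)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  th <- class_thresholds(config$spawn_threshold, config$heavy_threshold)
  files <- character()

  raw <- utils::read.csv(config$calendar, stringsAsFactors = FALSE)
  species <- sort(unique(raw$species_id))
  campaigns <- list()
  for (sp in species) {
    yrs <- sort(unique(format(as.Date(raw$date[raw$species_id == sp]), "%Y")))
    for (yr in yrs) {
      sub <- raw[raw$species_id == sp &
                   format(as.Date(raw$date), "%Y") == yr, , drop = FALSE]
      tmp <- tempfile(fileext = ".csv")
      utils::write.csv(sub, tmp, row.names = FALSE, quote = FALSE)
      campaigns[[paste(sp, yr, sep = "/")]] <-
        read_calendar(tmp, species = sp, year = as.integer(yr),
                      nights = config$nights)
      unlink(tmp)
    }
  }

  sync_rows <- lapply(names(campaigns), function(key) {
    cmp <- campaigns[[key]]
    res <- campaign_synchrony(cmp, weight = config$weight_light,
                              thresholds = th)
    data.frame(species_id = cmp$species_id, year = cmp$year,
               n_colonies = res$n_colonies, n_nights = res$n_nights,
               total_spawner_days = res$total_spawner_days,
               weight_light = res$weight_light, index = res$index)
  })
  synchrony_table <- do.call(rbind, sync_rows)

  season_rows <- lapply(split(synchrony_table, synchrony_table$species_id),
                        function(d) {
    pc <- if (nrow(d) >= 2L) {
      d <- d[order(d$year), , drop = FALSE]
      percent_change(d$index[1L], d$index[nrow(d)])
    } else NA_real_
    data.frame(species_id = d$species_id[1L],
               season_average = season_average(d$index),
               percent_change = pc)
  })
  season_table <- do.call(rbind, season_rows)
  rownames(season_table) <- NULL
  fold <- if (nrow(season_table) >= 2L) {
    fold_ratio(max(season_table$season_average),
               min(season_table$season_average))
  } else NA_real_

  output_rows <- lapply(species, function(sp) {
    keys <- grep(paste0("^", sp, "/"), names(campaigns), value = TRUE)
    pooled <- do.call(rbind, lapply(campaigns[keys],
                                    function(cmp) cmp$observations))
    cmp0 <- campaigns[[keys[1L]]]
    pooled_campaign <- campaign(sp, cmp0$year,
                                unique(pooled$colony_id),
                                unique(pooled$date), pooled)
    output_table(pooled_campaign, config$fragment_area_cm2,
                 config$colony_area_cm2, thresholds = th)
  })
  output_tab <- do.call(rbind, output_rows)

  gamete_results <- NULL
  if (!is.null(config$gametes)) {
    if (!file.exists(config$gametes)) {
      warning(sprintf("gamete file not found, stage skipped: %s",
                      config$gametes), call. = FALSE)
    } else {
      g <- read_gametes(config$gametes)
      gamete_results <- lapply(split(g, g$species_id), function(d) {
        oo <- d[d$sex == "oocyte", , drop = FALSE]
        hist_by_month <- if (nrow(oo)) {
          lapply(split(oo$diameter_um, oo$month), bin_diameters,
                 bin_width_um = config$bin_width_um)
        } else NULL
        list(stage_frequency_oocyte = if (nrow(oo))
               monthly_stage_frequency(d, "oocyte") else NULL,
             stage_frequency_spermary = if (any(d$sex == "spermary"))
               monthly_stage_frequency(d, "spermary") else NULL,
             size_histograms = hist_by_month)
      })
    }
  }

  predictor_tab <- NULL
  if (!is.null(config$env)) {
    if (!file.exists(config$env)) {
      warning(sprintf("environmental file not found, stage skipped: %s",
                      config$env), call. = FALSE)
    } else if (is.null(gamete_results)) {
      warning("predictor stage needs gamete records (stage-IV months); skipped",
              call. = FALSE)
    } else {
      clim <- monthly_climatology(read_env(config$env))
      pred_rows <- lapply(species, function(sp) {
        keys <- grep(paste0("^", sp, "/"), names(campaigns), value = TRUE)
        g <- read_gametes(config$gametes, species = sp)
        stage4 <- unique(g$month[g$stage == "IV"])
        msp <- unique(unlist(lapply(campaigns[keys], main_spawning_months,
                                    stage4_months = stage4,
                                    participation_threshold =
                                      config$participation_threshold,
                                    thresholds = th)))
        spawn_cal_months <- unique(as.integer(substr(msp, 6, 7)))
        y <- as.integer(clim$month %in% spawn_cal_months)
        if (length(unique(y)) < 2L) return(NULL)
        fits <- list(sst = fit_spawning_logistic(y, clim$mean_sst_c),
                     irradiance = fit_spawning_logistic(y, clim$mean_irradiance))
        cbind(species_id = sp, rank_predictors(fits))
      })
      predictor_tab <- do.call(rbind, pred_rows)
    }
  }

  write_tab <- function(tab, name) {
    p <- file.path(config$out_dir, name)
    utils::write.csv(tab, p, row.names = FALSE)
    p
  }
  files <- c(files, write_tab(synchrony_table, "synchrony.csv"),
             write_tab(season_table, "season_summary.csv"),
             write_tab(output_tab, "output_estimates.csv"))
  if (!is.null(predictor_tab)) {
    files <- c(files, write_tab(predictor_tab, "predictor_ranking.csv"))
  }

  summary <- list(config = unclass(config),
                  synchrony = synchrony_table,
                  season = season_table,
                  fold_ratio = fold,
                  output = output_tab,
                  predictors = predictor_tab)
  json_path <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  files <- c(files, json_path)

  invisible(list(synchrony = synchrony_table, season = season_table,
                 fold_ratio = fold, output = output_tab,
                 gametes = gamete_results, predictors = predictor_tab,
                 files = files))
}
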