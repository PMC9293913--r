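# Seeded generators emulating the two observed spawning archetypes, plus
# stage-structured gamete cohorts and a seasonal environmental series.

#' Archetype parameters for the spawning-calendar generator
#'
#' Two behavioural archetypes are modelled. `"lunar_broadcaster"`: large
#' episodic spawning events concentrated on a few nights after the new moon
#' in two consecutive months, nearly all heavy, with bundle counts in the
#' thousands (lognormal, median ~8000). `"aperiodic_dribbler"`: a constant
#' low nightly spawn probability over a ~4-month season, mostly light spawns
#' of tens of bundles (mean ~64), occasional heavy spawns of a few hundred
#' (mean ~395), and at most `max_heavy_per_night` simultaneously heavy
#' colonies (default 3, matching the observed maximum of three of sixteen).
#' Bundle-count dispersion is unpublished; the lognormal CV of 0.5 is an
#' assumption, recorded in the parameter object.
#'
#' @param archetype `"lunar_broadcaster"` or `"aperiodic_dribbler"`.
#' @param n_colonies colonies monitored (10 broadcaster / 16 dribbler).
#' @param season length-2 date range (first, last monitored night).
#' @param lunar_window named numeric vector: per-night spawn probability at
#'   integer day offsets after new moon (broadcaster only).
#' @param baseline_nightly_prob nightly spawn probability outside the window
#'   (the dribbler's constant rate).
#' @param heavy_prob_given_spawn probability a spawn is heavy.
#' @param max_heavy_per_night cap on simultaneously heavy colonies; excess
#'   heavy spawns are demoted to light.
#' @param light_mean,light_cv,heavy_mean,heavy_cv lognormal bundle-count
#'   parameters (mean/CV); for the broadcaster `heavy_mean` is interpreted as
#'   the lognormal median.
#' @param species_id,year campaign labels.
#' @param seed integer seed; identical seed gives an identical calendar.
#' @return List of class `archetype_params`.
#' @export
archetype_params <- function(archetype = c("lunar_broadcaster",
                                           "aperiodic_dribbler"),
                             n_colonies = NULL, season = NULL,
                             lunar_window = NULL,
                             baseline_nightly_prob = NULL,
                             heavy_prob_given_spawn = NULL,
                             max_heavy_per_night = NULL,
                             light_mean = 64, light_cv = 0.5,
                             heavy_mean = NULL, heavy_cv = 0.5,
                             species_id = NULL, year = 2018L, seed = 1L) {
  archetype <- match.arg(archetype)
  if (archetype == "lunar_broadcaster") {
    if (is.null(n_colonies)) n_colonies <- 10L
    if (is.null(season)) season <- as.Date(c("2018-06-01", "2018-07-31"))
    if (is.null(lunar_window)) {
      lunar_window <- c("0" = 0.70, "1" = 0.45, "2" = 0.20, "3" = 0.10)
    }
    if (is.null(baseline_nightly_prob)) baseline_nightly_prob <- 0.01
    if (is.null(heavy_prob_given_spawn)) heavy_prob_given_spawn <- 0.95
    if (is.null(max_heavy_per_night)) max_heavy_per_night <- Inf
    if (is.null(heavy_mean)) heavy_mean <- 8000
    if (is.null(species_id)) species_id <- "broadcaster"
  } else {
    if (is.null(n_colonies)) n_colonies <- 16L
    if (is.null(season)) season <- as.Date(c("2018-06-01", "2018-09-30"))
    if (is.null(lunar_window)) lunar_window <- numeric()
    if (is.null(baseline_nightly_prob)) baseline_nightly_prob <- 0.08
    if (is.null(heavy_prob_given_spawn)) heavy_prob_given_spawn <- 0.25
    if (is.null(max_heavy_per_night)) max_heavy_per_night <- 3L
    if (is.null(heavy_mean)) heavy_mean <- 395
    if (is.null(species_id)) species_id <- "dribbler"
  }
  season <- as.Date(season)
  if (length(season) != 2L || anyNA(season) || season[2L] < season[1L]) {
    stop_input("season must be a valid (first, last) date pair")
  }
  probs <- c(lunar_window, baseline_nightly_prob, heavy_prob_given_spawn)
  if (any(probs < 0 | probs > 1)) stop_input("probabilities must lie in [0, 1]")
  structure(list(archetype = archetype, n_colonies = as.integer(n_colonies),
                 season = season, lunar_window = lunar_window,
                 baseline_nightly_prob = baseline_nightly_prob,
                 heavy_prob_given_spawn = heavy_prob_given_spawn,
                 max_heavy_per_night = max_heavy_per_night,
                 light_mean = light_mean, light_cv = light_cv,
                 heavy_mean = heavy_mean, heavy_cv = heavy_cv,
                 species_id = species_id, year = as.integer(year),
                 seed = as.integer(seed)),
            class = "archetype_params")
}

# lognormal parameterised by arithmetic mean and CV
lnorm_pars <- function(mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic spawning calendar
#'
#' Simulates nightly per-colony spawning over the season of `params`. Each
#' colony spawns independently each night with the archetype's probability
#' (lunar-window-driven for the broadcaster, constant for the dribbler); a
#' spawn is heavy with `heavy_prob_given_spawn`, subject to the per-night
#' heavy cap; light bundle counts are drawn lognormal and clamped into the
#' light classification band, heavy counts clamped above it. Deterministic
#' for a given seed, and every night of the season is a monitored night.
#'
#' @param params an [archetype_params()] object.
#' @param lunar a [lunar_calendar()]; required for the broadcaster, used only
#'   to locate the spawning window.
#' @param thresholds a [class_thresholds()] object (the clamping band).
#' @return A [campaign()] object.
#' @export
gen_calendar <- function(params, lunar = NULL,
                         thresholds = class_thresholds()) {
  stopifnot(inherits(params, "archetype_params"))
  nights <- seq(params$season[1L], params$season[2L], by = "day")
  if (length(nights) == 0L) stop_input("empty season")
  if (params$archetype == "lunar_broadcaster" && length(params$lunar_window)) {
    if (is.null(lunar)) stop_input("broadcaster generation needs a lunar calendar")
    offsets <- as.integer(names(params$lunar_window))
    day <- floor(lunar_age(nights, lunar))
    p_night <- ifelse(day %in% offsets,
                      params$lunar_window[as.character(day)],
                      params$baseline_nightly_prob)
  } else {
    p_night <- rep(params$baseline_nightly_prob, length(nights))
  }
  lp <- lnorm_pars(params$light_mean, params$light_cv)
  hp <- if (params$archetype == "lunar_broadcaster") {
    list(meanlog = log(params$heavy_mean),  # median in the thousands
         sdlog = sqrt(log(1 + params$heavy_cv^2)))
  } else {
    lnorm_pars(params$heavy_mean, params$heavy_cv)
  }
  colonies <- sprintf("%s-%02d", params$species_id, seq_len(params$n_colonies))
  obs <- with_stream(params$seed, "calendar", {
    rows <- vector("list", length(nights))
    for (i in seq_along(nights)) {
      spawned <- which(stats::runif(params$n_colonies) < p_night[i])
      if (length(spawned) == 0L) next
      heavy <- stats::runif(length(spawned)) < params$heavy_prob_given_spawn
      over <- sum(heavy) - params$max_heavy_per_night
      if (is.finite(params$max_heavy_per_night) && over > 0) {
        demote <- sample(which(heavy), over)
        heavy[demote] <- FALSE
      }
      count <- numeric(length(spawned))
      if (any(!heavy)) {
        count[!heavy] <- pmin(pmax(
          round(stats::rlnorm(sum(!heavy), lp$meanlog, lp$sdlog)),
          thresholds$spawn_threshold), thresholds$heavy_threshold)
      }
      if (any(heavy)) {
        count[heavy] <- pmax(
          round(stats::rlnorm(sum(heavy), hp$meanlog, hp$sdlog)),
          thresholds$heavy_threshold + 1)
      }
      rows[[i]] <- data.frame(colony_id = colonies[spawned],
                              date = nights[i], bundle_count = count,
                              is_estimate = heavy)
    }
    do.call(rbind, rows)
  })
  if (is.null(obs)) {
    obs <- data.frame(colony_id = character(), date = as.Date(character()),
                      bundle_count = numeric(), is_estimate = logical())
  }
  campaign(params$species_id, params$year, colonies, nights, obs)
}

#' Generate stage-structured gamete records
#'
#' Draws per-month developmental stages from supplied stage mixtures and, for
#' oocytes, a Feret diameter uniform within the drawn stage's size range
#' (stage IV capped at `stage4_cap_um`).
#'
#' @param mixtures named list: month label ("YYYY-MM") -> numeric vector of 4
#'   stage probabilities (I..IV), each summing to 1.
#' @param n_per_month records per month (recycled over months).
#' @param seed integer seed.
#' @param sex `"oocyte"` or `"spermary"` (spermaries get no diameter).
#' @param species_id species label.
#' @param n_colonies colonies the records are spread over.
#' @param stage4_cap_um upper diameter bound used for stage IV draws
#'   (default 700 um; the published range is open above 600).
#' @return Gamete record data frame (see [read_gametes()] for the dialect).
#' @export
gen_gametes <- function(mixtures, n_per_month, seed = 1L,
                        sex = c("oocyte", "spermary"),
                        species_id = "synthetic", n_colonies = 10L,
                        stage4_cap_um = 700) {
  sex <- match.arg(sex)
  if (length(mixtures) == 0L) stop_input("need at least one month")
  bad <- vapply(mixtures, function(p)
    length(p) != 4L || any(p < 0) || abs(sum(p) - 1) > 1e-8, TRUE)
  if (any(bad)) {
    stop_input("invalid stage mixture for month(s): %s",
               paste(names(mixtures)[bad], collapse = ", "))
  }
  n_per_month <- rep_len(n_per_month, length(mixtures))
  rules <- stage_rules()
  rules$upper_um[rules$stage == "IV"] <- stage4_cap_um
  with_stream(seed, "gametes", {
    rows <- lapply(seq_along(mixtures), function(i) {
      n <- n_per_month[i]
      if (n == 0L) return(NULL)
      stage <- sample(rules$stage, n, replace = TRUE, prob = mixtures[[i]])
      diam <- if (sex == "oocyte") {
        idx <- match(stage, rules$stage)
        stats::runif(n, rules$lower_um[idx], rules$upper_um[idx])
      } else {
        rep(NA_real_, n)
      }
      data.frame(colony_id = sprintf("%s-%02d", species_id,
                                     sample.int(n_colonies, n, replace = TRUE)),
                 species_id = species_id, month = names(mixtures)[i],
                 sex = sex, stage = stage, diameter_um = diam)
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) {
      out <- data.frame(colony_id = character(), species_id = character(),
                        month = character(), sex = character(),
                        stage = character(), diameter_um = numeric())
    }
    rownames(out) <- NULL
    out
  })
}

#' Generate an hourly environmental series
#'
#' Hourly sea-surface temperature and irradiance as annual sinusoids plus
#' Gaussian noise, with an optional station-outage gap (whole months removed).
#' Defaults emulate a subtropical embayment: SST mean 25.8 C, amplitude
#' 1.9 C peaking in early September (so mid-summer through early-autumn
#' months sit at or above ~25.6 C), irradiance peaking at the solstice.
#'
#' @param years integer vector of calendar years to simulate.
#' @param seed integer seed.
#' @param sst_mean,sst_amplitude,sst_peak_doy annual SST sinusoid (degrees C,
#'   peak day-of-year).
#' @param irr_mean,irr_amplitude,irr_peak_doy irradiance sinusoid.
#' @param sst_noise_sd,irr_noise_sd Gaussian noise standard deviations.
#' @param outage character vector of "YYYY-MM" months with no rows (station
#'   outage).
#' @return Environmental series data frame (see [read_env()]).
#' @export
gen_env <- function(years, seed = 1L, sst_mean = 25.8, sst_amplitude = 1.9,
                    sst_peak_doy = 245, irr_mean = 500, irr_amplitude = 250,
                    irr_peak_doy = 172, sst_noise_sd = 0.15,
                    irr_noise_sd = 40, outage = character()) {
  if (sst_amplitude < 0 || irr_amplitude < 0) {
    stop_input("amplitudes must be non-negative")
  }
  from <- as.POSIXct(sprintf("%d-01-01 00:00:00", min(years)), tz = "UTC")
  to <- as.POSIXct(sprintf("%d-12-31 23:00:00", max(years)), tz = "UTC")
  ts <- seq(from, to, by = "hour")
  ts <- ts[as.integer(format(ts, "%Y")) %in% years]
  if (length(outage)) {
    ts <- ts[!format(ts, "%Y-%m") %in% outage]
  }
  doy <- as.numeric(format(ts, "%j")) + as.numeric(format(ts, "%H")) / 24
  phase <- function(peak) cos(2 * pi * (doy - peak) / 365.2425)
  with_stream(seed, "env", {
    data.frame(
      timestamp = ts,
      sst_c = sst_mean + sst_amplitude * phase(sst_peak_doy) +
        stats::rnorm(length(ts), 0, sst_noise_sd),
      irradiance = irr_mean + irr_amplitude * phase(irr_peak_doy) +
        stats::rnorm(length(ts), 0, irr_noise_sd)
    )
  })
}
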