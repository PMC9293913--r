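# Lunar-age annotation of observation nights.

#' Lunar calendar (mean synodic month approximation)
#'
#' Lunar phase is modelled as elapsed days since a reference new moon, modulo
#' the mean synodic month (29.530588 d). This is accurate to about a day over
#' a few years, which matches the day-level resolution of spawning
#' observations; no ephemeris is used, and the epoch must be supplied
#' explicitly so the module stays testable without astronomical data.
#'
#' @param epoch_new_moon date (or ISO string) of a reference new moon.
#' @param synodic_days length of the synodic month in days.
#' @return An object of class `lunar_calendar`.
#' @export
lunar_calendar <- function(epoch_new_moon, synodic_days = 29.530588) {
  if (!is.finite(synodic_days) || synodic_days <= 0) {
    stop_input("synodic_days must be positive")
  }
  structure(list(epoch_new_moon = as.Date(epoch_new_moon),
                 synodic_days = synodic_days),
            class = "lunar_calendar")
}

#' Lunar age of calendar dates
#'
#' @param date `Date` vector (or ISO strings).
#' @param cal a [lunar_calendar()].
#' @return Days since new moon in `[0, synodic_days)`; 0 is new moon,
#'   `synodic_days / 2` is (approximately) full moon.
#' @export
lunar_age <- function(date, cal) {
  stopifnot(inherits(cal, "lunar_calendar"))
  delta <- as.numeric(as.Date(date) - cal$epoch_new_moon)
  delta %% cal$synodic_days
}

#' Spawner-nights per integer lunar day
#'
#' Tallies qualifying colony-nights (one per spawning colony per night, no
#' light/heavy weighting) into integer lunar-day bins 0..29. A lunar-cued mass
#' broadcaster piles its mass near day 0; an aperiodic dribbler spreads it
#' roughly uniformly.
#'
#' @param x a [campaign()] object.
#' @param cal a [lunar_calendar()].
#' @param classes spawn classes to count (default light and heavy).
#' @param thresholds a [class_thresholds()] object.
#' @return Integer vector of length 30 named "0".."29"; sums to the number of
#'   qualifying spawner-nights.
#' @export
lunar_day_histogram <- function(x, cal, classes = c("light", "heavy"),
                                thresholds = class_thresholds()) {
  stopifnot(inherits(x, "spawn_campaign"))
  bins <- stats::setNames(integer(30), as.character(0:29))
  obs <- x$observations
  if (nrow(obs) == 0L) return(bins)
  cls <- classify_spawn(obs$bundle_count, thresholds)
  keep <- cls %in% classes & cls != "none"
  if (!any(keep)) return(bins)
  day <- floor(lunar_age(obs$date[keep], cal))
  day <- pmin(day, 29)  # ages in [29, synodic) share the last bin
  tab <- table(factor(day, levels = 0:29))
  bins[] <- as.integer(tab)
  bins
}
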