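# Nightly per-colony spawning observations: data model, I/O, classification.

#' Spawn classification thresholds
#'
#' A colony-night counts as a spawn only when at least `spawn_threshold`
#' egg-sperm bundles were released; spawns are "light" when it is practical to
#' count the bundles (up to about `heavy_threshold`) and "heavy" beyond that.
#' The defaults are the field-standard 10 and ~200 bundle cuts; both are
#' approximate field judgements, hence configurable.
#'
#' @param spawn_threshold minimum bundles for a colony to count as having
#'   spawned (default 10, inclusive).
#' @param heavy_threshold largest bundle count still classed as a light spawn
#'   (default 200, inclusive; counts above it are heavy).
#' @return An object of class `class_thresholds`.
#' @examples
#' th <- class_thresholds()
#' classify_spawn(c(5, 10, 200, 400), th)
#' @export
class_thresholds <- function(spawn_threshold = 10L, heavy_threshold = 200L) {
  spawn_threshold <- as.numeric(spawn_threshold)
  heavy_threshold <- as.numeric(heavy_threshold)
  if (!(spawn_threshold > 0 && spawn_threshold <= heavy_threshold)) {
    stop_input("thresholds must satisfy 0 < spawn_threshold <= heavy_threshold (got %s, %s)",
               spawn_threshold, heavy_threshold)
  }
  structure(list(spawn_threshold = spawn_threshold,
                 heavy_threshold = heavy_threshold),
            class = "class_thresholds")
}

#' Classify bundle counts into none / light / heavy spawns
#'
#' A pure function of the count and the active thresholds: counts below
#' `spawn_threshold` are `"none"`, counts from `spawn_threshold` up to and
#' including `heavy_threshold` are `"light"`, and counts above it are
#' `"heavy"`. The boundary count equal to `heavy_threshold` classifies as
#' light because heavy spawning starts strictly beyond the (approximate) cut.
#'
#' @param bundle_count non-negative integer vector of egg-sperm bundle counts
#'   (visual estimates for heavy spawns are acceptable).
#' @param thresholds a [class_thresholds()] object.
#' @return An ordered factor with levels `none < light < heavy`.
#' @export
classify_spawn <- function(bundle_count, thresholds = class_thresholds()) {
  stopifnot(inherits(thresholds, "class_thresholds"))
  if (length(bundle_count) == 0L) {
    return(factor(character(), levels = spawn_classes(), ordered = TRUE))
  }
  if (any(!is.finite(bundle_count)) || any(bundle_count < 0)) {
    stop_input("bundle_count must be finite and non-negative")
  }
  cls <- ifelse(bundle_count < thresholds$spawn_threshold, "none",
                ifelse(bundle_count <= thresholds$heavy_threshold, "light", "heavy"))
  factor(cls, levels = spawn_classes(), ordered = TRUE)
}

#' @rdname classify_spawn
#' @export
spawn_classes <- function() c("none", "light", "heavy")

#' Construct a monitoring campaign
#'
#' A campaign is one species monitored over a fixed colony set and an ordered
#' set of nights. Observations are per colony-night bundle counts; a (colony,
#' night) pair absent from `observations` means "observed, zero bundles" as
#' long as the night is in `nights` — nights outside `nights` were not
#' monitored and never enter the synchrony denominator.
#'
#' @param species_id species label.
#' @param year campaign year (integer).
#' @param colonies character vector of colony ids monitored.
#' @param nights `Date` vector of monitored nights (deduplicated, sorted).
#' @param observations data frame with columns `colony_id`, `date` (`Date`),
#'   `bundle_count`, and optionally `is_estimate` (logical; does not affect
#'   classification).
#' @return An object of class `spawn_campaign`.
#' @export
campaign <- function(species_id, year, colonies, nights, observations) {
  nights <- sort(unique(as.Date(nights)))
  colonies <- unique(as.character(colonies))
  obs <- as.data.frame(observations)
  if (nrow(obs) > 0L) {
    required <- c("colony_id", "date", "bundle_count")
    missing_cols <- setdiff(required, names(obs))
    if (length(missing_cols)) {
      stop_input("observations missing column(s): %s",
                 paste(missing_cols, collapse = ", "))
    }
    obs$colony_id <- as.character(obs$colony_id)
    obs$date <- as.Date(obs$date)
    if (any(!obs$colony_id %in% colonies)) {
      stop_input("observation colony not in campaign colony set: %s",
                 paste(unique(setdiff(obs$colony_id, colonies)), collapse = ", "))
    }
    if (any(!obs$date %in% nights)) {
      stop_input("observation on a night outside the monitored set: %s",
                 paste(unique(format(obs$date[!obs$date %in% nights])), collapse = ", "))
    }
    if (anyDuplicated(obs[c("colony_id", "date")])) {
      stop_input("duplicate (colony, date) observation rows")
    }
    if (any(!is.finite(obs$bundle_count)) || any(obs$bundle_count < 0)) {
      stop_input("bundle_count must be finite and non-negative")
    }
    if (is.null(obs$is_estimate)) obs$is_estimate <- FALSE
    obs <- obs[order(obs$date, obs$colony_id), , drop = FALSE]
    rownames(obs) <- NULL
  } else {
    obs <- data.frame(colony_id = character(), date = as.Date(character()),
                      bundle_count = numeric(), is_estimate = logical())
  }
  structure(list(species_id = as.character(species_id),
                 year = as.integer(year),
                 colonies = colonies,
                 nights = nights,
                 observations = obs),
            class = "spawn_campaign")
}

#' @export
print.spawn_campaign <- function(x, ...) {
  cat(sprintf("Spawning campaign: %s, %d\n", x$species_id, x$year))
  cat(sprintf("  %d colonies, %d monitored nights (%s to %s)\n",
              length(x$colonies), length(x$nights),
              if (length(x$nights)) format(min(x$nights)) else "-",
              if (length(x$nights)) format(max(x$nights)) else "-"))
  cat(sprintf("  %d non-zero observations\n", nrow(x$observations)))
  invisible(x)
}

#' Read a spawning calendar CSV into a campaign
#'
#' The calendar dialect is `colony_id,species_id,date,bundle_count[,is_estimate]`
#' with ISO-8601 dates. Monitored nights are taken from a companion nights
#' table (`species_id,date`) when supplied; otherwise they are inferred as the
#' full calendar span between the first and last observed date, i.e. nightly
#' monitoring is assumed.
#'
#' @param path calendar CSV path.
#' @param species species to extract; may be omitted when the file holds one.
#' @param year campaign year; defaults to the year of the first observation.
#' @param nights optional `Date` vector or path to a nights CSV
#'   (`species_id,date`) listing the monitored nights.
#' @param colonies optional colony set; defaults to colonies present.
#' @return A [campaign()] object.
#' @export
read_calendar <- function(path, species = NULL, year = NULL, nights = NULL,
                          colonies = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("colony_id", "species_id", "date", "bundle_count")
  unknown <- setdiff(names(raw), c(required, "is_estimate"))
  if (length(unknown)) {
    stop_input("unknown calendar column(s): %s", paste(unknown, collapse = ", "))
  }
  if (length(setdiff(required, names(raw)))) {
    stop_input("calendar must have columns %s", paste(required, collapse = ","))
  }
  if (is.null(species)) {
    sp <- unique(raw$species_id)
    if (length(sp) > 1L) {
      stop_input("calendar holds %d species (%s); pass `species`",
                 length(sp), paste(sp, collapse = ", "))
    }
    species <- if (length(sp)) sp else "unknown"
  }
  rows <- if (nrow(raw)) raw[raw$species_id == species, , drop = FALSE] else raw
  if (nrow(rows)) {
    parsed <- as.Date(rows$date, format = "%Y-%m-%d")
    if (anyNA(parsed)) {
      bad <- which(is.na(parsed))[1L]
      stop_input("malformed date '%s' in calendar row %d", rows$date[bad], bad)
    }
    rows$date <- parsed
    if (any(!is.finite(rows$bundle_count)) || any(rows$bundle_count < 0)) {
      bad <- which(!is.finite(rows$bundle_count) | rows$bundle_count < 0)[1L]
      stop_input("negative or missing bundle_count in calendar row %d", bad)
    }
    dup <- anyDuplicated(rows[c("colony_id", "date")])
    if (dup) {
      stop_input("duplicate (colony,date) row for colony '%s' on %s",
                 rows$colony_id[dup], format(rows$date[dup]))
    }
  } else {
    rows$date <- as.Date(character())
  }
  if (is.character(nights) && length(nights) == 1L && file.exists(nights)) {
    ntab <- utils::read.csv(nights, stringsAsFactors = FALSE)
    nights <- as.Date(ntab$date[ntab$species_id == species])
  }
  if (is.null(nights)) {
    nights <- if (nrow(rows)) seq(min(rows$date), max(rows$date), by = "day")
              else as.Date(character())
  }
  if (is.null(year)) {
    year <- if (nrow(rows)) as.integer(format(min(rows$date), "%Y")) else NA_integer_
  }
  if (is.null(colonies)) colonies <- unique(rows$colony_id)
  campaign(species, year, colonies, nights,
           rows[setdiff(names(rows), "species_id")])
}

#' Write a campaign back to the calendar CSV dialect
#'
#' Inverse of [read_calendar()]: `read_calendar(write_calendar(x, f))`
#' reproduces `x` when the companion nights file is also written.
#'
#' @param x a [campaign()] object.
#' @param path output CSV path.
#' @param nights_path optional path for the companion monitoring-nights CSV.
#' @return `path`, invisibly.
#' @export
write_calendar <- function(x, path, nights_path = NULL) {
  stopifnot(inherits(x, "spawn_campaign"))
  obs <- x$observations
  out <- data.frame(colony_id = obs$colony_id,
                    species_id = rep(x$species_id, nrow(obs)),
                    date = format(obs$date, "%Y-%m-%d"),
                    bundle_count = obs$bundle_count,
                    is_estimate = obs$is_estimate)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  if (!is.null(nights_path)) {
    utils::write.csv(data.frame(species_id = rep(x$species_id, length(x$nights)),
                                date = format(x$nights, "%Y-%m-%d")),
                     nights_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Weighted nightly spawner counts
#'
#' For each monitored night t the weighted count is
#' d_t = (heavy spawners) + w * (light spawners), where w is the light-spawn
#' weight. Nights with no qualifying spawn contribute d_t = 0; the returned
#' series has one entry per monitored night, in order.
#'
#' @param x a [campaign()] object.
#' @param weight_light light-spawn weight in (0, 1]; 1 counts light and heavy
#'   spawns equally.
#' @param thresholds a [class_thresholds()] object.
#' @return Named numeric vector of d_t, names ISO dates of the nights.
#' @export
nightly_counts <- function(x, weight_light = 0.16,
                           thresholds = class_thresholds()) {
  stopifnot(inherits(x, "spawn_campaign"))
  if (!is.numeric(weight_light) || length(weight_light) != 1L ||
      !is.finite(weight_light) || weight_light <= 0 || weight_light > 1) {
    stop_input("weight_light must be a single number in (0, 1]")
  }
  d <- stats::setNames(numeric(length(x$nights)), format(x$nights, "%Y-%m-%d"))
  obs <- x$observations
  if (nrow(obs)) {
    cls <- classify_spawn(obs$bundle_count, thresholds)
    key <- format(obs$date, "%Y-%m-%d")
    heavy <- table(factor(key[cls == "heavy"], levels = names(d)))
    light <- table(factor(key[cls == "light"], levels = names(d)))
    d <- as.numeric(heavy) + weight_light * as.numeric(light)
    names(d) <- format(x$nights, "%Y-%m-%d")
  }
  d
}
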