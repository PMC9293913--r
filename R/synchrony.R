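# The weighted daily Marquis spawning-synchrony index and season summaries.

#' Light-spawn weight from mean bundle counts
#'
#' Light spawns enter the synchrony index as fractional colonies. The weight
#' is the average light-spawn bundle number divided by the average heavy-spawn
#' bundle number, i.e. the average contribution of a light spawn relative to a
#' heavy one (about 0.16 in the motivating dataset, reported as "16%").
#'
#' @param mean_light_bundles mean bundles per colony for light spawns (> 0).
#' @param mean_heavy_bundles mean bundles per colony for heavy spawns (> 0).
#' @return An object of class `light_weight` with the unrounded `ratio`.
#' @examples
#' w <- light_weight(64, 395)
#' report_percent(w)  # "16%"
#' @export
light_weight <- function(mean_light_bundles, mean_heavy_bundles) {
  if (!is.finite(mean_light_bundles) || mean_light_bundles <= 0) {
    stop_input("mean_light_bundles must be positive")
  }
  if (!is.finite(mean_heavy_bundles) || mean_heavy_bundles <= 0) {
    stop_input("mean_heavy_bundles must be positive (weight undefined otherwise)")
  }
  structure(list(ratio = mean_light_bundles / mean_heavy_bundles,
                 mean_light_bundles = mean_light_bundles,
                 mean_heavy_bundles = mean_heavy_bundles),
            class = "light_weight")
}

#' @export
print.light_weight <- function(x, ...) {
  cat(sprintf("Light-spawn weight: %.4f (%s; mean light %.1f / mean heavy %.1f bundles)\n",
              x$ratio, report_percent(x), x$mean_light_bundles,
              x$mean_heavy_bundles))
  invisible(x)
}

#' Marquis index of daily spawning synchrony
#'
#' S_M = sum_t (d_t / D) * p_t, where d_t is the (possibly weighted) number of
#' colonies spawning on night t, D = sum_t d_t is the total number of
#' spawner-days, and p_t = d_t / N is the proportion of the N monitored
#' colonies spawning that night. Equivalently S_M = sum(d_t^2) / (D * N). The
#' index is 1 when every colony spawned on a single shared night and tends to
#' 0 as spawning spreads thinly across nights. It is undefined (an error, not
#' 0) when no spawning occurred: absence of spawning is not asynchrony.
#'
#' @param d_series numeric vector of nightly spawner counts d_t, one per
#'   monitored night (zeros allowed).
#' @param n_colonies number of colonies monitored, N; constant for the
#'   campaign, so p_t = d_t / N even on nights when fewer were seen.
#' @param weight_light the light-spawn weight the series was computed with
#'   (metadata only; recorded in the result).
#' @return An object of class `synchrony_result`: `index`, `n_colonies`,
#'   `n_nights`, `total_spawner_days` (D), `weight_light`.
#' @examples
#' marquis_index(c(10), 10)$index        # 1: all colonies on one night
#' marquis_index(c(1, 1, 1, 1, 1), 10)$index  # 0.1
#' @export
marquis_index <- function(d_series, n_colonies, weight_light = NA_real_) {
  if (!is.numeric(d_series) || length(d_series) == 0L) {
    stop_input("d_series must be a non-empty numeric vector")
  }
  if (any(!is.finite(d_series)) || any(d_series < 0)) {
    stop_input("all d_t must be finite and non-negative")
  }
  if (!is.numeric(n_colonies) || n_colonies <= 0) {
    stop_input("n_colonies must be a positive integer")
  }
  if (any(d_series > n_colonies + 1e-9)) {
    stop_input("d_t cannot exceed the number of colonies monitored")
  }
  D <- sum(d_series)
  if (D == 0) {
    stop_input("no spawning in series: synchrony index undefined")
  }
  structure(list(index = sum(d_series^2) / (D * n_colonies),
                 n_colonies = as.integer(n_colonies),
                 n_nights = length(d_series),
                 total_spawner_days = D,
                 weight_light = weight_light),
            class = "synchrony_result")
}

#' @export
print.synchrony_result <- function(x, digits = 3, ...) {
  cat(sprintf("Marquis synchrony index: %s\n",
              format(round_half_away(x$index, digits), nsmall = digits)))
  cat(sprintf("  N = %d colonies, n = %d nights, D = %.3f spawner-days%s\n",
              x$n_colonies, x$n_nights, x$total_spawner_days,
              if (is.na(x$weight_light)) ""
              else sprintf(", light weight w = %.3f", x$weight_light)))
  invisible(x)
}

#' Campaign-level synchrony
#'
#' Composes [nightly_counts()] and [marquis_index()] over all monitored nights
#' of a campaign. With `weight = "auto"` the light-spawn weight is recomputed
#' from the campaign's own mean light and heavy bundle counts via
#' [light_weight()]; a fixed numeric weight (e.g. 0.16) can be supplied
#' instead, for example to pool the weight across years.
#'
#' @param x a [campaign()] object with at least one spawning night.
#' @param weight `"auto"`, a number in (0, 1], or a [light_weight()] object.
#' @param thresholds a [class_thresholds()] object.
#' @return A `synchrony_result` (see [marquis_index()]).
#' @export
campaign_synchrony <- function(x, weight = "auto",
                               thresholds = class_thresholds()) {
  stopifnot(inherits(x, "spawn_campaign"))
  if (inherits(weight, "light_weight")) weight <- weight$ratio
  if (identical(weight, "auto")) {
    cls <- classify_spawn(x$observations$bundle_count, thresholds)
    mean_light <- mean(x$observations$bundle_count[cls == "light"])
    mean_heavy <- mean(x$observations$bundle_count[cls == "heavy"])
    weight <- if (is.finite(mean_light) && is.finite(mean_heavy)) {
      min(1, light_weight(mean_light, mean_heavy)$ratio)
    } else {
      1  # only one spawn class present: nothing to down-weight
    }
  }
  d <- nightly_counts(x, weight_light = weight, thresholds = thresholds)
  marquis_index(d, length(x$colonies), weight_light = weight)
}

#' Average synchrony indices across years
#'
#' @param indices_by_year named numeric vector (or list) of per-year indices.
#' @return Arithmetic mean (unrounded); render with [report_index()].
#' @examples
#' season_average(c("2018" = 0.102, "2019" = 0.134))  # 0.118 -> "0.12"
#' @export
season_average <- function(indices_by_year) {
  v <- unlist(indices_by_year)
  if (length(v) == 0L) stop_input("need at least one yearly index")
  mean(v)
}

#' Fold ratio between two synchrony indices
#'
#' @param index_a,index_b positive indices; the result is `index_a / index_b`.
#' @return Unrounded fold ratio; render with [report_fold()].
#' @examples
#' fold_ratio(0.49, 0.12)  # 4.083..., reported as "4-fold"
#' @export
fold_ratio <- function(index_a, index_b) {
  if (!is.finite(index_a) || index_a <= 0 ||
      !is.finite(index_b) || index_b <= 0) {
    stop_input("fold ratio needs two positive values")
  }
  index_a / index_b
}

#' Percent change between two values
#'
#' @param old baseline value (> 0).
#' @param new new value.
#' @return `100 * (new - old) / old`, unrounded; render with
#'   [report_percent()].
#' @examples
#' percent_change(0.102, 0.134)  # 31.37..., reported "31%"
#' @export
percent_change <- function(old, new) {
  if (!is.finite(old) || old <= 0) stop_input("baseline value must be positive")
  100 * (new - old) / old
}

#' Render helpers for reported values
#'
#' All internal values are unrounded; rounding (half away from zero) happens
#' only at render time. `report_index()` renders to the conventional 2 or 3
#' decimals, `report_percent()` to the nearest integer percent, and
#' `report_fold()` to the nearest integer fold.
#'
#' @param x numeric value.
#' @param digits decimal places for `report_index`.
#' @return A character rendering.
#' @export
report_index <- function(x, digits = 2) {
  formatC(round_half_away(x, digits), format = "f", digits = digits)
}

#' @rdname report_index
#' @export
report_percent <- function(x) {
  # percent-scale input; a light_weight object is converted from its ratio
  if (inherits(x, "light_weight")) x <- 100 * x$ratio
  sprintf("%d%%", as.integer(round_half_away(x, 0)))
}

#' @rdname report_index
#' @export
report_fold <- function(x) {
  sprintf("%d-fold", as.integer(round_half_away(x, 0)))
}
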