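# Fragment-to-colony reproductive-output scaling.

#' Representative bundles-per-fragment value
#'
#' Summarises per-spawn bundle counts as their arithmetic mean and then rounds
#' the mean up to a representative "nice" reporting value on a configurable
#' grid (mantissas 1, 1.5, 2, 2.5, 3, 4, 5, 6, 7.5, 8 times powers of ten by
#' default, so e.g. a mean of 64 reports as 75 and a mean of 395 as 400).
#' This reporting rounding is editorial, not statistical: the raw mean is
#' always retained alongside.
#'
#' @param per_spawn_counts positive numeric vector of bundles per spawn.
#' @param grid ascending vector of admissible representative values; the
#'   smallest grid value at or above the mean is chosen.
#' @return List with `mean` (unrounded) and `representative` (grid value).
#' @examples
#' representative_bundles(c(60, 68))$representative  # 75
#' @export
representative_bundles <- function(per_spawn_counts, grid = reporting_grid()) {
  if (length(per_spawn_counts) == 0L) stop_input("need at least one count")
  if (any(!is.finite(per_spawn_counts)) || any(per_spawn_counts <= 0)) {
    stop_input("counts must be positive")
  }
  m <- mean(per_spawn_counts)
  grid <- sort(grid)
  at_or_above <- grid[grid >= m - 1e-9]
  if (length(at_or_above) == 0L) {
    stop_input("mean %.1f exceeds the reporting grid; extend `grid`", m)
  }
  list(mean = m, representative = at_or_above[1L])
}

#' @rdname representative_bundles
#' @export
reporting_grid <- function() {
  sort(as.vector(outer(c(1, 1.5, 2, 2.5, 3, 4, 5, 6, 7.5, 8), 10^(0:5))))
}

#' Scale fragment-level output to a whole colony
#'
#' Bundles released per fragment are scaled linearly by surface area to a
#' (typically 1 m^2 = 10,000 cm^2) adult colony:
#' bundles_per_colony = bundles_per_fragment * colony_area / fragment_area.
#'
#' @param bundles_per_fragment bundles released by the monitored fragment.
#' @param fragment_area_cm2 fragment surface area (default 250 cm^2).
#' @param colony_area_cm2 target colony surface area (default 10,000 cm^2).
#' @return Estimated bundles per colony (exact arithmetic, no rounding).
#' @examples
#' scale_output(75, 250, 10000)    # 3000  (light spawn)
#' scale_output(400, 250, 10000)   # 16000 (heavy spawn)
#' scale_output(8000, 250, 10000)  # 320000 (typical mass spawn)
#' @export
scale_output <- function(bundles_per_fragment, fragment_area_cm2 = 250,
                         colony_area_cm2 = 10000) {
  vals <- c(bundles_per_fragment, fragment_area_cm2, colony_area_cm2)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop_input("all inputs must be positive")
  }
  bundles_per_fragment * colony_area_cm2 / fragment_area_cm2
}

#' Fold difference between two colony-level outputs
#'
#' @param colony_a_bundles,colony_b_bundles positive bundle outputs.
#' @return `colony_a_bundles / colony_b_bundles`.
#' @examples
#' output_fold(320000, 16000)  # 20
#' @export
output_fold <- function(colony_a_bundles, colony_b_bundles) {
  if (!is.finite(colony_a_bundles) || colony_a_bundles <= 0 ||
      !is.finite(colony_b_bundles) || colony_b_bundles <= 0) {
    stop_input("outputs must be positive")
  }
  colony_a_bundles / colony_b_bundles
}

#' Reproductive-output table for a campaign
#'
#' Summarises a campaign's observed light/heavy (or typical) spawns into
#' representative bundles-per-fragment values and colony-level projections,
#' one row per spawn kind.
#'
#' @param x a [campaign()] object.
#' @param fragment_area_cm2,colony_area_cm2 areas used for scaling.
#' @param thresholds a [class_thresholds()] object.
#' @return Data frame with one row per spawn kind present: `species_id`,
#'   `spawn_kind`, `n_spawns`, `mean_bundles`, `bundles_per_fragment`
#'   (representative), `fragment_area_cm2`, `colony_area_cm2`,
#'   `bundles_per_colony`.
#' @export
output_table <- function(x, fragment_area_cm2 = 250, colony_area_cm2 = 10000,
                         thresholds = class_thresholds()) {
  stopifnot(inherits(x, "spawn_campaign"))
  obs <- x$observations
  cls <- classify_spawn(obs$bundle_count, thresholds)
  kinds <- intersect(c("light", "heavy"), unique(as.character(cls)))
  rows <- lapply(kinds, function(k) {
    rep_val <- representative_bundles(obs$bundle_count[cls == k])
    data.frame(species_id = x$species_id, spawn_kind = k,
               n_spawns = sum(cls == k),
               mean_bundles = rep_val$mean,
               bundles_per_fragment = rep_val$representative,
               fragment_area_cm2 = fragment_area_cm2,
               colony_area_cm2 = colony_area_cm2,
               bundles_per_colony = scale_output(rep_val$representative,
                                                 fragment_area_cm2,
                                                 colony_area_cm2))
  })
  do.call(rbind, rows)
}
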