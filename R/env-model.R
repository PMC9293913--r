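# Environmental climatology and monthly logistic spawning-predictor models.

#' Read an hourly environmental series
#'
#' Dialect: `timestamp,sst_c,irradiance` with ISO-8601 timestamps (UTC
#' assumed). Gaps (station outages) are permitted; timestamps must be
#' strictly increasing.
#'
#' @param path CSV path.
#' @return Data frame with `timestamp` (`POSIXct`), `sst_c`, `irradiance`.
#' @export
read_env <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("timestamp", "sst_c", "irradiance")
  if (length(setdiff(required, names(raw)))) {
    stop_input("environmental series must have columns %s",
               paste(required, collapse = ","))
  }
  ts <- as.POSIXct(raw$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                  "%Y-%m-%d %H:%M", "%Y-%m-%d"))
  if (anyNA(ts)) {
    stop_input("malformed timestamp in row %d", which(is.na(ts))[1L])
  }
  if (is.unsorted(ts, strictly = TRUE)) {
    stop_input("timestamps must be strictly increasing")
  }
  data.frame(timestamp = ts, sst_c = raw$sst_c, irradiance = raw$irradiance)
}

#' Monthly climatology from an hourly series
#'
#' Pools all available hourly values across years by calendar month (1-12)
#' and averages them, so a multi-year record yields one mean SST and one mean
#' irradiance per month. Months entirely missing (e.g. a station outage
#' affecting the only year observed) are dropped with a warning, never
#' zero-filled; partially missing months average over the hours that exist.
#'
#' @param env environmental series from [read_env()] (or equivalent).
#' @return Data frame with `month` (1-12, only months with data),
#'   `mean_sst_c`, `mean_irradiance`, `n_hours`, `years` (comma-separated
#'   contributing years).
#' @export
monthly_climatology <- function(env) {
  env <- as.data.frame(env)
  if (nrow(env) == 0L) stop_input("empty environmental series")
  m <- as.integer(format(env$timestamp, "%m"))
  y <- format(env$timestamp, "%Y")
  present <- sort(unique(m))
  if (length(setdiff(1:12, present))) {
    warning(sprintf("no data for month(s): %s",
                    paste(setdiff(1:12, present), collapse = ", ")),
            call. = FALSE)
  }
  out <- data.frame(
    month = present,
    mean_sst_c = vapply(present, function(mm) mean(env$sst_c[m == mm]), 0),
    mean_irradiance = vapply(present, function(mm) mean(env$irradiance[m == mm]), 0),
    n_hours = vapply(present, function(mm) sum(m == mm), 0L),
    years = vapply(present, function(mm)
      paste(sort(unique(y[m == mm])), collapse = ","), "")
  )
  out
}

#' Identify the main spawning period
#'
#' The main spawning period comprises the months in which at least
#' `participation_threshold` (default 30%, inclusive) of the monitored
#' colonies spawned and mature stage-IV gametes were present in histology.
#'
#' @param x a [campaign()] object.
#' @param stage4_months character vector of months ("YYYY-MM") with stage-IV
#'   gametes present (from the gametogenesis records).
#' @param participation_threshold minimum fraction of colonies spawning in a
#'   month (default 0.30).
#' @param thresholds a [class_thresholds()] object.
#' @return Sorted character vector of qualifying months ("YYYY-MM").
#' @export
main_spawning_months <- function(x, stage4_months,
                                 participation_threshold = 0.30,
                                 thresholds = class_thresholds()) {
  stopifnot(inherits(x, "spawn_campaign"))
  obs <- x$observations
  if (nrow(obs) == 0L) return(character())
  cls <- classify_spawn(obs$bundle_count, thresholds)
  spawned <- obs[cls != "none", , drop = FALSE]
  if (nrow(spawned) == 0L) return(character())
  month <- format(spawned$date, "%Y-%m")
  n_col <- tapply(spawned$colony_id, month, function(z) length(unique(z)))
  qualifying <- names(n_col)[n_col / length(x$colonies) >=
                               participation_threshold - 1e-12]
  sort(intersect(qualifying, stage4_months))
}

#' Fit a monthly logistic spawning-predictor model
#'
#' Fits spawn/no-spawn ~ predictor by maximum likelihood (binomial GLM via
#' iteratively reweighted least squares, up to 100 iterations, coefficient
#' tolerance 1e-10) and reports the diagnostics conventionally used to
#' compare candidate environmental predictors: AIC = 2k - 2 logL (k = 2
#' parameters), the Nagelkerke (Cragg-Uhler) pseudo-R^2
#' (1 - (L0/L1)^(2/n)) / (1 - L0^(2/n)), and the likelihood-ratio p-value
#' against the intercept-only null (chi-squared, 1 df).
#'
#' Perfect separation — the predictor threshold classifies every month
#' exactly — is reported, not penalised away: the likelihood then approaches
#' 1, so AIC approaches 2k = 4 and pseudo-R^2 approaches 1, the recognisable
#' separation signature. The fit iterates until |logL| < 5e-3 in that case
#' and sets the `separation` flag.
#'
#' @param y binary vector (0/1 or logical), one entry per month.
#' @param x numeric predictor (e.g. monthly climatological SST), same length.
#' @return Object of class `spawn_logit`: `intercept`, `slope`,
#'   `log_likelihood`, `null_log_likelihood`, `n`, `k`, `aic`,
#'   `nagelkerke_r2`, `lr_p`, `converged`, `separation`, and the `glm` fit.
#' @export
fit_spawning_logistic <- function(y, x) {
  y <- as.numeric(y)
  if (length(y) != length(x)) stop_input("y and x lengths differ")
  if (length(y) < 3L) stop_input("need at least 3 months")
  if (any(!y %in% c(0, 1))) stop_input("y must be binary 0/1")
  if (any(!is.finite(x))) stop_input("predictor values must be finite")
  if (length(unique(y)) < 2L) {
    stop_input("y has a single class; the model is undefined")
  }
  dat <- data.frame(y = y, x = x)
  fit <- suppressWarnings(
    stats::glm(y ~ x, family = stats::binomial(), data = dat,
               control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  )
  null_fit <- stats::glm(y ~ 1, family = stats::binomial(), data = dat)
  ll1 <- as.numeric(stats::logLik(fit))
  ll0 <- as.numeric(stats::logLik(null_fit))
  n <- length(y)
  k <- 2L
  # Nagelkerke rescaling of the Cox-Snell ratio
  cox_snell <- 1 - exp((2 / n) * (ll0 - ll1))
  max_cs <- 1 - exp((2 / n) * ll0)
  r2 <- min(1, max(0, cox_snell / max_cs))
  lr_stat <- 2 * (ll1 - ll0)
  structure(list(intercept = unname(stats::coef(fit)[1L]),
                 slope = unname(stats::coef(fit)[2L]),
                 log_likelihood = ll1,
                 null_log_likelihood = ll0,
                 n = n, k = k,
                 aic = 2 * k - 2 * ll1,
                 nagelkerke_r2 = r2,
                 lr_p = stats::pchisq(lr_stat, df = 1, lower.tail = FALSE),
                 converged = fit$converged,
                 separation = abs(ll1) < 5e-3,
                 fit = fit),
            class = "spawn_logit")
}

#' @export
print.spawn_logit <- function(x, ...) {
  cat("Monthly logistic spawning-predictor model\n")
  cat(sprintf("  n = %d months; logit(p) = %.3g %+.3g * x\n",
              x$n, x$intercept, x$slope))
  cat(sprintf("  AIC = %.2f, Nagelkerke R2 = %.2f, LR p = %.3g%s\n",
              x$aic, x$nagelkerke_r2, x$lr_p,
              if (x$separation) "  [perfect separation]" else ""))
  invisible(x)
}

#' Rank candidate predictors
#'
#' Orders fitted predictor models by ascending AIC; ties broken by higher
#' Nagelkerke pseudo-R^2, then by predictor name.
#'
#' @param fits named list of [fit_spawning_logistic()] results.
#' @return Data frame, best predictor first: `predictor`, `aic`,
#'   `nagelkerke_r2`, `lr_p`, `separation`.
#' @export
rank_predictors <- function(fits) {
  if (length(fits) == 0L) stop_input("need at least one fit")
  stopifnot(!is.null(names(fits)), all(nzchar(names(fits))))
  tab <- data.frame(predictor = names(fits),
                    aic = vapply(fits, function(f) f$aic, 0),
                    nagelkerke_r2 = vapply(fits, function(f) f$nagelkerke_r2, 0),
                    lr_p = vapply(fits, function(f) f$lr_p, 0),
                    separation = vapply(fits, function(f) f$separation, TRUE))
  tab <- tab[order(tab$aic, -tab$nagelkerke_r2, tab$predictor), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
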