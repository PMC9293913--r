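# Stage-classified oocyte/spermary records and their monthly summaries.

#' Developmental stage size rules
#'
#' The standard histological staging for gametogenesis uses four stages I-IV.
#' For oocytes each stage carries an approximate Feret-diameter range (um):
#' I ~20-70 (nucleus fills most of the oocyte), II ~50-300 (vitellogenesis
#' apparent), III ~200-500 (lipid vesicles, nucleus migrating), IV ~300-600+
#' (nucleus at the periphery; no upper bound). Adjacent ranges deliberately
#' overlap: stage is a morphological call, and size alone cannot classify.
#' Spermaries are staged by morphology only and carry no diameter rule.
#'
#' @return Data frame with columns `stage`, `lower_um`, `upper_um`.
#' @export
stage_rules <- function() {
  data.frame(stage = c("I", "II", "III", "IV"),
             lower_um = c(20, 50, 200, 300),
             upper_um = c(70, 300, 500, Inf))
}

#' Flag oocyte diameters inconsistent with their assigned stage
#'
#' Stages are microscopists' morphology calls; the size ranges only validate
#' them. A record is consistent when its diameter lies within the stage range
#' widened by a symmetric relative slack that absorbs the approximate ("~")
#' nature of the published ranges. Stage IV has no upper bound.
#'
#' @param records data frame of gamete records (see [read_gametes()]); only
#'   oocyte rows are meaningful here.
#' @param rules stage size rules, default [stage_rules()].
#' @param slack_fraction symmetric relative slack on the range ends
#'   (default 0.10).
#' @return Logical vector: `TRUE` = consistent, `FALSE` = flagged.
#' @export
validate_stage_size <- function(records, rules = stage_rules(),
                                slack_fraction = 0.10) {
  records <- as.data.frame(records)
  if (any(records$sex != "oocyte")) {
    stop_input("size validation applies to oocyte records only")
  }
  if (any(!is.finite(records$diameter_um)) || any(records$diameter_um <= 0)) {
    stop_input("oocyte records need positive diameters")
  }
  idx <- match(records$stage, rules$stage)
  if (anyNA(idx)) stop_input("unknown stage: %s",
                             paste(unique(records$stage[is.na(idx)]), collapse = ", "))
  lo <- rules$lower_um[idx] * (1 - slack_fraction)
  hi <- ifelse(is.finite(rules$upper_um[idx]),
               rules$upper_um[idx] * (1 + slack_fraction), Inf)
  records$diameter_um >= lo & records$diameter_um <= hi
}

#' Bin oocyte diameters into fixed-width size classes
#'
#' Left-closed, right-open bins of `bin_width_um` starting at 0 (the
#' conventional 25 um increments by default).
#'
#' @param diameters positive numeric vector of Feret diameters (um).
#' @param bin_width_um bin width, default 25.
#' @return Data frame with `lower_um`, `upper_um`, `count` covering 0 up to
#'   the largest occupied bin; counts sum to `length(diameters)`.
#' @export
bin_diameters <- function(diameters, bin_width_um = 25) {
  if (!is.finite(bin_width_um) || bin_width_um <= 0) {
    stop_input("bin width must be positive")
  }
  if (length(diameters) == 0L) {
    return(data.frame(lower_um = numeric(), upper_um = numeric(),
                      count = integer()))
  }
  if (any(!is.finite(diameters)) || any(diameters <= 0)) {
    stop_input("diameters must be positive")
  }
  idx <- floor(diameters / bin_width_um)
  tab <- table(factor(idx, levels = 0:max(idx)))
  data.frame(lower_um = (0:max(idx)) * bin_width_um,
             upper_um = (1:(max(idx) + 1)) * bin_width_um,
             count = as.integer(tab))
}

#' Monthly stage frequency (percent)
#'
#' Per sampling month, the percentage of records in each developmental stage.
#' Months are campaign labels like "2018-06" so multi-year studies do not
#' collide. Months with zero records are omitted (with a warning if they were
#' requested), never zero-filled.
#'
#' @param records gamete record data frame.
#' @param sex `"oocyte"` or `"spermary"`.
#' @return Matrix of percentages, rows = months present, columns = stages
#'   I-IV; every row sums to 100.
#' @export
monthly_stage_frequency <- function(records, sex = c("oocyte", "spermary")) {
  sex <- match.arg(sex)
  records <- as.data.frame(records)
  rows <- records[records$sex == sex, , drop = FALSE]
  if (nrow(rows) == 0L) stop_input("no %s records", sex)
  stages <- stage_rules()$stage
  bad <- setdiff(unique(rows$stage), stages)
  if (length(bad)) stop_input("unknown stage: %s", paste(bad, collapse = ", "))
  tab <- table(rows$month, factor(rows$stage, levels = stages))
  100 * sweep(unclass(tab), 1, rowSums(tab), "/")
}

#' One-way ANOVA of oocyte diameter by month, with Tukey HSD
#'
#' Diameters are square-root transformed by default (the customary variance
#' stabilisation for these right-skewed size data) and compared across
#' sampling months with a classical one-way ANOVA; pairwise month contrasts
#' use Tukey's HSD in its unbalanced (Tukey-Kramer) form at alpha = 0.05.
#'
#' @param records gamete record data frame; only oocyte rows are used.
#' @param transform transformation applied to diameters before the ANOVA
#'   (default `sqrt`; use `identity` for none).
#' @return Object of class `oocyte_anova`: `f_stat`, `df_between`,
#'   `df_within`, `p_value`, `group_means` (transformed scale), `tukey`
#'   (the month-by-month HSD table), and the underlying `aov` fit.
#' @export
oocyte_size_anova <- function(records, transform = sqrt) {
  records <- as.data.frame(records)
  rows <- records[records$sex == "oocyte", , drop = FALSE]
  if (nrow(rows) == 0L) stop_input("no oocyte records")
  n_by_month <- table(rows$month)
  if (length(n_by_month) < 2L) stop_input("need at least two months")
  if (any(n_by_month < 2L)) {
    stop_input("month(s) with fewer than 2 oocytes: %s",
               paste(names(n_by_month)[n_by_month < 2L], collapse = ", "))
  }
  dat <- data.frame(y = transform(rows$diameter_um),
                    month = factor(rows$month))
  fit <- stats::aov(y ~ month, data = dat)
  tab <- summary(fit)[[1L]]
  structure(list(f_stat = tab[["F value"]][1L],
                 df_between = tab[["Df"]][1L],
                 df_within = tab[["Df"]][2L],
                 p_value = tab[["Pr(>F)"]][1L],
                 group_means = c(tapply(dat$y, dat$month, mean)),
                 tukey = stats::TukeyHSD(fit, conf.level = 0.95)$month,
                 fit = fit),
            class = "oocyte_anova")
}

#' @export
print.oocyte_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA of (transformed) oocyte diameter by month\n"))
  cat(sprintf("  F_%d,%d = %.4g, p = %.3g\n",
              x$df_between, x$df_within, x$f_stat, x$p_value))
  cat(sprintf("  %d months; Tukey HSD table in $tukey\n",
              x$df_between + 1L))
  invisible(x)
}

#' Read a gamete record CSV
#'
#' Dialect: `colony_id,species_id,month,sex,stage[,diameter_um]` where `sex`
#' is `oocyte` or `spermary`, `stage` is I-IV, and `diameter_um` is required
#' for oocytes and must be absent/NA for spermaries.
#'
#' @param path CSV path.
#' @param species optional species filter.
#' @return Validated data frame of gamete records.
#' @export
read_gametes <- function(path, species = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("colony_id", "species_id", "month", "sex", "stage")
  if (length(setdiff(required, names(raw)))) {
    stop_input("gamete table must have columns %s",
               paste(required, collapse = ","))
  }
  if (is.null(raw$diameter_um)) raw$diameter_um <- NA_real_
  if (!is.null(species)) raw <- raw[raw$species_id == species, , drop = FALSE]
  if (any(!raw$sex %in% c("oocyte", "spermary"))) {
    stop_input("sex must be 'oocyte' or 'spermary'")
  }
  if (any(!raw$stage %in% stage_rules()$stage)) {
    stop_input("stage must be one of I, II, III, IV")
  }
  oo <- raw$sex == "oocyte"
  if (any(oo & (is.na(raw$diameter_um) | raw$diameter_um <= 0))) {
    stop_input("oocyte rows need a positive diameter_um")
  }
  if (any(!oo & !is.na(raw$diameter_um))) {
    stop_input("spermary rows must not carry a diameter")
  }
  rownames(raw) <- NULL
  raw
}
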