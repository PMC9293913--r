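# Shared fixtures and independent oracles.

# Build a small campaign from per-night bundle-count lists:
# nights = list("2018-06-01" = c(A = 400, B = 50), ...)
make_campaign <- function(nights, colonies = NULL, species = "sp",
                          year = 2018L, extra_nights = character()) {
  rows <- do.call(rbind, lapply(names(nights), function(d) {
    counts <- nights[[d]]
    if (length(counts) == 0L) return(NULL)
    data.frame(colony_id = names(counts), date = as.Date(d),
               bundle_count = unname(counts))
  }))
  if (is.null(colonies)) colonies <- unique(rows$colony_id)
  all_nights <- sort(unique(c(as.Date(names(nights)), as.Date(extra_nights))))
  if (is.null(rows)) {
    rows <- data.frame(colony_id = character(), date = as.Date(character()),
                       bundle_count = numeric())
  }
  campaign(species, year, colonies, all_nights, rows)
}

# Definition-form oracle for the synchrony index: sum over nights of
# (d_t / D) * (d_t / N), computed term by term, independent of the
# closed-form sum(d^2)/(D*N) used by the implementation.
marquis_oracle <- function(d, n_colonies) {
  D <- sum(d)
  s <- 0
  for (t in seq_along(d)) s <- s + (d[t] / D) * (d[t] / n_colonies)
  s
}

# All non-negative integer d-series with given total D spread over n nights.
compositions <- function(total, n_parts) {
  if (n_parts == 1L) return(matrix(total, ncol = 1L))
  out <- NULL
  for (first in 0:total) {
    rest <- compositions(total - first, n_parts - 1L)
    out <- rbind(out, cbind(first, rest))
  }
  unname(out)
}

# Brute-force one-way ANOVA from the explicit sum-of-squares decomposition.
anova_oracle <- function(values, groups) {
  groups <- as.character(groups)
  grand <- mean(values)
  ss_between <- 0
  ss_within <- 0
  for (g in unique(groups)) {
    v <- values[groups == g]
    ss_between <- ss_between + length(v) * (mean(v) - grand)^2
    ss_within <- ss_within + sum((v - mean(v))^2)
  }
  df_b <- length(unique(groups)) - 1L
  df_w <- length(values) - length(unique(groups))
  f <- (ss_between / df_b) / (ss_within / df_w)
  list(f = f, df_between = df_b, df_within = df_w,
       ss_between = ss_between, ss_within = ss_within,
       ss_total = sum((values - grand)^2))
}

# Dense grid-search oracle for the 2-parameter logistic MLE log-likelihood.
logit_grid_loglik <- function(y, x, lim = 10, step = 0.05) {
  b0 <- seq(-lim, lim, by = step)
  b1 <- seq(-lim, lim, by = step)
  best <- -Inf
  for (a in b0) {
    eta <- a + outer(x, b1)          # n x length(b1)
    p <- 1 / (1 + exp(-eta))
    ll <- colSums(y * log(p) + (1 - y) * log(1 - p))
    best <- max(best, max(ll))
  }
  best
}
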