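test_that("marquis index matches hand-derived values", {
  expect_equal(marquis_index(10, 10)$index, 1)
  expect_equal(marquis_index(rep(1, 5), 10)$index, 0.1)
  expect_equal(marquis_index(c(3, 1), 4)$index, 0.625)
  res <- marquis_index(c(3, 1), 4)
  expect_equal(res$total_spawner_days, 4)
  expect_equal(res$n_nights, 2L)
})

test_that("index is undefined without spawning and validates inputs", {
  expect_error(marquis_index(c(0, 0, 0), 10), "undefined")
  expect_error(marquis_index(c(-1, 2), 10), "non-negative")
  expect_error(marquis_index(c(5, 2), 4), "cannot exceed")
})

test_that("closed form equals the definition-form oracle exhaustively", {
  # every d-series with total spawner-days D <= 6 over up to 4 nights, N <= 4
  for (N in 1:4) {
    for (D in 1:6) {
      for (n_nights in 1:4) {
        for (i in seq_len(nrow(compositions(D, n_nights)))) {
          d <- compositions(D, n_nights)[i, ]
          if (any(d > N)) next
          expect_equal(marquis_index(d, N)$index, marquis_oracle(d, N),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("index is bounded by the largest nightly proportion", {
  set.seed(42)
  for (rep in 1:200) {
    N <- sample(2:20, 1)
    n <- sample(1:30, 1)
    d <- sample(0:N, n, replace = TRUE)
    if (sum(d) == 0) d[1] <- 1
    s <- marquis_index(d, N)$index
    expect_gt(s, 0)
    expect_lte(s, max(d) / N + 1e-12)
    expect_lte(s, 1)
  }
})

test_that("index is 1 exactly when every spawning night is at full participation", {
  expect_equal(marquis_index(c(0, 7, 0), 7)$index, 1)
  expect_lt(marquis_index(c(0, 6, 0), 7)$index, 1)   # partial night
  # two full-participation nights still give 1 ("the same days", plural)
  expect_equal(marquis_index(c(7, 7), 7)$index, 1)
  expect_lt(marquis_index(c(7, 1), 7)$index, 1)      # any partial night breaks it
})

test_that("concentrating spawner-days never decreases the index", {
  # move one spawner-day from a lower night onto the highest night
  for (N in 2:4) {
    for (D in 2:6) {
      comps <- compositions(D, 3)
      for (i in seq_len(nrow(comps))) {
        d <- comps[i, ]
        if (any(d > N)) next
        hi <- which.max(d)
        lo <- which(d > 0 & seq_along(d) != hi)
        if (length(lo) == 0 || d[hi] >= N) next
        d2 <- d
        d2[lo[1]] <- d2[lo[1]] - 1
        d2[hi] <- d2[hi] + 1
        expect_gte(marquis_index(d2, N)$index + 1e-12,
                   marquis_index(d, N)$index)
      }
    }
  }
})

test_that("uniform weighting scales the index linearly", {
  set.seed(7)
  for (rep in 1:50) {
    N <- sample(4:20, 1)
    d <- sample(0:N, 10, replace = TRUE)
    if (sum(d) == 0) d[2] <- 2
    w <- runif(1, 0.05, 1)
    expect_equal(marquis_index(w * d, N)$index,
                 w * marquis_index(d, N)$index, tolerance = 1e-12)
  }
})

test_that("duplicating a campaign's d-pattern reproduces the oracle", {
  # concatenating identical d-patterns doubles both sum(d^2) and D, so the
  # index is unchanged; checked against the brute-force oracle, not algebra
  d <- c(3, 1, 0, 2)
  N <- 4
  expect_equal(marquis_index(c(d, d), N)$index, marquis_oracle(c(d, d), N),
               tolerance = 1e-12)
  expect_equal(marquis_index(c(d, d), N)$index, marquis_index(d, N)$index,
               tolerance = 1e-12)
})

test_that("light-spawn weight derives from mean bundle counts", {
  w <- light_weight(64, 395)
  expect_equal(w$ratio, 64 / 395)
  expect_equal(report_percent(w), "16%")
  expect_equal(light_weight(100, 100)$ratio, 1)
  expect_error(light_weight(64, 0), "positive")
  expect_error(light_weight(0, 395), "positive")
})

test_that("campaign synchrony composes counts and index", {
  # all N colonies heavy on a single night -> perfect synchrony
  cmp <- make_campaign(list("2018-06-01" = c(A = 400, B = 300, C = 250)),
                       extra_nights = c("2018-06-02", "2018-06-03"))
  expect_equal(campaign_synchrony(cmp, weight = 0.16)$index, 1)

  # replacing every heavy by light scales the index by exactly w
  heavy_nights <- list("2018-06-01" = c(A = 400, B = 300),
                       "2018-06-04" = c(A = 250))
  light_nights <- list("2018-06-01" = c(A = 40, B = 30),
                       "2018-06-04" = c(A = 25))
  w <- 0.16
  s_heavy <- campaign_synchrony(make_campaign(heavy_nights), weight = w)$index
  s_light <- campaign_synchrony(make_campaign(light_nights), weight = w)$index
  expect_equal(s_light, w * s_heavy, tolerance = 1e-12)

  # auto weight recomputes from the campaign's own means: 64/395 here
  mixed <- make_campaign(list("2018-06-01" = c(A = 395, B = 64)))
  res <- campaign_synchrony(mixed, weight = "auto")
  expect_equal(res$weight_light, 64 / 395)
})

test_that("season summaries render to the conventional precision", {
  expect_equal(season_average(c(`2018` = 0.102, `2019` = 0.134)), 0.118)
  expect_equal(report_index(0.118), "0.12")
  # 0.495 rounds half away from zero; both printed renderings are defensible
  expect_true(report_index(season_average(c(0.47, 0.52))) %in%
                c("0.49", "0.50"))
  expect_equal(season_average(0.3), 0.3)
  expect_error(season_average(numeric()), "at least one")

  expect_equal(fold_ratio(0.49, 0.12), 0.49 / 0.12)
  expect_equal(report_fold(fold_ratio(0.49, 0.12)), "4-fold")
  expect_equal(fold_ratio(0.2, 0.2), 1)
  expect_equal(fold_ratio(0.134, 0.102), 0.134 / 0.102)
  expect_error(fold_ratio(0.1, 0), "positive")

  expect_equal(percent_change(0.102, 0.134), 100 * 0.032 / 0.102)
  expect_equal(report_percent(percent_change(0.102, 0.134)), "31%")
  expect_equal(report_percent(percent_change(0.47, 0.52)), "11%")
  expect_equal(percent_change(0.3, 0.3), 0)
  expect_error(percent_change(0, 0.1), "positive")
})
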