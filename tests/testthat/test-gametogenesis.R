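test_that("stage size validation flags diameters outside the stage range", {
  rec <- data.frame(colony_id = "A", species_id = "sp", month = "2018-06",
                    sex = "oocyte",
                    stage = c("IV", "I", "II", "I", "III"),
                    diameter_um = c(450, 450, 60, 20, 800))
  ok <- validate_stage_size(rec)
  expect_equal(ok, c(TRUE,    # stage IV has no upper bound
                     FALSE,   # 450 um far beyond stage I's ~20-70
                     TRUE,    # stage II overlaps stage I: 60 um legal
                     TRUE,    # at the lower bound
                     FALSE))  # beyond 500 * 1.1
  # slack widens the accepted band
  rec2 <- data.frame(sex = "oocyte", stage = "I", diameter_um = 75)
  expect_false(validate_stage_size(rec2, slack_fraction = 0))
  expect_true(validate_stage_size(rec2, slack_fraction = 0.10))
  expect_error(validate_stage_size(data.frame(sex = "spermary", stage = "I",
                                              diameter_um = NA)),
               "oocyte records only")
})

test_that("diameter binning uses left-closed 25 um bins from zero", {
  h <- bin_diameters(c(30, 55, 60))
  expect_equal(h$count[h$lower_um == 25], 1L)
  expect_equal(h$count[h$lower_um == 50], 2L)
  expect_equal(sum(h$count), 3L)
  # boundary value goes into the right-hand (left-closed) bin
  expect_equal(bin_diameters(25)$count, c(0L, 1L))
  expect_equal(nrow(bin_diameters(numeric())), 0L)
  set.seed(1)
  d <- runif(1000, 20, 620)
  expect_equal(sum(bin_diameters(d)$count), 1000L)
  expect_error(bin_diameters(c(10, -2)), "positive")
})

test_that("monthly stage frequencies are percentages summing to 100", {
  rec <- data.frame(colony_id = "A", species_id = "sp",
                    month = c(rep("2018-05", 4), rep("2018-06", 2)),
                    sex = "oocyte",
                    stage = c("I", "I", "II", "IV", "IV", "IV"),
                    diameter_um = 100)
  f <- monthly_stage_frequency(rec, "oocyte")
  expect_equal(unname(f["2018-05", ]), c(50, 25, 0, 25))
  expect_equal(unname(f["2018-06", "IV"]), 100)
  expect_equal(unname(rowSums(f)), rep(100, 2), tolerance = 1e-9)
  # permutation invariance in record order
  perm <- rec[sample(nrow(rec)), ]
  expect_equal(monthly_stage_frequency(perm, "oocyte"), f)
})

test_that("generated stage mixtures are recovered within sampling error", {
  mix <- list("2018-06" = c(0.1, 0.2, 0.3, 0.4))
  g <- gen_gametes(mix, n_per_month = 10000, seed = 5)
  f <- monthly_stage_frequency(g, "oocyte")
  expect_equal(unname(f["2018-06", ]), c(10, 20, 30, 40), tolerance = 0.2)
})

test_that("oocyte ANOVA matches hand computation on a tiny dataset", {
  rec <- data.frame(colony_id = "A", species_id = "sp",
                    month = rep(c("m1", "m2"), each = 3),
                    sex = "oocyte", stage = "II",
                    diameter_um = c(1, 2, 3, 4, 5, 6))
  a <- oocyte_size_anova(rec, transform = identity)
  expect_equal(a$f_stat, 13.5)          # SSB = 13.5, SSW = 4, F = 13.5/1
  expect_equal(a$df_between, 1L)
  expect_equal(a$df_within, 4L)
  expect_equal(unname(a$group_means), c(2, 5))
  # identical groups: no between-group variance
  rec$diameter_um <- rep(c(1, 2, 3), 2)
  expect_equal(oocyte_size_anova(rec, transform = identity)$f_stat, 0)
})

test_that("ANOVA agrees with the sum-of-squares oracle on random data", {
  set.seed(99)
  for (rep in 1:10) {
    k <- sample(3:6, 1)
    n_per <- sample(3:8, k, replace = TRUE)
    rec <- data.frame(colony_id = "A", species_id = "sp",
                      month = rep(sprintf("m%02d", seq_len(k)), n_per),
                      sex = "oocyte", stage = "II",
                      diameter_um = exp(rnorm(sum(n_per), 5, 0.4)))
    a <- oocyte_size_anova(rec)   # sqrt transform, as in the analysis
    o <- anova_oracle(sqrt(rec$diameter_um), rec$month)
    expect_equal(a$f_stat, o$f, tolerance = 1e-9)
    expect_equal(a$df_between, o$df_between)
    expect_equal(a$df_within, o$df_within)
    expect_equal(o$ss_between + o$ss_within, o$ss_total, tolerance = 1e-9)
  }
})

test_that("a 10-month, 1297-oocyte design yields the (9, 1287) df structure", {
  months <- sprintf("2018-%02d", 1:10)
  n_per <- c(130, 130, 130, 130, 130, 130, 130, 130, 130, 127)
  mix <- stats::setNames(rep(list(c(0.25, 0.25, 0.25, 0.25)), 10), months)
  g <- gen_gametes(mix, n_per_month = n_per, seed = 21)
  a <- oocyte_size_anova(g)
  expect_equal(a$df_between, 9L)
  expect_equal(a$df_within, 1287L)
})

test_that("Tukey HSD is symmetric and null under equal means", {
  months <- c("m1", "m2", "m3")
  # identical within-group values: group means exactly equal, diffs exactly 0
  rec <- data.frame(colony_id = "A", species_id = "sp",
                    month = rep(months, each = 30),
                    sex = "oocyte", stage = "II",
                    diameter_um = rep(seq(90, 110, length.out = 30), 3))
  a <- oocyte_size_anova(rec, transform = identity)
  expect_true(all(a$tukey[, "p adj"] > 0.99))
  # unbalanced groups are handled (Tukey-Kramer)
  rec2 <- rec[-(1:10), ]
  a2 <- oocyte_size_anova(rec2, transform = identity)
  expect_equal(nrow(a2$tukey), 3L)
})

test_that("ANOVA input validation names the offending month", {
  rec <- data.frame(colony_id = "A", species_id = "sp",
                    month = c("m1", "m1", "m2"),
                    sex = "oocyte", stage = "II", diameter_um = c(1, 2, 3))
  expect_error(oocyte_size_anova(rec), "m2")
})

test_that("gamete CSV reader enforces the dialect", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("colony_id,species_id,month,sex,stage,diameter_um",
               "A,sp,2018-06,oocyte,IV,450",
               "A,sp,2018-06,spermary,III,"), f)
  g <- read_gametes(f)
  expect_equal(nrow(g), 2L)
  expect_true(is.na(g$diameter_um[2]))
  writeLines(c("colony_id,species_id,month,sex,stage,diameter_um",
               "A,sp,2018-06,oocyte,V,450"), f)
  expect_error(read_gametes(f), "stage")
  writeLines(c("colony_id,species_id,month,sex,stage,diameter_um",
               "A,sp,2018-06,oocyte,IV,"), f)
  expect_error(read_gametes(f), "positive diameter")
  unlink(f)
})
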