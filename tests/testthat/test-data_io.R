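test_that("gosling reader passes valid rows through and filters the capture window", {
  path <- gosling_csv()
  expect_message(recs <- read_gosling_records(path), "dropped 1")
  expect_equal(nrow(recs), 3)                       # age 50 dropped
  expect_equal(attr(recs, "n_rejected"), 1)
  expect_equal(recs$mass_g, c(500, 610, 820))
  # n_in = n_out + n_rejected
  expect_equal(nrow(read.csv(path)), nrow(recs) + attr(recs, "n_rejected"))
})

test_that("gosling reader filtering is idempotent", {
  path <- gosling_csv()
  suppressMessages(once <- read_gosling_records(path))
  path2 <- write_temp_csv(once)
  twice <- read_gosling_records(path2)
  expect_equal(attr(twice, "n_rejected"), 0)
  expect_equal(twice$mass_g, once$mass_g)
})

test_that("gosling reader rejects degenerate or malformed files", {
  empty <- write_temp_csv(data.frame(id = character(), year = numeric(),
                                     age_days = numeric(), mass_g = numeric()))
  expect_error(read_gosling_records(empty), "no gosling records")
  nocol <- write_temp_csv(data.frame(id = "a", year = 1990, mass_g = 500))
  expect_error(read_gosling_records(nocol), "age_days")
  allbad <- write_temp_csv(data.frame(id = "a", year = 1990, age_days = 50,
                                      mass_g = 500))
  expect_error(suppressMessages(read_gosling_records(allbad)), "filtered")
})

test_that("photo reader validates the binomial invariant", {
  good <- write_temp_csv(data.frame(year = 1991, points_total = 100,
                                    points_lawn = 4))
  p <- read_photo_samples(good)
  expect_equal(p$points_lawn, 4)
  bad <- write_temp_csv(data.frame(year = c(1991, 1993, 1994),
                                   points_total = c(100, 180, 180),
                                   points_lawn = c(4, 181, 12)))
  expect_error(read_photo_samples(bad), "row 2")
  expect_message(kept <- read_photo_samples(bad, on_invalid = "drop"),
                 "dropped 1")
  expect_equal(nrow(kept), 2)
  expect_equal(attr(kept, "n_rejected"), 1)
})

test_that("behavior reader applies the 30-minute bout filter", {
  d <- rbind(bout_row(1990, "gosling", 60, 60, foraging = 42, resting = 8),
             bout_row(1990, "gosling", 25, 25, foraging = 20),
             bout_row(1991, "female", 45, 45, foraging = 30, alert = 10))
  path <- write_temp_csv(d)
  expect_message(bouts <- read_behavior_bouts(path), "excluded 1")
  expect_equal(nrow(bouts), 2)
  expect_equal(attr(bouts, "n_rejected"), 1)
  # bout exactly at the threshold is retained
  at30 <- write_temp_csv(bout_row(1990, "male", 30, 30, foraging = 10))
  expect_equal(nrow(read_behavior_bouts(at30)), 1)
})

test_that("behavior reader rejects invalid counts and unknown labels", {
  over <- write_temp_csv(bout_row(1990, "gosling", 60, 60, foraging = 55,
                                  resting = 6))
  expect_error(read_behavior_bouts(over), "exceed total_scans at row 1")
  d <- bout_row(1990, "gosling", 60, 60, foraging = 10)
  d$sleeping <- 5
  expect_error(read_behavior_bouts(write_temp_csv(d)),
               "valid labels are: foraging, alert, walking")
})

test_that("trend tables round-trip losslessly", {
  tbl <- data.frame(label = c("growth", "growth"),
                    parameter = c("alpha_growth", "beta_growth"),
                    mean = c(21.42195, -0.1003217), sd = c(0.77, 0.045),
                    `cri_2.5` = c(19.964, -0.191),
                    `cri_97.5` = c(22.991, -0.016),
                    f = c(1, 0.988), check.names = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trend_table(tbl, path)
  back <- read_trend_table(path)
  expect_equal(signif(back$mean, 6), signif(tbl$mean, 6))
  expect_equal(back$f, tbl$f)
  expect_equal(back$parameter, tbl$parameter)
  # empty list -> header-only file
  write_trend_table(tbl[0, ], path)
  expect_equal(length(readLines(path)), 1)
  expect_equal(nrow(read_trend_table(path)), 0)
  # duplicate label/parameter pairs are refused
  expect_error(write_trend_table(rbind(tbl, tbl[1, ]), path), "duplicate")
})
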