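test_that("sample_table enforces record invariants", {
  expect_error(sample_table("A", "oak", 0, -5, censored = FALSE),
               "strictly positive")
  # without an explicit flag, non-positive activity is read as censored
  expect_true(sample_table("A", "oak", 0, -5)$censored)
  expect_error(sample_table("A", "oak", 2, 5), "origin")
  expect_error(sample_table("", "oak", 0, 5), "stand_id")
  expect_error(sample_table("A", "", 0, 5), "species")
  # non-positive activity is fine when flagged censored
  tab <- sample_table("A", "oak", 0, NA, censored = TRUE)
  expect_true(tab$censored)
})

test_that("CSV parsing handles defaults, censoring conventions and errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("stand,species,origin,activity",
               "A,oak,0,10", "A,oak,1,20", "B,cherry,sprout,5"), path)
  tab <- read_samples(path)
  expect_s3_class(tab, "sample_table")
  expect_equal(nrow(tab), 3)
  expect_equal(length(unique(tab$stand_id)), 2)
  expect_equal(tab$origin, c(0L, 1L, 0L))

  # empty activity cell -> censored record
  writeLines(c("stand,species,origin,activity",
               "A,oak,0,10", "A,oak,0,"), path)
  expect_equal(read_samples(path)$censored, c(FALSE, TRUE))

  # garbage activity on a non-censored row is a parse error naming the row
  writeLines(c("stand,species,origin,activity",
               "A,oak,0,10", "A,oak,0,abc"), path)
  expect_error(read_samples(path), "row.*2")

  # missing required column is a schema error naming the column
  writeLines(c("stand,species,activity", "A,oak,10"), path)
  expect_error(read_samples(path), "origin")

  # column_map remaps non-default headers
  writeLines(c("plot,sp,org,cs137", "A,oak,0,10"), path)
  tab <- read_samples(path, column_map = c(stand_id = "plot",
                                           species = "sp", origin = "org",
                                           activity = "cs137"))
  expect_equal(tab$activity, 10)
})

test_that("write/read round trip is lossless for all fields", {
  tab <- toy_table()
  tab$censored[2] <- TRUE
  path <- withr::local_tempfile(fileext = ".csv")
  write_samples(tab, path)
  back <- read_samples(path)
  for (col in c("stand_id", "species", "origin", "activity", "censored")) {
    expect_equal(back[[col]], tab[[col]], info = col)
  }
  # second round trip identical too
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_samples(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("exclude_censored filters, reports the fraction, and is idempotent", {
  tab <- sample_table(stand_id = rep("A", 10), species = rep("oak", 10),
                      origin = rep(0, 10),
                      activity = c(NA, 2:10),
                      censored = c(TRUE, rep(FALSE, 9)))
  res <- exclude_censored(tab)
  expect_equal(nrow(res$table), 9)
  expect_equal(res$excluded_fraction, 0.1)
  again <- exclude_censored(res$table)
  expect_equal(again$excluded_fraction, 0)
  expect_equal(again$table$activity, res$table$activity)

  all_cens <- sample_table("A", "oak", 0, NA, censored = TRUE)
  expect_error(exclude_censored(all_cens), "all records are censored")
})

test_that("stand summaries match hand computation and survive duplication", {
  tab <- sample_table(stand_id = c("A", "A", "A", "B"),
                      species = rep("oak", 4), origin = rep(0, 4),
                      activity = exp(c(1, 2, 3, 5)))
  s <- stand_summaries(tab)
  expect_equal(s$mean_log, c(2, 5))
  expect_equal(s$sd_log, c(1, NA))  # single-record stand: sd undefined
  expect_equal(s$n, c(3L, 1L))

  # duplicating every stand k times leaves mean_log unchanged
  dup <- sample_table(stand_id = rep(tab$stand_id, 3),
                      species = rep(tab$species, 3),
                      origin = rep(tab$origin, 3),
                      activity = rep(tab$activity, 3))
  expect_equal(stand_summaries(dup)$mean_log, s$mean_log)

  cens <- toy_table()
  cens$censored[1] <- TRUE
  expect_error(stand_summaries(cens), "exclude_censored")
})

test_that("IQR outlier rule matches a brute-force type-7 quantile oracle", {
  oracle <- function(v) {
    q <- quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    v > q[2] + 1.5 * (q[2] - q[1]) | v < q[1] - 1.5 * (q[2] - q[1])
  }
  expect_equal(flag_outliers(c(1, 2, 3, 4, 100)),
               c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(flag_outliers(c(-10, 1, 2, 3, 10)),
               c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(flag_outliers(c(5, 5, 5, 5)), rep(FALSE, 4))
  set.seed(17)
  for (i in 1:20) {
    v <- rlnorm(sample(4:30, 1), 2, 1)
    expect_equal(flag_outliers(v), oracle(v))
  }
  expect_warning(out <- flag_outliers(c(1, 2, 3)), "fewer than 4")
  expect_equal(out, rep(FALSE, 3))
})
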