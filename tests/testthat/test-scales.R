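scales <- list(gses_scale(), phq9_scale())

make_items <- function(n, seed = 1) {
  set.seed(seed)
  df <- as.data.frame(cbind(
    matrix(sample(1:4, n * 10, TRUE), n, 10,
           dimnames = list(NULL, paste0("s", 1:10))),
    matrix(sample(0:3, n * 9, TRUE), n, 9,
           dimnames = list(NULL, paste0("d", 1:9)))))
  df$age <- sample(12:18, n, TRUE)
  df$gender <- sample(0:1, n, TRUE)
  df$education <- sample(1:3, n, TRUE)
  df
}

test_that("reading keeps in-range rows and drops out-of-range ones", {
  df <- make_items(3)
  m <- read_item_table(write_study_csv(df), scales)
  expect_equal(nrow(m$values), 3)
  expect_equal(m$n_dropped, 0)
  expect_equal(names(m$covariates), c("age", "gender", "education"))

  df$d4[2] <- 4   # PHQ-9 items are coded 0-3
  m2 <- read_item_table(write_study_csv(df), scales)
  expect_equal(nrow(m2$values), 2)
  expect_equal(m2$n_dropped, 1)

  df$d4[2] <- NA  # missing responses are dropped too (complete case)
  m3 <- read_item_table(write_study_csv(df), scales)
  expect_equal(m3$n_dropped, 1)
})

test_that("schema violations and empty tables raise typed errors", {
  df <- make_items(3)
  df$s7 <- NULL
  expect_error(read_item_table(write_study_csv(df), scales),
               class = "schema_error")
  df2 <- make_items(2)
  df2$d1 <- 9L
  expect_error(read_item_table(write_study_csv(df2), scales),
               class = "empty_data_error")
})

test_that("a generated study round-trips through write/read bit-identically", {
  cfg <- default_study_config(n_control = 60L, n_depressed = 40L, seed = 5L)
  st <- generate_two_group_study(cfg)
  path <- tempfile(fileext = ".csv")
  write_item_table(st$data, path)
  back <- read_item_table(path, scales)
  expect_identical(back$values, st$data$values)
  expect_equal(back$covariates$age, st$data$covariates$age)
})

test_that("scale scoring is the arithmetic sum with the documented ranges", {
  n <- 5
  df <- make_items(n)
  phq0 <- df; phq0[paste0("d", 1:9)] <- 0L
  m <- item_response_matrix(phq0[c(paste0("s", 1:10), paste0("d", 1:9))],
                            scales)
  expect_equal(score_scale(m, phq9_scale()), rep(0L, n))

  phq3 <- df; phq3[paste0("d", 1:9)] <- 3L
  m3 <- item_response_matrix(phq3[c(paste0("s", 1:10), paste0("d", 1:9))],
                             scales)
  expect_equal(score_scale(m3, phq9_scale()), rep(27L, n))
  expect_equal(phq9_scale()$score_range, c(0L, 27L))

  gses4 <- df; gses4[paste0("s", 1:10)] <- 4L
  m4 <- item_response_matrix(gses4[c(paste0("s", 1:10), paste0("d", 1:9))],
                             scales)
  expect_equal(score_scale(m4, gses_scale()), rep(40L, n))
  expect_equal(gses_scale()$score_range, c(10L, 40L))

  expect_error(score_scale(
    item_response_matrix(df[paste0("d", 1:9)], list(phq9_scale())),
    gses_scale()), class = "schema_error")
})

test_that("depression classification honors the cutoff and severity bands", {
  cls <- classify_depression(c(0, 9, 10, 14, 15, 19, 20, 27))
  expect_equal(as.character(cls$group),
               c("control", "control", rep("depressed", 6)))
  expect_equal(as.character(cls$severity),
               c("control", "control", "moderate", "moderate",
                 "moderate-severe", "moderate-severe", "severe", "severe"))
  expect_error(classify_depression(5, cutoff = 30), class = "parameter_error")
})

test_that("group sizes sum to n and severity bands partition the depressed", {
  set.seed(42)
  totals <- sample(0:27, 500, TRUE)
  cls <- classify_depression(totals)
  expect_equal(sum(table(cls$group)), 500)
  dep <- cls$severity[cls$group == "depressed"]
  expect_equal(sum(table(droplevels(dep))), sum(cls$group == "depressed"))
  expect_true(!any(dep == "control"))
})

test_that("scoring is invariant to row order", {
  df <- make_items(20, seed = 9)
  m <- item_response_matrix(df[c(paste0("s", 1:10), paste0("d", 1:9))],
                            scales)
  perm <- sample(20)
  mp <- item_response_matrix(
    df[perm, c(paste0("s", 1:10), paste0("d", 1:9))], scales)
  expect_equal(score_scale(m, gses_scale())[perm],
               score_scale(mp, gses_scale()))
})

test_that("cronbach alpha matches its defining formula on a worked case", {
  set.seed(3)
  X <- matrix(rnorm(50 * 4), 50, 4) + rnorm(50)   # shared factor
  k <- 4
  expected <- (k / (k - 1)) *
    (1 - sum(apply(X, 2, var)) / var(rowSums(X)))
  expect_equal(cronbach_alpha(X), expected)
  expect_gt(cronbach_alpha(X), 0.5)
})
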