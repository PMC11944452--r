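test_that("metrics agree with independent brute-force implementations", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(2:40, 1)
    y <- rnorm(n)
    z <- rnorm(n)
    expect_lt(abs(mae(y, z) - bf_mae(y, z)), 1e-9)
    expect_lt(abs(r_squared(y, z) - bf_r2(y, z)), 1e-9)
    expect_lt(abs(pearson(y, z) - bf_pearson(y, z)), 1e-9)
  }
  # equal-size transport vs exhaustive matching
  for (i in 1:100) {
    n <- sample(2:6, 1)
    p <- rnorm(n)
    q <- rnorm(n)
    expect_lt(abs(wasserstein1(p, q) - bf_w1_exhaustive(p, q)), 1e-9)
  }
  # unequal sizes vs the sample-replication construction
  for (i in 1:100) {
    p <- rnorm(sample(2:8, 1))
    q <- rnorm(sample(2:8, 1))
    expect_lt(abs(wasserstein1(p, q) - bf_w1_lcm(p, q)), 1e-9)
  }
})

test_that("metric identities and hand-computed values hold", {
  y <- c(1, 2, 3)
  expect_identical(mae(y, y), 0)
  expect_equal(mae(c(0, 0), c(1, -1)), 1)
  expect_equal(mae(2, 5), 3)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 3)), 0)
  expect_equal(r_squared(y, c(1, 2, 4)), 0.5)
  expect_equal(pearson(y, y), 1)
  expect_equal(pearson(y, -y), -1)
  expect_equal(pearson(y, c(1, 3, 2)), 0.5)
  expect_error(r_squared(c(1, 1), c(1, 2)), "undefined-denominator")
  expect_error(pearson(c(1, 1), c(1, 2)), "undefined-correlation")
  expect_identical(wasserstein1(y, y), 0)
  expect_equal(wasserstein1(2, 5), 3)
  expect_equal(wasserstein1(c(0, 1), c(0, 3)), 1)
})

test_that("pearson is invariant under positive affine transforms", {
  set.seed(55)
  for (i in 1:25) {
    y <- rnorm(12)
    z <- rnorm(12)
    r0 <- pearson(y, z)
    expect_equal(pearson(3.2 * y + 7, z), r0, tolerance = 1e-12)
    expect_equal(pearson(y, 0.1 * z - 2), r0, tolerance = 1e-12)
  }
})

test_that("wasserstein1 is symmetric and satisfies the triangle inequality", {
  set.seed(77)
  for (i in 1:50) {
    a <- rnorm(sample(2:9, 1))
    b <- rnorm(sample(2:9, 1))
    c_ <- rnorm(sample(2:9, 1))
    expect_equal(wasserstein1(a, b), wasserstein1(b, a), tolerance = 1e-12)
    expect_lte(wasserstein1(a, c_),
               wasserstein1(a, b) + wasserstein1(b, c_) + 1e-12)
  }
})

test_that("linear interpolation matches its closed form and guards its domain", {
  expect_identical(linear_interpolate(250, c(0.2), 300, c(0.4), 250), c(0.2))
  expect_equal(linear_interpolate(250, c(0.2), 300, c(0.4), 275), c(0.3))
  expect_equal(linear_interpolate(250, c(0.2), 300, c(0.4), 260), c(0.24))
  y1 <- rnorm(5)
  y2 <- rnorm(5)
  expect_equal(linear_interpolate(0, y1, 1, y2, 0.5), (y1 + y2) / 2)
  expect_error(linear_interpolate(1, y1, 1, y2, 1), "degenerate-interval")
  expect_error(linear_interpolate(0, y1, 1, y2, 2), "domain error")
})

test_that("generation evaluation interpolates the bracketing anchors", {
  anchors <- list(`250` = c(1, 2), `300` = c(3, 6), `350` = c(5, 2), `400` = c(7, 8))
  gen_equal <- list(`260` = c(1.4, 2.8), `315` = c(3.6, 4.8))
  rows <- evaluate_generation(gen_equal, anchors)
  expect_equal(rows$mae, c(0, 0))
  expect_equal(rows$r2, c(1, 1))
  expect_equal(rows$pearson, c(1, 1))

  # constant offset: mae = offset, pearson stays 1
  gen_off <- list(`260` = c(1.4, 2.8) + 0.5)
  row <- evaluate_generation(gen_off, anchors)
  expect_equal(row$mae, 0.5)
  expect_equal(row$pearson, 1)
  expect_error(evaluate_generation(list(`240` = c(1, 2)), anchors), "domain error")
})

test_that("prediction evaluation runs per temperature over the 10 fractions", {
  p1 <- composition_vector(c(0.3, 0.2, rep(0.0625, 8)), 260)
  p2 <- composition_vector(c(0.25, 0.15, rep(0.075, 8)), 280)
  refs <- list(`260` = p1, `280` = p2)
  rows <- evaluate_prediction(refs, refs)
  expect_equal(nrow(rows), 2L)
  expect_equal(rows$mae, c(0, 0))
  expect_equal(rows$r2, c(1, 1))

  uni <- list(`260` = composition_vector(rep(0.1, 10), 260), `280` = p2)
  rows <- evaluate_prediction(uni, refs)
  expect_equal(rows$mae[1], mean(abs(p1$fractions - 0.1)))
  expect_true(is.na(rows$pearson[1]))  # constant prediction: no correlation
  expect_error(evaluate_prediction(uni, list(`260` = p1)), "argument error")
})

test_that("reports are deterministic files with headers", {
  dir <- withr::local_tempdir()
  tables <- list(audit = data.frame(temperature_c = 250, wasserstein = 1e-3),
                 empty = data.frame(temperature_c = numeric(), mae = numeric()))
  make_report(tables, dir)
  first <- tools::md5sum(file.path(dir, c("audit.csv", "empty.csv", "summary.json")))
  expect_identical(readLines(file.path(dir, "empty.csv"))[1], "temperature_c,mae")
  make_report(tables, dir)
  second <- tools::md5sum(file.path(dir, c("audit.csv", "empty.csv", "summary.json")))
  expect_identical(unname(first), unname(second))
})
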