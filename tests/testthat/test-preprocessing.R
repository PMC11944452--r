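test_that("TGA binning reproduces brute-force centered-bin means", {
  # constant curve: every bin is the constant
  temps0 <- seq(39.6, 787.5, by = 0.25)
  raw <- thermogram_raw(temps0, rep(100, length(temps0)), 300)
  rs <- clip_resample_tga(raw)
  expect_length(rs$mass_pct, 721L)
  expect_true(all(rs$mass_pct == 100))

  # linear curve sampled at instrument spacing: bin mean tracks the line
  temps <- seq(39.6, 787.5, by = 0.034)
  raw <- thermogram_raw(temps, 100 - 0.05 * temps, 320)
  rs <- clip_resample_tga(raw)
  grid <- 40:760
  # interior bins are unbiased local means; the two edge bins are half-bins
  inner <- 2:720
  expect_lt(max(abs(rs$mass_pct[inner] - (100 - 0.05 * grid[inner]))), 0.002)
  expect_lt(max(abs(rs$mass_pct - (100 - 0.05 * grid))), 0.01)

  # brute-force bin means on a small irregular sample
  set.seed(21)
  t_irr <- sort(runif(4000, 39.5, 788))
  t_irr <- t_irr[c(TRUE, diff(t_irr) > 0)]
  m_irr <- 100 - 0.06 * t_irr + rnorm(length(t_irr), sd = 0.2)
  rs <- clip_resample_tga(thermogram_raw(t_irr, m_irr, 300))
  for (t_chk in c(40, 123, 456, 760)) {
    in_bin <- t_irr >= t_chk - 0.5 & t_irr < t_chk + 0.5
    if (any(in_bin)) {
      expect_equal(rs$mass_pct[t_chk - 39], mean(m_irr[in_bin]), tolerance = 1e-12)
    }
  }
})

test_that("TGA resampling is idempotent and fills empty bins by interpolation", {
  rs <- clip_resample_tga(simulate_tga_raw(300, noiseless_params(), 1))
  again <- clip_resample_tga(thermogram_raw(40:760, rs$mass_pct, 300))
  expect_equal(again$mass_pct, rs$mass_pct, tolerance = 1e-12)

  # sparse scan with a gap: missing bins interpolate linearly
  temps <- c(seq(39.6, 99.6, by = 0.5), seq(110.4, 790, by = 0.5))
  raw <- thermogram_raw(temps, 100 - 0.05 * temps, 300)
  rs <- clip_resample_tga(raw)
  expect_length(rs$mass_pct, 721L)
  expect_true(all(is.finite(rs$mass_pct)))
  expect_lt(max(abs(rs$mass_pct - (100 - 0.05 * (40:760)))), 0.05)

  short <- thermogram_raw(seq(100, 500, by = 1), rep(90, 401), 300)
  expect_error(clip_resample_tga(short), "coverage error")
})

test_that("FT-IR transform follows mean -> clip -> offset -> floor -> log", {
  grid <- ftir_grid()
  mk <- function(val, k) ir_spectrum_raw(grid, rep(val, length(grid)), k, 300)
  out <- preprocess_ftir(list(mk(91, 1), mk(91, 2)))
  expect_equal(out$values, rep(1, 3476), tolerance = 1e-12)     # log10(101-91)
  expect_equal(preprocess_ftir(list(mk(100, 1)))$values, rep(0, 3476))
  expect_equal(preprocess_ftir(list(mk(105, 1)))$values, rep(0, 3476))  # clipped

  # replicate averaging happens before the nonlinearities
  out <- preprocess_ftir(list(mk(80, 1), mk(102, 2)))
  expect_equal(out$values, rep(log10(101 - 91), 3476), tolerance = 1e-12)

  expect_error(preprocess_ftir(list()), "argument error")

  # off-grid replicate is interpolated onto the canonical grid
  coarse <- ir_spectrum_raw(seq(600, 4100, by = 10), rep(95, 351), 1, 300)
  out <- preprocess_ftir(list(coarse))
  expect_equal(out$values, rep(log10(6), 3476), tolerance = 1e-12)
  off <- ir_spectrum_raw(seq(5000, 6000, by = 10), rep(95, 101), 1, 300)
  expect_error(preprocess_ftir(list(off)), "grid error")
})

test_that("FT-IR outputs are bounded for any physical transmittance", {
  set.seed(4)
  grid <- ftir_grid()
  for (i in 1:20) {
    tr <- runif(length(grid), 0, 110)
    out <- preprocess_ftir(list(ir_spectrum_raw(grid, tr, 1, 300)))
    expect_true(all(out$values >= 0))
    expect_true(all(out$values <= log10(101)))
  }
})

test_that("GC-MS aggregation closes the composition with 'Other'", {
  groups <- gcms_groups()[1:9]
  # detected total 91.16 -> Other 0.0884, as in the anchor-condition tables
  tab <- derivative_table(paste0("c", 1:9), groups,
                          c(30, 25, 10, 10, 5, 5, 3, 2, 1.16),
                          rep(TRUE, 9), 250)
  comp <- aggregate_gcms(tab)
  expect_equal(unname(comp$fractions["Other"]), 0.0884, tolerance = 1e-12)
  expect_equal(sum(comp$fractions), 1, tolerance = 1e-12)

  # single detected group at 50%
  tab <- derivative_table(paste0("c", 1:9), groups, c(50, rep(10, 8)),
                          c(TRUE, rep(FALSE, 8)), 300)
  comp <- aggregate_gcms(tab)
  expect_equal(unname(comp$fractions["Syringyl"]), 0.5)
  expect_equal(unname(comp$fractions["Other"]), 0.5)
  expect_true(all(comp$fractions[2:9] == 0))

  # full closure when everything is detected
  tab <- derivative_table(paste0("c", 1:10), rep(groups[1:5], 2), rep(10, 10),
                          rep(TRUE, 10), 300)
  expect_equal(unname(aggregate_gcms(tab)$fractions["Other"]), 0)

  # aggregation output is always on the simplex for simulated tables
  for (t_c in c(252, 301, 377, 399)) {
    comp <- aggregate_gcms(simulate_gcms_table(t_c, simulator_params(), seed = t_c))
    expect_true(all(comp$fractions >= 0))
    expect_lt(abs(sum(comp$fractions) - 1), 1e-9)
  }
})

test_that("Wasserstein audit is small for dense noiseless scans and zero at identity", {
  raw <- simulate_tga_raw(300, noiseless_params(), 1)
  rs <- clip_resample_tga(raw)
  loss <- preprocessing_information_loss(raw, rs)
  expect_lt(loss, 5e-3)
  expect_gte(loss, 0)

  ident <- thermogram_raw(40:760, rs$mass_pct, 300)
  expect_equal(preprocessing_information_loss(ident, rs), 0)
})
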