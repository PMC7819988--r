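test_that("the generator is a deterministic function of the seed", {
  cfg <- synthetic_config(grid_dim = c(3, 3), modes = "positive", seed = 42)
  a <- generate_msi_dataset(cfg)
  b <- generate_msi_dataset(cfg)
  expect_identical(a, b)
  # a different seed gives different data
  cfg2 <- synthetic_config(grid_dim = c(3, 3), modes = "positive", seed = 43)
  expect_false(identical(generate_msi_dataset(cfg2)$datasets, a$datasets))
})

test_that("zero-noise spectra sit exactly on theoretical adduct m/z", {
  cfg <- noiseless_config()
  ex <- generate_msi_dataset(cfg)
  d <- ex$datasets$positive
  expect_equal(nrow(d$samples), 2)
  theo <- sort(unname(panel_theoretical_mz(cfg, "positive")))
  for (sid in d$samples$sample_id) {
    sp <- pixel_spectrum(d, sid, 1, 1)
    expect_equal(sp$mz, theo, tolerance = 1e-12)
  }
})

test_that("truth table covers the panel with the 27-up / 7-down signature", {
  cfg <- synthetic_config(grid_dim = c(2, 2))
  ex <- generate_msi_dataset(cfg)
  expect_setequal(ex$truth$compound_id, unique(cfg$panel$compound_id))
  expect_equal(sum(ex$truth$direction == "up"), 27)
  expect_equal(sum(ex$truth$direction == "down"), 7)
  expect_equal(sum(ex$truth$differential), 34)
  # cohort ages: children vs adults
  expect_true(all(ex$samples$age[ex$samples$group == "control"] >= 28))
  expect_lt(mean(ex$samples$age[ex$samples$group == "patient"]), 12)
})

test_that("config validation rejects inconsistent panels", {
  expect_error(synthetic_config(effects = c(not_a_compound = 1)),
               "config error")
  expect_error(synthetic_config(spatial_compounds = "nope"), "config error")
  expect_error(synthetic_config(sigma_sample = -1))
})

test_that("planted group effects are recovered in sample-mean log intensity", {
  # Monte-Carlo over replicate seeds: the patient-minus-control difference
  # of per-sample mean log intensity of an 'up' compound matches the
  # planted shift within 2 SE
  target <- "pc_36_1"
  diffs <- vapply(1:20, function(s) {
    cfg <- synthetic_config(grid_dim = c(2, 2), modes = "positive", seed = s)
    ex <- generate_msi_dataset(cfg)
    d <- ex$datasets$positive
    theo <- panel_theoretical_mz(cfg, "positive")[[target]]
    p <- d$peaks[abs(d$peaks$mz / theo - 1) * 1e6 < 5, ]
    m <- tapply(log(p$intensity), p$sample_id, mean)
    grp <- d$samples$group[match(names(m), d$samples$sample_id)]
    mean(m[grp == "patient"]) - mean(m[grp == "control"])
  }, numeric(1))
  planted <- 0.8 # 2 * default sigma_sample
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - planted), 2 * se + 0.05)
})

test_that("stronger planted effects give larger test statistics", {
  # Monte-Carlo monotonicity of E|t| in the effect size
  tstat_at <- function(effect, seeds) {
    mean(vapply(seeds, function(s) {
      cfg <- synthetic_config(grid_dim = c(2, 2), modes = "positive",
                              age_scheme = "balanced", seed = s,
                              effects = c(pc_36_1 = effect))
      ex <- generate_msi_dataset(cfg)
      d <- ex$datasets$positive
      theo <- panel_theoretical_mz(cfg, "positive")[["pc_36_1"]]
      p <- d$peaks[abs(d$peaks$mz / theo - 1) * 1e6 < 5, ]
      m <- tapply(log(p$intensity), p$sample_id, mean)
      grp <- d$samples$group[match(names(m), d$samples$sample_id)]
      abs(t.test(m[grp == "patient"], m[grp == "control"],
                 var.equal = TRUE)$statistic)
    }, numeric(1)))
  }
  seeds <- 1:12
  expect_lt(tstat_at(0, seeds), tstat_at(1, seeds))
  expect_lt(tstat_at(1, seeds), tstat_at(3, seeds))
})

test_that("CSV round trip is the identity", {
  cfg <- synthetic_config(grid_dim = c(3, 2), modes = "negative", seed = 5)
  d <- generate_msi_dataset(cfg)$datasets$negative
  stem <- tempfile()
  write_msi_dataset(d, stem, "csv")
  back <- read_msi_dataset(stem)
  expect_equal(back$peaks$mz, d$peaks$mz, tolerance = 0)
  expect_identical(back$peaks$intensity, d$peaks$intensity)
  expect_identical(back$peaks$sample_id, d$peaks$sample_id)
  expect_identical(back$peaks$x, d$peaks$x)
  expect_equal(back$samples$age, d$samples$age)
  expect_identical(back$mode, d$mode)
})

test_that("imzML round trip preserves m/z to 1e-9 and intensities exactly", {
  cfg <- synthetic_config(n_patients = 2, n_controls = 2, grid_dim = c(3, 2),
                          modes = "positive", seed = 6)
  d <- generate_msi_dataset(cfg)$datasets$positive
  dir <- tempfile()
  write_msi_dataset(d, dir, "imzml")
  back <- read_msi_dataset(dir)
  key <- function(x) x$peaks[order(x$peaks$sample_id, x$peaks$y, x$peaks$x,
                                   x$peaks$mz), ]
  a <- key(d); b <- key(back)
  expect_equal(b$mz, a$mz, tolerance = 1e-12)
  expect_identical(b$intensity, a$intensity)
  expect_identical(b$x, a$x)
  expect_identical(b$y, a$y)
})

test_that("unknown formats and malformed files raise parse errors", {
  cfg <- noiseless_config()
  d <- generate_msi_dataset(cfg)$datasets$positive
  expect_error(write_msi_dataset(d, tempfile(), "netcdf"), "format error")
  # truncated/garbled CSV header
  stem <- tempfile()
  writeLines(c("not,a,header", "1,2,3"), paste0(stem, ".csv"))
  jsonlite::write_json(list(mode = "positive", grid_dim = c(1, 1),
                            samples = d$samples),
                       paste0(stem, ".json"), auto_unbox = TRUE)
  expect_error(read_msi_dataset(stem), "parse error")
  expect_error(read_msi_dataset(tempfile()), "format error")
})

test_that("age-correlated drift is absorbed by the covariate-adjusted test", {
  # zero effects + intensity drift with age + confounded cohort ages:
  # the unadjusted two-group test rejects massively, the age-adjusted
  # model does not (the reason the analysis includes age as covariate)
  cfg <- synthetic_config(grid_dim = c(2, 2), modes = "positive", seed = 9,
                          effects = setNames(numeric(0), character(0)),
                          age_drift = 0.05, age_scheme = "cohort")
  ex <- generate_msi_dataset(cfg)
  d <- tic_normalize_dataset(recalibrate_dataset(ex$datasets$positive),
                             target = "mean-tic")
  fm <- log_transform(bin_features(d))
  adj <- differential_test(fm)
  unadj <- differential_test(fm, age = NULL)
  expect_lt(sum(adj$p < 0.05, na.rm = TRUE),
            sum(unadj$p < 0.05, na.rm = TRUE))
  expect_gt(sum(unadj$p < 0.05, na.rm = TRUE), nrow(fm$features) / 2)
})
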