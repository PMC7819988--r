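cal_neg <- load_calibrants(mode = "negative")
cal_pos <- load_calibrants(mode = "positive")

test_that("calibrant list recomputes and verifies stored m/z", {
  cal <- load_calibrants()
  expect_true(all(abs(cal$mz - cal$mz_ref) <= 1e-5))
  # a corrupted stored value is caught at load
  tmp <- tempfile(fileext = ".tsv")
  bad <- cal
  bad$mz_ref[1] <- bad$mz_ref[1] + 0.001
  write.table(bad[, c("mode", "name", "formula", "adduct", "mz_ref")], tmp,
              sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(load_calibrants(tmp), "inconsistent")
})

test_that("single-point recalibration zeroes a constructed uniform drift", {
  atp <- ion_mz("C10H16N5O13P3", "[M-H]-")
  truth <- c(200.123, atp, 700.456)
  sp <- data.frame(mz = truth * (1 + 1e-6), intensity = c(10, 100, 20))
  r <- recalibrate(sp, cal_neg, "single-point")
  expect_false(r$flagged)
  expect_equal(r$offset_ppm, 1, tolerance = 1e-6)
  expect_equal(r$spectrum$mz[2], 505.988470, tolerance = 1e-5)
  # the correction is uniform: every m/z is scaled by the same factor
  expect_equal(r$spectrum$mz / truth, rep(r$spectrum$mz[2] / atp, 3),
               tolerance = 1e-12)
})

test_that("an already-calibrated spectrum passes through unchanged", {
  sp <- data.frame(mz = cal_neg$mz, intensity = rep(50, nrow(cal_neg)))
  r <- recalibrate(sp, cal_neg, "single-point")
  expect_equal(r$offset_ppm, 0, tolerance = 1e-9)
  expect_equal(r$spectrum$mz, sp$mz, tolerance = 1e-12)
})

test_that("spectra with no calibrant are flagged, not altered", {
  sp <- data.frame(mz = c(300.1, 301.2), intensity = c(5, 6))
  r <- recalibrate(sp, cal_neg, "single-point")
  expect_true(r$flagged)
  expect_identical(r$spectrum, sp)
})

test_that("linear recalibration recovers an m/z-dependent drift", {
  drift_ppm <- function(mz) 0.5 + 0.002 * mz
  sp <- data.frame(mz = cal_neg$mz * (1 + drift_ppm(cal_neg$mz) * 1e-6),
                   intensity = rep(10, nrow(cal_neg)))
  r <- recalibrate(sp, cal_neg, "linear")
  expect_false(r$flagged)
  expect_equal(r$spectrum$mz, cal_neg$mz, tolerance = 1e-8)
  expect_true(all(abs(r$after$ppm_before) < 0.01))
})

test_that("dataset-level recalibration matches the per-spectrum operation", {
  cfg <- synthetic_config(n_patients = 2, n_controls = 2, grid_dim = c(2, 2),
                          modes = "negative", seed = 31)
  d <- generate_msi_dataset(cfg)$datasets$negative
  dd <- recalibrate_dataset(d, cal_neg)
  for (sid in c("C01", "P02")) {
    raw <- pixel_spectrum(d, sid, 2, 1)
    ref <- recalibrate(raw, cal_neg, "single-point")
    got <- pixel_spectrum(dd, sid, 2, 1)
    expect_equal(got$mz, ref$spectrum$mz, tolerance = 1e-12)
  }
  rec <- attr(dd, "recalibration")
  expect_true(all(!rec$flagged))
})

test_that("TIC normalization hits the target and preserves ratios", {
  a <- data.frame(mz = c(100, 200), intensity = c(4, 6))    # TIC 10
  b <- data.frame(mz = c(100, 200), intensity = c(15, 5))   # TIC 20
  na <- tic_normalize(a, 1); nb <- tic_normalize(b, 1)
  expect_equal(sum(na$intensity), 1)
  expect_equal(sum(nb$intensity), 1)
  expect_equal(na$intensity[1] / na$intensity[2],
               a$intensity[1] / a$intensity[2])
  expect_error(tic_normalize(data.frame(mz = 1, intensity = 0)), "TIC")
})

test_that("dataset mean-TIC normalization makes pixel TICs equal", {
  cfg <- synthetic_config(n_patients = 2, n_controls = 2, grid_dim = c(3, 3),
                          modes = "positive", seed = 12)
  d <- generate_msi_dataset(cfg)$datasets$positive
  nd <- tic_normalize_dataset(d, "mean-tic")
  tics <- tapply(nd$peaks$intensity,
                 paste(nd$peaks$sample_id, nd$peaks$x, nd$peaks$y), sum)
  expect_lt(sd(tics) / mean(tics), 1e-10)
  expect_equal(mean(tics), attr(nd, "target_tic"))
})

test_that("binning merges sub-ppm peaks and splits distant ones", {
  mk <- function(mzs) {
    samples <- data.frame(sample_id = c("A", "B"), group = c("control", "patient"),
                          age = c(30, 5), stringsAsFactors = FALSE)
    peaks <- data.frame(sample_id = c("A", "B"), x = 1L, y = 1L, mz = mzs,
                        intensity = c(10, 20), stringsAsFactors = FALSE)
    msimetab:::new_msi_dataset(peaks, samples, "negative", c(1, 1))
  }
  # 0.49 ppm apart: one feature
  fm <- bin_features(mk(c(505.988470, 505.988720)))
  expect_equal(nrow(fm$features), 1)
  expect_equal(fm$features$n_members, 2)
  # ~3 ppm apart: two features
  fm2 <- bin_features(mk(c(505.988470, 505.990000)))
  expect_equal(nrow(fm2$features), 2)
  expect_error(bin_features(mk(c(505.1, 505.2)), tolerance_ppm = 0), "domain")
})

test_that("binning an empty dataset gives an empty matrix", {
  samples <- data.frame(sample_id = "A", group = "control", age = 30,
                        stringsAsFactors = FALSE)
  d <- msimetab:::new_msi_dataset(
    data.frame(sample_id = character(0), x = integer(0), y = integer(0),
               mz = numeric(0), intensity = numeric(0)),
    samples, "positive", c(1, 1))
  fm <- bin_features(d)
  expect_equal(nrow(fm$features), 0)
  expect_equal(dim(fm$intensity), c(0, 1))
})

test_that("binning is invariant to sample order", {
  cfg <- synthetic_config(n_patients = 2, n_controls = 2, grid_dim = c(2, 2),
                          modes = "positive", seed = 77)
  d <- generate_msi_dataset(cfg)$datasets$positive
  d2 <- d
  ord <- rev(seq_len(nrow(d$peaks)))
  d2$peaks <- d$peaks[ord, ]
  fa <- bin_features(d); fb <- bin_features(d2)
  expect_equal(fa$features$mz, fb$features$mz)
  expect_equal(fa$intensity, fb$intensity)
})

test_that("binning agrees with brute-force single-linkage on small instances", {
  set.seed(88)
  for (i in 1:30) {
    k <- sample(2:6, 1)
    centers <- sort(500 * (1 + cumsum(runif(k, 5, 50)) * 1e-6))
    n_each <- sample(2:8, k, replace = TRUE)
    mz <- unlist(mapply(function(c0, n) c0 * (1 + rnorm(n, 0, 0.2) * 1e-6),
                        centers, n_each))
    mz <- sort(mz)
    stopifnot(length(mz) <= 50)
    mine <- msimetab:::bin_mz(mz, rep(1, length(mz)), 1)
    oracle <- brute_force_single_linkage(mz, 1)
    # same partition (labels may differ; compare co-membership)
    expect_equal(outer(mine, mine, "=="), outer(oracle, oracle, "=="))
  }
})

test_that("default-noise synthesis reassembles one feature per compound", {
  cfg <- synthetic_config(grid_dim = c(4, 4), modes = "negative", seed = 21)
  d <- generate_msi_dataset(cfg)$datasets$negative
  d <- tic_normalize_dataset(recalibrate_dataset(d), "mean-tic")
  fm <- bin_features(d, tolerance_ppm = 1)
  theo <- panel_theoretical_mz(cfg, "negative")
  expect_equal(nrow(fm$features), length(theo))
  # every feature consensus lies within 1 ppm of a distinct planted species
  nearest <- vapply(fm$features$mz,
                    function(m) min(abs(m / theo - 1)) * 1e6, numeric(1))
  expect_true(all(nearest < 1))
  expect_true(all(fm$intensity > 0))
})

test_that("feature matrices round-trip through CSV + JSON sidecar", {
  cfg <- synthetic_config(n_patients = 2, n_controls = 2, grid_dim = c(2, 2),
                          modes = "positive", seed = 3)
  d <- generate_msi_dataset(cfg)$datasets$positive
  fm <- bin_features(tic_normalize_dataset(recalibrate_dataset(d)))
  stem <- tempfile()
  write_feature_matrix(fm, stem)
  back <- read_feature_matrix(stem)
  expect_equal(back$intensity, fm$intensity, tolerance = 1e-12)
  expect_equal(back$features$mz, fm$features$mz, tolerance = 1e-12)
  expect_identical(back$samples$sample_id, fm$samples$sample_id)
})
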