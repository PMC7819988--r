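# Ground-truthed synthetic MSI generator emulating a two-group biopsy
# cohort: 9 children with dystrophin-deficient muscle vs 9 adult controls,
# a panel of ~60 metabolites of which 34 are truly differential (27 up,
# 7 down in patients), FTICR-grade sub-ppm m/z jitter, log-normal pixel
# intensities, per-pixel TIC variation and ubiquitous matrix peaks.

#' Synthetic MSI study configuration
#'
#' Builds the configuration for [generate_msi_dataset()]. Defaults emulate
#' the study design the package targets: two groups of 9 samples, patients
#' aged 5.5 +/- 1.9 years vs adult controls aged 28-58, a compound panel
#' with 27 up- and 7 down-regulated species (log-scale shifts of
#' `2 * sigma_sample`), sub-ppm mass jitter and a per-sample calibration
#' offset that the preprocessing stage must remove.
#'
#' @param n_patients,n_controls Samples per group.
#' @param grid_dim Pixel grid per sample, `c(nx, ny)`.
#' @param modes Ionization modes to simulate.
#' @param db Compound database ([load_compound_db()] by default).
#' @param panel Data frame `compound_id, mode, adduct, base_log`; `NULL`
#'   builds the default panel from every non-matrix database compound.
#' @param effects Named numeric vector of true log-scale group shifts
#'   (patient minus control); `NULL` uses the default 27-up/7-down
#'   signature at `effect_size`.
#' @param effect_size Absolute default effect, in log units. The default is
#'   `2 * sigma_sample` (a two-standard-deviation shift at the sample
#'   level).
#' @param sigma_sample Between-sample biological SD of log intensity (per
#'   compound, independent across compounds).
#' @param sigma_pixel Within-sample pixel SD of log intensity.
#' @param tic_sdlog Log-SD of the per-pixel TIC scale factor.
#' @param sample_scale_sdlog Log-SD of the per-sample technical intensity
#'   scale (matrix deposition / ion yield), shared by every species of a
#'   sample; this is the systematic variation that TIC normalization is
#'   meant to remove.
#' @param sigma_matrix Sample-level log SD of the matrix peaks (technical
#'   only; matrix ions carry no biology).
#' @param mz_jitter_ppm Per-peak m/z jitter SD in ppm.
#' @param calib_offset_ppm_sd SD of the per-sample multiplicative
#'   calibration drift, in ppm.
#' @param age_scheme `"cohort"` draws patient ages from N(5.5, 1.9^2) and
#'   control ages from U(28, 58) (the emulated study; note this makes age
#'   nearly collinear with group); `"balanced"` draws both groups from the
#'   patient distribution so that age carries no group information.
#' @param age_drift Log-intensity change per year of age applied to every
#'   panel compound (0 = off); the knob for stress-testing age confounding.
#' @param matrix_base_log Base log intensity of matrix peaks.
#' @param spatial_compounds Compound ids confined to the left half of the
#'   tissue grid (two-region mask); empty = spatially uniform (default).
#' @param seed Master RNG seed. Per-(sample, mode) child seeds are derived
#'   from it by counter, so partial regeneration is stable.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_patients = 9, n_controls = 9,
                             grid_dim = c(40, 40),
                             modes = c("positive", "negative"),
                             db = NULL, panel = NULL, effects = NULL,
                             effect_size = NULL,
                             sigma_sample = 0.4, sigma_pixel = 0.3,
                             tic_sdlog = 0.3, sample_scale_sdlog = 0.5,
                             sigma_matrix = 0.1, mz_jitter_ppm = 0.3,
                             calib_offset_ppm_sd = 1,
                             age_scheme = c("cohort", "balanced"),
                             age_drift = 0,
                             matrix_base_log = 10,
                             spatial_compounds = character(0),
                             seed = 42) {
  age_scheme <- match.arg(age_scheme)
  if (is.null(db)) db <- load_compound_db()
  stopifnot(n_patients >= 1, n_controls >= 1, length(grid_dim) == 2,
            all(grid_dim >= 1), sigma_sample >= 0, sigma_pixel >= 0,
            tic_sdlog >= 0, sample_scale_sdlog >= 0, sigma_matrix >= 0,
            mz_jitter_ppm >= 0, calib_offset_ppm_sd >= 0)
  modes <- match.arg(modes, several.ok = TRUE)
  if (is.null(effect_size)) effect_size <- 2 * sigma_sample
  if (is.null(panel)) panel <- default_panel(db)
  panel <- panel[panel$mode %in% modes, , drop = FALSE]
  if (is.null(effects)) {
    effects <- default_effects(effect_size)
    effects <- effects[names(effects) %in% panel$compound_id]
  }
  bad <- setdiff(names(effects), panel$compound_id)
  if (length(bad)) {
    stop("config error: effect assigned to compound(s) not in panel: ",
         paste(bad, collapse = ", "))
  }
  up <- names(effects)[effects > 0]; dn <- names(effects)[effects < 0]
  if (length(intersect(up, dn))) stop("config error: effect sets not disjoint")
  bad_sp <- setdiff(spatial_compounds, panel$compound_id)
  if (length(bad_sp)) {
    stop("config error: spatial compound(s) not in panel: ",
         paste(bad_sp, collapse = ", "))
  }
  structure(list(n_patients = n_patients, n_controls = n_controls,
                 grid_dim = as.integer(grid_dim), modes = modes, db = db,
                 panel = panel, effects = effects,
                 sigma_sample = sigma_sample, sigma_pixel = sigma_pixel,
                 tic_sdlog = tic_sdlog,
                 sample_scale_sdlog = sample_scale_sdlog,
                 sigma_matrix = sigma_matrix,
                 mz_jitter_ppm = mz_jitter_ppm,
                 calib_offset_ppm_sd = calib_offset_ppm_sd,
                 age_scheme = age_scheme,
                 patient_age = c(mean = 5.5, sd = 1.9),
                 control_age_range = c(28, 58),
                 age_drift = age_drift, matrix_base_log = matrix_base_log,
                 spatial_compounds = spatial_compounds,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# ids of the always-present MALDI matrix / background species in the
# packaged database; these never enter the statistical panel
MATRIX_IDS <- c("dhb", "dhb_cluster2", "dhb_cluster3", "aminoacridine")

default_panel <- function(db) {
  db <- db[!db$id %in% MATRIX_IDS, , drop = FALSE]
  rows <- lapply(seq_len(nrow(db)), function(i) {
    pos <- split_adducts(db$adducts_pos[i])
    neg <- split_adducts(db$adducts_neg[i])
    if (length(pos)) {
      data.frame(compound_id = db$id[i], mode = "positive", adduct = pos[[1]],
                 stringsAsFactors = FALSE)
    } else {
      data.frame(compound_id = db$id[i], mode = "negative", adduct = neg[[1]],
                 stringsAsFactors = FALSE)
    }
  })
  panel <- do.call(rbind, rows)
  # fixed, documented spread of base abundances across the panel
  panel$base_log <- rep(c(5, 5.5, 6, 6.5, 7), length.out = nrow(panel))
  panel
}

# the 7-down / 27-up differential signature over the packaged database
default_effects <- function(effect_size) {
  down <- c("atp", "adtp", "cmp", "gpc", "ip5", "ip4", "prpp")
  up <- c("pc_32_0", "pc_34_1", "pc_34_2", "pc_36_1", "pc_36_2", "pc_36_4",
          "pc_38_4", "pc_38_6",
          "sm_d34_1", "sm_d36_1", "sm_d38_1", "sm_d40_1", "sm_d42_1",
          "sm_d42_2",
          "lpc_20_4", "lpc_16_0", "lpc_18_0", "lpc_18_1",
          "tg_52_2", "tg_54_3",
          "pa_34_1", "pa_36_2", "pa_38_4", "pa_40_6",
          "ps_36_1", "ps_38_4", "ps_40_6")
  setNames(c(rep(-effect_size, length(down)), rep(effect_size, length(up))),
           c(down, up))
}

# matrix peaks added to every pixel of a given mode
matrix_entries <- function(db, mode) {
  db <- db[db$id %in% MATRIX_IDS, , drop = FALSE]
  col <- if (mode == "positive") "adducts_pos" else "adducts_neg"
  rows <- lapply(seq_len(nrow(db)), function(i) {
    adds <- split_adducts(db[[col]][i])
    if (!length(adds)) return(NULL)
    data.frame(compound_id = db$id[i], mode = mode, adduct = adds,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

child_seed <- function(master, counter) {
  as.integer((as.numeric(master) * 10007 + counter * 101) %% 2147483629)
}

#' Generate a ground-truthed synthetic MSI experiment
#'
#' Per pixel, each panel compound contributes one centroided peak at its
#' theoretical adduct m/z perturbed by the per-sample calibration offset and
#' per-peak jitter; its intensity is
#' `exp(base + group effect + age drift + sample noise + pixel noise) * TIC scale`.
#' Matrix peaks are added to every pixel. The whole dataset is a
#' deterministic function of the config seed.
#'
#' @param config A [synthetic_config()].
#' @return An `msi_experiment`: list with `samples` (id, group, age),
#'   `datasets` (one `msi_dataset` per mode), `truth` (per-compound true
#'   effect, direction, differential flag) and the `config`.
#' @export
#' @examples
#' cfg <- synthetic_config(grid_dim = c(4, 4), modes = "positive", seed = 1)
#' exp <- generate_msi_dataset(cfg)
#' exp$samples
generate_msi_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  np <- config$n_patients; nc <- config$n_controls
  samples <- data.frame(
    sample_id = c(sprintf("C%02d", seq_len(nc)), sprintf("P%02d", seq_len(np))),
    group = rep(c("control", "patient"), c(nc, np)),
    stringsAsFactors = FALSE)
  set.seed(config$seed)
  age_c <- if (config$age_scheme == "cohort") {
    runif(nc, config$control_age_range[1], config$control_age_range[2])
  } else {
    pmax(rnorm(nc, config$patient_age["mean"], config$patient_age["sd"]), 0.5)
  }
  age_p <- pmax(rnorm(np, config$patient_age["mean"], config$patient_age["sd"]), 0.5)
  samples$age <- c(age_c, age_p)
  n_s <- nrow(samples)
  # per-sample, per-mode uniform calibration drift (ppm)
  offsets <- matrix(rnorm(n_s * length(config$modes), 0,
                          config$calib_offset_ppm_sd),
                    nrow = n_s,
                    dimnames = list(samples$sample_id, config$modes))
  age_ref <- mean(samples$age)

  truth <- data.frame(compound_id = unique(config$panel$compound_id),
                      stringsAsFactors = FALSE)
  truth$effect <- ifelse(truth$compound_id %in% names(config$effects),
                         config$effects[truth$compound_id], 0)
  truth$direction <- ifelse(truth$effect > 0, "up",
                            ifelse(truth$effect < 0, "down", "none"))
  truth$differential <- truth$effect != 0

  nx <- config$grid_dim[1]; ny <- config$grid_dim[2]
  n_pix <- nx * ny
  datasets <- list()
  for (mi in seq_along(config$modes)) {
    mode <- config$modes[mi]
    entries <- config$panel[config$panel$mode == mode,
                            c("compound_id", "adduct", "base_log")]
    mat <- matrix_entries(config$db, mode)
    if (!is.null(mat) && nrow(mat)) {
      mat$base_log <- config$matrix_base_log
      entries <- rbind(entries, mat[, c("compound_id", "adduct", "base_log")])
    }
    fmap <- setNames(config$db$formula, config$db$id)
    entries$mz <- mapply(function(id, a) ion_mz(fmap[[id]], a),
                         entries$compound_id, entries$adduct)
    entries$effect <- ifelse(entries$compound_id %in% names(config$effects),
                             config$effects[entries$compound_id], 0)
    n_e <- nrow(entries)
    is_matrix <- entries$compound_id %in% MATRIX_IDS
    spatial <- entries$compound_id %in% config$spatial_compounds

    px <- rep(seq_len(nx), times = ny)
    py <- rep(seq_len(ny), each = nx)
    in_mask <- px <= max(floor(nx / 2), 1L)

    per_sample <- vector("list", n_s)
    for (si in seq_len(n_s)) {
      set.seed(child_seed(config$seed, (si - 1L) * length(config$modes) + mi))
      is_patient <- samples$group[si] == "patient"
      tic <- rlnorm(n_pix, 0, config$tic_sdlog)
      scale_s <- rnorm(1, 0, config$sample_scale_sdlog)
      delta <- rnorm(n_e, 0, ifelse(is_matrix, config$sigma_matrix,
                                    config$sigma_sample))
      meanlog <- entries$base_log + scale_s + delta +
        if (is_patient) entries$effect else 0
      # age-correlated drift is biological: matrix ions are unaffected
      meanlog <- meanlog + ifelse(is_matrix, 0, config$age_drift) *
        (samples$age[si] - age_ref)
      # n_pix x n_e intensity and m/z draws, column-major by compound
      noise <- matrix(rnorm(n_pix * n_e, 0, config$sigma_pixel), n_pix, n_e)
      inten <- exp(sweep(noise, 2, meanlog, "+")) * tic
      if (any(spatial)) inten[!in_mask, spatial] <- 0
      jit <- matrix(rnorm(n_pix * n_e, 0, config$mz_jitter_ppm), n_pix, n_e)
      mzm <- sweep(1 + (jit + offsets[si, mi]) * 1e-6, 2, entries$mz, "*")
      keep <- inten > 0
      per_sample[[si]] <- data.frame(
        sample_id = samples$sample_id[si],
        x = rep(px, n_e)[keep], y = rep(py, n_e)[keep],
        mz = mzm[keep], intensity = inten[keep],
        stringsAsFactors = FALSE)
    }
    peaks <- do.call(rbind, per_sample)
    peaks <- peaks[order(peaks$sample_id, peaks$y, peaks$x, peaks$mz), ,
                   drop = FALSE]
    rownames(peaks) <- NULL
    datasets[[mode]] <- new_msi_dataset(peaks, samples, mode, config$grid_dim)
  }
  structure(list(samples = samples, datasets = datasets, truth = truth,
                 config = config),
            class = "msi_experiment")
}

new_msi_dataset <- function(peaks, samples, mode, grid_dim) {
  stopifnot(all(peaks$intensity >= 0),
            mode %in% c("positive", "negative"))
  structure(list(peaks = peaks, samples = samples, mode = mode,
                 grid_dim = as.integer(grid_dim)),
            class = "msi_dataset")
}

#' @export
print.msi_dataset <- function(x, ...) {
  cat("<msi_dataset> mode ", x$mode, ": ", nrow(x$samples), " samples, ",
      x$grid_dim[1], "x", x$grid_dim[2], " pixels, ",
      nrow(x$peaks), " peaks\n", sep = "")
  invisible(x)
}

#' @export
print.msi_experiment <- function(x, ...) {
  cat("<msi_experiment> ", sum(x$samples$group == "patient"), " patients vs ",
      sum(x$samples$group == "control"), " controls; modes: ",
      paste(names(x$datasets), collapse = ", "), "; ",
      sum(x$truth$differential), "/", nrow(x$truth),
      " panel compounds truly differential\n", sep = "")
  invisible(x)
}

#' Extract one pixel's spectrum
#'
#' @param dataset An `msi_dataset`.
#' @param sample_id Sample id.
#' @param x,y Pixel coordinates.
#' @return Data frame `mz`, `intensity`, sorted by m/z.
#' @export
pixel_spectrum <- function(dataset, sample_id, x, y) {
  p <- dataset$peaks
  sel <- p$sample_id == sample_id & p$x == x & p$y == y
  sp <- p[sel, c("mz", "intensity")]
  sp <- sp[order(sp$mz), , drop = FALSE]
  rownames(sp) <- NULL
  sp
}
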