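# Config-driven orchestration: simulate/ingest -> recalibrate -> TIC
# normalize -> bin -> annotate -> differential stats -> correlation and
# clustering -> ion images, with a run manifest for reproducibility.

#' Pipeline configuration
#'
#' Collects every stage parameter. Defaults equal the analysis parameters
#' the package targets: MS1 tolerance 2 ppm, MS/MS tolerance 500 ppb,
#' binning tolerance 1 ppm, alpha 0.05 with BY adjustment.
#'
#' @param input A [synthetic_config()] to simulate from, or a path to a
#'   dataset written by [write_msi_dataset()] (one per mode, named list
#'   `list(positive = path, negative = path)` or a single path).
#' @param compound_db Path to the compound DB TSV, or `NULL` for the
#'   packaged one.
#' @param calibrants Path to the calibrant TSV, or `NULL` for packaged.
#' @param ms1_ppm,ms2_ppb,bin_ppm Stage tolerances.
#' @param alpha Significance level on adjusted p-values.
#' @param fdr_method `"BY"` or `"BH"`.
#' @param linkage Clustering linkage.
#' @param calibration_model `"single-point"` or `"linear"`.
#' @param out_dir Output directory for stage files and the manifest;
#'   `NULL` = in-memory only.
#' @param n_images Number of top significant features to render as ion
#'   images when writing outputs.
#' @param seed Seed recorded in the manifest (the synthetic config carries
#'   its own generation seed).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = synthetic_config(),
                            compound_db = NULL, calibrants = NULL,
                            ms1_ppm = 2, ms2_ppb = 500, bin_ppm = 1,
                            alpha = 0.05, fdr_method = c("BY", "BH"),
                            linkage = "complete",
                            calibration_model = "single-point",
                            out_dir = NULL, n_images = 2, seed = 42) {
  fdr_method <- match.arg(fdr_method)
  stopifnot(alpha > 0, alpha < 1, ms1_ppm > 0, ms2_ppb > 0, bin_ppm > 0)
  if (!is.null(compound_db) && !file.exists(compound_db)) {
    stop("config error: compound database path does not exist: ", compound_db)
  }
  if (!is.null(calibrants) && !file.exists(calibrants)) {
    stop("config error: calibrant list path does not exist: ", calibrants)
  }
  structure(list(input = input, compound_db = compound_db,
                 calibrants = calibrants, ms1_ppm = ms1_ppm,
                 ms2_ppb = ms2_ppb, bin_ppm = bin_ppm, alpha = alpha,
                 fdr_method = fdr_method, linkage = linkage,
                 calibration_model = calibration_model,
                 out_dir = out_dir, n_images = n_images,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Scalar fields of the file override [pipeline_config()] defaults; a
#' `synthetic` section is passed to [synthetic_config()].
#'
#' @param path Config file (`.yaml`/`.yml`/`.json`).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config error: file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("config error: YAML support needs the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  syn <- raw$synthetic
  raw$synthetic <- NULL
  args <- raw
  if (!is.null(syn)) args$input <- do.call(synthetic_config, syn)
  do.call(pipeline_config, args)
}

stage_log <- function(run, stage, ...) {
  msg <- sprintf(...)
  run$log <- c(run$log, sprintf("[%s] %s", stage, msg))
  message(sprintf("[%s] %s", stage, msg))
  run
}

#' Run the full MSI analysis pipeline
#'
#' Executes every stage on the configured input and returns a results
#' bundle (and writes stage CSVs plus a JSON manifest with config echo and
#' file checksums when `out_dir` is set). Identical config and seed give a
#' bit-identical bundle.
#'
#' @param config A [pipeline_config()].
#' @return An `msi_run` list: `experiment`, `features` (combined annotated
#'   matrix), `stats` (`msi_diff`), `correlation`, `clustering`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  run <- list(config = config, log = character(0))
  db <- load_compound_db(config$compound_db)

  # stage 1: obtain the experiment
  if (inherits(config$input, "synthetic_config")) {
    exper <- generate_msi_dataset(config$input)
    run <- stage_log(run, "simulate", "generated %d samples x %s modes",
                     nrow(exper$samples),
                     paste(names(exper$datasets), collapse = "+"))
  } else {
    paths <- config$input
    if (!is.list(paths)) paths <- list(paths)
    ds <- lapply(paths, read_msi_dataset)
    names(ds) <- vapply(ds, function(d) d$mode, character(1))
    exper <- structure(list(samples = ds[[1]]$samples, datasets = ds,
                            truth = NULL, config = NULL),
                       class = "msi_experiment")
    run <- stage_log(run, "ingest", "read %d dataset(s)", length(ds))
  }

  # stages 2-4 per mode: recalibrate, TIC normalize, bin
  fms <- list()
  for (mode in names(exper$datasets)) {
    d <- exper$datasets[[mode]]
    cal <- load_calibrants(config$calibrants, mode = mode)
    d <- recalibrate_dataset(d, cal, model = config$calibration_model)
    rec <- attr(d, "recalibration")
    run <- stage_log(run, "recalibrate", "%s: %d/%d pixels calibrated",
                     mode, sum(!rec$flagged), nrow(rec))
    d <- tic_normalize_dataset(d, target = "mean-tic")
    run <- stage_log(run, "normalize", "%s: target TIC %.4g", mode,
                     attr(d, "target_tic"))
    fm <- bin_features(d, tolerance_ppm = config$bin_ppm)
    run <- stage_log(run, "bin", "%s: %d peaks -> %d features", mode,
                     nrow(d$peaks), nrow(fm$features))
    fms[[mode]] <- fm
    exper$datasets[[mode]] <- d
  }
  fm <- combine_features(fms)

  # stage 5: annotate features
  fm <- annotate_features(fm, db, tolerance_ppm = config$ms1_ppm)
  run <- stage_log(run, "annotate", "%d/%d features annotated",
                   sum(!is.na(fm$features$annotation_id)), nrow(fm$features))

  # stage 6: differential statistics on candidate metabolite features only;
  # known MALDI matrix / background ions are identified a priori and are
  # not candidate metabolites, so they are excluded from the tested family
  background <- !is.na(fm$features$annotation_id) &
    fm$features$annotation_id %in% MATRIX_IDS
  if (any(background)) {
    run <- stage_log(run, "stats", "excluding %d matrix/background feature(s)",
                     sum(background))
  }
  lfm <- log_transform(subset_features(fm, !background))
  stats <- differential_test(lfm, adjust = config$fdr_method,
                             alpha = config$alpha)
  s <- summary(stats)
  run <- stage_log(run, "stats", "%d significant (%d up, %d down)",
                   s$n_significant, s$n_up, s$n_down)

  # stage 7: co-expression and clustering on significant features
  sig_ids <- stats$feature_id[stats$significant]
  correlation <- if (length(sig_ids) >= 2) {
    spearman_matrix(lfm, features = sig_ids)
  } else NULL
  clustering <- cluster_samples(
    lfm, features = if (length(sig_ids)) sig_ids else NULL,
    linkage = config$linkage)
  if (!is.null(clustering)) {
    run <- stage_log(run, "cluster", "k=2 cut: %s",
                     paste(sprintf("%s=%d", names(table(clustering$labels)),
                                   table(clustering$labels)), collapse = " "))
  }

  run$experiment <- exper
  run$features <- fm
  run$log_features <- lfm
  run$stats <- stats
  run$correlation <- correlation
  run$clustering <- clustering
  class(run) <- "msi_run"

  if (!is.null(config$out_dir)) run <- write_run_outputs(run)
  run$manifest <- build_manifest(run)
  if (!is.null(config$out_dir)) {
    jsonlite::write_json(run$manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  run
}

write_run_outputs <- function(run) {
  out <- run$config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_feature_matrix(run$features, file.path(out, "feature_matrix"))
  write_stat_table(run$stats, file.path(out, "stats.csv"))
  if (!is.null(run$correlation)) {
    write.table(as.data.frame(unclass(run$correlation)),
                file.path(out, "spearman.csv"), sep = ",",
                col.names = NA, quote = FALSE)
  }
  if (!is.null(run$clustering)) {
    write_newick(run$clustering, file.path(out, "clustering.nwk"))
  }
  # ion images of the top significant features, first sample of each group
  sig <- run$stats[run$stats$significant, ]
  sig <- sig[order(sig$p_adj), ]
  n_img <- min(run$config$n_images, nrow(sig))
  if (n_img > 0) {
    for (i in seq_len(n_img)) {
      mode <- sig$mode[i]
      d <- run$experiment$datasets[[mode]]
      for (g in c("control", "patient")) {
        sid <- d$samples$sample_id[d$samples$group == g][1]
        if (is.na(sid)) next
        img <- ion_image(d, sid, sig$mz[i], tolerance_ppm = run$config$bin_ppm)
        fn <- file.path(out, sprintf("ion_%s_%s.png", sig$feature_id[i], sid))
        png(fn, width = 480, height = 480)
        plot(img, main = sprintf("%s %s", sig$feature_id[i], sid))
        dev.off()
      }
    }
  }
  run <- stage_log(run, "write", "outputs in %s", out)
  run
}

build_manifest <- function(run) {
  cfg <- run$config
  cfg_echo <- cfg
  cfg_echo$input <- if (inherits(cfg$input, "synthetic_config")) {
    c(cfg$input[setdiff(names(cfg$input), c("db", "panel", "effects"))],
      list(panel_size = nrow(cfg$input$panel),
           n_up = sum(cfg$input$effects > 0),
           n_down = sum(cfg$input$effects < 0)))
  } else cfg$input
  checksums <- NULL
  if (!is.null(cfg$out_dir) && dir.exists(cfg$out_dir)) {
    files <- list.files(cfg$out_dir, full.names = TRUE)
    files <- files[!grepl("manifest\\.json$", files)]
    checksums <- as.list(tools::md5sum(files))
    names(checksums) <- basename(files)
  }
  list(package = "msimetab",
       version = as.character(packageVersion("msimetab")),
       seed = cfg$seed, config = unclass(cfg_echo), log = run$log,
       checksums = checksums)
}

#' @export
print.msi_run <- function(x, ...) {
  cat("<msi_run>\n")
  for (l in x$log) cat(" ", l, "\n")
  invisible(x)
}

#' Render an ion image
#'
#' Per-pixel summed intensity of all peaks within the ppm window around a
#' center m/z, for one sample. Pixels without a matching peak are 0.
#'
#' @param dataset An `msi_dataset`.
#' @param sample_id Sample to render.
#' @param center_mz Window center, Da.
#' @param tolerance_ppm Half-window, ppm (default 1).
#' @return An `ion_image`: the intensity matrix (`nx` x `ny`) with the
#'   window recorded in attributes.
#' @export
ion_image <- function(dataset, sample_id, center_mz, tolerance_ppm = 1) {
  stopifnot(inherits(dataset, "msi_dataset"))
  if (!sample_id %in% dataset$samples$sample_id) {
    stop("lookup error: unknown sample '", sample_id, "'")
  }
  nx <- dataset$grid_dim[1]; ny <- dataset$grid_dim[2]
  p <- dataset$peaks
  sel <- p$sample_id == sample_id &
    abs(p$mz / center_mz - 1) * 1e6 <= tolerance_ppm
  img <- matrix(0, nx, ny)
  if (any(sel)) {
    acc <- rowsum(p$intensity[sel], (p$x[sel] - 1L) + nx * (p$y[sel] - 1L))
    img[as.integer(rownames(acc)) + 1L] <- acc
  }
  structure(img, class = "ion_image", center_mz = center_mz,
            tolerance_ppm = tolerance_ppm, sample_id = sample_id)
}

#' @export
plot.ion_image <- function(x, scale = c("linear", "log"), ...) {
  scale <- match.arg(scale)
  m <- unclass(x)
  if (scale == "log") m <- log1p(m)
  image(seq_len(nrow(m)), seq_len(ncol(m)), m, col = hcl.colors(64, "Inferno"),
        xlab = "x", ylab = "y", useRaster = TRUE, ...)
  invisible(x)
}
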