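# Spectrum recalibration against a calibrant list, per-pixel TIC
# normalization, and ppm-tolerance peak binning into a sample-by-feature
# matrix of mean pixel intensities.

#' Load a calibrant list
#'
#' Reads a TSV of internal calibrants (`mode, name, formula, adduct,
#' mz_ref`). The theoretical m/z of each entry is recomputed from its
#' formula and adduct at load time and must agree with the stored reference
#' value to 1e-5 Da; disagreement aborts the load.
#'
#' @param path Calibrant TSV (default: packaged list).
#' @param mode Optional mode filter.
#' @return Data frame with recomputed `mz` column.
#' @export
load_calibrants <- function(path = NULL, mode = NULL) {
  if (is.null(path)) path <- .extdata("calibrants.tsv")
  cal <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("mode", "name", "formula", "adduct", "mz_ref") %in% names(cal)))
  cal$mz <- mapply(function(f, a) ion_mz(f, a), cal$formula, cal$adduct)
  bad <- abs(cal$mz - cal$mz_ref) > 1e-5
  if (any(bad)) {
    stop("calibrant list inconsistent: stored m/z differs from formula-derived ",
         "value by > 1e-5 Da for ", paste(cal$name[bad], collapse = ", "))
  }
  if (!is.null(mode)) cal <- cal[cal$mode == mode, , drop = FALSE]
  rownames(cal) <- NULL
  cal
}

#' Recalibrate a spectrum against a calibrant list
#'
#' Matches calibrants to the spectrum within a ppm search window.
#' `"single-point"` applies the uniform multiplicative correction that
#' zeroes the error of the matched calibrant (the most intense matched
#' calibrant peak; ties broken by lower m/z), emulating single-point
#' recalibration. `"linear"` least-squares fits the ppm drift as a linear
#' function of m/z over all matched calibrants (requires >= 2).
#'
#' If no calibrant is found the spectrum is passed through unchanged and
#' flagged rather than corrected.
#'
#' @param spectrum Data frame with columns `mz`, `intensity`.
#' @param calibrants Calibrant table from [load_calibrants()].
#' @param model `"single-point"` or `"linear"`.
#' @param search_ppm Half-window for calibrant matching (default 5 ppm).
#' @return List of class `recal_spectrum`: `spectrum` (corrected),
#'   `offset_ppm` (fitted drift; for linear, at the matched calibrants'
#'   mean m/z), `matched` (per-calibrant pre/post errors), `flagged`.
#' @export
recalibrate <- function(spectrum, calibrants,
                        model = c("single-point", "linear"),
                        search_ppm = 5) {
  model <- match.arg(model)
  stopifnot(is.data.frame(spectrum), all(c("mz", "intensity") %in% names(spectrum)))
  matched <- match_calibrants(spectrum, calibrants, search_ppm)
  n_min <- if (model == "single-point") 1L else 2L
  if (nrow(matched) < n_min) {
    return(structure(list(spectrum = spectrum, offset_ppm = NA_real_,
                          matched = matched, flagged = TRUE, model = model),
                     class = "recal_spectrum"))
  }
  if (model == "single-point") {
    pick <- order(-matched$intensity, matched$mz_obs)[1]
    factor_fun <- function(mz) rep(matched$mz_theo[pick] / matched$mz_obs[pick],
                                   length(mz))
    offset <- matched$ppm_before[pick]
  } else {
    fit <- lm(ppm_before ~ mz_obs, data = matched)
    factor_fun <- function(mz) {
      1 / (1 + unname(predict_linear(fit, mz)) * 1e-6)
    }
    offset <- unname(predict_linear(fit, mean(matched$mz_obs)))
  }
  corrected <- spectrum
  corrected$mz <- spectrum$mz * factor_fun(spectrum$mz)
  after <- match_calibrants(corrected, calibrants, search_ppm)
  structure(list(spectrum = corrected, offset_ppm = offset, matched = matched,
                 after = after, flagged = FALSE, model = model),
            class = "recal_spectrum")
}

predict_linear <- function(fit, x) coef(fit)[1] + coef(fit)[2] * x

match_calibrants <- function(spectrum, calibrants, search_ppm) {
  rows <- lapply(seq_len(nrow(calibrants)), function(i) {
    theo <- calibrants$mz[i]
    rel <- abs(spectrum$mz / theo - 1) * 1e6
    j <- which(rel <= search_ppm)
    if (!length(j)) return(NULL)
    j <- j[which.max(spectrum$intensity[j])]
    data.frame(name = calibrants$name[i], mz_theo = theo,
               mz_obs = spectrum$mz[j], intensity = spectrum$intensity[j],
               ppm_before = (spectrum$mz[j] - theo) / theo * 1e6,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(name = character(0), mz_theo = numeric(0),
                      mz_obs = numeric(0), intensity = numeric(0),
                      ppm_before = numeric(0))
  }
  out
}

#' @export
print.recal_spectrum <- function(x, ...) {
  if (x$flagged) {
    cat("<recal_spectrum> FLAGGED: no calibrant matched; spectrum unchanged\n")
  } else {
    cat("<recal_spectrum> ", x$model, " model, fitted offset ",
        sprintf("%+.3f", x$offset_ppm), " ppm, ", nrow(x$matched),
        " calibrant(s) matched\n", sep = "")
  }
  invisible(x)
}

#' Recalibrate every pixel of a dataset
#'
#' Applies single-point (or linear) recalibration pixel by pixel, using a
#' vectorized implementation equivalent to calling [recalibrate()] on each
#' pixel spectrum. Pixels where no calibrant is found are passed through
#' and flagged.
#'
#' @param dataset An `msi_dataset`.
#' @param calibrants Calibrant table; defaults to the packaged list for the
#'   dataset's mode.
#' @param model Calibration model (see [recalibrate()]).
#' @param search_ppm Calibrant search half-window in ppm.
#' @return The dataset with corrected m/z; per-pixel fitted offsets in
#'   `attr(, "recalibration")`.
#' @export
recalibrate_dataset <- function(dataset, calibrants = NULL,
                                model = c("single-point", "linear"),
                                search_ppm = 5) {
  model <- match.arg(model)
  if (is.null(calibrants)) calibrants <- load_calibrants(mode = dataset$mode)
  p <- dataset$peaks
  key <- paste(p$sample_id, p$x, p$y, sep = "\r")
  ukey <- unique(key)
  ki <- match(key, ukey)
  if (model == "linear") {
    # linear drift is rarely needed at FTICR scale; reuse the per-spectrum
    # path (clarity over speed)
    pieces <- split(seq_len(nrow(p)), ki)
    offs <- rep(NA_real_, length(ukey))
    for (u in seq_along(pieces)) {
      idx <- pieces[[u]]
      r <- recalibrate(p[idx, c("mz", "intensity")], calibrants, model,
                       search_ppm)
      p$mz[idx] <- r$spectrum$mz
      offs[u] <- r$offset_ppm
    }
  } else {
    # single-point, vectorized: per pixel pick the most intense matched
    # calibrant peak (ties: lower m/z), derive one multiplicative factor
    best <- data.frame(pix = integer(0), inten = numeric(0),
                       factor = numeric(0), ppm = numeric(0),
                       mz = numeric(0))
    for (i in seq_len(nrow(calibrants))) {
      theo <- calibrants$mz[i]
      sel <- which(abs(p$mz / theo - 1) * 1e6 <= search_ppm)
      if (!length(sel)) next
      cand <- data.frame(pix = ki[sel], inten = p$intensity[sel],
                         factor = theo / p$mz[sel],
                         ppm = (p$mz[sel] - theo) / theo * 1e6,
                         mz = p$mz[sel])
      best <- rbind(best, cand)
    }
    offs <- rep(NA_real_, length(ukey))
    fac <- rep(1, length(ukey))
    if (nrow(best)) {
      best <- best[order(best$pix, -best$inten, best$mz), , drop = FALSE]
      top <- best[!duplicated(best$pix), , drop = FALSE]
      fac[top$pix] <- top$factor
      offs[top$pix] <- top$ppm
    }
    p$mz <- p$mz * fac[ki]
  }
  out <- new_msi_dataset(p, dataset$samples, dataset$mode, dataset$grid_dim)
  pk <- do.call(rbind, strsplit(ukey, "\r", fixed = TRUE))
  attr(out, "recalibration") <- data.frame(
    sample_id = pk[, 1], x = as.integer(pk[, 2]), y = as.integer(pk[, 3]),
    offset_ppm = offs, flagged = is.na(offs), stringsAsFactors = FALSE)
  out
}

#' TIC-normalize a spectrum
#'
#' Scales intensities so the spectrum's total ion current equals the
#' target, preserving within-spectrum intensity ratios.
#'
#' @param spectrum Data frame `mz`, `intensity` with positive TIC.
#' @param target Target TIC (default 1).
#' @return The scaled spectrum.
#' @export
tic_normalize <- function(spectrum, target = 1) {
  tic <- sum(spectrum$intensity)
  if (!is.finite(tic) || tic <= 0) stop("domain error: spectrum TIC must be > 0")
  spectrum$intensity <- spectrum$intensity * (target / tic)
  spectrum
}

#' TIC-normalize every pixel of a dataset
#'
#' Scales each pixel so its total ion current equals the target: the
#' dataset-wide mean TIC (default) or 1. Zero-TIC pixels are excluded and
#' reported.
#'
#' @param dataset An `msi_dataset`.
#' @param target `"mean-tic"` or `"unit"`.
#' @return The normalized dataset; excluded pixel count in
#'   `attr(, "excluded_pixels")`.
#' @export
tic_normalize_dataset <- function(dataset, target = c("mean-tic", "unit")) {
  target <- match.arg(target)
  p <- dataset$peaks
  key <- paste(p$sample_id, p$x, p$y, sep = "\r")
  ukey <- unique(key)
  ki <- match(key, ukey)
  tic <- as.vector(rowsum(p$intensity, ki, reorder = TRUE))
  goal <- if (target == "unit") 1 else mean(tic[tic > 0])
  zero <- tic <= 0
  n_zero <- sum(zero)
  if (n_zero) message("tic_normalize_dataset: excluding ", n_zero,
                      " zero-TIC pixel(s)")
  scale <- ifelse(zero, NA_real_, goal / tic)
  keep <- !zero[ki]
  p$intensity <- p$intensity * scale[ki]
  p <- p[keep, , drop = FALSE]
  out <- new_msi_dataset(p, dataset$samples, dataset$mode, dataset$grid_dim)
  attr(out, "excluded_pixels") <- n_zero
  attr(out, "target_tic") <- goal
  out
}

new_msi_features <- function(intensity, features, samples, logged = FALSE,
                             imputed_value = NA_real_) {
  stopifnot(nrow(intensity) == nrow(features),
            ncol(intensity) == nrow(samples))
  structure(list(intensity = intensity, features = features,
                 samples = samples, logged = logged,
                 imputed_value = imputed_value),
            class = "msi_features")
}

#' @export
print.msi_features <- function(x, ...) {
  cat("<msi_features> ", nrow(x$features), " features x ", nrow(x$samples),
      " samples", if (isTRUE(x$logged)) " (log scale)", "\n", sep = "")
  invisible(x)
}

#' Bin peaks across a dataset into features
#'
#' Clusters all peaks (across pixels and samples) on the m/z axis so that
#' every member lies within the ppm tolerance of its feature's consensus
#' (intensity-weighted mean) m/z. The algorithm sorts peaks by m/z, splits
#' at gaps exceeding the tolerance (single-linkage), recenters each
#' cluster on its intensity-weighted consensus, and extracts the feature
#' from the +/- tolerance interval around that consensus: stray tail peaks
#' outside the interval are excluded from the feature (the interval
#' semantics of vendor MSI software), iterating until the consensus is
#' stable. The procedure is deterministic and independent of sample order.
#'
#' Per sample, the feature intensity is the mean over all of that sample's
#' pixels (pixels without the peak contribute 0); cells that remain zero
#' are imputed at half the smallest positive cell of the matrix so that
#' every cell is finite after log transformation.
#'
#' @param dataset An `msi_dataset` (recalibrated and normalized).
#' @param tolerance_ppm Half-window tolerance in ppm (default 1).
#' @return An `msi_features` object.
#' @export
bin_features <- function(dataset, tolerance_ppm = 1) {
  if (!is.numeric(tolerance_ppm) || tolerance_ppm <= 0) {
    stop("domain error: tolerance_ppm must be > 0")
  }
  p <- dataset$peaks
  samples <- dataset$samples
  n_pix <- prod(dataset$grid_dim)
  if (nrow(p) == 0L) {
    return(new_msi_features(
      matrix(numeric(0), 0, nrow(samples),
             dimnames = list(NULL, samples$sample_id)),
      data.frame(feature_id = character(0), mz = numeric(0),
                 mode = character(0), n_members = integer(0)),
      samples))
  }
  ord <- order(p$mz)
  cl <- bin_mz(p$mz[ord], p$intensity[ord], tolerance_ppm)
  cluster <- integer(nrow(p))
  cluster[ord] <- cl
  n_trimmed <- sum(cluster == 0L)
  if (n_trimmed) {
    p <- p[cluster != 0L, , drop = FALSE]
    cluster <- cluster[cluster != 0L]
  }
  n_feat <- max(cluster)
  # consensus m/z: intensity-weighted mean per cluster
  wsum <- as.vector(rowsum(p$intensity * p$mz, cluster))
  w <- as.vector(rowsum(p$intensity, cluster))
  consensus <- wsum / w
  # per (feature, sample) mean over all pixels of the sample
  si <- match(p$sample_id, samples$sample_id)
  idx <- (si - 1L) * n_feat + cluster
  tot <- numeric(n_feat * nrow(samples))
  acc <- rowsum(p$intensity, idx)
  tot[as.integer(rownames(acc))] <- acc
  m <- matrix(tot, nrow = n_feat, ncol = nrow(samples),
              dimnames = list(NULL, samples$sample_id)) / n_pix
  ford <- order(consensus)
  m <- m[ford, , drop = FALSE]
  consensus <- consensus[ford]
  n_members <- tabulate(cluster, nbins = n_feat)[ford]
  features <- data.frame(
    feature_id = make.unique(sprintf("%s_%0.5f", substr(dataset$mode, 1, 3),
                                     consensus), sep = "_"),
    mz = consensus, mode = dataset$mode, n_members = n_members,
    stringsAsFactors = FALSE)
  rownames(m) <- features$feature_id
  # imputation floor: half the smallest positive cell
  imput <- NA_real_
  if (any(m == 0) && any(m > 0)) {
    imput <- min(m[m > 0]) / 2
    m[m == 0] <- imput
  }
  out <- new_msi_features(m, features, samples, logged = FALSE,
                          imputed_value = imput)
  attr(out, "n_trimmed") <- n_trimmed
  out
}

# cluster a sorted m/z vector; returns integer cluster ids (1-based,
# increasing with m/z); 0 marks stray peaks outside every feature interval
bin_mz <- function(mz, intensity, tolerance_ppm) {
  n <- length(mz)
  if (n == 1L) return(1L)
  tol <- tolerance_ppm * 1e-6
  gap_rel <- diff(mz) / mz[-n]
  seg <- cumsum(c(1L, as.integer(gap_rel > tol)))
  out <- integer(n)
  nxt <- 1L
  for (s in unique(seg)) {
    idx <- which(seg == s)
    keep <- trim_to_interval(mz[idx], intensity[idx], tol)
    if (any(keep)) {
      out[idx[keep]] <- nxt
      nxt <- nxt + 1L
    }
  }
  out
}

# iterate: consensus = intensity-weighted mean of in-interval members;
# members are the peaks within +/- tol of the consensus
trim_to_interval <- function(mz, intensity, tol, max_iter = 20L) {
  keep <- rep(TRUE, length(mz))
  for (i in seq_len(max_iter)) {
    cons <- sum(mz[keep] * intensity[keep]) / sum(intensity[keep])
    new <- abs(mz - cons) / cons <= tol
    if (!any(new)) return(keep) # degenerate; keep previous membership
    if (identical(new, keep)) return(keep)
    keep <- new
  }
  keep
}

#' Combine per-mode feature matrices
#'
#' Stacks feature matrices from different ionization modes over the same
#' samples.
#'
#' @param fms List of `msi_features` objects.
#' @return A single `msi_features`.
#' @export
combine_features <- function(fms) {
  stopifnot(length(fms) >= 1)
  if (length(fms) == 1L) return(fms[[1]])
  ids <- lapply(fms, function(f) f$samples$sample_id)
  if (!all(vapply(ids, identical, logical(1), ids[[1]]))) {
    stop("combine error: feature matrices have different sample sets")
  }
  m <- do.call(rbind, lapply(fms, function(f) f$intensity))
  features <- do.call(rbind, lapply(fms, function(f) f$features))
  rownames(features) <- NULL
  logged <- vapply(fms, function(f) isTRUE(f$logged), logical(1))
  stopifnot(all(logged) || !any(logged))
  new_msi_features(m, features, fms[[1]]$samples, logged = all(logged),
                   imputed_value = min(vapply(fms, function(f)
                     ifelse(is.na(f$imputed_value), Inf, f$imputed_value),
                     numeric(1))))
}

#' Subset a feature matrix by feature index
#'
#' @param fm An `msi_features`.
#' @param idx Logical or integer feature index.
#' @return The subsetted `msi_features`.
#' @export
subset_features <- function(fm, idx) {
  fm$intensity <- fm$intensity[idx, , drop = FALSE]
  fm$features <- fm$features[idx, , drop = FALSE]
  rownames(fm$features) <- NULL
  fm
}

#' Annotate binned features by accurate mass
#'
#' Runs [annotate_ms1()] on each feature's consensus m/z and stores the
#' top-ranked candidate (with its error and the competing-candidate count)
#' in the feature table.
#'
#' @param fm An `msi_features`.
#' @param db Compound database.
#' @param tolerance_ppm MS1 tolerance (default 2 ppm).
#' @return `fm` with annotation columns added to `fm$features`.
#' @export
annotate_features <- function(fm, db = load_compound_db(), tolerance_ppm = 2) {
  ions <- list(positive = compound_ions(db, "positive"),
               negative = compound_ions(db, "negative"))
  f <- fm$features
  f$annotation_id <- NA_character_
  f$annotation_name <- NA_character_
  f$annotation_adduct <- NA_character_
  f$annotation_ppm <- NA_real_
  f$n_candidates <- 0L
  for (i in seq_len(nrow(f))) {
    res <- annotate_ms1(f$mz[i], f$mode[i], db, tolerance_ppm,
                        ions = ions[[f$mode[i]]])
    f$n_candidates[i] <- nrow(res)
    if (nrow(res)) {
      f$annotation_id[i] <- res$compound_id[1]
      f$annotation_name[i] <- res$name[1]
      f$annotation_adduct[i] <- res$adduct[1]
      f$annotation_ppm[i] <- res$error_ppm[1]
    }
  }
  fm$features <- f
  fm
}
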