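# Independent oracles and small fixture builders used across the suite.

# brute-force MS1 annotation: scan every (compound, adduct) pair directly
brute_force_ms1 <- function(observed_mz, mode, db, tolerance_ppm) {
  hits <- list()
  col <- if (mode == "positive") "adducts_pos" else "adducts_neg"
  for (i in seq_len(nrow(db))) {
    adds <- msimetab:::split_adducts(db[[col]][i])
    for (a in adds) {
      theo <- ion_mz(db$formula[i], a)
      ppm <- (observed_mz - theo) / theo * 1e6
      if (abs(ppm) <= tolerance_ppm) {
        hits[[length(hits) + 1L]] <- data.frame(
          compound_id = db$id[i], adduct = a, theoretical_mz = theo,
          error_ppm = ppm, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(compound_id = character(0), adduct = character(0),
                      theoretical_mz = numeric(0), error_ppm = numeric(0)))
  }
  out <- do.call(rbind, hits)
  out[order(abs(out$error_ppm), out$compound_id), , drop = FALSE]
}

# brute-force single-linkage clustering of m/z values at a relative
# tolerance, via union-find over all pairs
brute_force_single_linkage <- function(mz, tol_ppm) {
  n <- length(mz)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (abs(mz[i] - mz[j]) / min(mz[i], mz[j]) * 1e6 <= tol_ppm) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots[order(mz)]))
}

# direct Spearman rho via average ranks and the Pearson formula on ranks
brute_force_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# independently coded BY/BH step-up adjustment (the formulaic oracle)
step_up_adjust <- function(p, method = c("BY", "BH")) {
  method <- match.arg(method)
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  cm <- if (method == "BY") sum(1 / seq_len(m)) else 1
  adj <- pmin(1, rev(cummin(rev(m * cm * ps / seq_len(m)))))
  out <- numeric(m)
  out[o] <- adj
  out
}

# tiny noiseless config: every peak lands exactly on its theoretical m/z
noiseless_config <- function(..., grid_dim = c(1, 1), modes = "positive",
                             n_patients = 1, n_controls = 1) {
  synthetic_config(n_patients = n_patients, n_controls = n_controls,
                   grid_dim = grid_dim, modes = modes,
                   sigma_sample = 0, sigma_pixel = 0, tic_sdlog = 0,
                   sample_scale_sdlog = 0, sigma_matrix = 0,
                   mz_jitter_ppm = 0, calib_offset_ppm_sd = 0,
                   effects = setNames(numeric(0), character(0)), ...)
}

# theoretical m/z of every species (panel + matrix) synthesized in a mode
panel_theoretical_mz <- function(config, mode) {
  pan <- config$panel[config$panel$mode == mode, ]
  mat <- msimetab:::matrix_entries(config$db, mode)
  fmap <- setNames(config$db$formula, config$db$id)
  ids <- c(pan$compound_id, mat$compound_id)
  adds <- c(pan$adduct, mat$adduct)
  setNames(mapply(function(id, a) ion_mz(fmap[[id]], a), ids, adds), ids)
}
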