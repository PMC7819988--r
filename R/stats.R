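# Differential analysis on the feature matrix: per-feature ordinary least
# squares of log intensity on group + age (the "t-test with age as
# covariate"), Benjamini-Yekutieli FDR control, Spearman co-expression and
# Euclidean hierarchical clustering.

#' Log-transform a feature matrix
#'
#' Natural-log transforms every cell. All cells must be positive (the
#' binning stage imputes zeros before this point); a non-positive cell
#' aborts with the offending feature and sample named.
#'
#' @param fm An `msi_features`.
#' @return The transformed `msi_features` (`logged = TRUE`).
#' @export
log_transform <- function(fm) {
  stopifnot(inherits(fm, "msi_features"))
  if (isTRUE(fm$logged)) stop("transform error: matrix is already on the log scale")
  bad <- which(!(fm$intensity > 0), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("transform error: non-positive cell at feature '",
         fm$features$feature_id[bad[1, 1]], "', sample '",
         fm$samples$sample_id[bad[1, 2]], "'")
  }
  fm$intensity <- log(fm$intensity)
  fm$logged <- TRUE
  fm
}

#' FDR adjustment (Benjamini-Yekutieli / Benjamini-Hochberg)
#'
#' Step-up FDR adjustment. `"BY"` (default) is the arbitrary-dependence
#' variant, inflating the BH adjustment by the harmonic factor
#' `c(m) = sum(1/(1:m))`; appropriate when features (correlated metabolite
#' intensities) are not independent. Missing p-values propagate as missing
#' and are excluded from the family size `m`.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @param method `"BY"` or `"BH"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
#' @examples
#' adjust_fdr(c(0.01, 0.02, 0.04)) # about 0.0550 0.0550 0.0733
adjust_fdr <- function(p, method = c("BY", "BH")) {
  method <- match.arg(method)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop("domain error: p-values must lie in [0, 1]")
  }
  out <- rep(NA_real_, length(p))
  out[ok] <- p.adjust(p[ok], method = method)
  out
}

#' Per-feature differential test with an age covariate
#'
#' For every feature, fits ordinary least squares of log intensity on a
#' group indicator (patient = 1) plus age, and tests the group coefficient
#' with a two-sided t-test on `n - 3` residual degrees of freedom
#' (`n - 2` when no covariate is supplied, which reduces exactly to the
#' pooled-variance two-sample t-test). P-values are FDR-adjusted across
#' features.
#'
#' @param fm An `msi_features` on the log scale (or a plain numeric matrix
#'   features x samples, with `group`/`age` supplied).
#' @param group Group labels (`"patient"`/`"control"`); taken from the
#'   sample table when `fm` is an `msi_features`.
#' @param age Numeric covariate; `NULL` drops the covariate. Taken from the
#'   sample table by default.
#' @param adjust FDR method, `"BY"` (default) or `"BH"`.
#' @param alpha Significance threshold on the adjusted p-value.
#' @return An `msi_diff` data frame with per-feature `estimate` (log
#'   patient-minus-control difference), `t`, `p`, `p_adj`, `direction` and
#'   `significant`; features with a degenerate fit get `NA` p-values and a
#'   `singular` flag.
#' @export
differential_test <- function(fm, group = NULL, age = NULL,
                              adjust = c("BY", "BH"), alpha = 0.05) {
  adjust <- match.arg(adjust)
  if (inherits(fm, "msi_features")) {
    if (!isTRUE(fm$logged)) {
      stop("differential_test expects log-scale intensities; call log_transform() first")
    }
    y <- fm$intensity
    if (is.null(group)) group <- fm$samples$group
    if (missing(age)) age <- fm$samples$age
    features <- fm$features
  } else {
    y <- as.matrix(fm)
    features <- data.frame(feature_id = rownames(y) %||%
                             paste0("f", seq_len(nrow(y))),
                           stringsAsFactors = FALSE)
  }
  g <- as.integer(group == "patient")
  if (length(unique(g)) != 2L || min(tabulate(g + 1L, 2L)) < 2L) {
    stop("differential_test needs two groups with n >= 2 each")
  }
  X <- cbind(`(Intercept)` = 1, group = g)
  if (!is.null(age)) {
    if (any(!is.finite(age))) stop("ages must be finite")
    X <- cbind(X, age = age)
  }
  n <- ncol(y); k <- ncol(X)
  if (qr(X)$rank < k) {
    stop("singular design: group and covariate are exactly collinear")
  }
  df <- n - k
  xtx_inv <- chol2inv(chol(crossprod(X)))
  beta <- xtx_inv %*% crossprod(X, t(y))       # k x n_features
  resid <- t(y) - X %*% beta
  rss <- colSums(resid^2)
  s2 <- rss / df
  se <- sqrt(s2 * xtx_inv[2, 2])
  est <- beta[2, ]
  singular <- se <= sqrt(.Machine$double.eps) * pmax(abs(est), 1)
  tstat <- ifelse(singular, NA_real_, est / se)
  p <- 2 * pt(-abs(tstat), df = df)
  p_adj <- adjust_fdr(p, adjust)
  res <- data.frame(feature_id = features$feature_id,
                    estimate = est, t = tstat, p = p, p_adj = p_adj,
                    direction = ifelse(est > 0, "up",
                                       ifelse(est < 0, "down", "none")),
                    significant = !is.na(p_adj) & p_adj < alpha,
                    singular = singular,
                    stringsAsFactors = FALSE, row.names = NULL)
  extra <- setdiff(names(features), names(res))
  if (length(extra)) res <- cbind(res, features[extra])
  attr(res, "alpha") <- alpha
  attr(res, "adjust") <- adjust
  attr(res, "covariates") <- if (is.null(age)) character(0) else "age"
  attr(res, "df") <- df
  class(res) <- c("msi_diff", "data.frame")
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
`[.msi_diff` <- function(x, ...) {
  # subsetting returns a plain data frame; the msi_diff print method only
  # makes sense for the full result table
  y <- NextMethod()
  if (is.data.frame(y)) class(y) <- "data.frame"
  y
}

#' @export
print.msi_diff <- function(x, n = 10, ...) {
  cat("<msi_diff> ", nrow(x), " features; ", sum(x$significant),
      " significant at adjusted p < ", attr(x, "alpha"), " (",
      attr(x, "adjust"), ")",
      if (length(attr(x, "covariates"))) paste0("; covariates: ",
        paste(attr(x, "covariates"), collapse = ", ")), "\n", sep = "")
  ord <- order(x$p_adj)
  print.data.frame(head(as.data.frame(x)[ord, c("feature_id", "estimate",
                                                "t", "p", "p_adj",
                                                "direction", "significant")],
                        n), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.msi_diff <- function(object, ...) {
  sig <- object[object$significant & !is.na(object$significant), ]
  out <- list(n_features = nrow(object), n_significant = nrow(sig),
              n_up = sum(sig$direction == "up"),
              n_down = sum(sig$direction == "down"),
              alpha = attr(object, "alpha"), adjust = attr(object, "adjust"))
  class(out) <- "summary.msi_diff"
  out
}

#' @export
print.summary.msi_diff <- function(x, ...) {
  cat("Differential analysis: ", x$n_significant, " of ", x$n_features,
      " features significant (adjusted p < ", x$alpha, ", ", x$adjust,
      "): ", x$n_up, " up, ", x$n_down, " down in patients\n", sep = "")
  invisible(x)
}

#' @export
coef.msi_diff <- function(object, ...) {
  setNames(object$estimate, object$feature_id)
}

#' @export
plot.msi_diff <- function(x, ...) {
  sig <- x[x$significant & !is.na(x$significant), ]
  sig <- sig[order(sig$estimate), ]
  if (!nrow(sig)) {
    plot.new(); title("No significant features"); return(invisible(x))
  }
  lab <- if (!is.null(sig$annotation_name)) {
    ifelse(is.na(sig$annotation_name), sig$feature_id, sig$annotation_name)
  } else sig$feature_id
  sev <- -log10(sig$p_adj)
  cols <- hcl.colors(100, "Reds", rev = TRUE)[
    pmax(1, pmin(100, round(sev / max(sev) * 100)))]
  op <- par(mar = c(4, 10, 2, 1)); on.exit(par(op))
  barplot(sig$estimate, names.arg = lab, horiz = TRUE, las = 1,
          col = cols, cex.names = 0.6,
          xlab = "log intensity difference (patient - control)", ...)
  abline(v = 0)
  invisible(x)
}

#' Spearman correlation matrix of features
#'
#' Pairwise Spearman rank correlation (average ranks for ties) across
#' samples. Zero-variance features have undefined correlation with any
#' other feature and are reported as `NA` off-diagonal; the diagonal is 1.
#'
#' @param fm An `msi_features` (log scale or not; Spearman is rank-based)
#'   or a features-x-samples matrix.
#' @param features Optional subset of feature ids.
#' @return A symmetric correlation matrix of class `msi_corr`.
#' @export
spearman_matrix <- function(fm, features = NULL) {
  y <- if (inherits(fm, "msi_features")) fm$intensity else as.matrix(fm)
  if (!is.null(features)) y <- y[rownames(y) %in% features, , drop = FALSE]
  if (ncol(y) < 3L) stop("spearman_matrix needs >= 3 samples")
  rho <- suppressWarnings(cor(t(y), method = "spearman"))
  diag(rho) <- 1
  class(rho) <- c("msi_corr", class(rho))
  rho
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of the samples on their (significant-) feature
#' vectors using Euclidean distance. Samples are ordered lexicographically
#' by id before clustering so the merge order, and hence the tree, is
#' deterministic.
#'
#' @param fm An `msi_features`.
#' @param features Optional feature-id subset (e.g. the significant ones).
#' @param linkage Agglomeration method for [hclust()] (default
#'   `"complete"`; `"ward.D2"`, `"average"`, `"single"` also supported).
#' @param k Number of flat clusters to cut (default 2).
#' @return An `msi_clust` list: `hclust` tree, flat `labels` at `k`, and
#'   the sample table.
#' @export
cluster_samples <- function(fm, features = NULL, linkage = "complete", k = 2) {
  stopifnot(inherits(fm, "msi_features"))
  if (nrow(fm$samples) < 2L) stop("domain error: clustering needs >= 2 samples")
  y <- t(fm$intensity)
  if (!is.null(features)) {
    y <- y[, colnames(y) %in% features, drop = FALSE]
    if (ncol(y) == 0L) stop("domain error: no features left to cluster on")
  }
  ord <- order(rownames(y))
  y <- y[ord, , drop = FALSE]
  hc <- hclust(dist(y, method = "euclidean"), method = linkage)
  labels <- cutree(hc, k = k)
  structure(list(hclust = hc, labels = labels,
                 samples = fm$samples[match(names(labels),
                                            fm$samples$sample_id), ],
                 linkage = linkage, k = k),
            class = "msi_clust")
}

#' @export
print.msi_clust <- function(x, ...) {
  cat("<msi_clust> ", length(x$labels), " samples, ", x$linkage,
      " linkage, k = ", x$k, "\n", sep = "")
  print(table(cluster = x$labels, group = x$samples$group))
  invisible(x)
}

#' @export
plot.msi_clust <- function(x, ...) {
  plot(x$hclust, xlab = "", sub = "", ...)
  invisible(x)
}

#' Export a clustering tree as Newick
#'
#' @param x An `msi_clust`.
#' @param path Output file.
#' @export
write_newick <- function(x, path) {
  stopifnot(inherits(x, "msi_clust"))
  ape::write.tree(ape::as.phylo(x$hclust), file = path)
  invisible(path)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two clusterings of the same items
#' (1 = identical partitions, ~0 = random agreement).
#'
#' @param a,b Cluster label vectors of equal length.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(length(a))
  expected <- sum_a * sum_b / n
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

#' Write a differential-result table as CSV
#'
#' @param x An `msi_diff`.
#' @param path Output CSV.
#' @export
write_stat_table <- function(x, path) {
  write.table(as.data.frame(x), path, sep = ",", row.names = FALSE,
              quote = TRUE)
  invisible(path)
}
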