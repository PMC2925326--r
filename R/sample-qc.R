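#' Sample quality-control parameters
#'
#' Thresholds for the four per-sample QC criteria applied to a normalized
#' expression matrix: median probe intensity, mean correlation with the
#' other samples of the same tissue, behaviour of known housekeeping
#' probes, and principal component analysis over samples. The original
#' array-QC thresholds behind these criteria are conventions, not
#' measurements; every one is configurable and can be disabled.
#'
#' @param min_mean_intersample_correlation flag a sample whose mean Pearson
#'   correlation with all other samples falls below this value (default 0.80).
#' @param median_intensity_z_min flag a sample whose median probe intensity,
#'   z-scored across samples, falls below this (default -3).
#' @param pca_outlier_sd flag a sample lying more than this many standard
#'   deviations from the centre on PC1 or PC2 of the sample-space PCA
#'   (default 4).
#' @param housekeeping_probe_ids optional character vector of probes whose
#'   within-sample rank should be stable; the criterion is off when `NULL`.
#' @param hk_rank_z_max flag a sample whose mean housekeeping-probe rank,
#'   z-scored across samples, deviates by more than this in absolute value.
#' @param enabled named logical vector switching individual criteria
#'   (`correlation`, `median_intensity`, `pca`, `housekeeping`) on or off.
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(min_mean_intersample_correlation = 0.80,
                      median_intensity_z_min = -3,
                      pca_outlier_sd = 4,
                      housekeeping_probe_ids = NULL,
                      hk_rank_z_max = 4,
                      enabled = c(correlation = TRUE, median_intensity = TRUE,
                                  pca = TRUE, housekeeping = TRUE)) {
  stopifnot(min_mean_intersample_correlation >= 0,
            min_mean_intersample_correlation <= 1,
            pca_outlier_sd > 0, hk_rank_z_max > 0)
  en <- c(correlation = TRUE, median_intensity = TRUE, pca = TRUE,
          housekeeping = TRUE)
  en[names(enabled)] <- enabled
  structure(list(min_mean_intersample_correlation =
                   min_mean_intersample_correlation,
                 median_intensity_z_min = median_intensity_z_min,
                 pca_outlier_sd = pca_outlier_sd,
                 housekeeping_probe_ids = housekeeping_probe_ids,
                 hk_rank_z_max = hk_rank_z_max,
                 enabled = en),
            class = "qc_params")
}

#' Per-sample quality control
#'
#' Computes all QC metrics once on the full input matrix (single pass),
#' then removes every sample failing any enabled criterion. Metrics are
#' never recomputed on the reduced matrix, so the flagged set does not
#' depend on removal order.
#'
#' @param x a normalized [expression_matrix()] with at least 3 samples.
#' @param params a [qc_params()] object.
#' @return A list with elements `matrix` (the filtered `expr_matrix`) and
#'   `report`, a data.frame of per-sample metrics (`median_intensity`,
#'   `median_intensity_z`, `mean_correlation`, `pc1`, `pc2`,
#'   `hk_rank_z`), a `flagged` logical and a `reasons` string.
#' @export
sample_qc <- function(x, params = qc_params()) {
  stopifnot(inherits(x, "expr_matrix"), inherits(params, "qc_params"))
  if (!x$normalized)
    stop("sample_qc expects a quantile-normalized matrix")
  v <- x$values
  if (ncol(v) < 3L) stop("sample_qc needs at least 3 samples")
  n <- ncol(v)
  med <- apply(v, 2L, stats::median)
  med_z <- if (stats::sd(med) > 0) (med - mean(med)) / stats::sd(med)
           else rep(0, n)
  cm <- stats::cor(v)
  mean_cor <- (colSums(cm) - 1) / (n - 1)
  pc <- stats::prcomp(t(v), center = TRUE, scale. = FALSE)
  pc1 <- pc$x[, 1L]
  pc2 <- if (ncol(pc$x) >= 2L) pc$x[, 2L] else rep(0, n)
  z1 <- if (stats::sd(pc1) > 0) abs(pc1 - mean(pc1)) / stats::sd(pc1) else rep(0, n)
  z2 <- if (stats::sd(pc2) > 0) abs(pc2 - mean(pc2)) / stats::sd(pc2) else rep(0, n)
  hk_z <- rep(NA_real_, n)
  hk <- intersect(params$housekeeping_probe_ids, rownames(v))
  if (length(hk)) {
    rk <- apply(v, 2L, rank)
    hk_mean <- colMeans(rk[hk, , drop = FALSE])
    hk_z <- if (stats::sd(hk_mean) > 0)
      (hk_mean - mean(hk_mean)) / stats::sd(hk_mean) else rep(0, n)
  }
  en <- params$enabled
  reasons <- vector("list", n)
  add <- function(idx, why) for (i in which(idx)) reasons[[i]] <<- c(reasons[[i]], why)
  if (en[["correlation"]])
    add(mean_cor < params$min_mean_intersample_correlation, "low_mean_correlation")
  if (en[["median_intensity"]])
    add(med_z < params$median_intensity_z_min, "low_median_intensity")
  if (en[["pca"]])
    add(z1 > params$pca_outlier_sd | z2 > params$pca_outlier_sd, "pca_outlier")
  if (en[["housekeeping"]] && length(hk))
    add(abs(hk_z) > params$hk_rank_z_max, "housekeeping_deviation")
  flagged <- lengths(reasons) > 0L
  report <- data.frame(sample_id = colnames(v), median_intensity = med,
                       median_intensity_z = med_z, mean_correlation = mean_cor,
                       pc1 = pc1, pc2 = pc2, hk_rank_z = hk_z,
                       flagged = flagged,
                       reasons = vapply(reasons, function(r)
                         paste(r, collapse = ";"), character(1L)),
                       row.names = NULL, stringsAsFactors = FALSE)
  if (all(flagged))
    stop("all samples flagged by QC; refusing to return an empty matrix")
  keep <- expression_matrix(v[, !flagged, drop = FALSE], tissue = x$tissue,
                            normalized = TRUE)
  list(matrix = keep, report = report)
}
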