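#' Per-test Bonferroni threshold
#'
#' Family-wise error control at level `alpha` over `n_tests` tests:
#' `alpha / n_tests`. With 67 modules and 14 traits at alpha 0.05 this is
#' 5.33e-5.
#'
#' @param alpha family-wise level in (0, 1).
#' @param n_tests number of tests (>= 1).
#' @return The per-test threshold.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  alpha / n_tests
}

#' SAT-vs-VAT per-probe differential expression
#'
#' Two-sided Wilcoxon Mann-Whitney test per probe between the two depots,
#' on the shared probe panel (the intersection; mismatches are reported in
#' a message). The exact null distribution is used when both group sizes
#' are at most `exact_max_n` and there are no ties; otherwise the normal
#' approximation with mid-rank tie correction and continuity correction.
#' Fold change is the ratio larger/smaller of the two per-group summaries
#' of linear-scale normalized intensities, with a direction label;
#' significance is Bonferroni at `alpha` over the probes tested.
#'
#' @param sat,vat normalized [expression_matrix()]s for the two depots,
#'   each with at least 2 samples.
#' @param alpha family-wise level (default 0.05).
#' @param exact_max_n largest group size for the exact test (default 8).
#' @param fc_estimator per-group location estimator for the fold change:
#'   `"mean"` (default) or `"median"`.
#' @return An object of class `de_result`: data.frame with columns
#'   `probe_id`, `p`, `fold_change`, `direction` (`up_in_SAT`,
#'   `up_in_VAT`, `none`), `significant`; attributes `alpha`, `n_tests`,
#'   `threshold`.
#' @export
tissue_differential_expression <- function(sat, vat, alpha = 0.05,
                                           exact_max_n = 8,
                                           fc_estimator = c("mean", "median")) {
  stopifnot(inherits(sat, "expr_matrix"), inherits(vat, "expr_matrix"))
  fc_estimator <- match.arg(fc_estimator)
  if (!sat$normalized || !vat$normalized)
    stop("both matrices must be normalized")
  if (ncol(sat$values) < 2L || ncol(vat$values) < 2L)
    stop("need at least 2 samples per depot")
  shared <- intersect(rownames(sat$values), rownames(vat$values))
  if (!length(shared)) stop("no shared probes between depots")
  n_drop <- length(union(rownames(sat$values), rownames(vat$values))) -
    length(shared)
  if (n_drop > 0)
    message(n_drop, " probe(s) absent from one depot dropped from the comparison")
  s <- sat$values[shared, , drop = FALSE]
  v <- vat$values[shared, , drop = FALSE]
  use_exact <- ncol(s) <= exact_max_n && ncol(v) <= exact_max_n
  est <- if (fc_estimator == "mean") rowMeans else
    function(m) apply(m, 1L, stats::median)
  ms <- est(s); mv <- est(v)
  p <- vapply(seq_along(shared), function(i) {
    suppressWarnings(stats::wilcox.test(s[i, ], v[i, ], exact = use_exact,
                                        correct = TRUE)$p.value)
  }, numeric(1L))
  # fully tied probes have zero rank variance; no evidence of a difference
  p[!is.finite(p)] <- 1
  fc <- pmax(ms, mv) / pmin(ms, mv)
  tol <- 1e-8
  direction <- ifelse(abs(fc - 1) < tol, "none",
                      ifelse(ms > mv, "up_in_SAT", "up_in_VAT"))
  thr <- bonferroni_threshold(alpha, length(shared))
  out <- data.frame(probe_id = shared, p = p, fold_change = fc,
                    direction = direction, significant = p < thr,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, alpha = alpha, n_tests = length(shared), threshold = thr,
            class = c("de_result", "data.frame"))
}

#' Count significant probes/genes per fold-change bin
#'
#' For each direction and each threshold, counts the Bonferroni-significant
#' probes with fold change strictly greater than the threshold; with an
#' annotation, also the distinct genes (a gene counts when any of its
#' probes qualifies).
#'
#' @param de a [tissue_differential_expression()] result.
#' @param thresholds fold-change thresholds (default `c(1.5, 10)`, the
#'   study's reporting bins).
#' @param annotation optional named probe -> gene symbol vector.
#' @return data.frame with columns `direction`, `threshold`, `n_probes`
#'   and (if annotated) `n_genes`.
#' @export
fold_change_bins <- function(de, thresholds = c(1.5, 10), annotation = NULL) {
  stopifnot(inherits(de, "de_result"), all(thresholds > 1))
  grid <- expand.grid(direction = c("up_in_SAT", "up_in_VAT"),
                      threshold = thresholds, stringsAsFactors = FALSE)
  grid$n_probes <- mapply(function(d, t)
    sum(de$significant & de$direction == d & de$fold_change > t),
    grid$direction, grid$threshold)
  if (!is.null(annotation)) {
    grid$n_genes <- mapply(function(d, t) {
      probes <- de$probe_id[de$significant & de$direction == d &
                              de$fold_change > t]
      length(module_gene_symbols(probes, annotation))
    }, grid$direction, grid$threshold)
  }
  grid
}

#' Random stratified selection of validation candidates
#'
#' Reproduces the study's qRT-PCR candidate selection: all significantly
#' upregulated genes in one depot are sorted by fold change (descending),
#' split into `n_bins` contiguous bins as equal in size as possible (any
#' remainder spread over the first bins), and one gene is drawn uniformly
#' from each bin. Probes are collapsed to genes first, keeping the
#' smallest-p probe per gene.
#'
#' @param de a [tissue_differential_expression()] result.
#' @param direction `"up_in_SAT"` or `"up_in_VAT"`.
#' @param n_bins number of strata (default 10).
#' @param seed integer seed for the per-bin draws.
#' @param annotation optional probe -> gene symbol vector; without it
#'   probes are treated as genes.
#' @return data.frame with one row per bin: `bin`, `gene`, `fold_change`.
#' @export
stratified_random_selection <- function(de, direction, n_bins = 10, seed,
                                        annotation = NULL) {
  stopifnot(inherits(de, "de_result"),
            direction %in% c("up_in_SAT", "up_in_VAT"), n_bins >= 1)
  sub <- de[de$significant & de$direction == direction, , drop = FALSE]
  if (!is.null(annotation)) {
    sym <- annotation[sub$probe_id]
    miss <- is.na(sym) | !(sub$probe_id %in% names(annotation))
    sym[miss] <- sub$probe_id[miss]
    sub$gene <- unname(sym)
    # best probe per gene = smallest p
    sub <- sub[order(sub$p), , drop = FALSE]
    sub <- sub[!duplicated(sub$gene), , drop = FALSE]
  } else {
    sub$gene <- sub$probe_id
  }
  if (nrow(sub) < n_bins)
    stop("only ", nrow(sub), " gene(s) in direction ", direction,
         ", need at least ", n_bins)
  sub <- sub[order(-sub$fold_change, sub$gene), , drop = FALSE]
  n <- nrow(sub)
  base <- n %/% n_bins
  sizes <- rep(base, n_bins)
  extra <- n %% n_bins
  if (extra) sizes[seq_len(extra)] <- base + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  set.seed(as.integer(seed))
  picks <- mapply(function(a, b) if (a == b) a else sample(a:b, 1L),
                  starts, ends)
  data.frame(bin = seq_len(n_bins), gene = sub$gene[picks],
             fold_change = sub$fold_change[picks],
             stringsAsFactors = FALSE)
}
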