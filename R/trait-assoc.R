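#' Spearman rank correlation with t-approximation p-value
#'
#' Pairs with a missing value in either variable are dropped
#' (pairwise-complete). rho is the Pearson correlation of mid-ranks
#' (tie-corrected); the two-sided p-value comes from the t approximation
#' with n - 2 degrees of freedom, the same large-sample treatment
#' `stats::cor.test(..., method = "spearman", exact = FALSE)` applies.
#'
#' @param x,y paired numeric vectors.
#' @return list with `rho`, `p` and `n` (complete pairs used).
#' @examples
#' spearman_correlation(1:5, c(5, 6, 7, 8, 7))  # rho = 0.8208
#' @export
spearman_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5L) stop("need at least 5 complete pairs, got ", n)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("zero variance in ranked vector")
  rho <- stats::cor(rx, ry)
  p <- spearman_t_p(rho, n, k = 0L)
  list(rho = rho, p = p, n = n)
}

# two-sided p for a (partial) rank correlation via the t approximation,
# df = n - 2 - k with k conditioning variables
spearman_t_p <- function(rho, n, k = 0L) {
  df <- n - 2L - k
  if (abs(rho) >= 1) return(0)
  tstat <- rho * sqrt(df / (1 - rho^2))
  2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
}

#' Confounder-adjusted (partial) Spearman correlation
#'
#' All variables are mid-rank transformed on the complete cases; the ranks
#' of `x` and `y` are residualized on the confounder ranks by least squares
#' (with intercept), and rho is the Pearson correlation of the residuals.
#' The two-sided p-value uses the t approximation with n - 2 - k degrees of
#' freedom, k the number of confounders. This residualization scheme is an
#' approximation to a fully conditional Spearman correlation; with an empty
#' confounder list it reduces exactly to [spearman_correlation()].
#'
#' @param x,y paired numeric vectors.
#' @param confounders list (possibly empty) of numeric vectors of the same
#'   length.
#' @return list with `rho`, `p`, `n`.
#' @export
partial_spearman <- function(x, y, confounders = list()) {
  if (!length(confounders)) return(spearman_correlation(x, y))
  stopifnot(is.list(confounders),
            all(lengths(confounders) == length(x)), length(x) == length(y))
  cc <- stats::complete.cases(x, y, do.call(cbind, confounders))
  n <- sum(cc)
  k <- length(confounders)
  if (n < k + 5L)
    stop("need at least ", k + 5L, " complete cases, got ", n)
  rx <- rank(x[cc]); ry <- rank(y[cc])
  Z <- cbind(1, vapply(confounders, function(z) rank(z[cc]), numeric(n)))
  qr_z <- qr(Z)
  if (qr_z$rank < ncol(Z))
    stop("collinear confounders: rank-deficient design")
  ex <- stats::residuals(stats::lm.fit(Z, rx))
  ey <- stats::residuals(stats::lm.fit(Z, ry))
  tol <- sqrt(.Machine$double.eps) * length(ex)
  if (stats::sd(ex) <= tol || stats::sd(ey) <= tol)
    stop("degenerate partial correlation: residual variance is (near) zero")
  rho <- stats::cor(ex, ey)
  list(rho = rho, p = spearman_t_p(rho, n, k = k), n = n)
}

# module profile matrix (samples x modules) from a module_set
profile_matrix <- function(ms) {
  stopifnot(inherits(ms, "module_set"))
  pm <- vapply(ms$modules, `[[`, numeric(length(ms$sample_ids)), "profile")
  colnames(pm) <- vapply(ms$modules, `[[`, character(1L), "module_id")
  rownames(pm) <- ms$sample_ids
  pm
}

#' Associate module profiles with clinical traits
#'
#' Spearman rank correlation of every module profile against every trait
#' (binary gender is tested with the same machinery as a 0/1 trait), with
#' a Bonferroni family of size modules x traits: the significance
#' threshold is `alpha / (n_modules * n_traits)`. Missing trait values are
#' handled pairwise-complete per test. Zero-variance traits are rejected.
#'
#' @param ms a [build_modules()] (usually
#'   [filter_modules_by_gene_count()]-ed) result, or a samples x modules
#'   profile matrix with sample row names.
#' @param traits trait data.frame, first column `sample_id` (see
#'   [read_trait_table()]); samples are matched by id with the profiles.
#' @param alpha family-wise level (default 0.05).
#' @return An object of class `assoc_result`: data.frame with columns
#'   `module_id`, `trait`, `n`, `rho`, `p`, `significant`; attributes
#'   `threshold`, `alpha`, `n_modules`, `n_traits`.
#' @export
associate_modules <- function(ms, traits, alpha = 0.05) {
  pm <- if (inherits(ms, "module_set")) profile_matrix(ms) else as.matrix(ms)
  stopifnot(is.data.frame(traits), names(traits)[1L] == "sample_id")
  shared <- intersect(rownames(pm), traits$sample_id)
  if (!length(shared)) stop("no shared samples between profiles and traits")
  pm <- pm[shared, , drop = FALSE]
  tt <- traits[match(shared, traits$sample_id), -1L, drop = FALSE]
  zv <- vapply(tt, function(col) stats::sd(col, na.rm = TRUE) == 0 ||
                 all(is.na(col)), logical(1L))
  if (any(zv)) stop("zero-variance trait(s): ",
                    paste(names(tt)[zv], collapse = ", "))
  n_modules <- ncol(pm); n_traits <- ncol(tt)
  thr <- bonferroni_threshold(alpha, n_modules * n_traits)
  rows <- vector("list", n_modules * n_traits)
  idx <- 0L
  for (m in colnames(pm)) for (tr in names(tt)) {
    res <- spearman_correlation(pm[, m], tt[[tr]])
    idx <- idx + 1L
    rows[[idx]] <- data.frame(module_id = m, trait = tr, n = res$n,
                              rho = res$rho, p = res$p,
                              significant = res$p < thr,
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  structure(out, threshold = thr, alpha = alpha, n_modules = n_modules,
            n_traits = n_traits, class = c("assoc_result", "data.frame"))
}

#' Conditional re-analysis of significant module-trait pairs
#'
#' For every Bonferroni-significant (module, trait) pair and every named
#' confounder set, recomputes the association as a partial Spearman
#' correlation given the confounders. The verdict is `"confounded"` when
#' the partial p-value rises to 0.05 or above, `"robust"` otherwise. The
#' reverse direction is also tested — each confounder as the outcome,
#' adjusted for the originally associated trait — to expose which variable
#' drives the module (the logic behind concluding that HDL, not BMI or
#' insulin, drives a module).
#'
#' @param assoc an [associate_modules()] result.
#' @param ms the `module_set` (or profile matrix) used for `assoc`.
#' @param traits the trait table used for `assoc`.
#' @param confounder_sets named list; each element a character vector of
#'   trait names to adjust for.
#' @param self what to do when a confounder set reduces to the tested
#'   trait itself: `"skip"` (default) drops that pair-set combination, so
#'   a grid of per-trait sets can be applied to all significant pairs;
#'   `"error"` refuses to adjust a pair for itself.
#' @param level verdict level on the partial p (default 0.05).
#' @return data.frame with columns `module_id`, `trait`, `confounder_set`,
#'   `direction` (`forward` = original trait adjusted for confounders;
#'   `reverse` = confounder tested, adjusted for the original trait),
#'   `tested`, `partial_rho`, `partial_p`, `n`, `verdict`.
#' @export
conditional_reassessment <- function(assoc, ms, traits, confounder_sets,
                                     self = c("skip", "error"),
                                     level = 0.05) {
  stopifnot(inherits(assoc, "assoc_result"), is.list(confounder_sets),
            !is.null(names(confounder_sets)))
  self <- match.arg(self)
  pm <- if (inherits(ms, "module_set")) profile_matrix(ms) else as.matrix(ms)
  shared <- intersect(rownames(pm), traits$sample_id)
  pm <- pm[shared, , drop = FALSE]
  tt <- traits[match(shared, traits$sample_id), , drop = FALSE]
  sig <- assoc[assoc$significant, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(sig))) {
    m <- sig$module_id[i]; tr <- sig$trait[i]
    for (cs in names(confounder_sets)) {
      conf <- setdiff(confounder_sets[[cs]], tr)
      if (!length(conf)) {
        if (self == "error")
          stop("confounder set '", cs, "' reduces to the tested trait '",
               tr, "': cannot adjust a pair for itself")
        next
      }
      missing_tr <- setdiff(conf, names(tt))
      if (length(missing_tr))
        stop("unknown confounder trait(s): ", paste(missing_tr, collapse = ", "))
      zl <- lapply(conf, function(nm) tt[[nm]])
      res <- partial_spearman(pm[, m], tt[[tr]], zl)
      rows[[length(rows) + 1L]] <- data.frame(
        module_id = m, trait = tr, confounder_set = cs,
        direction = "forward", tested = tr, partial_rho = res$rho,
        partial_p = res$p, n = res$n,
        verdict = if (res$p >= level) "confounded" else "robust",
        stringsAsFactors = FALSE)
      for (cv in conf) {
        rev <- partial_spearman(pm[, m], tt[[cv]], list(tt[[tr]]))
        rows[[length(rows) + 1L]] <- data.frame(
          module_id = m, trait = tr, confounder_set = cs,
          direction = "reverse", tested = cv, partial_rho = rev$rho,
          partial_p = rev$p, n = rev$n,
          verdict = if (rev$p >= level) "confounded" else "robust",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(module_id = character(0), trait = character(0),
                      confounder_set = character(0), direction = character(0),
                      tested = character(0), partial_rho = numeric(0),
                      partial_p = numeric(0), n = integer(0),
                      verdict = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Flag module genes individually correlated with a trait
#'
#' Per-probe Spearman test of each module member against the trait; a
#' probe is flagged when p < `p_cut` (default 0.01, the figure-colouring
#' criterion), and a gene is flagged when any of its probes is.
#'
#' @param members character vector of member probe ids (or a module
#'   element).
#' @param x the [expression_matrix()].
#' @param trait numeric per-sample trait vector aligned with the matrix
#'   columns.
#' @param p_cut flag threshold on the per-probe p-value.
#' @param annotation optional probe -> gene symbol vector.
#' @return list with `probe_flags` (named logical per probe) and
#'   `gene_flags` (named logical per distinct gene).
#' @export
flag_trait_correlated_genes <- function(members, x, trait, p_cut = 0.01,
                                        annotation = NULL) {
  if (is.list(members)) members <- members$members
  stopifnot(inherits(x, "expr_matrix"), length(trait) == ncol(x$values))
  pf <- vapply(members, function(pr) {
    res <- spearman_correlation(x$values[pr, ], trait)
    res$p < p_cut
  }, logical(1L))
  genes <- module_gene_symbols(members, annotation)
  sym <- if (is.null(annotation)) members else {
    s <- annotation[members]
    miss <- is.na(s) | !(members %in% names(annotation))
    s[miss] <- members[miss]
    unname(s)
  }
  gf <- vapply(genes, function(g) any(pf[sym == g]), logical(1L))
  list(probe_flags = pf, gene_flags = gf)
}
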