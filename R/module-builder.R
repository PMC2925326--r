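#' All pairwise Pearson correlations between probes
#'
#' Correlations are computed across samples on the normalized intensities.
#' Probes with zero variance are excluded with a warning (their correlation
#' is undefined).
#'
#' @param x a normalized [expression_matrix()] with at least 3 samples.
#' @return A symmetric probe x probe correlation matrix (unit diagonal);
#'   attribute `excluded` lists zero-variance probes removed first.
#' @export
pairwise_pearson <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  v <- x$values
  if (ncol(v) < 3L) stop("need at least 3 samples for pairwise correlation")
  sds <- apply(v, 1L, stats::sd)
  zero <- rownames(v)[sds == 0]
  if (length(zero)) {
    warning("excluding ", length(zero), " zero-variance probe(s): ",
            paste(utils::head(zero, 5L), collapse = ", "))
    v <- v[sds > 0, , drop = FALSE]
  }
  r <- stats::cor(t(v))
  attr(r, "excluded") <- zero
  r
}

# Shared greedy merging loop. Items are columns of a profile matrix; each
# carries its creation index (probes get 1..p, every merge the next index).
# One iteration: find the maximum Pearson r over all current item pairs,
# positive correlations only; stop when it drops below r_stop; otherwise
# merge the arg-max pair (ties broken by the lexicographically smallest
# (older creation index, newer creation index) pair), recompute the merged
# profile per profile_rule, and record the merge.
#
# engine = "naive" recomputes the full correlation matrix from the profile
# matrix at every iteration; "fast" keeps the matrix and only recomputes
# the merged item's row. Pairwise Pearson r depends only on the two columns
# involved, so the two engines produce bitwise-identical merge sequences.
# scalar correlation shared by both engines: the fast engine only ever
# refreshes single entries, so every R[i, j] must come from the identical
# floating-point path in either engine (cor on a matrix takes a different
# BLAS route and can differ in the last ulp)
pair_cor <- function(a, b) {
  r <- suppressWarnings(stats::cor(a, b))
  if (!is.finite(r)) -Inf else r
}

full_cor_table <- function(profiles) {
  k <- ncol(profiles)
  R <- matrix(-Inf, k, k)
  if (k >= 2L)
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
      R[i, j] <- R[j, i] <- pair_cor(profiles[, i], profiles[, j])
  R
}

greedy_merge <- function(profiles, r_stop, profile_rule, members, raw,
                         engine = c("fast", "naive")) {
  engine <- match.arg(engine)
  p0 <- ncol(profiles)
  creation <- seq_len(p0)
  next_idx <- p0 + 1L
  sizes <- lengths(members)
  history <- list()
  R <- full_cor_table(profiles)

  repeat {
    k <- ncol(profiles)
    if (k < 2L) break
    if (engine == "naive")
      R <- full_cor_table(profiles)
    rmax <- max(R)
    if (!(rmax > 0) || rmax < r_stop) break
    hits <- which(R == rmax, arr.ind = TRUE)
    hits <- hits[hits[, 1L] < hits[, 2L], , drop = FALSE]
    key_old <- pmin(creation[hits[, 1L]], creation[hits[, 2L]])
    key_new <- pmax(creation[hits[, 1L]], creation[hits[, 2L]])
    pick <- order(key_old, key_new)[1L]
    i <- hits[pick, 1L]; j <- hits[pick, 2L]

    new_members <- c(members[[i]], members[[j]])
    new_profile <- if (profile_rule == "probe_mean") {
      colMeans(raw[new_members, , drop = FALSE])
    } else {
      (profiles[, i] + profiles[, j]) / 2
    }
    history[[length(history) + 1L]] <-
      list(left = creation[i], right = creation[j], r = rmax,
           new = next_idx)
    keep <- setdiff(seq_len(k), c(i, j))
    profiles <- cbind(profiles[, keep, drop = FALSE], new_profile)
    members <- c(members[keep], list(new_members))
    sizes <- c(sizes[keep], length(new_members))
    creation <- c(creation[keep], next_idx)
    next_idx <- next_idx + 1L
    if (engine == "fast") {
      R <- R[keep, keep, drop = FALSE]
      newr <- vapply(seq_along(keep), function(q)
        pair_cor(profiles[, q], new_profile), numeric(1L))
      R <- rbind(cbind(R, newr), c(newr, -Inf))
      dimnames(R) <- NULL
    }
  }
  list(members = members, creation = creation, history = history)
}

#' Build co-expression modules by iterative greedy merging
#'
#' The central fitting function. Starting from the individual probes, the
#' algorithm repeatedly finds the most strongly positively correlated pair
#' of current items — unmerged probes or previously formed modules — and
#' merges it into one module whose per-sample profile is recomputed from
#' its members; merging stops once the strongest remaining positive
#' correlation falls below `r_stop`. Negative correlations are never
#' merged, so anti-correlated processes stay in separate modules. Every
#' final item, including singleton probes, is returned with its full merge
#' history.
#'
#' Exact mean-profile averaging is not monotone in the merge correlation:
#' averaging denoises, so a later merge may exceed an earlier one. The only
#' guarantee is that every recorded merge had `r >= r_stop`.
#'
#' @param x a normalized [expression_matrix()].
#' @param r_stop stop threshold on the merge correlation (default 0.65).
#' @param profile_rule `"probe_mean"` (default): a module's profile is the
#'   unweighted mean over all constituent probe rows; `"pair_mean"`: the
#'   mean of the two merged profiles (WPGMA-style), which differs for
#'   unequal sizes.
#' @param engine `"fast"` caches the correlation matrix and recomputes only
#'   the merged item's row; `"naive"` recomputes the full matrix every
#'   iteration. Both produce identical results; `"naive"` is the reference.
#' @return An object of class `module_set`: list with `modules` (each a
#'   list with `module_id`, `members`, `profile`), `merge_history`
#'   (data.frame `step`, `left_id`, `right_id`, `r`, `new_id`), `params`,
#'   `probe_universe`, `excluded_probes` (zero-variance), `sample_ids`,
#'   `tissue`. Modules are ordered by member count, largest first, and
#'   labelled `M1`, `M2`, ...
#' @seealso [filter_modules_by_gene_count()], [associate_modules()],
#'   [heatmap_matrix()], [coexpression_edges()]
#' @export
build_modules <- function(x, r_stop = 0.65,
                          profile_rule = c("probe_mean", "pair_mean"),
                          engine = c("fast", "naive")) {
  stopifnot(inherits(x, "expr_matrix"), r_stop > 0, r_stop < 1)
  profile_rule <- match.arg(profile_rule)
  engine <- match.arg(engine)
  v <- x$values
  if (nrow(v) == 0L) stop("empty expression matrix")
  sds <- apply(v, 1L, stats::sd)
  excluded <- rownames(v)[sds == 0]
  if (length(excluded))
    warning("excluding ", length(excluded),
            " zero-variance probe(s) from clustering")
  vv <- v[sds > 0, , drop = FALSE]
  probes <- rownames(vv)
  fit <- greedy_merge(t(vv), r_stop = r_stop, profile_rule = profile_rule,
                      members = as.list(probes), raw = vv, engine = engine)
  # translate creation indices in the history to probe ids / module labels
  members <- c(fit$members, lapply(excluded, identity))
  ord <- order(lengths(members), decreasing = TRUE)
  members <- members[ord]
  ids <- sprintf("M%d", seq_along(members))
  modules <- lapply(seq_along(members), function(i) {
    mem <- members[[i]]
    list(module_id = ids[i], members = mem,
         profile = colMeans(v[mem, , drop = FALSE]))
  })
  hist_df <- if (length(fit$history)) {
    data.frame(step = seq_along(fit$history),
               left_id = vapply(fit$history, function(h) h$left, numeric(1)),
               right_id = vapply(fit$history, function(h) h$right, numeric(1)),
               r = vapply(fit$history, function(h) h$r, numeric(1)),
               new_id = vapply(fit$history, function(h) h$new, numeric(1)))
  } else {
    data.frame(step = integer(0), left_id = numeric(0),
               right_id = numeric(0), r = numeric(0), new_id = numeric(0))
  }
  structure(list(modules = modules, merge_history = hist_df,
                 params = list(r_stop = r_stop, profile_rule = profile_rule,
                               engine = engine),
                 probe_universe = rownames(v), excluded_probes = excluded,
                 sample_ids = colnames(v), tissue = x$tissue),
            class = "module_set")
}

#' Per-sample profile of a module
#'
#' The module expression is the unweighted per-sample mean over its member
#' probe rows.
#'
#' @param members character vector of member probe ids (or a module element
#'   of a `module_set`).
#' @param x the [expression_matrix()] the module was built from.
#' @return Numeric per-sample vector.
#' @export
module_profile <- function(members, x) {
  if (is.list(members)) members <- members$members
  stopifnot(inherits(x, "expr_matrix"))
  missing <- setdiff(members, rownames(x$values))
  if (length(missing))
    stop("member probe(s) not in matrix: ", paste(missing, collapse = ", "))
  colMeans(x$values[members, , drop = FALSE])
}

#' Retain modules with enough distinct genes
#'
#' Collapses each module's probes to gene symbols through the annotation
#' and keeps modules with at least `min_genes` distinct genes. Probes
#' without an annotated symbol each count as their own gene.
#'
#' @param ms a [build_modules()] result.
#' @param annotation named character vector mapping probe_id to gene
#'   symbol (`NA` or missing entries mean unannotated), or `NULL` to count
#'   probes as genes.
#' @param min_genes minimum distinct gene count (default 5, the study's
#'   module-size floor).
#' @return A `module_set` containing only the retained modules (order and
#'   ids preserved); `probe_universe` is restricted accordingly.
#' @export
filter_modules_by_gene_count <- function(ms, annotation = NULL, min_genes = 5) {
  stopifnot(inherits(ms, "module_set"), min_genes >= 1)
  keep <- vapply(ms$modules, function(m)
    module_gene_count(m$members, annotation) >= min_genes, logical(1L))
  out <- ms
  out$modules <- ms$modules[keep]
  out$probe_universe <- unlist(lapply(out$modules, `[[`, "members"),
                               use.names = FALSE)
  out$params$min_genes <- min_genes
  out
}

# distinct-gene count of a probe set; unannotated probes count individually
module_gene_count <- function(members, annotation = NULL) {
  if (is.null(annotation)) return(length(members))
  sym <- annotation[members]
  unann <- is.na(sym) | !(members %in% names(annotation))
  length(unique(sym[!unann])) + sum(unann)
}

# distinct gene symbols of a probe set (annotated probes only fall back to
# the probe id when unannotated, so unannotated probes stay distinct)
module_gene_symbols <- function(members, annotation = NULL) {
  if (is.null(annotation)) return(unique(members))
  sym <- annotation[members]
  miss <- is.na(sym) | !(members %in% names(annotation))
  sym[miss] <- members[miss]
  unique(unname(sym))
}

#' @export
print.module_set <- function(x, ...) {
  sizes <- lengths(lapply(x$modules, `[[`, "members"))
  cat(sprintf("module_set [%s]: %d final item(s) over %d probes (%d merges, r_stop = %g)\n",
              x$tissue, length(x$modules), length(x$probe_universe),
              nrow(x$merge_history), x$params$r_stop))
  multi <- sum(sizes > 1L)
  cat(sprintf("  %d multi-probe module(s); largest: %s\n", multi,
              paste(utils::head(sizes[sizes > 1L], 5L), collapse = ", ")))
  invisible(x)
}

#' @export
summary.module_set <- function(object, annotation = NULL, ...) {
  sizes <- lengths(lapply(object$modules, `[[`, "members"))
  genes <- vapply(object$modules, function(m)
    module_gene_count(m$members, annotation), numeric(1L))
  out <- data.frame(module_id = vapply(object$modules, `[[`, character(1L),
                                       "module_id"),
                    n_probes = sizes, n_genes = genes,
                    stringsAsFactors = FALSE)
  class(out) <- c("summary.module_set", "data.frame")
  out
}

#' Plot the module-ordered correlation heatmap
#'
#' Renders the pairwise probe correlation matrix ordered by module (largest
#' module in the upper-left corner), with module boundaries drawn; the
#' ordered matrix itself comes from [heatmap_matrix()].
#'
#' @param x a `module_set`.
#' @param expr the [expression_matrix()] it was built from.
#' @param ... passed to [graphics::image()].
#' @return Invisibly, the [heatmap_matrix()] result.
#' @export
plot.module_set <- function(x, expr, ...) {
  hm <- heatmap_matrix(x, expr)
  n <- nrow(hm$correlation)
  graphics::image(seq_len(n), seq_len(n), hm$correlation[, rev(seq_len(n))],
                  zlim = c(-1, 1),
                  col = grDevices::hcl.colors(64, "Red-Green"),
                  xlab = "", ylab = "", axes = FALSE, ...)
  b <- c(0, hm$boundaries) + 0.5
  graphics::abline(v = b, h = n - b + 1, col = "white", lwd = 0.5)
  invisible(hm)
}
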