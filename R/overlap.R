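#' A named gene set
#'
#' Gene symbols are case-normalized (upper-cased) and de-duplicated.
#'
#' @param name set label.
#' @param genes character vector of gene symbols.
#' @return list of class `gene_set` with `name` and `genes`.
#' @export
gene_set <- function(name, genes) {
  stopifnot(is.character(name), length(name) == 1L, is.character(genes))
  structure(list(name = name, genes = unique(toupper(genes))),
            class = "gene_set")
}

#' Read gene lists from text
#'
#' Accepts either one symbol per line (the whole file is one set, named
#' after `default_name`) or a two-column TSV (`set_name`, `gene`) holding
#' several sets.
#'
#' @param path file path.
#' @param default_name name for a one-column file.
#' @return A named list of [gene_set()] objects.
#' @export
read_gene_sets <- function(path, default_name = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (all(lengths(fields) == 1L)) {
    sets <- list(gene_set(default_name, trimws(lines)))
  } else if (all(lengths(fields) == 2L)) {
    nm <- vapply(fields, `[[`, character(1L), 1L)
    gs <- vapply(fields, `[[`, character(1L), 2L)
    if (identical(tolower(nm[1L]), "set_name")) { nm <- nm[-1L]; gs <- gs[-1L] }
    sets <- lapply(split(gs, nm), function(g)
      gene_set(unique(nm[gs %in% g])[1L], g))
    sets <- mapply(function(g, n) gene_set(n, g$genes), sets, names(sets),
                   SIMPLIFY = FALSE)
  } else {
    stop("gene list must have one or two tab-separated columns throughout")
  }
  stats::setNames(sets, vapply(sets, `[[`, character(1L), "name"))
}

#' Hypergeometric overlap between two gene sets
#'
#' One-sided over-representation test: the probability of drawing at least
#' `k` of set A's genes when `|B|` genes are drawn without replacement from
#' a universe of `N`, i.e. the upper hypergeometric tail `P(X >= k)`,
#' evaluated in log space so that values far below double underflow of the
#' individual terms (down to 1e-45 and beyond) remain representable.
#'
#' @param a,b [gene_set()] objects, or for a count-only test, the sizes can
#'   be given via `sizes`.
#' @param universe integer universe size `N` (default 20000, the
#'   conventional unique-gene universe), or a `gene_set`/character vector
#'   to which `a` and `b` are restricted.
#' @param sizes optional named list `list(n_a =, n_b =, k =)` overriding
#'   set contents (for published contingency inputs without gene lists).
#' @param alternative `"greater"` (over-representation, default) or
#'   `"two.sided"` (delegated to [stats::fisher.test()]).
#' @return An object of class `overlap_result`: list with `n_a`, `n_b`,
#'   `k`, `universe`, `table` (the 2x2 contingency matrix), `p`,
#'   `odds_ratio`.
#' @examples
#' fisher_overlap(sizes = list(n_a = 31, n_b = 103, k = 13),
#'                universe = 20000)  # p ~ 1.6e-22
#' @export
fisher_overlap <- function(a = NULL, b = NULL, universe = 20000,
                           sizes = NULL,
                           alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (is.null(sizes)) {
    stopifnot(inherits(a, "gene_set"), inherits(b, "gene_set"))
    ga <- a$genes; gb <- b$genes
    if (inherits(universe, "gene_set") || is.character(universe)) {
      uni <- if (inherits(universe, "gene_set")) universe$genes
             else unique(toupper(universe))
      extra <- c(setdiff(ga, uni), setdiff(gb, uni))
      if (length(extra))
        stop("gene(s) outside the universe: ",
             paste(utils::head(extra, 5L), collapse = ", "))
      N <- length(uni)
    } else N <- as.integer(universe)
    n_a <- length(ga); n_b <- length(gb); k <- length(intersect(ga, gb))
  } else {
    n_a <- sizes$n_a; n_b <- sizes$n_b; k <- sizes$k
    N <- as.integer(universe)
  }
  if (k > min(n_a, n_b)) stop("overlap exceeds a set size")
  if (N < n_a + n_b - k)
    stop("universe smaller than the union of the sets")
  tab <- matrix(c(k, n_a - k, n_b - k, N - n_a - n_b + k), 2L, 2L,
                dimnames = list(in_a = c("yes", "no"),
                                in_b = c("yes", "no")))
  p <- if (alternative == "greater") {
    # upper tail P(X >= k); phyper sums the exact terms in log space
    if (k == 0L) 1 else
      stats::phyper(k - 1L, n_a, N - n_a, n_b, lower.tail = FALSE)
  } else {
    stats::fisher.test(tab, alternative = "two.sided")$p.value
  }
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  structure(list(n_a = n_a, n_b = n_b, k = k, universe = N, table = tab,
                 p = p, odds_ratio = or, alternative = alternative),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap: k = %d of |A| = %d, |B| = %d in N = %d; one-sided p = %.3g (OR = %.3g)\n",
              x$k, x$n_a, x$n_b, x$universe, x$p, x$odds_ratio))
  invisible(x)
}

#' Cross-tabulate gene overlap between two module sets
#'
#' Rows and columns are the `top_k` largest modules (by distinct gene
#' count, descending) of each set; cells are distinct-gene intersection
#' counts, each with a one-sided hypergeometric p against the given
#' universe — the layout of the study's module cross-tabulation.
#'
#' @param a,b `module_set` objects (e.g. one per tissue depot).
#' @param annotation named probe -> gene symbol vector (unannotated probes
#'   count as their own gene).
#' @param top_k number of largest modules per set (default 10; clamped
#'   with a warning when a set has fewer modules).
#' @param universe gene universe size (default 20000).
#' @return list of class `module_overlap` with `counts` (matrix, rows = a,
#'   cols = b), `p` (matrix of one-sided p-values), `row_sizes`,
#'   `col_sizes`.
#' @export
module_overlap_table <- function(a, b, annotation = NULL, top_k = 10,
                                 universe = 20000) {
  stopifnot(inherits(a, "module_set"), inherits(b, "module_set"))
  sets_of <- function(ms) {
    g <- lapply(ms$modules, function(m)
      module_gene_symbols(m$members, annotation))
    names(g) <- vapply(ms$modules, `[[`, character(1L), "module_id")
    g[order(lengths(g), decreasing = TRUE)]
  }
  ga <- sets_of(a); gb <- sets_of(b)
  ka <- min(top_k, length(ga)); kb <- min(top_k, length(gb))
  if (ka < top_k || kb < top_k)
    warning("top_k clamped to ", ka, " x ", kb, " available modules")
  ga <- ga[seq_len(ka)]; gb <- gb[seq_len(kb)]
  counts <- matrix(0L, ka, kb, dimnames = list(names(ga), names(gb)))
  pmat <- matrix(1, ka, kb, dimnames = dimnames(counts))
  for (i in seq_len(ka)) for (j in seq_len(kb)) {
    k <- length(intersect(ga[[i]], gb[[j]]))
    counts[i, j] <- k
    pmat[i, j] <- fisher_overlap(sizes = list(n_a = length(ga[[i]]),
                                              n_b = length(gb[[j]]), k = k),
                                 universe = universe)$p
  }
  structure(list(counts = counts, p = pmat, row_sizes = lengths(ga),
                 col_sizes = lengths(gb), universe = universe),
            class = "module_overlap")
}

#' @export
print.module_overlap <- function(x, ...) {
  cat(sprintf("module overlap (universe %d): %d x %d largest modules\n",
              x$universe, nrow(x$counts), ncol(x$counts)))
  print(x$counts)
  invisible(x)
}
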