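#' Within-module co-expression edges
#'
#' All unordered pairs of module members whose pairwise Pearson
#' correlation is strictly greater than `r_min` (the figure convention:
#' genes with r > 0.65 are connected). Members with no edge are listed
#' separately as isolated (they belong to the module because they
#' correlate with the module average, not with any single gene).
#'
#' @param members character vector of member probe ids (or a module
#'   element of a `module_set`).
#' @param x the [expression_matrix()].
#' @param r_min edge threshold (default 0.65, strict).
#' @return list of class `edge_list` with `edges` (data.frame `probe_a`,
#'   `probe_b`, `r`), `isolated` (character) and `r_min`.
#' @export
coexpression_edges <- function(members, x, r_min = 0.65) {
  if (is.list(members)) members <- members$members
  stopifnot(inherits(x, "expr_matrix"))
  missing <- setdiff(members, rownames(x$values))
  if (length(missing))
    stop("member probe(s) not in matrix: ", paste(missing, collapse = ", "))
  if (length(members) < 2L)
    return(structure(list(edges = data.frame(probe_a = character(0),
                                             probe_b = character(0),
                                             r = numeric(0)),
                          isolated = members, r_min = r_min),
                     class = "edge_list"))
  r <- stats::cor(t(x$values[members, , drop = FALSE]))
  idx <- which(upper.tri(r) & r > r_min, arr.ind = TRUE)
  edges <- data.frame(probe_a = members[idx[, 1L]],
                      probe_b = members[idx[, 2L]],
                      r = r[idx], stringsAsFactors = FALSE)
  connected <- unique(c(edges$probe_a, edges$probe_b))
  structure(list(edges = edges, isolated = setdiff(members, connected),
                 r_min = r_min),
            class = "edge_list")
}

#' @export
print.edge_list <- function(x, ...) {
  cat(sprintf("edge_list: %d edge(s) at r > %g; %d isolated member(s)\n",
              nrow(x$edges), x$r_min, length(x$isolated)))
  invisible(x)
}

#' Export a co-expression network
#'
#' Writes the edge list as TSV, or as GraphML (via igraph) with gene
#' symbol and per-gene trait-correlation flag as node attributes —
#' matching the figure colouring of trait-correlated genes at p < 0.01.
#'
#' @param el a [coexpression_edges()] result.
#' @param path output file.
#' @param format `"tsv"` or `"graphml"`.
#' @param annotation optional probe -> gene symbol vector.
#' @param trait_flags optional named logical per probe (from
#'   [flag_trait_correlated_genes()]`$probe_flags`).
#' @return `path`, invisibly.
#' @export
export_network <- function(el, path, format = c("tsv", "graphml"),
                           annotation = NULL, trait_flags = NULL) {
  stopifnot(inherits(el, "edge_list"))
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(el$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("GraphML export needs the 'igraph' package")
  nodes <- unique(c(el$edges$probe_a, el$edges$probe_b))
  g <- igraph::graph_from_data_frame(el$edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  sym <- if (is.null(annotation)) nodes else {
    s <- annotation[nodes]; s[is.na(s)] <- nodes[is.na(s)]; unname(s)
  }
  igraph::V(g)$gene_symbol <- sym
  if (!is.null(trait_flags)) {
    tf <- trait_flags[nodes]
    tf[is.na(tf)] <- FALSE
    igraph::V(g)$trait_correlated <- unname(tf)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Module-ordered pairwise correlation matrix
#'
#' Orders probes by module size descending (within a module, merge order
#' is kept) and returns the full symmetric pairwise correlation matrix
#' with module boundary indices — the structure behind the module heatmap
#' figures, with the largest module in the upper-left corner.
#'
#' @param ms a `module_set`.
#' @param x the [expression_matrix()] it was built from.
#' @return list with `order` (probe ids), `correlation` (symmetric matrix,
#'   unit diagonal) and `boundaries` (cumulative probe counts marking
#'   module extents).
#' @export
heatmap_matrix <- function(ms, x) {
  stopifnot(inherits(ms, "module_set"), inherits(x, "expr_matrix"))
  sizes <- lengths(lapply(ms$modules, `[[`, "members"))
  ord_mod <- order(sizes, decreasing = TRUE)
  probes <- unlist(lapply(ms$modules[ord_mod], `[[`, "members"),
                   use.names = FALSE)
  r <- stats::cor(t(x$values[probes, , drop = FALSE]))
  diag(r) <- 1
  list(order = probes, correlation = r,
       boundaries = cumsum(sizes[ord_mod]))
}

#' Write the module membership and merge-history tables
#'
#' `module table`: one row per probe with its module id, the module's
#' probe and distinct-gene counts, and the gene symbol. `merge history`:
#' one row per merge with the two item ids and the correlation at merge.
#'
#' @param ms a `module_set`.
#' @param dir output directory.
#' @param annotation optional probe -> gene symbol vector.
#' @return `dir`, invisibly.
#' @export
write_module_tables <- function(ms, dir, annotation = NULL) {
  stopifnot(inherits(ms, "module_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(ms$modules, function(m) {
    sym <- if (is.null(annotation)) rep(NA_character_, length(m$members))
           else unname(annotation[m$members])
    data.frame(module_id = m$module_id, n_probes = length(m$members),
               n_genes = module_gene_count(m$members, annotation),
               probe_id = m$members, gene_symbol = sym,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), file.path(dir, "modules.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(ms$merge_history, file.path(dir, "merge_history.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
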