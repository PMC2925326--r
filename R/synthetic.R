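#' Specify one planted co-expression module
#'
#' A planted module follows a single-factor linear model: every member
#' probe j of module m has expression `x_ij = base + a * f_mi + e_ij`,
#' where `f_mi` is a standard-normal latent factor per sample i (shared by
#' all members), `a` is the loading and `e_ij` i.i.d. Gaussian measurement
#' noise. The population within-module Pearson correlation is then
#' `a^2 / (a^2 + sigma^2)` (see [expected_within_module_correlation()]).
#' Traits can be coupled to the same factor with effect `b`:
#' `t_i = b * f_mi + eta_i`.
#'
#' @param n_probes number of member probes (>= 2).
#' @param loading per-probe coefficient `a` on the latent factor, in (0, 1].
#' @param trait_links named numeric vector of per-trait effects `b`, e.g.
#'   `c(HDL_cholesterol = -0.8)`.
#' @param tissue which depot(s) carry the module: `"both"`, `"SAT"` or
#'   `"VAT"`. In a non-carrying depot the same probes are pure noise.
#' @return A list of class `module_spec`.
#' @export
module_spec <- function(n_probes, loading, trait_links = NULL,
                        tissue = c("both", "SAT", "VAT")) {
  tissue <- match.arg(tissue)
  stopifnot(n_probes >= 2, loading > 0, abs(loading) <= 1)
  if (!is.null(trait_links))
    stopifnot(is.numeric(trait_links), !is.null(names(trait_links)))
  structure(list(n_probes = as.integer(n_probes), loading = loading,
                 trait_links = trait_links, tissue = tissue),
            class = "module_spec")
}

#' Default clinical trait panel
#'
#' The fourteen traits of the study design: thirteen numeric metabolic
#' traits plus binary gender.
#' @return Character vector of trait names.
#' @export
default_trait_names <- function() {
  c("gender", "age", "BMI", "glucose", "insulin", "HbA1c",
    "total_cholesterol", "HDL_cholesterol", "LDL_cholesterol",
    "TG", "NEFA", "ALAT", "ASAT", "CRP")
}

#' Design of a synthetic two-depot cohort
#'
#' Collects everything [generate_cohort()] needs: cohort size, planted
#' modules, background probe count, noise levels, tissue-specific
#' differential-expression classes (multiplicative fold changes on the
#' linear intensity scale), and confounded trait pairs generated through
#' shared Gaussian components.
#'
#' @param n_samples subjects per tissue (both depots are sampled from the
#'   same subjects); default 70, the scale of the study cohort after QC.
#' @param n_background_probes probes of pure i.i.d. noise.
#' @param modules list of [module_spec()] objects.
#' @param noise_sd measurement noise standard deviation `sigma`.
#' @param trait_noise_sd standard deviation of the trait residual `eta`.
#' @param tissue_shifts data.frame with columns `n_probes`, `fold_change`
#'   (> 1) and `direction` (`"up_in_SAT"` / `"up_in_VAT"`): dedicated noise
#'   probes multiplied by `fold_change` in the designated depot.
#' @param confounders data.frame with columns `trait_a`, `trait_b`,
#'   `correlation` in (-1, 1): `trait_b` is regenerated as a correlated
#'   copy of `trait_a` plus independent noise.
#' @param base_intensity additive baseline intensity (keeps values on a
#'   positive fluorescence-like scale).
#' @param trait_names traits to generate; must include any linked trait.
#' @param trait_missing_rate fraction of trait cells set missing at random.
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(n_samples = 70, n_background_probes = 200,
                          modules = list(), noise_sd = 1, trait_noise_sd = 1,
                          tissue_shifts = NULL, confounders = NULL,
                          base_intensity = 100,
                          trait_names = default_trait_names(),
                          trait_missing_rate = 0.02) {
  stopifnot(n_samples >= 2, n_background_probes >= 0, noise_sd > 0,
            trait_noise_sd > 0, base_intensity > 0,
            trait_missing_rate >= 0, trait_missing_rate < 1)
  for (m in modules) stopifnot(inherits(m, "module_spec"))
  linked <- unique(unlist(lapply(modules, function(m) names(m$trait_links))))
  if (length(setdiff(linked, trait_names)))
    stop("linked trait(s) not in trait_names: ",
         paste(setdiff(linked, trait_names), collapse = ", "))
  if (!is.null(tissue_shifts)) {
    stopifnot(all(c("n_probes", "fold_change", "direction") %in%
                    names(tissue_shifts)),
              all(tissue_shifts$fold_change > 1),
              all(tissue_shifts$direction %in% c("up_in_SAT", "up_in_VAT")))
  }
  if (!is.null(confounders)) {
    stopifnot(all(c("trait_a", "trait_b", "correlation") %in%
                    names(confounders)),
              all(abs(confounders$correlation) < 1),
              all(confounders$trait_a %in% trait_names),
              all(confounders$trait_b %in% trait_names))
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_background_probes = as.integer(n_background_probes),
                 modules = modules, noise_sd = noise_sd,
                 trait_noise_sd = trait_noise_sd,
                 tissue_shifts = tissue_shifts, confounders = confounders,
                 base_intensity = base_intensity, trait_names = trait_names,
                 trait_missing_rate = trait_missing_rate),
            class = "cohort_design")
}

#' Population within-module Pearson correlation
#'
#' Closed form for the single-factor model: two probes sharing a factor
#' with loading `a` and independent noise of standard deviation `sigma`
#' have correlation `a^2 / (a^2 + sigma^2)`.
#'
#' @param loading factor loading `a`.
#' @param noise_sd noise standard deviation `sigma` (> 0).
#' @return The population correlation.
#' @examples
#' expected_within_module_correlation(1, 1)      # 0.5
#' expected_within_module_correlation(0.9, 0.43) # 0.814
#' @export
expected_within_module_correlation <- function(loading, noise_sd) {
  stopifnot(noise_sd > 0)
  loading^2 / (loading^2 + noise_sd^2)
}

#' Generate a synthetic two-depot cohort
#'
#' Simulates SAT and VAT expression matrices over a shared subject panel,
#' a trait table, and the ground truth for every planted structure. Probe
#' `j` of module `m` gets `base + a * f_mi + e_ij` in the depot(s) carrying
#' the module and `base + e_ij` elsewhere; background probes are pure
#' noise; tissue-shift probes are multiplied by their fold change in the
#' designated depot; linked traits get `b * f_mi + eta_i`. The result is
#' fully reproducible given `seed`.
#'
#' @param design a [cohort_design()].
#' @param seed integer seed.
#' @return A list of class `synthetic_cohort` with elements `sat`, `vat`
#'   (raw [expression_matrix()]s), `traits` (data.frame, first column
#'   `sample_id`) and `truth` (lists `probe_modules`, `trait_links`,
#'   `tissue_fc`).
#' @export
generate_cohort <- function(design, seed) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(as.integer(seed))
  n <- design$n_samples
  samples <- sprintf("S%03d", seq_len(n))
  nmod <- length(design$modules)
  factors <- matrix(stats::rnorm(n * max(nmod, 1L)), nrow = n)

  probe_rows <- list(); probe_names <- character(0)
  tissue_of <- character(0)  # per probe: module tissue or "background"
  module_of <- character(0)
  for (k in seq_len(nmod)) {
    m <- design$modules[[k]]
    ids <- sprintf("mod%d_p%d", k, seq_len(m$n_probes))
    probe_names <- c(probe_names, ids)
    module_of <- c(module_of, rep(sprintf("mod%d", k), m$n_probes))
    tissue_of <- c(tissue_of, rep(m$tissue, m$n_probes))
  }
  shift_tab <- design$tissue_shifts
  n_shift <- if (is.null(shift_tab)) 0L else sum(shift_tab$n_probes)
  if (design$n_background_probes) {
    ids <- sprintf("bg_p%d", seq_len(design$n_background_probes))
    probe_names <- c(probe_names, ids)
    module_of <- c(module_of, rep(NA_character_, length(ids)))
    tissue_of <- c(tissue_of, rep("background", length(ids)))
  }
  fc_of <- rep(1, length(probe_names))
  fc_dir <- rep("none", length(probe_names))
  if (n_shift) {
    sid <- character(0); sfc <- numeric(0); sdir <- character(0)
    for (k in seq_len(nrow(shift_tab))) {
      ids <- sprintf("fc%d_p%d", k, seq_len(shift_tab$n_probes[k]))
      sid <- c(sid, ids)
      sfc <- c(sfc, rep(shift_tab$fold_change[k], shift_tab$n_probes[k]))
      sdir <- c(sdir, rep(shift_tab$direction[k], shift_tab$n_probes[k]))
    }
    probe_names <- c(probe_names, sid)
    module_of <- c(module_of, rep(NA_character_, length(sid)))
    tissue_of <- c(tissue_of, rep("background", length(sid)))
    fc_of <- c(fc_of, sfc)
    fc_dir <- c(fc_dir, sdir)
  }
  p <- length(probe_names)
  if (p == 0L) stop("design generates no probes")

  build_tissue <- function(depot) {
    vals <- matrix(design$base_intensity +
                     stats::rnorm(p * n, sd = design$noise_sd),
                   nrow = p, dimnames = list(probe_names, samples))
    for (k in seq_len(nmod)) {
      m <- design$modules[[k]]
      if (m$tissue %in% c("both", depot)) {
        rows <- which(module_of == sprintf("mod%d", k))
        vals[rows, ] <- vals[rows, ] +
          matrix(rep(m$loading * factors[, k], each = length(rows)),
                 nrow = length(rows))
      }
    }
    up <- if (depot == "SAT") "up_in_SAT" else "up_in_VAT"
    rows <- which(fc_dir == up)
    if (length(rows)) vals[rows, ] <- vals[rows, ] * fc_of[rows]
    expression_matrix(vals, tissue = depot, normalized = FALSE)
  }
  sat <- build_tissue("SAT")
  vat <- build_tissue("VAT")

  traits <- data.frame(sample_id = samples, stringsAsFactors = FALSE)
  link_rows <- list()
  for (nm in design$trait_names) {
    if (identical(nm, "gender")) {
      traits[[nm]] <- stats::rbinom(n, 1L, 0.5)
      next
    }
    t <- stats::rnorm(n, sd = design$trait_noise_sd)
    for (k in seq_len(nmod)) {
      b <- design$modules[[k]]$trait_links
      if (!is.null(b) && nm %in% names(b)) {
        t <- t + b[[nm]] * factors[, k]
        link_rows[[length(link_rows) + 1L]] <-
          data.frame(module_id = sprintf("mod%d", k), trait = nm,
                     effect = b[[nm]], stringsAsFactors = FALSE)
      }
    }
    traits[[nm]] <- t
  }
  if (!is.null(design$confounders)) {
    for (k in seq_len(nrow(design$confounders))) {
      a <- design$confounders$trait_a[k]
      b <- design$confounders$trait_b[k]
      r <- design$confounders$correlation[k]
      za <- scale(traits[[a]])[, 1L]
      traits[[b]] <- design$trait_noise_sd *
        (r * za + sqrt(1 - r^2) * stats::rnorm(n))
    }
  }
  if (design$trait_missing_rate > 0) {
    for (nm in setdiff(names(traits), "sample_id")) {
      miss <- stats::runif(n) < design$trait_missing_rate
      traits[[nm]][miss] <- NA
    }
  }

  truth <- list(
    probe_modules = data.frame(probe_id = probe_names, module_id = module_of,
                               tissue = tissue_of, stringsAsFactors = FALSE),
    trait_links = if (length(link_rows)) do.call(rbind, link_rows)
                  else data.frame(module_id = character(0),
                                  trait = character(0), effect = numeric(0)),
    tissue_fc = data.frame(probe_id = probe_names, fold_change = fc_of,
                           direction = fc_dir, stringsAsFactors = FALSE))
  structure(list(sat = sat, vat = vat, traits = traits, truth = truth,
                 design = design, seed = as.integer(seed)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d probes x %d samples per tissue, %d planted module(s), seed %d\n",
              nrow(x$sat$values), ncol(x$sat$values),
              length(x$design$modules), x$seed))
  invisible(x)
}

#' Write a synthetic cohort to a directory
#'
#' Writes `sat.tsv` and `vat.tsv` expression matrices, `traits.tsv`, and
#' `truth.tsv` (probe_id, module_id, tissue, fold_change, direction) plus
#' `trait_links.tsv`.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_matrix(cohort$sat, file.path(dir, "sat.tsv"))
  write_expression_matrix(cohort$vat, file.path(dir, "vat.tsv"))
  write_trait_table(cohort$traits, file.path(dir, "traits.tsv"))
  truth <- merge(cohort$truth$probe_modules, cohort$truth$tissue_fc,
                 by = "probe_id", sort = FALSE)
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(cohort$truth$trait_links,
                     file.path(dir, "trait_links.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
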