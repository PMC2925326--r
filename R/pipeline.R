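#' Pipeline configuration
#'
#' Either a synthetic design (`design`) or file inputs (`sat_path`,
#' `vat_path`, `trait_path`) must be given. All stage parameters are
#' collected here; `pipeline_config()` validates them and
#' [read_pipeline_config()] loads the same structure from a YAML file.
#'
#' @param design optional [cohort_design()] for a simulated run.
#' @param sat_path,vat_path,trait_path input files for a real-data run.
#' @param annotation optional named probe -> gene symbol vector.
#' @param qc a [qc_params()] object, or `NULL` to skip QC.
#' @param r_stop,min_genes module-building parameters.
#' @param alpha family-wise level for association and DE.
#' @param confounder_sets named list of confounder trait-name vectors for
#'   the conditional re-analysis.
#' @param universe gene universe size for overlap tests.
#' @param seed integer seed recorded in the manifest and used for every
#'   random draw.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(design = NULL, sat_path = NULL, vat_path = NULL,
                            trait_path = NULL, annotation = NULL,
                            qc = qc_params(), r_stop = 0.65, min_genes = 5,
                            alpha = 0.05,
                            confounder_sets = list(BMI = "BMI"),
                            universe = 20000, seed = 1) {
  if (is.null(design)) {
    for (f in c(sat_path, vat_path, trait_path))
      if (!file.exists(f)) stop("input file not found: ", f)
    if (is.null(sat_path) || is.null(vat_path) || is.null(trait_path))
      stop("either 'design' or all of sat_path/vat_path/trait_path required")
  } else stopifnot(inherits(design, "cohort_design"))
  structure(list(design = design, sat_path = sat_path, vat_path = vat_path,
                 trait_path = trait_path, annotation = annotation, qc = qc,
                 r_stop = r_stop, min_genes = min_genes, alpha = alpha,
                 confounder_sets = confounder_sets, universe = universe,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full co-expression analysis pipeline
#'
#' Stages, in order: read or simulate the two-depot cohort; quantile
#' normalize per tissue; sample QC; SAT-vs-VAT differential expression
#' with fold-change bins; module construction per tissue; gene-count
#' filter; module-trait association with Bonferroni correction;
#' conditional re-analysis of the significant pairs; cross-tissue module
#' overlap table; network edge export for significant modules. Every
#' output is a TSV under `outdir`, plus a `manifest.yaml` recording the
#' package version, seed, parameters and input digests. Identical config
#' and seed reproduce identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results
#'   (`cohort`/`matrices`, `de`, `modules`, `assoc`, `conditional`,
#'   `overlap`).
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- "input"
  res <- tryCatch({
    if (!is.null(config$design)) {
      cohort <- generate_cohort(config$design, seed = config$seed)
      sat <- cohort$sat; vat <- cohort$vat; traits <- cohort$traits
      digests <- list(design = "synthetic")
    } else {
      sat <- read_expression_matrix(config$sat_path, tissue = "SAT")
      vat <- read_expression_matrix(config$vat_path, tissue = "VAT")
      traits <- read_trait_table(config$trait_path)
      digests <- as.list(tools::md5sum(c(sat = config$sat_path,
                                         vat = config$vat_path,
                                         traits = config$trait_path)))
      cohort <- NULL
    }
    stage <- "normalize"
    sat <- quantile_normalize(sat); vat <- quantile_normalize(vat)
    stage <- "qc"
    if (!is.null(config$qc)) {
      qs <- sample_qc(sat, config$qc); sat <- qs$matrix
      qv <- sample_qc(vat, config$qc); vat <- qv$matrix
      utils::write.table(rbind(cbind(tissue = "SAT", qs$report),
                               cbind(tissue = "VAT", qv$report)),
                         file.path(outdir, "qc_report.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    stage <- "diffexpr"
    de <- tissue_differential_expression(sat, vat, alpha = config$alpha)
    utils::write.table(de, file.path(outdir, "diffexpr.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(fold_change_bins(de, annotation = config$annotation),
                       file.path(outdir, "fold_change_bins.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    stage <- "modules"
    ms_sat <- build_modules(sat, r_stop = config$r_stop)
    ms_vat <- build_modules(vat, r_stop = config$r_stop)
    f_sat <- filter_modules_by_gene_count(ms_sat, config$annotation,
                                          config$min_genes)
    f_vat <- filter_modules_by_gene_count(ms_vat, config$annotation,
                                          config$min_genes)
    write_module_tables(f_sat, file.path(outdir, "sat_modules"),
                        config$annotation)
    write_module_tables(f_vat, file.path(outdir, "vat_modules"),
                        config$annotation)
    stage <- "associate"
    assoc <- list(SAT = NULL, VAT = NULL)
    cond <- list(SAT = NULL, VAT = NULL)
    for (tis in c("SAT", "VAT")) {
      fm <- if (tis == "SAT") f_sat else f_vat
      if (!length(fm$modules)) next
      a <- associate_modules(fm, traits, alpha = config$alpha)
      a_out <- cbind(a, threshold = attr(a, "threshold"))
      utils::write.table(a_out,
                         file.path(outdir, sprintf("%s_associations.tsv",
                                                   tolower(tis))),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      assoc[[tis]] <- a
      stage <- "conditional"
      cr <- conditional_reassessment(a, fm, traits, config$confounder_sets)
      utils::write.table(cr,
                         file.path(outdir, sprintf("%s_conditional.tsv",
                                                   tolower(tis))),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      cond[[tis]] <- cr
    }
    stage <- "overlap"
    ov <- NULL
    if (length(f_sat$modules) && length(f_vat$modules)) {
      ov <- module_overlap_table(f_sat, f_vat, config$annotation,
                                 top_k = min(10, length(f_sat$modules),
                                             length(f_vat$modules)),
                                 universe = config$universe)
      utils::write.table(cbind(module_id = rownames(ov$counts), ov$counts),
                         file.path(outdir, "module_overlap_counts.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(cbind(module_id = rownames(ov$p),
                               format(ov$p, digits = 6)),
                         file.path(outdir, "module_overlap_p.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    stage <- "export"
    for (tis in c("SAT", "VAT")) {
      a <- assoc[[tis]]
      if (is.null(a)) next
      fm <- if (tis == "SAT") f_sat else f_vat
      mat <- if (tis == "SAT") sat else vat
      for (mid in unique(a$module_id[a$significant])) {
        mod <- fm$modules[[which(vapply(fm$modules, `[[`, character(1L),
                                        "module_id") == mid)]]
        el <- coexpression_edges(mod, mat, r_min = config$r_stop)
        export_network(el, file.path(outdir,
                                     sprintf("%s_%s_network.tsv",
                                             tolower(tis), mid)))
      }
    }
    stage <- "manifest"
    manifest <- list(package = "coexmod",
                     version = as.character(utils::packageVersion("coexmod")),
                     seed = config$seed,
                     params = list(r_stop = config$r_stop,
                                   min_genes = config$min_genes,
                                   alpha = config$alpha,
                                   universe = config$universe),
                     inputs = digests)
    yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
    list(cohort = cohort, sat = sat, vat = vat, de = de,
         modules = list(SAT = f_sat, VAT = f_vat), assoc = assoc,
         conditional = cond, overlap = ov)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

#' @rdname pipeline_config
#' @param path YAML file mirroring the `pipeline_config` fields; the
#'   `design` section (if present) holds `cohort_design` fields, with
#'   `modules` a list of `module_spec` field lists.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  design <- NULL
  if (!is.null(y$design)) {
    d <- y$design
    mods <- lapply(d$modules, function(m)
      module_spec(m$n_probes, m$loading,
                  trait_links = if (!is.null(m$trait_links))
                    unlist(m$trait_links),
                  tissue = if (is.null(m$tissue)) "both" else m$tissue))
    design <- cohort_design(
      n_samples = d$n_samples %||% 70,
      n_background_probes = d$n_background_probes %||% 200,
      modules = mods,
      noise_sd = d$noise_sd %||% 1,
      trait_noise_sd = d$trait_noise_sd %||% 1,
      tissue_shifts = if (!is.null(d$tissue_shifts))
        do.call(rbind, lapply(d$tissue_shifts, as.data.frame)),
      confounders = if (!is.null(d$confounders))
        do.call(rbind, lapply(d$confounders, as.data.frame)),
      base_intensity = d$base_intensity %||% 100)
  }
  pipeline_config(design = design, sat_path = y$sat_path,
                  vat_path = y$vat_path, trait_path = y$trait_path,
                  r_stop = y$r_stop %||% 0.65,
                  min_genes = y$min_genes %||% 5,
                  alpha = y$alpha %||% 0.05,
                  confounder_sets = y$confounder_sets %||% list(BMI = "BMI"),
                  universe = y$universe %||% 20000,
                  seed = y$seed %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
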