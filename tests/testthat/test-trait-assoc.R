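test_that("Spearman correlation: exact values, ties, missingness", {
  expect_equal(spearman_correlation(1:8, (1:8)^3)$rho, 1)
  expect_equal(spearman_correlation(1:8, -(1:8))$rho, -1)
  # tied y-ranks (1, 2, 3.5, 5, 3.5): Pearson on mid-ranks
  res <- spearman_correlation(1:5, c(5, 6, 7, 8, 7))
  expect_equal(res$rho, 0.8208, tolerance = 1e-4)
  # agrees with cor.test's large-sample treatment
  set.seed(3)
  x <- rnorm(40); y <- round(x + rnorm(40), 1)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  res <- spearman_correlation(x, y)
  expect_equal(res$rho, unname(ct$estimate))
  expect_equal(res$p, ct$p.value, tolerance = 1e-10)
  # pairwise-complete deletion
  x[5] <- NA; y[9] <- NA
  expect_equal(spearman_correlation(x, y)$n, 38L)
  expect_error(spearman_correlation(1:4, 2:5), "at least 5")
  expect_error(spearman_correlation(1:6, rep(2, 6)), "zero variance")
})

test_that("Spearman rho is invariant under strictly monotone transforms", {
  set.seed(13)
  x <- rnorm(30); y <- x + rnorm(30)
  r0 <- spearman_correlation(x, y)$rho
  expect_equal(spearman_correlation(exp(x), y)$rho, r0)
  expect_equal(spearman_correlation(x, y^3 + 5 * y)$rho, r0)
})

test_that("partial Spearman: reduction, confounder removal, degeneracy", {
  set.seed(19)
  x <- rnorm(50); y <- x + rnorm(50)
  # empty confounder list reduces exactly
  expect_identical(partial_spearman(x, y, list()), spearman_correlation(x, y))
  # confounder identical to y: residual variance collapses
  expect_error(partial_spearman(x, y, list(y)), "degenerate")
  # adjusting for a collinear pair of confounders
  z <- rnorm(50)
  expect_error(partial_spearman(x, y, list(z, 2 * z + 1)), "collinear")

  # x and y both driven by z: marginal rho ~ 0.5, partial ~ 0
  set.seed(29)
  n <- 500
  z <- rnorm(n)
  x <- z + rnorm(n); y <- z + rnorm(n)   # marginal cor = 0.5
  marg <- spearman_correlation(x, y)
  part <- partial_spearman(x, y, list(z))
  expect_lt(abs(marg$rho - 0.5), 0.1)
  expect_lt(abs(part$rho), 0.1)
  expect_gt(part$p, 1e-3)

  # an independent confounder barely moves rho
  w <- rnorm(n)
  part2 <- partial_spearman(x, y, list(w))
  expect_lt(abs(part2$rho - marg$rho), 0.05)
})

test_that("module-trait association flags a planted link under Bonferroni", {
  # population Spearman ~ 0.6 between module profile and glucose
  d <- cohort_design(n_samples = 70, n_background_probes = 10,
                     modules = list(module_spec(10, 0.9,
                                                trait_links = c(glucose = 0.81))),
                     noise_sd = 0.5, trait_missing_rate = 0)
  co <- generate_cohort(d, seed = 44)
  ms <- build_modules(as_normalized(co$sat))
  fm <- filter_modules_by_gene_count(ms, min_genes = 5)
  assoc <- associate_modules(fm, co$traits, alpha = 0.05)
  # judge against the study-scale family (67 modules x 14 traits)
  fam_thr <- bonferroni_threshold(0.05, 67 * 14)
  hit <- assoc[assoc$trait == "glucose", ]
  expect_equal(nrow(hit), 1L)
  expect_lt(hit$p, fam_thr)
  expect_lt(hit$rho, 0.9)
  expect_gt(hit$rho, 0.3)
  # the threshold recorded is alpha / (modules x traits actually tested)
  expect_equal(attr(assoc, "threshold"),
               0.05 / (length(fm$modules) * 14))
})

test_that("association verdicts are invariant to module and trait order", {
  set.seed(31)
  pm <- matrix(rnorm(40 * 3), 40, 3,
               dimnames = list(sprintf("S%02d", 1:40), c("M1", "M2", "M3")))
  traits <- data.frame(sample_id = rownames(pm), t1 = pm[, 2] + rnorm(40),
                       t2 = rnorm(40), t3 = rnorm(40))
  a <- associate_modules(pm, traits)
  b <- associate_modules(pm[, c(3, 1, 2)], traits[, c(1, 4, 2, 3)])
  key <- function(d) d[order(d$module_id, d$trait),
                       c("module_id", "trait", "rho", "p", "significant")]
  expect_equal(key(as.data.frame(a)), key(as.data.frame(b)),
               ignore_attr = TRUE)
})

test_that("family-wise error under the global null stays at alpha", {
  set.seed(57)
  reps <- 100
  any_hit <- replicate(reps, {
    pm <- matrix(rnorm(30 * 10), 30, 10,
                 dimnames = list(sprintf("S%02d", 1:30), sprintf("M%d", 1:10)))
    traits <- data.frame(sample_id = rownames(pm),
                         matrix(rnorm(30 * 5), 30, 5,
                                dimnames = list(NULL, paste0("t", 1:5))))
    a <- associate_modules(pm, traits, alpha = 0.05)
    any(a$significant)
  })
  expect_lte(mean(any_hit), 0.05 + 2 * sqrt(0.05 * 0.95 / reps))
})

test_that("conditional reassessment separates driver from confounded trait", {
  # module driven by trait A; trait B is a correlated shadow of A
  d <- cohort_design(n_samples = 200, n_background_probes = 5,
                     modules = list(module_spec(8, 0.9,
                                                trait_links = c(glucose = 1.2))),
                     noise_sd = 0.4,
                     confounders = data.frame(trait_a = "glucose",
                                              trait_b = "TG",
                                              correlation = 0.8),
                     trait_missing_rate = 0)
  co <- generate_cohort(d, seed = 61)
  ms <- filter_modules_by_gene_count(
    build_modules(as_normalized(co$sat)), min_genes = 5)
  assoc <- associate_modules(ms, co$traits)
  sig <- assoc[assoc$significant, ]
  expect_true(all(c("glucose", "TG") %in% sig$trait))
  cond <- conditional_reassessment(assoc, ms, co$traits,
                                   list(glucose = "glucose", TG = "TG"))
  fwd <- cond[cond$direction == "forward", ]
  # (module, TG) collapses once glucose is adjusted for
  expect_equal(fwd$verdict[fwd$trait == "TG" &
                             fwd$confounder_set == "glucose"], "confounded")
  # (module, glucose) survives adjustment for TG
  expect_equal(fwd$verdict[fwd$trait == "glucose" &
                             fwd$confounder_set == "TG"], "robust")
  # adjusting a pair for itself can be made an error
  expect_error(conditional_reassessment(assoc, ms, co$traits,
                                        list(bad = c("glucose")),
                                        self = "error"),
               "cannot adjust a pair for itself")
})

test_that("per-gene trait flags follow the p < 0.01 rule", {
  m <- random_expr(6, 70, seed = 91, normalized = TRUE)
  trait <- m$values["p001", ]          # probe equal to the trait
  fl <- flag_trait_correlated_genes(rownames(m$values), m, trait)
  expect_true(fl$probe_flags[["p001"]])
  # an independent probe with a known unremarkable p stays unflagged
  pcheck <- spearman_correlation(m$values["p002", ], trait)$p
  expect_gt(pcheck, 0.05)
  expect_false(fl$probe_flags[["p002"]])
  # p_cut = 1 flags everything
  fl2 <- flag_trait_correlated_genes(rownames(m$values), m, trait, p_cut = 1)
  expect_true(all(fl2$probe_flags))
  # gene flagged when any probe is
  ann <- c(p001 = "GA", p002 = "GA", p003 = "GB", p004 = "GB",
           p005 = "GC", p006 = "GC")
  fl3 <- flag_trait_correlated_genes(rownames(m$values), m, trait,
                                     annotation = ann)
  expect_true(fl3$gene_flags[["GA"]])
})
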