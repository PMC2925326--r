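make_pair <- function(s_vals, v_vals, probes = NULL) {
  p <- nrow(s_vals)
  if (is.null(probes)) probes <- sprintf("p%02d", seq_len(p))
  s <- expression_matrix(`dimnames<-`(s_vals, list(probes,
         sprintf("a%02d", seq_len(ncol(s_vals))))), "SAT", normalized = TRUE)
  v <- expression_matrix(`dimnames<-`(v_vals, list(probes,
         sprintf("b%02d", seq_len(ncol(v_vals))))), "VAT", normalized = TRUE)
  list(sat = s, vat = v)
}

test_that("Mann-Whitney per-probe test: exact values, identity and symmetry", {
  # identical groups: FC = 1, p = 1, direction none
  m <- make_pair(matrix(c(1, 2, 3, 5, 5, 5), 2, 3, byrow = TRUE),
                 matrix(c(1, 2, 3, 5, 5, 5), 2, 3, byrow = TRUE))
  de <- tissue_differential_expression(m$sat, m$vat)
  expect_equal(de$p, c(1, 1))
  expect_equal(de$fold_change, c(1, 1))
  expect_equal(de$direction, c("none", "none"))

  # (1,2,3) vs (10,11,12): exact two-sided p = 2/20 = 0.1
  m <- make_pair(matrix(c(1, 2, 3), 1), matrix(c(10, 11, 12), 1))
  de <- tissue_differential_expression(m$sat, m$vat)
  expect_equal(de$p, 0.1)
  expect_equal(de$direction, "up_in_VAT")
  expect_equal(de$fold_change, 11 / 2)

  # swapping depots: identical p and FC, direction reversed
  de2 <- tissue_differential_expression(
    expression_matrix(m$vat$values, "SAT", normalized = TRUE),
    expression_matrix(m$sat$values, "VAT", normalized = TRUE))
  expect_equal(de2$p, de$p)
  expect_equal(de2$fold_change, de$fold_change)
  expect_equal(de2$direction, "up_in_SAT")
})

test_that("Mann-Whitney p is invariant under strictly monotone transforms", {
  set.seed(17)
  s <- matrix(100 + rnorm(5 * 12), 5)
  v <- matrix(100 + rnorm(5 * 12, mean = 0.5), 5)
  m1 <- make_pair(s, v)
  m2 <- make_pair(exp(s / 20), exp(v / 20))
  p1 <- tissue_differential_expression(m1$sat, m1$vat)$p
  p2 <- tissue_differential_expression(m2$sat, m2$vat)$p
  expect_equal(p1, p2)
})

test_that("exact and asymptotic p agree closely at 8 vs 8", {
  set.seed(23)
  diffs <- replicate(100, {
    x <- rnorm(8); y <- rnorm(8)
    abs(wilcox.test(x, y, exact = TRUE)$p.value -
          wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
  })
  expect_lt(max(diffs), 0.02)
})

test_that("Bonferroni threshold", {
  expect_equal(signif(bonferroni_threshold(0.05, 67 * 14), 3), 5.33e-5)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 100), 1e-4)
})

test_that("fold-change bins are strict and match planted truth", {
  d <- cohort_design(n_samples = 25, n_background_probes = 30,
                     tissue_shifts = data.frame(
                       n_probes = c(10, 3),
                       fold_change = c(2, 12),
                       direction = "up_in_VAT"),
                     trait_missing_rate = 0)
  co <- generate_cohort(d, seed = 8)
  sat <- quantile_normalize(co$sat); vat <- quantile_normalize(co$vat)
  de <- tissue_differential_expression(sat, vat)
  bins <- fold_change_bins(de, thresholds = c(1.5, 10))
  get <- function(dir, thr)
    bins$n_probes[bins$direction == dir & bins$threshold == thr]
  expect_equal(get("up_in_VAT", 1.5), 13L)
  expect_equal(get("up_in_VAT", 10), 3L)
  expect_equal(get("up_in_SAT", 1.5), 0L)

  # all FC = 1 -> empty bins
  m <- make_pair(matrix(1:6 + 0, 2, 3), matrix(1:6 + 0, 2, 3))
  de0 <- tissue_differential_expression(m$sat, m$vat)
  expect_true(all(fold_change_bins(de0)$n_probes == 0L))

  # FC exactly at the threshold is excluded (strict inequality)
  de1 <- de0
  de1$fold_change <- c(2, 2)
  de1$significant <- c(TRUE, TRUE)
  de1$direction <- c("up_in_SAT", "up_in_SAT")
  expect_equal(fold_change_bins(de1, thresholds = 2)$n_probes, c(0L, 0L))
})

test_that("stratified random selection: bins, remainders, determinism", {
  fake_de <- function(n, direction = "up_in_SAT") {
    structure(data.frame(probe_id = sprintf("g%03d", seq_len(n)),
                         p = seq_len(n) * 1e-6,
                         fold_change = seq(20, 1.6, length.out = n),
                         direction = direction, significant = TRUE,
                         stringsAsFactors = FALSE),
              class = c("de_result", "data.frame"),
              alpha = 0.05, n_tests = n, threshold = 0.05 / n)
  }
  # 10 genes, 10 bins: all selected whatever the seed
  sel <- stratified_random_selection(fake_de(10), "up_in_SAT", seed = 1)
  expect_setequal(sel$gene, sprintf("g%03d", 1:10))

  # 100 genes: one per FC decile, identical on repeat
  de <- fake_de(100)
  s1 <- stratified_random_selection(de, "up_in_SAT", seed = 99)
  s2 <- stratified_random_selection(de, "up_in_SAT", seed = 99)
  expect_identical(s1, s2)
  # gene g001 has the largest FC: bin b holds ranks (10b-9)..(10b)
  ranks <- as.integer(sub("g", "", s1$gene))
  expect_true(all(ranks > (s1$bin - 1) * 10 & ranks <= s1$bin * 10))

  # 95 genes over 10 bins: first 5 bins of 10, last 5 of 9
  s3 <- stratified_random_selection(fake_de(95), "up_in_SAT", seed = 4)
  ranks <- as.integer(sub("g", "", s3$gene))
  starts <- c(1, cumsum(c(rep(10, 5), rep(9, 5))) + 1)[1:10]
  ends <- cumsum(c(rep(10, 5), rep(9, 5)))
  expect_true(all(ranks >= starts[s3$bin] & ranks <= ends[s3$bin]))

  expect_error(stratified_random_selection(fake_de(5), "up_in_SAT", seed = 1),
               "need at least")
})

test_that("probes are collapsed to best-p probe per gene before selection", {
  de <- structure(data.frame(probe_id = c("pA1", "pA2", "pB", "pC", "pD",
                                          "pE", "pF", "pG", "pH", "pI", "pJ"),
                             p = c(1e-8, 1e-3, rep(1e-6, 9)),
                             fold_change = c(5, 4.9, seq(4, 2, length.out = 9)),
                             direction = "up_in_SAT", significant = TRUE,
                             stringsAsFactors = FALSE),
                  class = c("de_result", "data.frame"))
  ann <- c(pA1 = "GENEA", pA2 = "GENEA", pB = "GENEB", pC = "GENEC",
           pD = "GENED", pE = "GENEE", pF = "GENEF", pG = "GENEG",
           pH = "GENEH", pI = "GENEI", pJ = "GENEJ")
  sel <- stratified_random_selection(de, "up_in_SAT", n_bins = 10, seed = 2,
                                     annotation = ann)
  expect_equal(nrow(sel), 10L)
  expect_equal(sum(sel$gene == "GENEA"), 1L)  # duplicate probe collapsed
})

test_that("null type-I error of the per-probe test is at its nominal level", {
  set.seed(2024)
  n_probe <- 1000
  p <- replicate(n_probe, {
    suppressWarnings(wilcox.test(rnorm(30), rnorm(30), exact = FALSE,
                                 correct = TRUE)$p.value)
  })
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.02)
})
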