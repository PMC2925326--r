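test_that("pairwise Pearson matches the longhand covariance formula", {
  m <- random_expr(10, 20, seed = 55, normalized = TRUE)
  r <- pairwise_pearson(m)
  v <- m$values
  longhand <- function(a, b) {
    n <- length(a)
    sxy <- sum((a - mean(a)) * (b - mean(b)))
    sxy / sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  for (i in 1:9) for (j in (i + 1):10)
    expect_equal(r[i, j], longhand(v[i, ], v[j, ]), tolerance = 1e-12)

  # duplicated probe: r = 1; negated probe: r = -1
  v2 <- rbind(v, dup = v[1, ], neg = max(v) - v[1, ])
  m2 <- expression_matrix(v2, "SAT", normalized = TRUE)
  r2 <- pairwise_pearson(m2)
  expect_equal(r2["p001", "dup"], 1)
  expect_equal(r2["p001", "neg"], -1)

  expect_error(pairwise_pearson(random_expr(5, 2)), "at least 3 samples")
  v3 <- rbind(v, flat = rep(100, 20))
  expect_warning(r3 <- pairwise_pearson(
    expression_matrix(v3, "SAT", normalized = TRUE)), "zero-variance")
  expect_false("flat" %in% rownames(r3))
})

test_that("pure noise below the threshold yields zero merges", {
  m <- random_expr(50, 70, seed = 70, normalized = TRUE)
  r <- pairwise_pearson(m)
  expect_lt(max(r[upper.tri(r)]), 0.65)  # instance sanity
  ms <- build_modules(m)
  expect_equal(nrow(ms$merge_history), 0L)
  expect_true(all(lengths(lapply(ms$modules, `[[`, "members")) == 1L))
})

test_that("planted blocks are recovered exactly as the only multi-probe items", {
  d <- cohort_design(n_samples = 70, n_background_probes = 20,
                     modules = list(module_spec(5, 0.95),
                                    module_spec(5, 0.95)),
                     noise_sd = 0.3, trait_missing_rate = 0)
  for (seed in c(1, 2, 3)) {
    co <- generate_cohort(d, seed = seed)
    ms <- build_modules(quantile_normalize(co$sat))
    members <- lapply(ms$modules, `[[`, "members")
    multi <- members[lengths(members) > 1L]
    expect_length(multi, 2L)
    truth <- split(co$truth$probe_modules$probe_id,
                   co$truth$probe_modules$module_id)
    expect_setequal(lapply(multi, sort), lapply(truth, sort))
  }
})

test_that("fast engine reproduces the naive full-recompute reference exactly", {
  for (seed in 101:130) {
    m <- random_instance(seed)
    fast <- build_modules(m, engine = "fast")
    naive <- build_modules(m, engine = "naive")
    expect_identical(fast$merge_history, naive$merge_history)
    expect_identical(lapply(fast$modules, `[[`, "members"),
                     lapply(naive$modules, `[[`, "members"))
  }
})

test_that("module set is a partition with all merges at or above r_stop", {
  for (seed in c(301, 302, 303)) {
    m <- random_instance(seed, n_samples = 10)
    ms <- build_modules(m)
    members <- lapply(ms$modules, `[[`, "members")
    all_probes <- unlist(members)
    expect_false(any(duplicated(all_probes)))          # disjoint
    expect_setequal(all_probes, rownames(m$values))    # covering
    if (nrow(ms$merge_history))
      expect_true(all(ms$merge_history$r >= ms$params$r_stop))
    # at termination no positive pair of final profiles reaches r_stop
    if (length(members) > 1L) {
      profs <- sapply(ms$modules, `[[`, "profile")
      rr <- suppressWarnings(cor(profs))
      rr[!is.finite(rr)] <- -1
      diag(rr) <- -1
      expect_lt(max(rr), ms$params$r_stop)
    }
  }
})

test_that("pair_mean profile rule differs from probe_mean for unequal sizes", {
  d <- cohort_design(n_samples = 40, n_background_probes = 0,
                     modules = list(module_spec(6, 0.95)), noise_sd = 0.3,
                     trait_missing_rate = 0)
  m <- as_normalized(generate_cohort(d, seed = 77)$sat)
  a <- build_modules(m, profile_rule = "probe_mean")
  b <- build_modules(m, profile_rule = "pair_mean")
  # both find the block, but the WPGMA profile weights members unequally,
  # so the recorded merge correlations differ
  expect_equal(sort(a$modules[[1]]$members), sort(b$modules[[1]]$members))
  expect_false(isTRUE(all.equal(a$merge_history$r, b$merge_history$r)))
})

test_that("module profiles equal the unweighted member mean", {
  m <- random_expr(12, 15, seed = 12, normalized = TRUE)
  # singleton
  expect_equal(module_profile("p001", m), m$values["p001", ])
  # two probes: element-wise midpoint
  expect_equal(module_profile(c("p001", "p002"), m),
               (m$values["p001", ] + m$values["p002", ]) / 2)
  # 7 members vs independent column-mean oracle
  mem <- sprintf("p%03d", 1:7)
  expect_equal(module_profile(mem, m),
               apply(m$values[mem, ], 2, mean))
  expect_error(module_profile("nope", m), "not in matrix")
})

test_that("gene-count filter uses distinct symbols with unannotated fallback", {
  mk_ms <- function(member_sets) {
    mods <- lapply(seq_along(member_sets), function(i)
      list(module_id = sprintf("M%d", i), members = member_sets[[i]],
           profile = numeric(0)))
    structure(list(modules = mods, merge_history = NULL,
                   params = list(r_stop = 0.65),
                   probe_universe = unlist(member_sets),
                   excluded_probes = character(0),
                   sample_ids = character(0), tissue = "SAT"),
              class = "module_set")
  }
  ann <- c(a1 = "G1", a2 = "G2", a3 = "G3", a4 = "G4", a5 = "G5",
           b1 = "H1", b2 = "H1", b3 = "H2", b4 = "H3", b5 = "H4", b6 = "H4",
           c1 = "K1", c2 = "K2", c3 = "K3")
  ms <- mk_ms(list(paste0("a", 1:5),            # 5 probes -> 5 genes
                   paste0("b", 1:6),            # 6 probes -> 4 genes
                   c("c1", "c2", "c3", "u1", "u2")))  # 3 genes + 2 unannotated
  out <- filter_modules_by_gene_count(ms, ann, min_genes = 5)
  expect_setequal(vapply(out$modules, `[[`, character(1), "module_id"),
                  c("M1", "M3"))
})
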