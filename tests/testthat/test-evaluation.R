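test_that("make_folds produces disjoint, covering, balanced, seeded partitions", {
  f <- make_folds(paste0("p", 1:10), 5, seed = 1)
  expect_equal(as.integer(table(f$assignment)), rep(2L, 5))

  f11 <- make_folds(paste0("p", 1:11), 5, seed = 1)
  expect_setequal(as.integer(table(f11$assignment)), c(3L, 2L))

  expect_identical(make_folds(paste0("p", 1:20), 4, seed = 9)$assignment,
                   make_folds(paste0("p", 1:20), 4, seed = 9)$assignment)
  expect_false(identical(make_folds(paste0("p", 1:20), 4, seed = 9)$assignment,
                         make_folds(paste0("p", 1:20), 4, seed = 10)$assignment))

  expect_error(make_folds(paste0("p", 1:10), 1, seed = 1), ">= 2")
  expect_error(make_folds(paste0("p", 1:3), 5, seed = 1), "exceeds")
})

test_that("permutation_gene_sets draws seeded sets without replacement", {
  uni <- paste0("g", 1:100)
  sets <- permutation_gene_sets(uni, set_size = 10, n_sets = 50, seed = 2)
  expect_length(sets, 50L)
  expect_true(all(vapply(sets, function(s) length(unique(s$genes)) == 10L,
                         logical(1))))
  expect_identical(lapply(sets, `[[`, "genes"),
                   lapply(permutation_gene_sets(uni, 10, 50, seed = 2), `[[`, "genes"))

  forced <- permutation_gene_sets(paste0("g", 1:10), 10, 3, seed = 1)
  expect_true(all(vapply(forced, function(s) setequal(s$genes, paste0("g", 1:10)),
                         logical(1))))
  expect_error(permutation_gene_sets(paste0("g", 1:5), 10, 2, seed = 1), "smaller")
})

test_that("wilcoxon_signed_rank matches the exact distribution and wilcox.test", {
  # target uniformly higher over 10 folds (distinct differences so the exact
  # branch applies): minimal two-sided exact p
  x <- seq(0.6, 0.69, by = 0.01)
  y <- x - seq(0.01, 0.1, by = 0.01)
  w2 <- wilcoxon_signed_rank(x, y, "two.sided")
  expect_equal(w2$p_value, 2 / 2^10)
  expect_identical(w2$method, "exact")
  w1 <- wilcoxon_signed_rank(x, y, "greater")
  expect_equal(w1$p_value, 1 / 2^10)

  # identical vectors: all zero differences, p undefined
  expect_true(is.na(wilcoxon_signed_rank(x, x, "two.sided")$p_value))

  # exact branch agrees with exhaustive enumeration on random tie-free data
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(4:12, 1)
    a <- rnorm(n); b <- rnorm(n)
    for (alt in c("two.sided", "greater", "less")) {
      expect_equal(wilcoxon_signed_rank(a, b, alt)$p_value,
                   oracle_signed_rank_p(a, b, alt),
                   tolerance = 1e-12, label = paste("seed", seed, alt))
    }
  }

  # normal-approximation branch agrees with stats::wilcox.test when ties force it
  set.seed(3)
  a <- round(rnorm(15), 1); b <- round(rnorm(15), 1)
  keep <- a != b
  ours <- wilcoxon_signed_rank(a, b, "two.sided")
  ref <- suppressWarnings(stats::wilcox.test(a[keep], b[keep], paired = TRUE,
                                             correct = TRUE, exact = FALSE))
  expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-10)
})

test_that("wilcoxon_vs_nulls reports median p and beaten-null counts", {
  target <- seq(0.7, 0.79, by = 0.01)
  nulls <- lapply(1:20, function(i) { set.seed(i); runif(10, 0.45, 0.55) })
  cmp <- wilcoxon_vs_nulls(target, nulls, sided = "one")
  expect_length(cmp$p_values, 20L)
  expect_equal(cmp$n_beaten, 20L)
  expect_equal(cmp$median_p, 1 / 2^10)

  # raising the target can only decrease the one-sided p
  set.seed(5)
  t2 <- runif(10, 0.4, 0.6)
  p_lo <- wilcoxon_vs_nulls(t2, nulls, "one")$median_p
  p_hi <- wilcoxon_vs_nulls(t2 + 0.2, nulls, "one")$median_p
  expect_lte(p_hi, p_lo)

  # iid target: roughly calibrated false-positive count
  set.seed(6)
  null_mat <- matrix(runif(50 * 10, 0.45, 0.55), 50, 10)
  t3 <- runif(10, 0.45, 0.55)
  cmp3 <- wilcoxon_vs_nulls(t3, null_mat, "one")
  expect_lte(cmp3$n_beaten, 15L)

  expect_length(wilcoxon_vs_nulls(t2, list(), "one")$p_values, 0L)
})

test_that("simulated_p respects its bounds and is seeded", {
  out <- random_outcomes(16, 41, event_prob = 0.8)
  h <- random_hazard(out, 42)
  ctx <- list(survmediate:::fold_context(out$patient_id,
                                         partition_pairs(h, out)$correct))
  nulls <- survmediate:::random_pme_matrix(ctx, 50, seed = 7)
  expect_equal(simulated_p(1, nulls, ctx, n_sim = 200, seed = 1), 1)
  expect_equal(simulated_p(-1, nulls, ctx, n_sim = 200, seed = 1), 0)
  expect_identical(simulated_p(0.3, nulls, ctx, n_sim = 200, seed = 2),
                   simulated_p(0.3, nulls, ctx, n_sim = 200, seed = 2))
})

test_that("cross_validated_concordance separates planted signal from noise genes", {
  # strong-signal world: a single true mediator pathway and a high hazard scale
  co <- generate_cohort(synthetic_config(
    n_patients = 250, n_affected = 5, hazard_scale = 2.5,
    mediator_sets = list(list(name = "mediator", size = 8, link_type = "mediator")),
    n_noise = 20, seed = 60))
  folds <- make_folds(co$outcomes$patient_id, 5, seed = 61)
  cv_sig <- cross_validated_concordance(
    list(label = "driver", genes = co$gene_sets$driver_panel,
         config = fast_survnet(seed = 62, epochs = 80L)),
    co$expr, co$outcomes, folds)
  expect_gt(cv_sig$median, 0.75)

  cv_noise <- cross_validated_concordance(
    list(label = "noise", genes = paste0("NOISE", sprintf("%03d", 1:8)),
         config = fast_survnet(seed = 63, epochs = 80L)),
    co$expr, co$outcomes, folds)
  expect_lt(abs(cv_noise$median - 0.5), 0.1)

  # seeded determinism
  cv_rep <- cross_validated_concordance(
    list(label = "driver", genes = co$gene_sets$driver_panel,
         config = fast_survnet(seed = 62, epochs = 80L)),
    co$expr, co$outcomes, folds)
  expect_identical(cv_rep$per_fold, cv_sig$per_fold)
})
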