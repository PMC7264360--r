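test_that("PME limits: identity composition gives 1, negation gives 0", {
  out <- random_outcomes(20, 71, event_prob = 0.7)
  h <- random_hazard(out, 72)
  parts <- partition_pairs(h, out)
  expect_gt(nrow(parts$correct), 0L)
  expect_equal(concordance_on_pairs(h, out, parts$correct)$concordance, 1)
  expect_equal(concordance_on_pairs(-h, out, parts$correct)$concordance, 0)
})

test_that("randomized_pme is centred at 0.5 and reproducible", {
  out <- random_outcomes(25, 73, event_prob = 0.7)
  h <- random_hazard(out, 74)
  correct <- partition_pairs(h, out)$correct
  pmes <- randomized_pme(out, correct, n_reps = 500, seed = 75)
  expect_length(pmes, 500L)
  se <- stats::sd(pmes) / sqrt(500)
  expect_lt(abs(mean(pmes) - 0.5), 3 * se + 1e-9)

  expect_identical(randomized_pme(out, correct, 1, seed = 76),
                   randomized_pme(out, correct, 1, seed = 76))

  one <- correct[1, , drop = FALSE]
  expect_true(all(randomized_pme(out, one, 50, seed = 77) %in% c(0, 1)))
})

test_that("direct_effect partitions test pairs deterministically and finds planted signal", {
  co <- small_cohort(seed = 81)
  folds <- make_folds(co$outcomes$patient_id, 4, seed = 82)
  de1 <- direct_effect(co$expr, co$outcomes, co$gene_sets$driver_panel, folds, 1,
                       fast_survnet(seed = 83))
  de2 <- direct_effect(co$expr, co$outcomes, co$gene_sets$driver_panel, folds, 1,
                       fast_survnet(seed = 83))
  expect_identical(de1$correct, de2$correct)
  expect_identical(de1$hazard, de2$hazard)
  expect_gt(nrow(de1$correct), nrow(de1$incorrect))
  expect_true(all(!de1$test_ids %in% de1$train_ids))

  # pure-noise driver panel: correct fraction near 1/2
  noise_panel <- gene_set("noise", paste0("NOISE", sprintf("%03d", 1:6)))
  fracs <- vapply(1:4, function(f) {
    de <- direct_effect(co$expr, co$outcomes, noise_panel, folds, f,
                        fast_survnet(seed = 84))
    nrow(de$correct) / (nrow(de$correct) + nrow(de$incorrect))
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.5), 0.15)
})

test_that("no test-fold leakage: corrupting one test patient leaves others untouched", {
  co <- small_cohort(seed = 85)
  folds <- make_folds(co$outcomes$patient_id, 4, seed = 86)
  de <- direct_effect(co$expr, co$outcomes, co$gene_sets$driver_panel, folds, 2,
                      fast_survnet(seed = 87))
  victim <- de$test_ids[1]
  corrupted <- co$expr
  corrupted$values[, victim] <- corrupted$values[, victim] * 50 + 3
  de_c <- direct_effect(corrupted, co$outcomes, co$gene_sets$driver_panel,
                        folds, 2, fast_survnet(seed = 87))
  others <- setdiff(de$test_ids, victim)
  expect_identical(de_c$hazard[others], de$hazard[others])
  keep <- de$correct$id_early != victim & de$correct$id_late != victim
  keep_c <- de_c$correct$id_early != victim & de_c$correct$id_late != victim
  expect_identical(de_c$correct[keep_c, ], de$correct[keep, ])

  # corrupting training outcomes does change the model
  flipped <- co$outcomes
  train_events <- which(flipped$patient_id %in% de$train_ids & flipped$event)
  flipped$event[train_events[1:20]] <- FALSE
  de_f <- direct_effect(co$expr, flipped, co$gene_sets$driver_panel, folds, 2,
                        fast_survnet(seed = 87))
  expect_false(identical(de_f$hazard, de$hazard))
})

test_that("mediated_effect stays in [0,1] and recovers planted structure on a small cohort", {
  co <- small_cohort(seed = 91, n = 160)
  folds <- make_folds(co$outcomes$patient_id, 4, seed = 92)
  dcfg <- fast_survnet(seed = 93, epochs = 80L)
  pme <- matrix(NA_real_, 4, 2, dimnames = list(NULL, c("mediator", "inverse")))
  for (f in 1:4) {
    de <- direct_effect(co$expr, co$outcomes, co$gene_sets$driver_panel,
                        folds, f, dcfg)
    for (nm in colnames(pme)) {
      spec <- mediation_spec(co$gene_sets$driver_panel, co$gene_sets[[nm]],
                             direct_config = dcfg, mediator_config = dcfg,
                             mt_config = fast_multitask(seed = 94))
      pme[f, nm] <- mediated_effect(de, co$outcomes, spec, f)$pme
    }
  }
  expect_true(all(pme >= 0 & pme <= 1, na.rm = TRUE))
  expect_gt(stats::median(pme[, "mediator"]), stats::median(pme[, "inverse"]))
})

test_that("mediation_experiment aggregates reports, isolates failures, and is deterministic", {
  co <- small_cohort(seed = 95, n = 120)
  folds <- make_folds(co$outcomes$patient_id, 3, seed = 96)
  dcfg <- fast_survnet(seed = 97)
  mk <- function(nm) mediation_spec(co$gene_sets$driver_panel, co$gene_sets[[nm]],
                                    direct_config = dcfg, mediator_config = dcfg,
                                    mt_config = fast_multitask(seed = 98))
  specs <- list(mk("mediator"), mk("null"))

  expect_identical(mediation_experiment(co$expr, co$outcomes, list(), folds), list())

  reps <- mediation_experiment(co$expr, co$outcomes, specs, folds,
                               n_null_reps = 20, n_sim = 100, seed = 99)
  expect_named(reps, c("mediator", "null"))
  expect_equal(dim(reps$mediator$null_pme), c(20L, 3L))
  expect_true(all(reps$mediator$pme >= 0 & reps$mediator$pme <= 1, na.rm = TRUE))
  expect_true(reps$mediator$simulated_p >= 0 && reps$mediator$simulated_p <= 1)

  reps2 <- mediation_experiment(co$expr, co$outcomes, specs, folds,
                                n_null_reps = 20, n_sim = 100, seed = 99)
  expect_identical(reps$mediator$pme, reps2$mediator$pme)
  expect_identical(reps$mediator$simulated_p, reps2$mediator$simulated_p)

  # a failing spec (mediator set absent from the matrix) is reported, not fatal
  bad <- mediation_spec(co$gene_sets$driver_panel,
                        gene_set("ghost", c("NOPE1", "NOPE2")),
                        direct_config = dcfg, mediator_config = dcfg,
                        mt_config = fast_multitask(seed = 98))
  reps3 <- mediation_experiment(co$expr, co$outcomes, list(specs[[1]], bad), folds,
                                n_null_reps = 5, n_sim = 50, seed = 99)
  expect_false(reps3$mediator$failed)
  expect_true(reps3$ghost$failed)
  expect_match(reps3$ghost$error, "NOPE")
})
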