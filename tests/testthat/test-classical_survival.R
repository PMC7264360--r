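test_that("comparable_pairs follows the censoring rule", {
  # times (2,4,5), events (1,0,1): p2 censored before p3's death
  out <- survival_outcomes(c("p1", "p2", "p3"), c(2, 4, 5), c(TRUE, FALSE, TRUE))
  pairs <- comparable_pairs(out)
  expect_equal(nrow(pairs), 2L)
  expect_setequal(paste(pairs$id_early, pairs$id_late),
                  c("p1 p2", "p1 p3"))

  # all events, distinct times: every pair comparable
  out4 <- survival_outcomes(paste0("q", 1:4), 1:4, rep(TRUE, 4))
  expect_equal(nrow(comparable_pairs(out4)), 6L)

  # all censored: none
  outc <- survival_outcomes(paste0("c", 1:4), 1:4, rep(FALSE, 4))
  expect_equal(nrow(comparable_pairs(outc)), 0L)

  # tied event times are not comparable (no ordering observed)
  outt <- survival_outcomes(c("a", "b"), c(3, 3), c(TRUE, TRUE))
  expect_equal(nrow(comparable_pairs(outt)), 0L)
})

test_that("concordance matches hand counts, reversal and symmetry identities", {
  out <- survival_outcomes(paste0("p", 1:4), 1:4, rep(TRUE, 4))
  h <- stats::setNames(c(4, 3, 1, 2), out$patient_id)
  res <- concordance(h, out)
  expect_equal(res$concordant_count, 5L)
  expect_equal(res$discordant_count, 1L)
  expect_equal(res$concordance, 5 / 6)

  # perfectly anti-ranked
  h_rev <- stats::setNames(1:4, out$patient_id)
  expect_equal(concordance(h_rev, out)$concordance, 0)

  # concordance(h) + concordance(-h) = 1 when no ties
  out2 <- random_outcomes(15, 3)
  h2 <- random_hazard(out2, 4)
  expect_equal(concordance(h2, out2)$concordance +
                 concordance(-h2, out2)$concordance, 1)

  # invariant under strictly increasing transforms
  expect_equal(concordance(exp(h2 / 2) + 5, out2)$concordance,
               concordance(h2, out2)$concordance)
})

test_that("concordance and concordance_on_pairs agree with the exhaustive oracle", {
  for (seed in 1:30) {
    n <- sample(5:30, 1)
    out <- random_outcomes(n, seed, event_prob = runif(1, 0.3, 0.9),
                           tie_times = seed %% 3 == 0)
    h <- random_hazard(out, seed + 1000)
    if (seed %% 4 == 0) h <- round(h) # force hazard ties
    orc <- oracle_concordance(h, out)
    if (orc$concordant + orc$discordant == 0) {
      expect_error(concordance(h, out))
      next
    }
    res <- concordance(h, out)
    expect_identical(res$concordant_count, orc$concordant)
    expect_identical(res$discordant_count, orc$discordant)
    expect_identical(res$tied_hazard_count, orc$tied)
  }
})

test_that("concordance_on_pairs restricts correctly", {
  out <- random_outcomes(10, 11, event_prob = 0.8)
  h <- random_hazard(out, 12)
  pairs <- comparable_pairs(out)
  expect_equal(concordance_on_pairs(h, out, pairs),
               concordance(h, out))

  # single correctly ranked pair -> concordance 1
  parts <- partition_pairs(h, out)
  one <- parts$correct[1, , drop = FALSE]
  expect_equal(concordance_on_pairs(h, out, one)$concordance, 1)

  # 4-pair restriction matched by independent recount
  sub <- pairs[1:4, , drop = FALSE]
  orc <- oracle_concordance(h, out, restrict = sub)
  expect_equal(concordance_on_pairs(h, out, sub)$concordance, orc$concordance)

  expect_error(concordance_on_pairs(h, out, pair_set(character(0), character(0))),
               "empty")
})

test_that("shared_accuracy identities and Monte-Carlo behaviour", {
  out <- random_outcomes(20, 21, event_prob = 0.7)
  a <- random_hazard(out, 22)
  expect_equal(shared_accuracy(a, a, out), list(shared_correct = 1,
                                                shared_incorrect = 1))
  expect_equal(shared_accuracy(a, -a, out), list(shared_correct = 0,
                                                 shared_incorrect = 0))

  # independent random B: both fractions ~ 0.5
  set.seed(99)
  reps <- replicate(200, {
    b <- stats::setNames(rnorm(20), out$patient_id)
    unlist(shared_accuracy(a, b, out))
  })
  expect_equal(unname(rowMeans(reps)), c(0.5, 0.5), tolerance = 0.05)

  # zero incorrect pairs -> undefined, not 0
  out2 <- survival_outcomes(c("a", "b"), c(1, 2), c(TRUE, TRUE))
  perfect <- c(a = 2, b = 1)
  expect_true(is.na(shared_accuracy(perfect, perfect, out2)$shared_incorrect))
})

test_that("kaplan_meier matches product-limit arithmetic", {
  # no censoring: 1 - ECDF of death times
  out <- survival_outcomes(paste0("p", 1:5), c(1, 2, 3, 4, 5), rep(TRUE, 5))
  km <- kaplan_meier(out)[["all"]]
  expect_equal(km$surv, 1 - (1:5) / 5)

  # all censored: flat at 1
  outc <- survival_outcomes(paste0("c", 1:4), 1:4, rep(FALSE, 4))
  expect_true(all(kaplan_meier(outc)[["all"]]$surv == 1))

  # 6-patient mixed fixture, hand product-limit:
  # t=1 death (6 at risk) -> 5/6; t=2 censored; t=3 death (4 at risk) -> 5/6*3/4
  # t=4 death (3 at risk) -> ...*2/3; t=5 censored; t=6 death (1 at risk) -> 0
  outm <- survival_outcomes(paste0("m", 1:6), 1:6,
                            c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE))
  kmm <- kaplan_meier(outm)[["all"]]
  death_surv <- kmm$surv[kmm$n_event == 1]
  expect_equal(death_surv, c(5/6, 5/6 * 3/4, 5/6 * 3/4 * 2/3, 0))

  # stratified: one curve per label
  g <- stats::setNames(rep(c("x", "y"), 3), outm$patient_id)
  expect_named(kaplan_meier(outm, g), c("x", "y"))
})

test_that("fit_cox_ph recovers planted effects and matches a brute-force likelihood", {
  d <- ph_data(1000, beta = 1, seed = 5)
  fit <- fit_cox_ph(matrix(d$x, ncol = 1), d$outcomes)
  expect_true(abs(fit$coefficients - 1) < 3 * fit$se)
  expect_true(fit$converged)
  expect_equal(unname(fit$hazard_ratio), exp(unname(fit$coefficients)))

  # planted null: small coefficient
  dn <- ph_data(500, beta = 0, seed = 6)
  fitn <- fit_cox_ph(matrix(dn$x, ncol = 1), dn$outcomes)
  expect_true(abs(fitn$coefficients) < 3 * fitn$se)

  # coefficient equals the argmax of an independently coded partial likelihood
  ds <- ph_data(40, beta = 0.8, seed = 7)
  brute_nll <- function(b) {
    h <- b * ds$x
    tot <- 0
    for (i in which(ds$outcomes$event)) {
      rs <- which(ds$outcomes$time_days >= ds$outcomes$time_days[i])
      tot <- tot - (h[i] - log(sum(exp(h[rs]))))
    }
    tot
  }
  opt <- stats::optimize(brute_nll, c(-5, 5))$minimum
  fits <- fit_cox_ph(matrix(ds$x, ncol = 1), ds$outcomes)
  expect_equal(unname(fits$coefficients), opt, tolerance = 1e-4)

  expect_error(fit_cox_ph(matrix(1, 10, 1), random_outcomes(10, 1)), "constant")
})

test_that("stratify_by_expression cuts on full-cohort statistics", {
  em <- expr_matrix(matrix(1:8, 1, dimnames = list("g", paste0("p", 1:8))),
                    "g", paste0("p", 1:8), "raw")
  med <- stratify_by_expression(em, "g", "median")
  expect_identical(unname(med), c(rep("low", 4), rep("high", 4)))
  q <- stratify_by_expression(em, "g", "quartiles")
  expect_identical(unname(q), c("Q1", "Q1", "Q2", "Q2", rep("Q3/4", 4)))

  flat <- expr_matrix(matrix(5, 1, 8, dimnames = list("g", paste0("p", 1:8))),
                      "g", paste0("p", 1:8), "raw")
  expect_error(stratify_by_expression(flat, "g", "median"), "ties")
})
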