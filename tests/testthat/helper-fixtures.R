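# Shared fixture builders. Everything is generated in code; no binary files.

withr_tempfile <- function(ext = ".tsv") tempfile(fileext = ext)

# Random censored survival fixture with distinct-ish times.
random_outcomes <- function(n, seed, event_prob = 0.6, tie_times = FALSE) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    times <- if (tie_times) sample(1:max(3, n %/% 2), n, replace = TRUE)
             else round(runif(n, 1, 1000), 3)
    survival_outcomes(sprintf("p%03d", seq_len(n)), times,
                      runif(n) < event_prob)
  })
}

random_hazard <- function(outcomes, seed) {
  set.seed(seed)
  stats::setNames(rnorm(nrow(outcomes)), outcomes$patient_id)
}

# Exhaustive O(n^2) concordance oracle, deliberately independent of the
# package implementation: plain double loop over the verbal definition.
oracle_concordance <- function(hazard, outcomes, restrict = NULL) {
  h <- hazard[outcomes$patient_id]
  t <- outcomes$time_days
  e <- outcomes$event
  n <- nrow(outcomes)
  conc <- disc <- tied <- 0L
  in_restrict <- function(a, b) {
    if (is.null(restrict)) return(TRUE)
    any(restrict$id_early == a & restrict$id_late == b)
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (t[i] == t[j]) next
    early <- if (t[i] < t[j]) i else j
    late <- if (t[i] < t[j]) j else i
    if (!e[early]) next
    if (!in_restrict(outcomes$patient_id[early], outcomes$patient_id[late])) next
    if (h[early] > h[late]) conc <- conc + 1L
    else if (h[early] < h[late]) disc <- disc + 1L
    else tied <- tied + 1L
  }
  list(concordant = conc, discordant = disc, tied = tied,
       concordance = if (conc + disc > 0) conc / (conc + disc) else NA_real_)
}

# Exhaustive signed-rank oracle: enumerates all 2^n sign assignments of the
# ranked absolute differences (requires no zeros and no ties).
oracle_signed_rank_p <- function(x, y, alternative) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  stopifnot(!anyDuplicated(abs(d)))
  W <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  all_W <- as.matrix(signs) %*% r
  switch(alternative,
         greater = mean(all_W >= W),
         less = mean(all_W <= W),
         two.sided = min(1, 2 * min(mean(all_W >= W), mean(all_W <= W))))
}

# A small log_zscored expression matrix built directly from a latent matrix.
make_scaled_expr <- function(values, genes, patients) {
  expr_matrix(values, genes, patients, "log_zscored")
}

# Single-covariate proportional-hazards data: hazard rate exp(beta * x).
ph_data <- function(n, beta, seed, censor_rate = 0.1, base_rate = 0.5) {
  set.seed(seed)
  x <- rnorm(n)
  t_event <- rexp(n, rate = base_rate * exp(beta * x))
  t_cens <- rexp(n, rate = censor_rate * base_rate)
  out <- survival_outcomes(sprintf("p%04d", seq_len(n)),
                           pmax(pmin(t_event, t_cens), 1e-9),
                           t_event <= t_cens)
  expr <- make_scaled_expr(matrix(x, nrow = 1,
                                  dimnames = list("G1", out$patient_id)),
                           "G1", out$patient_id)
  list(x = x, expr = expr, outcomes = out)
}

# Small cohort for fast end-to-end tests.
small_cohort <- function(seed = 1, n = 120, set_size = 6L, n_noise = 30L) {
  generate_cohort(synthetic_config(
    n_patients = n, n_affected = 5L,
    mediator_sets = list(
      list(name = "mediator", size = set_size, link_type = "mediator"),
      list(name = "inverse", size = set_size, link_type = "inverse_mediator"),
      list(name = "null", size = set_size, link_type = "null")),
    n_noise = n_noise, seed = seed))
}

# Fast network configs for tests (reduced epochs / widths; the defaults are
# larger but the structure is identical).
fast_survnet <- function(seed = 1, ...) {
  args <- utils::modifyList(list(hidden_layer_sizes = 8L, dropout_rate = 0.1,
                                 epochs = 60L, batch_size = 64L, seed = seed),
                            list(...))
  do.call(survnet_config, args)
}

fast_multitask <- function(seed = 1, ...) {
  args <- utils::modifyList(list(hidden_layer_sizes = c(16L, 16L), epochs = 50L,
                                 batch_size = 64L, weight_decay = 2,
                                 seed = seed),
                            list(...))
  do.call(multitask_config, args)
}
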