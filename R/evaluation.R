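#' Partition patients into k cross-validation folds
#'
#' Seeded uniform shuffle followed by round-robin assignment, so fold sizes
#' differ by at most one and folds are disjoint and covering.
#'
#' @param patient_ids character vector of patient ids.
#' @param k number of folds (>= 2, <= number of patients).
#' @param seed integer seed.
#' @return an object of class `fold_partition`: `k`, `assignment` (named
#'   integer vector, values in `1:k`), `seed`.
#' @export
make_folds <- function(patient_ids, k, seed) {
  n <- length(patient_ids)
  if (!is_count(k) || k < 2) stopf("k must be an integer >= 2")
  if (k > n) stopf("k (%d) exceeds the number of patients (%d)", k, n)
  ord <- with_seed(seed, sample.int(n))
  assignment <- stats::setNames(rep_len(seq_len(k), n)[order(ord)], patient_ids)
  # invariant check: disjoint and covering with near-equal sizes
  sizes <- tabulate(assignment, k)
  stopifnot(sum(sizes) == n, max(sizes) - min(sizes) <= 1L)
  structure(list(k = as.integer(k), assignment = assignment,
                 seed = as.integer(seed)),
            class = "fold_partition")
}

fold_patients <- function(folds, fold, train = FALSE) {
  sel <- if (train) folds$assignment != fold else folds$assignment == fold
  names(folds$assignment)[sel]
}

#' Draw random same-size gene sets as a permutation baseline
#'
#' @param universe character vector of candidate genes (restrict to genes with
#'   complete data before calling).
#' @param set_size genes per set (default 10).
#' @param n_sets number of sets (default 50).
#' @param seed integer seed.
#' @return list of [gene_set()]s named `perm_01` ... `perm_<n>`.
#' @export
permutation_gene_sets <- function(universe, set_size = 10L, n_sets = 50L, seed = 1L) {
  universe <- unique(as.character(universe))
  if (length(universe) < set_size) {
    stopf("universe (%d genes) smaller than set_size (%d)", length(universe), set_size)
  }
  names <- sprintf("perm_%02d", seq_len(n_sets))
  sets <- lapply(seq_len(n_sets), function(i) {
    genes <- with_seed(derive_seed(seed, "perm-set", i),
                       sample(universe, set_size))
    gene_set(names[i], genes)
  })
  stats::setNames(sets, names)
}

#' Cross-validated concordance of one survival-network specification
#'
#' Per fold: scaling parameters are fitted on the training patients only
#' ([scale_with_train()]), the network is trained on the training patients,
#' and concordance is measured on the held-out fold. Model genes that are
#' constant on a training fold are dropped for that fold.
#'
#' @param model_spec list with `label` (character), `genes` (character vector
#'   or [gene_set()]) and `config` (a [survnet_config()]).
#' @param expr an [expr_matrix()] in state `"raw"`.
#' @param outcomes `survival_outcomes` covering the fold partition's patients.
#' @param folds a [make_folds()] partition.
#' @return an object of class `cv_result`: `label`, `per_fold` (numeric,
#'   `NA` for folds flagged missing), `median`, `mean`.
#' @export
cross_validated_concordance <- function(model_spec, expr, outcomes, folds) {
  stopifnot(inherits(folds, "fold_partition"))
  genes <- model_spec$genes
  if (inherits(genes, "gene_set")) genes <- genes$genes
  per_fold <- rep(NA_real_, folds$k)
  for (f in seq_len(folds$k)) {
    res <- try({
      train_ids <- fold_patients(folds, f, train = TRUE)
      test_ids <- fold_patients(folds, f)
      sc <- scale_with_train(expr, train_ids)
      use_genes <- setdiff(genes, sc$dropped)
      if (!length(use_genes)) stopf("all model genes constant on training fold")
      cfg <- model_spec$config
      cfg$seed <- derive_seed(cfg$seed, "cv-fold", f)
      model <- train_survival_net(
        sc$expr, outcomes[outcomes$patient_id %in% train_ids, , drop = FALSE],
        use_genes, cfg)
      h <- predict_hazard(model, sc$expr, test_ids)
      concordance(h, outcomes[outcomes$patient_id %in% test_ids, , drop = FALSE])$concordance
    }, silent = TRUE)
    if (!inherits(res, "try-error")) per_fold[f] <- res
  }
  structure(list(label = model_spec$label, per_fold = per_fold,
                 median = stats::median(per_fold, na.rm = TRUE),
                 mean = mean(per_fold, na.rm = TRUE)),
            class = "cv_result")
}

#' Wilcoxon signed-rank test for paired per-fold values
#'
#' Zero differences are dropped (Wilcoxon's original rule) and their count
#' reported. The exact signed-rank distribution is used for n <= 12 pairs when
#' the absolute differences are tie-free; otherwise the normal approximation
#' with continuity correction and tie correction is used.
#'
#' @param x,y paired numeric vectors (e.g. per-fold concordances).
#' @param alternative `"two.sided"`, `"greater"` (x > y) or `"less"`.
#' @return list: `statistic` (W+, rank sum of positive differences),
#'   `p_value` (`NA` when all differences are zero), `n_used`,
#'   `zeros_dropped`, `method` (`"exact"` or `"normal"`).
#' @export
wilcoxon_signed_rank <- function(x, y, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) == length(y))
  res <- signed_rank_batch(matrix(x - y, ncol = 1L), alternative)
  list(statistic = res$W[1], p_value = res$p[1], n_used = res$n[1],
       zeros_dropped = res$zeros[1],
       method = if (is.na(res$exact[1])) NA_character_
                else if (res$exact[1]) "exact" else "normal")
}

# Vectorized signed-rank machinery over the columns of a difference matrix D
# (rows = paired observations). Average ranks for tied |d|; zeros dropped.
# Returns per-column W+, p, n, zeros, exact flag.
signed_rank_batch <- function(D, alternative) {
  k <- nrow(D)
  m <- ncol(D)
  D[is.na(D)] <- 0 # missing paired values are dropped like zero differences
  nz <- D != 0
  n <- colSums(nz)
  A <- abs(D)
  ranks <- matrix(0, k, m)
  eqc <- matrix(1, k, m) # tie-group size containing each observation
  for (i in seq_len(k)) {
    less <- matrix(0, 1, m)
    eq <- matrix(0, 1, m)
    for (j in seq_len(k)) {
      if (i == j) next
      less <- less + (nz[j, ] & A[j, ] < A[i, ])
      eq <- eq + (nz[j, ] & A[j, ] == A[i, ])
    }
    ranks[i, ] <- (1 + less + 0.5 * eq) * nz[i, ]
    eqc[i, ] <- (1 + eq) * nz[i, ]
  }
  W <- colSums(ranks * (D > 0))
  tie_sum_cubed <- colSums(eqc^2 * nz) # = sum over tie groups of t^3
  tie_term <- tie_sum_cubed - n        # sum(t^3 - t)
  exact_ok <- tie_term == 0 & n >= 1 & n <= 12
  # exact branch
  p_exact <- rep(NA_real_, m)
  ok <- which(exact_ok)
  if (length(ok)) {
    w <- W[ok]; nn <- n[ok]
    p_greater <- 1 - stats::psignrank(w - 1, nn)
    p_less <- stats::psignrank(w, nn)
    p_exact[ok] <- switch(alternative,
      greater = p_greater,
      less = p_less,
      two.sided = pmin(1, 2 * pmin(p_greater, p_less)))
  }
  # normal approximation with continuity and tie corrections
  mu <- n * (n + 1) / 4
  sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - tie_term / 48)
  z_num <- W - mu
  p_norm <- switch(alternative,
    greater = stats::pnorm((z_num - 0.5) / sigma, lower.tail = FALSE),
    less = stats::pnorm((z_num + 0.5) / sigma),
    two.sided = pmin(1, 2 * pmin(
      stats::pnorm((z_num - sign(z_num) * 0.5) / sigma, lower.tail = FALSE),
      stats::pnorm((z_num - sign(z_num) * 0.5) / sigma))))
  p <- ifelse(exact_ok, p_exact, p_norm)
  p[n == 0] <- NA_real_
  sigma_zero <- !exact_ok & n > 0 & sigma == 0
  p[sigma_zero] <- 1
  list(W = W, p = p, n = n, zeros = k - n,
       exact = ifelse(n == 0, NA, exact_ok))
}

#' Compare a target's per-fold values against many null result sets
#'
#' One signed-rank p-value per null set, paired by fold index; reports the
#' median p and how many nulls are beaten at p <= 0.05.
#'
#' @param target numeric vector of per-fold values (concordances or PMEs).
#' @param nulls list of numeric vectors (or a matrix with one null per row),
#'   each paired with `target` by fold.
#' @param sided `"one"` (target greater) or `"two"`.
#' @return list of class `null_comparison`: `p_values`, `median_p`,
#'   `n_beaten` (p <= 0.05), `n_undefined`.
#' @export
wilcoxon_vs_nulls <- function(target, nulls, sided = c("one", "two")) {
  sided <- match.arg(sided)
  if (is.matrix(nulls)) nulls <- lapply(seq_len(nrow(nulls)), function(i) nulls[i, ])
  if (!length(nulls)) {
    return(structure(list(p_values = numeric(0), median_p = NA_real_,
                          n_beaten = 0L, n_undefined = 0L),
                     class = "null_comparison"))
  }
  D <- vapply(nulls, function(nu) target - nu, numeric(length(target)))
  alt <- if (sided == "one") "greater" else "two.sided"
  res <- signed_rank_batch(matrix(D, nrow = length(target)), alt)
  structure(list(p_values = res$p,
                 median_p = stats::median(res$p, na.rm = TRUE),
                 n_beaten = sum(res$p <= 0.05, na.rm = TRUE),
                 n_undefined = sum(is.na(res$p))),
            class = "null_comparison")
}

# Per-fold contexts carry what is needed to score any hazard function on the
# restricted pair sets: test patient ids and the direct model's correctly
# ranked pairs, as index pairs into the patient vector.
fold_context <- function(patient_ids, correct_pairs) {
  stopifnot(inherits(correct_pairs, "pair_set"))
  list(patient_ids = patient_ids,
       early = match(correct_pairs$id_early, patient_ids),
       late = match(correct_pairs$id_late, patient_ids))
}

# PME of n_funcs i.i.d. standard-normal hazard functions on each fold's
# correctly ranked pairs. Returns an n_funcs x n_folds matrix. Tied hazards
# (measure zero here) are excluded from the denominator.
random_pme_matrix <- function(fold_contexts, n_funcs, seed) {
  out <- matrix(NA_real_, n_funcs, length(fold_contexts))
  for (f in seq_along(fold_contexts)) {
    ctx <- fold_contexts[[f]]
    np <- length(ctx$patient_ids)
    H <- with_seed(derive_seed(seed, "random-hazard", f),
                   matrix(stats::rnorm(n_funcs * np), n_funcs, np))
    he <- H[, ctx$early, drop = FALSE]
    hl <- H[, ctx$late, drop = FALSE]
    conc <- rowSums(he > hl)
    disc <- rowSums(he < hl)
    out[, f] <- ifelse(conc + disc > 0, conc / (conc + disc), NA_real_)
  }
  out
}

#' Simulated p-value for an observed median Wilcoxon p
#'
#' Draws `n_sim` fresh random-hazard functions, scores each on the same
#' restricted pair sets, computes each one's median two-sided signed-rank p
#' against the same null PME sample sets, and returns the fraction of
#' simulated median p-values at or below the observed one. A value of 0 should
#' be read as `< 1/n_sim`.
#'
#' @param observed_median_p the observed median two-sided Wilcoxon p.
#' @param nulls matrix of null PMEs (one random-hazard replicate per row, one
#'   fold per column), the same replicates used for the observed comparison.
#' @param fold_contexts per-fold contexts from the mediation run (internal
#'   structure produced by [direct_effect()]).
#' @param n_sim number of simulated random-hazard functions (default 10000).
#' @param seed integer seed for the simulated draws.
#' @return the simulated p-value in `[0, 1]`.
#' @export
simulated_p <- function(observed_median_p, nulls, fold_contexts,
                        n_sim = 10000L, seed = 1L) {
  stopifnot(is.matrix(nulls), ncol(nulls) == length(fold_contexts))
  targets <- random_pme_matrix(fold_contexts, n_sim, derive_seed(seed, "simp"))
  k <- ncol(nulls)
  pmat <- matrix(NA_real_, n_sim, nrow(nulls))
  for (r in seq_len(nrow(nulls))) {
    D <- t(targets) - nulls[r, ] # k x n_sim differences, paired by fold
    pmat[, r] <- signed_rank_batch(D, "two.sided")$p
  }
  med <- apply(pmat, 1L, stats::median, na.rm = TRUE)
  mean(med <= observed_median_p)
}
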