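#' Enumerate comparable patient pairs under censoring
#'
#' A pair is comparable iff the two follow-up times are distinct and the
#' patient with the earlier time experienced the event (so the ordering of
#' deaths is actually observed). Pairs of deaths at exactly tied times are not
#' comparable: no ordering is observed. Each comparable pair is returned as
#' (`id_early`, `id_late`) where `id_early` is the patient known to have died
#' first.
#'
#' @param outcomes a `survival_outcomes` data frame with >= 2 patients.
#' @return a data frame of class `pair_set` with character columns `id_early`
#'   and `id_late` (zero rows when no pair is comparable).
#' @export
comparable_pairs <- function(outcomes) {
  n <- nrow(outcomes)
  if (n < 2L) stopf("need at least two patients")
  t <- outcomes$time_days
  e <- outcomes$event
  id <- outcomes$patient_id
  # all i<j pairs via index expansion (n is at most a few hundred per fold)
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L, from = 2L:n)
  earlier_i <- t[i] < t[j]
  distinct <- t[i] != t[j]
  early <- ifelse(earlier_i, i, j)
  late <- ifelse(earlier_i, j, i)
  keep <- distinct & e[early]
  pair_set(id[early[keep]], id[late[keep]])
}

#' Construct a pair set
#' @param id_early,id_late patient ids; `id_early` died first in each pair.
#' @return a `pair_set` data frame.
#' @export
pair_set <- function(id_early, id_late) {
  structure(data.frame(id_early = as.character(id_early),
                       id_late = as.character(id_late),
                       stringsAsFactors = FALSE),
            class = c("pair_set", "data.frame"))
}

#' Censored concordance of a hazard vector
#'
#' Among comparable pairs ([comparable_pairs()]), a pair is concordant when
#' the patient who died earlier has the strictly higher hazard, discordant
#' when strictly lower. Pairs with exactly tied hazards enter neither count
#' (there is no tie term in concordant / (concordant + discordant)); they are
#' reported in `tied_hazard_count`.
#'
#' @param hazard named numeric vector of log-hazards (names = patient ids)
#'   covering all patients in `outcomes`.
#' @param outcomes a `survival_outcomes` data frame.
#' @return a list of class `concordance_result`: `concordant_count`,
#'   `discordant_count`, `tied_hazard_count`, `concordance`.
#' @export
concordance <- function(hazard, outcomes) {
  pairs <- comparable_pairs(outcomes)
  if (!nrow(pairs)) stopf("no comparable pairs: concordance undefined")
  concordance_on_pairs(hazard, outcomes, pairs)
}

#' Concordance restricted to a given pair set
#'
#' Same counting rule as [concordance()] but over `restrict` only. This is the
#' quantity behind the percent mediated effect, where `restrict` is the set of
#' pairs the direct model ranked correctly.
#'
#' @inheritParams concordance
#' @param restrict a `pair_set`; must be a subset of the comparable pairs.
#' @return a `concordance_result` list.
#' @export
concordance_on_pairs <- function(hazard, outcomes, restrict) {
  stopifnot(inherits(restrict, "pair_set"))
  if (!nrow(restrict)) stopf("restricted pair set is empty")
  h <- hazard_lookup(hazard, outcomes)
  he <- h[restrict$id_early]
  hl <- h[restrict$id_late]
  if (anyNA(he) || anyNA(hl)) stopf("hazard missing for some patients in the pair set")
  conc <- sum(he > hl)
  disc <- sum(he < hl)
  tied <- sum(he == hl)
  if (conc + disc == 0L) stopf("all pairs have tied hazards: concordance undefined")
  structure(list(concordant_count = conc, discordant_count = disc,
                 tied_hazard_count = tied,
                 concordance = conc / (conc + disc)),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("concordance %.4f (%d concordant / %d discordant / %d tied-hazard)\n",
              x$concordance, x$concordant_count, x$discordant_count,
              x$tied_hazard_count))
  invisible(x)
}

hazard_lookup <- function(hazard, outcomes) {
  if (is.null(names(hazard))) {
    if (length(hazard) != nrow(outcomes)) {
      stopf("unnamed hazard vector must match outcomes length")
    }
    names(hazard) <- outcomes$patient_id
  }
  hazard
}

#' Partition comparable pairs by whether a hazard vector ranks them correctly
#'
#' "Correct" uses the concordant rule: strictly higher hazard on the patient
#' who died earlier. Tied-hazard pairs fall in neither partition.
#'
#' @inheritParams concordance
#' @return list with `pair_set`s `correct` and `incorrect` (and `tied`).
#' @export
partition_pairs <- function(hazard, outcomes) {
  pairs <- comparable_pairs(outcomes)
  h <- hazard_lookup(hazard, outcomes)
  he <- h[pairs$id_early]
  hl <- h[pairs$id_late]
  list(correct = pairs[he > hl, , drop = FALSE],
       incorrect = pairs[he < hl, , drop = FALSE],
       tied = pairs[he == hl, , drop = FALSE])
}

#' Shared ranking accuracy of two hazard vectors
#'
#' Among comparable pairs that model A ranks correctly, the fraction model B
#' also ranks correctly; and among pairs A ranks incorrectly, the fraction B
#' also ranks incorrectly. B's tied-hazard pairs count as neither correct nor
#' incorrect. When A has zero correct (or zero incorrect) pairs the
#' corresponding fraction is `NA` (undefined), not 0.
#'
#' @param hazard_a,hazard_b named hazard vectors covering all patients.
#' @param outcomes a `survival_outcomes` data frame.
#' @return list `shared_correct`, `shared_incorrect`.
#' @export
shared_accuracy <- function(hazard_a, hazard_b, outcomes) {
  pa <- partition_pairs(hazard_a, outcomes)
  hb <- hazard_lookup(hazard_b, outcomes)
  frac <- function(pairs, want_correct) {
    if (!nrow(pairs)) return(NA_real_)
    he <- hb[pairs$id_early]
    hl <- hb[pairs$id_late]
    if (want_correct) mean(he > hl) else mean(he < hl)
  }
  list(shared_correct = frac(pa$correct, TRUE),
       shared_incorrect = frac(pa$incorrect, FALSE))
}

#' Kaplan-Meier survival curves, optionally stratified
#'
#' Product-limit estimator (via the survival package); censored patients leave
#' the risk set without a drop.
#'
#' @param outcomes a `survival_outcomes` data frame.
#' @param groups optional named character vector (names = patient ids) of
#'   group labels; one curve per label. Default: a single curve.
#' @return named list of data frames (`time`, `surv`, `n_risk`, `n_event`),
#'   one per group, each of class `km_curve`.
#' @export
kaplan_meier <- function(outcomes, groups = NULL) {
  if (is.null(groups)) {
    groups <- stats::setNames(rep("all", nrow(outcomes)), outcomes$patient_id)
  }
  g <- groups[outcomes$patient_id]
  if (anyNA(g)) stopf("group label missing for patient(s): %s",
                      paste(outcomes$patient_id[is.na(g)], collapse = ", "))
  out <- lapply(split(seq_len(nrow(outcomes)), g), function(idx) {
    sub <- outcomes[idx, , drop = FALSE]
    fit <- survival::survfit(
      survival::Surv(sub$time_days, sub$event) ~ 1, conf.type = "none")
    structure(data.frame(time = fit$time, surv = fit$surv,
                         n_risk = fit$n.risk, n_event = fit$n.event),
              class = c("km_curve", "data.frame"))
  })
  out
}

#' Cox proportional-hazards fit (Breslow ties)
#'
#' Thin wrapper around `survival::coxph` with Breslow tie handling, exposing
#' coefficients, standard errors, hazard ratios, p-values and a convergence
#' flag. Used as the classical baseline and as the oracle for the linear
#' special case of the survival network.
#'
#' @param design numeric matrix (patients x covariates) with finite entries
#'   and no constant column; column names name the covariates.
#' @param outcomes a `survival_outcomes` data frame aligned with `design` rows.
#' @return a list of class `cox_fit`: `coefficients`, `se`, `hazard_ratio`,
#'   `p_value`, `converged`, `loglik`.
#' @export
fit_cox_ph <- function(design, outcomes) {
  design <- as.matrix(design)
  if (is.null(colnames(design))) {
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  }
  if (nrow(design) != nrow(outcomes)) stopf("design rows must match outcomes")
  if (any(!is.finite(design))) stopf("covariates must be finite")
  if (any(apply(design, 2L, function(v) max(v) == min(v)))) {
    stopf("constant covariate in design matrix")
  }
  if (!any(outcomes$event)) stopf("no events: Cox fit undefined")
  fit <- survival::coxph(
    survival::Surv(outcomes$time_days, outcomes$event) ~ design,
    ties = "breslow",
    control = survival::coxph.control(eps = 1e-9, iter.max = 50))
  s <- summary(fit)
  converged <- is.null(fit$fail) && fit$iter < 50
  structure(list(
    coefficients = stats::setNames(as.numeric(stats::coef(fit)), colnames(design)),
    se = stats::setNames(s$coefficients[, "se(coef)"], colnames(design)),
    hazard_ratio = stats::setNames(exp(as.numeric(stats::coef(fit))), colnames(design)),
    p_value = stats::setNames(s$coefficients[, "Pr(>|z|)"], colnames(design)),
    converged = converged,
    loglik = fit$loglik[2]
  ), class = "cox_fit")
}

#' Stratify patients by the expression of one gene
#'
#' Cut points come from the full patient set. `median` yields labels
#' `low`/`high`; `quartiles` yields `Q1`, `Q2`, `Q3/4` (the upper half pooled).
#' Patients exactly at a cut point go to the lower bin.
#'
#' @param expr an [expr_matrix()] in any state.
#' @param gene gene symbol, present with complete data.
#' @param scheme `"median"` or `"quartiles"`.
#' @return named character vector of labels (names = patient ids).
#' @export
stratify_by_expression <- function(expr, gene, scheme = c("median", "quartiles")) {
  scheme <- match.arg(scheme)
  if (!gene %in% expr$gene_ids) stopf("gene '%s' not in expression matrix", gene)
  v <- expr$values[gene, ]
  if (anyNA(v)) stopf("gene '%s' has missing expression values", gene)
  if (scheme == "median") {
    cut <- stats::median(v)
    lab <- ifelse(v <= cut, "low", "high")
  } else {
    q <- stats::quantile(v, c(0.25, 0.5))
    lab <- ifelse(v <= q[1], "Q1", ifelse(v <= q[2], "Q2", "Q3/4"))
  }
  if (length(unique(lab)) < if (scheme == "median") 2L else 3L) {
    stopf("heavy ties leave an empty stratum for gene '%s'", gene)
  }
  stats::setNames(lab, expr$patient_ids)
}
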