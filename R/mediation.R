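#' Specification of one mediation experiment
#'
#' Bundles the driver panel, one mediator gene set, and the configurations of
#' the three networks involved: the direct survival net (driver panel ->
#' hazard), the mediator survival net (observed mediator expression ->
#' hazard, trained independently of the multitask model), and the multitask
#' net (driver panel -> predicted mediator expression).
#'
#' @param driver_panel [gene_set()] of driver-panel genes.
#' @param mediator_set [gene_set()] of candidate mediator genes.
#' @param direct_config,mediator_config [survnet_config()]s.
#' @param mt_config a [multitask_config()].
#' @return an object of class `mediation_spec`.
#' @export
mediation_spec <- function(driver_panel, mediator_set,
                           direct_config = survnet_config(),
                           mediator_config = survnet_config(),
                           mt_config = multitask_config()) {
  stopifnot(inherits(driver_panel, "gene_set"), inherits(mediator_set, "gene_set"))
  structure(list(driver_panel = driver_panel, mediator_set = mediator_set,
                 direct_config = direct_config,
                 mediator_config = mediator_config,
                 mt_config = mt_config),
            class = "mediation_spec")
}

#' Direct effect of the driver panel on one test fold
#'
#' Trains the direct survival network on the fold's training patients (with
#' training-fold scaling), predicts hazard on the held-out patients, and
#' partitions the test fold's comparable pairs into correctly and incorrectly
#' ranked.
#'
#' @param expr an [expr_matrix()] in state `"raw"`.
#' @param outcomes `survival_outcomes` covering all partitioned patients.
#' @param driver_panel [gene_set()] or character vector.
#' @param folds a [make_folds()] partition.
#' @param fold fold index to hold out.
#' @param config [survnet_config()] for the direct net.
#' @return list of class `direct_effect`: `hazard` (named vector on test
#'   patients), `correct`, `incorrect`, `tied` (pair sets), `model`,
#'   `scaled` (the fold-scaled matrix, reused by [mediated_effect()]),
#'   `test_ids`, `train_ids`, `context` (internal fold context).
#' @export
direct_effect <- function(expr, outcomes, driver_panel, folds, fold,
                          config = survnet_config()) {
  if (inherits(driver_panel, "gene_set")) driver_panel <- driver_panel$genes
  train_ids <- fold_patients(folds, fold, train = TRUE)
  test_ids <- fold_patients(folds, fold)
  stopifnot(!length(intersect(train_ids, test_ids)))
  sc <- scale_with_train(expr, train_ids)
  use_genes <- setdiff(driver_panel, sc$dropped)
  if (!length(use_genes)) stopf("driver panel entirely constant on training fold")
  cfg <- config
  cfg$seed <- derive_seed(config$seed, "direct", fold)
  model <- train_survival_net(
    sc$expr, outcomes[outcomes$patient_id %in% train_ids, , drop = FALSE],
    use_genes, cfg)
  test_out <- outcomes[outcomes$patient_id %in% test_ids, , drop = FALSE]
  h <- predict_hazard(model, sc$expr, test_out$patient_id)
  if (!nrow(comparable_pairs(test_out))) stopf("no comparable pairs in test fold %d", fold)
  parts <- partition_pairs(h, test_out)
  structure(list(hazard = h, correct = parts$correct, incorrect = parts$incorrect,
                 tied = parts$tied, model = model, scaled = sc$expr,
                 dropped = sc$dropped, test_ids = test_out$patient_id,
                 train_ids = train_ids,
                 context = fold_context(test_out$patient_id, parts$correct)),
            class = "direct_effect")
}

#' Percent mediated effect for one mediator set on one fold
#'
#' Composes the fold's multitask prediction (driver panel -> predicted
#' mediator expression) with the independently trained mediator survival net
#' (observed mediator expression -> hazard, used exactly as trained, with no
#' fine-tuning on predicted expression), and returns the concordance of the
#' composed hazards restricted to the pairs the direct model ranked correctly.
#'
#' @param direct a [direct_effect()] result for this fold.
#' @param outcomes `survival_outcomes` covering all partitioned patients.
#' @param spec a [mediation_spec()].
#' @param fold fold index (seeds the mediator/multitask training streams).
#' @return list of class `mediated_effect`: `pme` (in `[0, 1]`),
#'   `composed_hazard`, `n_restricted_pairs`, `mediator_model`,
#'   `multitask_model`, `predicted` (predicted mediator expression on the
#'   test patients).
#' @export
mediated_effect <- function(direct, outcomes, spec, fold) {
  stopifnot(inherits(direct, "direct_effect"), inherits(spec, "mediation_spec"))
  if (!nrow(direct$correct)) stopf("direct model ranked no pairs correctly on this fold")
  sc_expr <- direct$scaled
  med_genes <- setdiff(spec$mediator_set$genes, direct$dropped)
  if (!length(med_genes)) stopf("mediator set entirely constant on training fold")
  train_out <- outcomes[outcomes$patient_id %in% direct$train_ids, , drop = FALSE]
  mcfg <- spec$mediator_config
  mcfg$seed <- derive_seed(mcfg$seed, "mediator", spec$mediator_set$name, fold)
  mediator_model <- train_survival_net(sc_expr, train_out, med_genes, mcfg)
  tcfg <- spec$mt_config
  tcfg$seed <- derive_seed(tcfg$seed, "multitask", spec$mediator_set$name, fold)
  panel <- setdiff(spec$driver_panel$genes, direct$dropped)
  multitask_model <- train_multitask(sc_expr, setdiff(panel, med_genes),
                                     med_genes, tcfg,
                                     patients = direct$train_ids)
  predicted <- predict_expression(multitask_model, sc_expr, direct$test_ids)
  composed <- predict_hazard(mediator_model, predicted)
  test_out <- outcomes[outcomes$patient_id %in% direct$test_ids, , drop = FALSE]
  he <- composed[direct$correct$id_early]
  hl <- composed[direct$correct$id_late]
  if (all(he == hl)) {
    # composed hazards constant on every restricted pair (e.g. a null set
    # whose predictions collapse): PME undefined for this fold
    warnf("composed hazards tied on all restricted pairs; PME undefined")
    res <- list(concordance = NA_real_, tied_hazard_count = length(he))
  } else {
    res <- concordance_on_pairs(composed, test_out, direct$correct)
  }
  structure(list(pme = res$concordance, composed_hazard = composed,
                 n_restricted_pairs = nrow(direct$correct),
                 tied_hazard_count = res$tied_hazard_count,
                 mediator_model = mediator_model,
                 multitask_model = multitask_model, predicted = predicted),
            class = "mediated_effect")
}

#' Randomized-hazard null PMEs for one fold
#'
#' Each replicate assigns every test patient an independent standard-normal
#' hazard and computes the concordance restricted to `correct_pairs`. The
#' expectation of these samples is 0.5 for any restriction.
#'
#' @param outcomes `survival_outcomes` of the test fold patients.
#' @param correct_pairs `pair_set` of pairs the direct model ranked correctly.
#' @param n_reps number of random hazard functions.
#' @param seed integer seed (a dedicated stream; changing `n_reps` does not
#'   perturb any other draw in the pipeline).
#' @return numeric vector of `n_reps` PME samples.
#' @export
randomized_pme <- function(outcomes, correct_pairs, n_reps, seed) {
  stopifnot(is_count(n_reps))
  ctx <- fold_context(outcomes$patient_id, correct_pairs)
  as.numeric(random_pme_matrix(list(ctx), n_reps, seed))
}

#' Run the full linked-network mediation experiment
#'
#' For each fold: trains the direct survival net once and partitions the test
#' pairs; then, for every mediation spec, trains the mediator survival net and
#' the multitask net on the same training patients and computes the percent
#' mediated effect on the direct model's correctly ranked pairs. Null
#' randomized-hazard PMEs are drawn once per fold (they do not depend on the
#' mediator) and shared across specs. Per-spec failures are caught and
#' reported without aborting other specs.
#'
#' @param expr raw [expr_matrix()].
#' @param outcomes `survival_outcomes`.
#' @param specs list of [mediation_spec()]s sharing driver panel and fold
#'   partition.
#' @param folds a [make_folds()] partition.
#' @param n_null_reps random-hazard replicates per experiment (default 50, so
#'   `n_null_reps * k` null PME points in total).
#' @param n_sim draws for the simulated p (default 10000).
#' @param seed master seed for null and simulated draws.
#' @return list of `mediation_report`s, one per spec: `mediator`, `pme`
#'   (per fold, `NA` where undefined), `n_restricted_pairs`, `null_pme`
#'   (matrix, replicate x fold), `median_wilcoxon_p` (two-sided vs the null
#'   replicates), `simulated_p`, `failed`/`error`.
#' @export
mediation_experiment <- function(expr, outcomes, specs, folds,
                                 n_null_reps = 50L, n_sim = 10000L, seed = 1L) {
  if (!length(specs)) return(list())
  panels <- unique(vapply(specs, function(s) paste(sort(s$driver_panel$genes),
                                                   collapse = ","), character(1)))
  if (length(panels) != 1L) stopf("all specs must share the same driver panel")
  k <- folds$k
  directs <- lapply(seq_len(k), function(f) {
    direct_effect(expr, outcomes, specs[[1]]$driver_panel, folds, f,
                  specs[[1]]$direct_config)
  })
  contexts <- lapply(directs, `[[`, "context")
  usable <- vapply(directs, function(d) nrow(d$correct) > 0, logical(1))
  if (!all(usable)) {
    warnf("%d fold(s) excluded: direct model ranked no pairs correctly",
          sum(!usable))
  }
  nulls <- random_pme_matrix(contexts[usable], n_null_reps,
                             derive_seed(seed, "null-stream"))
  reports <- lapply(specs, function(spec) {
    name <- spec$mediator_set$name
    res <- try({
      pme <- rep(NA_real_, k)
      npairs <- integer(k)
      for (f in seq_len(k)) {
        if (!usable[f]) next
        me <- mediated_effect(directs[[f]], outcomes, spec, f)
        pme[f] <- me$pme
        npairs[f] <- me$n_restricted_pairs
      }
      comp <- wilcoxon_vs_nulls(pme[usable], nulls, sided = "two")
      sp <- simulated_p(comp$median_p, nulls, contexts[usable],
                        n_sim = n_sim, seed = derive_seed(seed, "simp", name))
      structure(list(mediator = name, pme = pme, n_restricted_pairs = npairs,
                     null_pme = nulls, p_values = comp$p_values,
                     median_wilcoxon_p = comp$median_p, simulated_p = sp,
                     failed = FALSE, error = NULL),
                class = "mediation_report")
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      structure(list(mediator = name, pme = rep(NA_real_, k),
                     n_restricted_pairs = integer(k), null_pme = nulls,
                     p_values = numeric(0), median_wilcoxon_p = NA_real_,
                     simulated_p = NA_real_, failed = TRUE,
                     error = conditionMessage(attr(res, "condition"))),
                class = "mediation_report")
    } else res
  })
  stats::setNames(reports, vapply(specs, function(s) s$mediator_set$name,
                                  character(1)))
}

#' @export
print.mediation_report <- function(x, ...) {
  cat(sprintf("<mediation_report> %s: median PME %.3f, median Wilcoxon p %.4g, simulated p %.4g%s\n",
              x$mediator, stats::median(x$pme, na.rm = TRUE),
              x$median_wilcoxon_p, x$simulated_p,
              if (x$failed) " [FAILED]" else ""))
  invisible(x)
}
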