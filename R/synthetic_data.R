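#' Configuration of a synthetic cohort with known mediation structure
#'
#' The generated world mirrors the causal diagram the analysis assumes: a
#' driver gene whose expression modulates mediator gene-set expression, hazard
#' proportional to the exponential of a linear score of mediator expression,
#' exponential event times and independent exponential censoring. By default
#' the driver is protective (higher driver expression, lower hazard).
#'
#' Defaults describe a glioma-like cohort: 400 patients, a driver panel of 1 +
#' 11 affected genes, three 12-gene mediator sets (one true mediator, one
#' inverse mediator whose hazard contribution is reversed relative to the
#' driver path, one null set of independent noise), 200 background noise
#' genes, baseline event rate log(2)/900 per day (median survival ~900 days at
#' zero risk score) and censoring rate 4e-4 per day (~2/3 of patients die in
#' follow-up at zero risk score).
#'
#' @param n_patients cohort size (>= 20).
#' @param driver_effect scale of the driver -> affected-gene and driver ->
#'   mediator-gene loadings.
#' @param n_affected driver-panel genes beyond the driver itself.
#' @param mediator_sets list of lists with `name`, `size`, `link_type` in
#'   `{"mediator", "inverse_mediator", "null"}`.
#' @param n_noise background genes unrelated to anything (the permutation
#'   baseline universe).
#' @param noise_sd residual standard deviation of every gene given the driver.
#' @param hazard_scale magnitude of each linked mediator set's contribution to
#'   the log-hazard.
#' @param baseline_rate events per day at risk score 0.
#' @param censor_rate independent censoring rate per day.
#' @param protective_driver if `TRUE` (default) higher driver expression
#'   lowers hazard through `mediator` sets.
#' @param seed master seed; every gene block and the outcome draw use a
#'   dedicated derived stream, so adding a mediator set does not perturb any
#'   other draw.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 400L,
                             driver_effect = 1.0,
                             n_affected = 11L,
                             mediator_sets = list(
                               list(name = "mediator", size = 12L, link_type = "mediator"),
                               list(name = "inverse", size = 12L, link_type = "inverse_mediator"),
                               list(name = "null", size = 12L, link_type = "null")),
                             n_noise = 200L,
                             noise_sd = 0.5,
                             hazard_scale = 1.5,
                             baseline_rate = log(2) / 900,
                             censor_rate = 4e-4,
                             protective_driver = TRUE,
                             seed = 1L) {
  stopifnot(is_count(n_patients), n_patients >= 20,
            baseline_rate > 0, censor_rate > 0, noise_sd >= 0,
            is_count(n_affected))
  types <- vapply(mediator_sets, `[[`, character(1), "link_type")
  stopifnot(all(types %in% c("mediator", "inverse_mediator", "null")))
  structure(list(n_patients = as.integer(n_patients),
                 driver_effect = driver_effect, n_affected = as.integer(n_affected),
                 mediator_sets = mediator_sets, n_noise = as.integer(n_noise),
                 noise_sd = noise_sd, hazard_scale = hazard_scale,
                 baseline_rate = baseline_rate, censor_rate = censor_rate,
                 protective_driver = protective_driver, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic cohort with planted mediation structure
#'
#' Latent model, per patient i: driver `D_i ~ N(0,1)`; affected gene j is
#' `s_j * D_i + e`, with signed loadings `s_j` (alternating sign, magnitudes
#' spread over 0.6-1.4 times `driver_effect`) mimicking up/down-regulation
#' fold changes in a knockdown experiment; genes of a linked mediator set are
#' `w_k * D_i + e` with positive loadings; null-set and background genes are
#' independent noise. The log-hazard risk score is
#' `r_i = sum over linked sets of sign_set * hazard_scale * mean_k(H_ik)`
#' where `sign_set` is negative for `mediator` sets when the driver is
#' protective and flipped for `inverse_mediator` sets (their hazard
#' contribution opposes the driver path). Event times are
#' `Exponential(baseline_rate * exp(r_i))`, censoring `Exponential(censor_rate)`,
#' observed time the minimum. Stored expression is `exp(latent)`, a positive
#' raw-scale matrix, so the pipeline's log + z-scaling step is exercised.
#'
#' @param config a [synthetic_config()].
#' @return an object of class `synthetic_cohort`: `expr` (raw
#'   [expr_matrix()]), `outcomes`, `gene_sets` (driver panel named
#'   `driver_panel` plus one set per mediator set), `ground_truth` (list with
#'   `risk_score`, `link_types`, `loadings`, `config`).
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_patients
  exp_events <- n * config$baseline_rate / (config$baseline_rate + config$censor_rate)
  if (exp_events < 1) stopf("config yields fewer than one event in expectation")
  patients <- sprintf("P%04d", seq_len(n))
  seed <- config$seed

  D <- with_seed(derive_seed(seed, "driver"), stats::rnorm(n))
  rows <- list(DRV1 = D)

  # affected genes: signed loadings mimic up/down fold changes
  if (config$n_affected > 0) {
    aff <- with_seed(derive_seed(seed, "affected"), {
      lapply(seq_len(config$n_affected), function(j) {
        s <- (-1)^j * stats::runif(1, 0.6, 1.4) * config$driver_effect
        s * D + stats::rnorm(n, sd = config$noise_sd)
      })
    })
    names(aff) <- sprintf("AFF%02d", seq_len(config$n_affected))
    rows <- c(rows, aff)
  }

  risk <- numeric(n)
  link_types <- character(0)
  sets <- list(driver_panel = gene_set("driver_panel", names(rows)))
  dir_sign <- if (config$protective_driver) -1 else 1
  for (ms in config$mediator_sets) {
    blk <- with_seed(derive_seed(seed, "mediator-set", ms$name), {
      # Inverse-mediator sets load on a single mixed factor M = D + 2*U with
      # U a set-level latent pathway activity independent of the driver. The
      # mixing matters: if the genes carried D and U separably, a flexible
      # network could disentangle them and the composed model would re-align
      # with the direct model. Because the set only ever exposes M, the
      # observed hazard association (dominated by U) has the sign opposite to
      # the one implied by the driver path, which is the anti-mediation
      # regime.
      U <- stats::rnorm(n)
      genes <- lapply(seq_len(ms$size), function(k) {
        w <- stats::runif(1, 0.7, 1.3) * config$driver_effect
        switch(ms$link_type,
          mediator = w * D + stats::rnorm(n, sd = config$noise_sd),
          inverse_mediator = w * (D + 2 * U) + stats::rnorm(n, sd = config$noise_sd),
          null = stats::rnorm(n))
      })
      list(genes = genes, U = U)
    })
    gnames <- sprintf("MED_%s_%02d", toupper(ms$name), seq_len(ms$size))
    names(blk$genes) <- gnames
    H <- do.call(cbind, blk$genes)
    if (ms$link_type == "mediator") {
      risk <- risk + dir_sign * config$hazard_scale * rowMeans(H)
    } else if (ms$link_type == "inverse_mediator") {
      # hazard contribution sign is flipped relative to the driver pathway;
      # the weight 0.3 keeps the driver protective on net
      risk <- risk - dir_sign * 0.3 * config$hazard_scale * rowMeans(H)
    }
    rows <- c(rows, blk$genes)
    sets[[ms$name]] <- gene_set(ms$name, gnames)
    link_types[ms$name] <- ms$link_type
  }

  if (config$n_noise > 0) {
    noise <- with_seed(derive_seed(seed, "noise-genes"), {
      matrix(stats::rnorm(n * config$n_noise), config$n_noise, n)
    })
    rownames(noise) <- sprintf("NOISE%03d", seq_len(config$n_noise))
  } else noise <- NULL

  latent <- rbind(do.call(rbind, rows), noise)
  expr <- expr_matrix(exp(latent), rownames(latent), patients, "raw")

  outcomes <- with_seed(derive_seed(seed, "outcomes"), {
    t_event <- stats::rexp(n, rate = config$baseline_rate * exp(risk))
    t_cens <- stats::rexp(n, rate = config$censor_rate)
    survival_outcomes(patients, pmax(pmin(t_event, t_cens), 1e-6),
                      t_event <= t_cens)
  })

  structure(list(expr = expr, outcomes = outcomes, gene_sets = sets,
                 ground_truth = list(risk_score = stats::setNames(risk, patients),
                                     link_types = link_types,
                                     config = config)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d genes x %d patients, %d events, sets: %s\n",
              length(x$expr$gene_ids), length(x$expr$patient_ids),
              sum(x$outcomes$event), paste(names(x$gene_sets), collapse = ", ")))
  invisible(x)
}

#' Write a synthetic cohort to disk in the pipeline's input formats
#'
#' Emits `expression.tsv`, `clinical.tsv`, `gene_sets.gmt` and
#' `ground_truth.json`, all readable by the ingest functions.
#'
#' @param cohort a [generate_cohort()] result.
#' @param directory output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_cohort <- function(cohort, directory) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(directory, "expression.tsv"),
             clinical = file.path(directory, "clinical.tsv"),
             gene_sets = file.path(directory, "gene_sets.gmt"),
             ground_truth = file.path(directory, "ground_truth.json"))
  write_expression(cohort$expr, paths["expression"])
  write_clinical(cohort$outcomes, paths["clinical"])
  write_gene_sets(cohort$gene_sets, paths["gene_sets"])
  gt <- cohort$ground_truth
  jsonlite::write_json(
    list(risk_score = as.list(gt$risk_score),
         link_types = as.list(gt$link_types),
         config = unclass(gt$config)),
    paths["ground_truth"], digits = 17, auto_unbox = TRUE)
  invisible(paths)
}
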