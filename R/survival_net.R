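#' Survival network configuration
#'
#' @param hidden_layer_sizes integer vector of hidden-layer widths; may be
#'   empty (`integer(0)`) for the degenerate linear model, which coincides
#'   with a classical Cox proportional-hazards model.
#' @param dropout_rate dropout probability on hidden units, in `[0, 1)`.
#' @param batch_size minibatch size (capped at the training-set size). The
#'   partial likelihood of a minibatch is computed within the batch.
#' @param epochs number of full passes over the training data.
#' @param learning_rate ADAM step size.
#' @param seed integer; the single source of all training stochasticity
#'   (weight init, batch shuffling, dropout masks).
#' @return an object of class `survnet_config`.
#' @export
survnet_config <- function(hidden_layer_sizes = c(16L), dropout_rate = 0.1,
                           batch_size = 64L, epochs = 150L,
                           learning_rate = 1e-3, seed = 1L) {
  stopifnot(all(hidden_layer_sizes >= 1), dropout_rate >= 0, dropout_rate < 1,
            is_count(batch_size), is_count(epochs), learning_rate > 0)
  structure(list(hidden_layer_sizes = as.integer(hidden_layer_sizes),
                 dropout_rate = dropout_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "survnet_config")
}

#' Preset matching the original single-gene architecture
#'
#' Two 10-unit hidden layers, the architecture used for one-gene hazard
#' curves; optimized models instead search a single hidden layer.
#' @param ... overrides passed to [survnet_config()].
#' @export
survnet_config_single_gene <- function(...) {
  args <- utils::modifyList(list(hidden_layer_sizes = c(10L, 10L),
                                 dropout_rate = 0.0, epochs = 300L), list(...))
  do.call(survnet_config, args)
}

# Extract an aligned (patients x genes) design matrix for the named genes.
design_for_genes <- function(expr, genes, patient_ids) {
  mg <- setdiff(genes, expr$gene_ids)
  if (length(mg)) stopf("gene(s) missing from expression matrix: %s",
                        paste(mg, collapse = ", "))
  mp <- setdiff(patient_ids, expr$patient_ids)
  if (length(mp)) stopf("patient(s) missing from expression matrix: %s",
                        paste(mp, collapse = ", "))
  X <- t(expr$values[genes, patient_ids, drop = FALSE])
  if (anyNA(X)) stopf("expression for the model genes contains missing values")
  X
}

#' Train a survival network (Cox partial-likelihood loss)
#'
#' Maps a patient expression vector to a scalar log-hazard. The output layer
#' is linear and the loss is the Breslow negative log partial likelihood
#' ([cox_loss()]), summed over events. Minibatches that contain no event are
#' skipped (their partial likelihood is undefined).
#'
#' @param expr an [expr_matrix()] in state `"log_zscored"` containing all
#'   model genes with complete data.
#' @param outcomes a `survival_outcomes` data frame; every patient must be
#'   present in `expr`. At least one event is required.
#' @param genes a [gene_set()] or character vector: the model inputs.
#' @param config a [survnet_config()].
#' @return an object of class `risk_model` with elements `config`,
#'   `input_genes`, `layers` (weights) and `training_log` (full-data loss per
#'   epoch, evaluated with dropout off).
#' @export
train_survival_net <- function(expr, outcomes, genes, config = survnet_config()) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(config, "survnet_config"))
  if (expr$transform_state != "log_zscored") {
    stopf("survival networks train on log_zscored expression")
  }
  if (inherits(genes, "gene_set")) genes <- genes$genes
  if (!any(outcomes$event)) stopf("cannot train: all patients censored")
  X <- design_for_genes(expr, genes, outcomes$patient_id)
  layers <- mlp_init(ncol(X), config$hidden_layer_sizes, 1L,
                     derive_seed(config$seed, "survnet-init"))
  loss_fn <- function(out, idx) {
    sub <- outcomes[idx, , drop = FALSE]
    h <- as.numeric(out)
    list(loss = cox_loss(h, sub),
         grad = matrix(cox_loss_gradient(h, sub), ncol = 1L))
  }
  epoch_loss_fn <- function(ly) {
    cox_loss(as.numeric(mlp_forward(ly, X)$out), outcomes)
  }
  batch_ok <- function(idx) any(outcomes$event[idx])
  fit <- mlp_train(layers, X, loss_fn, epoch_loss_fn,
                   epochs = config$epochs, batch_size = config$batch_size,
                   lr = config$learning_rate, dropout_rate = config$dropout_rate,
                   seed = derive_seed(config$seed, "survnet-train"),
                   batch_ok = batch_ok)
  if (fit$training_log[length(fit$training_log)] > fit$training_log[1L]) {
    warnf("survival net did not reduce training loss (first %.4f, last %.4f)",
          fit$training_log[1L], fit$training_log[length(fit$training_log)])
  }
  structure(list(config = config, input_genes = genes, layers = fit$layers,
                 training_log = fit$training_log),
            class = "risk_model")
}

#' Predict per-patient log-hazard
#'
#' Deterministic (dropout disabled); no post-processing is applied to the
#' network output. Higher values mean shorter predicted survival.
#'
#' @param model a `risk_model` from [train_survival_net()].
#' @param expr an [expr_matrix()] in state `"log_zscored"` containing all
#'   `model$input_genes`.
#' @param patients optional patient subset (default: all columns of `expr`).
#' @return named numeric vector of log-hazards (names = patient ids).
#' @export
predict_hazard <- function(model, expr, patients = NULL) {
  stopifnot(inherits(model, "risk_model"), inherits(expr, "expr_matrix"))
  patients <- patients %||% expr$patient_ids
  X <- design_for_genes(expr, model$input_genes, patients)
  out <- as.numeric(mlp_forward(model$layers, X)$out)
  stats::setNames(out, patients)
}

#' Hyperparameter search for survival networks
#'
#' Seeded sequential model-based search over the four tuned dimensions:
#' dropout rate, single-hidden-layer width, batch size and number of epochs.
#' An inner holdout split of the training patients provides the validation
#' concordance that is maximized. `method = "random"` is a pure random-search
#' fallback behind the same interface; `method = "smbo"` (default) spends half
#' the budget on random exploration and then proposes candidates with the best
#' predicted concordance under a nearest-neighbour surrogate of the evaluated
#' configurations.
#'
#' @param expr log_zscored [expr_matrix()].
#' @param outcomes `survival_outcomes` (training patients only).
#' @param genes model input genes.
#' @param search_space list with entries `dropout_rate`, `width`, `batch_size`,
#'   `epochs`, each a numeric vector of candidate values (continuous ranges
#'   are given as `c(lo, hi)` for `dropout_rate`).
#' @param budget number of configurations to evaluate (>= 1).
#' @param seed integer seed driving the whole search.
#' @param val_fraction inner holdout fraction (default 0.25).
#' @param method `"smbo"` or `"random"`.
#' @return the selected [survnet_config()] with attribute `"search_log"`
#'   (a data frame of evaluated configs and validation concordances).
#' @export
optimize_hyperparameters <- function(expr, outcomes, genes, search_space,
                                     budget, seed,
                                     val_fraction = 0.25,
                                     method = c("smbo", "random")) {
  method <- match.arg(method)
  stopifnot(is_count(budget))
  if (inherits(genes, "gene_set")) genes <- genes$genes
  space <- utils::modifyList(
    list(dropout_rate = c(0, 0.5), width = c(4L, 8L, 16L, 32L, 64L, 100L),
         batch_size = c(16L, 32L, 64L, 128L), epochs = c(50L, 100L, 200L)),
    search_space %||% list())

  # inner holdout split, stratified on nothing (seeded uniform)
  n <- nrow(outcomes)
  val_idx <- with_seed(derive_seed(seed, "hp-split"), {
    sample.int(n, max(2L, round(val_fraction * n)))
  })
  val <- outcomes[val_idx, , drop = FALSE]
  trn <- outcomes[-val_idx, , drop = FALSE]
  if (!any(trn$event) || !any(val$event)) {
    stopf("inner holdout split has no events; enlarge the training fold")
  }

  draw_config <- function(s) {
    with_seed(s, {
      list(dropout_rate = stats::runif(1, min(space$dropout_rate),
                                       max(space$dropout_rate)),
           width = sample(space$width, 1L),
           batch_size = sample(space$batch_size, 1L),
           epochs = sample(space$epochs, 1L))
    })
  }
  as_vec <- function(cfg) {
    c(cfg$dropout_rate / max(space$dropout_rate, 1e-9),
      log2(cfg$width) / log2(max(space$width)),
      log2(cfg$batch_size) / log2(max(space$batch_size)),
      cfg$epochs / max(space$epochs))
  }
  evaluate <- function(cfg, k) {
    config <- survnet_config(hidden_layer_sizes = cfg$width,
                             dropout_rate = cfg$dropout_rate,
                             batch_size = cfg$batch_size, epochs = cfg$epochs,
                             seed = derive_seed(seed, "hp-eval", k))
    ok <- try({
      model <- train_survival_net(expr, trn, genes, config)
      h <- predict_hazard(model, expr, val$patient_id)
      concordance(h, val)$concordance
    }, silent = TRUE)
    if (inherits(ok, "try-error")) NA_real_ else ok
  }

  evaluated <- list()
  scores <- numeric(0)
  n_explore <- if (method == "random") budget else max(1L, ceiling(budget / 2))
  for (k in seq_len(budget)) {
    if (k <= n_explore || length(stats::na.omit(scores)) < 2L) {
      cfg <- draw_config(derive_seed(seed, "hp-draw", k))
    } else {
      # surrogate: predicted score of a candidate = inverse-distance-weighted
      # mean of the evaluated scores; propose the best of 50 random candidates
      cands <- lapply(seq_len(50L), function(j) {
        draw_config(derive_seed(seed, "hp-cand", k, j))
      })
      obs <- do.call(rbind, lapply(evaluated, as_vec))
      sc <- scores
      keep <- is.finite(sc)
      pred <- vapply(cands, function(cd) {
        d <- sqrt(colSums((t(obs[keep, , drop = FALSE]) - as_vec(cd))^2))
        w <- 1 / (d + 1e-3)
        sum(w * sc[keep]) / sum(w)
      }, numeric(1))
      cfg <- cands[[which.max(pred)]]
    }
    evaluated[[k]] <- cfg
    scores[k] <- evaluate(cfg, k)
  }
  if (all(is.na(scores))) stopf("hyperparameter budget exhausted with all-NaN runs")
  best <- which.max(scores)
  cfg <- evaluated[[best]]
  out <- survnet_config(hidden_layer_sizes = cfg$width,
                        dropout_rate = cfg$dropout_rate,
                        batch_size = cfg$batch_size, epochs = cfg$epochs,
                        seed = derive_seed(seed, "hp-final"))
  attr(out, "search_log") <- data.frame(
    eval = seq_len(budget),
    dropout_rate = vapply(evaluated, `[[`, numeric(1), "dropout_rate"),
    width = vapply(evaluated, `[[`, numeric(1), "width"),
    batch_size = vapply(evaluated, `[[`, numeric(1), "batch_size"),
    epochs = vapply(evaluated, `[[`, numeric(1), "epochs"),
    val_concordance = scores)
  out
}

#' Save a trained model (survival or multitask) as a versioned JSON archive
#'
#' @param model a `risk_model` or `multitask_model`.
#' @param path output file path.
#' @export
save_model <- function(model, path) {
  kind <- class(model)[1]
  payload <- list(
    format = "survmediate-model",
    format_version = 1L,
    kind = kind,
    config = unclass(model$config),
    input_genes = model$input_genes,
    output_genes = model$output_genes,
    layers = lapply(model$layers, function(l) {
      # flat column-major storage avoids any row/column-major JSON ambiguity
      list(W = as.numeric(l$W), b = as.numeric(l$b), dim = dim(l$W))
    }),
    training_log = model$training_log
  )
  jsonlite::write_json(payload, path, digits = 17, auto_unbox = TRUE)
  invisible(path)
}

#' Load a model archive written by [save_model()]
#' @param path archive path.
#' @return the reconstructed model object.
#' @export
load_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(p$format, "survmediate-model")) stopf("not a model archive: %s", path)
  layers <- lapply(p$layers, function(l) {
    d <- as.integer(unlist(l$dim))
    list(W = matrix(as.numeric(unlist(l$W)), nrow = d[1], ncol = d[2]),
         b = as.numeric(unlist(l$b)))
  })
  cfg_class <- if (p$kind == "risk_model") "survnet_config" else "multitask_config"
  cfg <- lapply(p$config, function(x) if (is.list(x)) unlist(x) else x)
  cfg$hidden_layer_sizes <- as.integer(unlist(p$config$hidden_layer_sizes))
  cfg <- structure(cfg, class = cfg_class)
  out <- list(config = cfg, input_genes = as.character(unlist(p$input_genes)),
              layers = layers, training_log = as.numeric(unlist(p$training_log)))
  if (!is.null(p$output_genes)) {
    out$output_genes <- as.character(unlist(p$output_genes))
  }
  structure(out, class = p$kind)
}
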