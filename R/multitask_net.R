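#' Multitask network configuration
#'
#' Feed-forward regression network with ReLU hidden layers (default two layers
#' of 100 units) and one linear output per mediator gene, trained with ADAM on
#' the unweighted sum of per-gene mean squared errors. All targets are
#' z-scaled, so the per-gene losses are on comparable scales.
#'
#' @param hidden_layer_sizes integer vector (default `c(100, 100)`).
#' @param epochs,batch_size,learning_rate,seed as in [survnet_config()].
#' @param weight_decay decoupled (AdamW-style) weight decay. Mediator-set
#'   expression is largely unpredictable from the driver panel, so without
#'   shrinkage the network memorizes sample noise and its predictions carry
#'   spurious patient-to-patient variation; the default 0.05 damps that
#'   without noticeably biasing the strong shared driver signal.
#' @return an object of class `multitask_config`.
#' @export
multitask_config <- function(hidden_layer_sizes = c(100L, 100L),
                             epochs = 150L, batch_size = 64L,
                             learning_rate = 1e-3, weight_decay = 0.05,
                             seed = 1L) {
  stopifnot(all(hidden_layer_sizes >= 1), is_count(epochs),
            is_count(batch_size), learning_rate > 0, weight_decay >= 0)
  structure(list(hidden_layer_sizes = as.integer(hidden_layer_sizes),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 weight_decay = weight_decay,
                 seed = as.integer(seed)),
            class = "multitask_config")
}

#' Train a multitask expression-prediction network
#'
#' Learns to predict mediator gene-set expression from the driver gene panel.
#' Inputs and outputs must be disjoint gene sets, both complete in `expr`.
#'
#' @param expr an [expr_matrix()] in state `"log_zscored"`.
#' @param input_genes driver panel (character vector or [gene_set()]).
#' @param output_genes mediator set (character vector or [gene_set()]).
#' @param config a [multitask_config()].
#' @param patients optional training patient subset (default all columns).
#' @return an object of class `multitask_model` with `config`, `input_genes`,
#'   `output_genes`, `layers`, `training_log` (full-data loss per epoch).
#' @export
train_multitask <- function(expr, input_genes, output_genes,
                            config = multitask_config(), patients = NULL) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(config, "multitask_config"))
  if (expr$transform_state != "log_zscored") {
    stopf("multitask networks train on log_zscored expression")
  }
  if (inherits(input_genes, "gene_set")) input_genes <- input_genes$genes
  if (inherits(output_genes, "gene_set")) output_genes <- output_genes$genes
  overlap <- intersect(input_genes, output_genes)
  if (length(overlap)) stopf("input and output gene sets overlap: %s",
                             paste(overlap, collapse = ", "))
  patients <- patients %||% expr$patient_ids
  X <- design_for_genes(expr, input_genes, patients)
  Y <- design_for_genes(expr, output_genes, patients)
  layers <- mlp_init(ncol(X), config$hidden_layer_sizes, ncol(Y),
                     derive_seed(config$seed, "multitask-init"))
  # loss = sum over genes of mean squared error over the batch
  loss_fn <- function(out, idx) {
    err <- out - Y[idx, , drop = FALSE]
    list(loss = sum(colMeans(err^2)), grad = 2 * err / length(idx))
  }
  epoch_loss_fn <- function(ly) {
    err <- mlp_forward(ly, X)$out - Y
    sum(colMeans(err^2))
  }
  fit <- mlp_train(layers, X, loss_fn, epoch_loss_fn,
                   epochs = config$epochs, batch_size = config$batch_size,
                   lr = config$learning_rate, dropout_rate = 0,
                   seed = derive_seed(config$seed, "multitask-train"),
                   weight_decay = config$weight_decay %||% 0)
  structure(list(config = config, input_genes = input_genes,
                 output_genes = output_genes, layers = fit$layers,
                 training_log = fit$training_log),
            class = "multitask_model")
}

#' Predict mediator gene-set expression from driver-panel expression
#'
#' Deterministic; outputs are on the same log-z scale as the training targets.
#'
#' @param model a `multitask_model`.
#' @param expr an [expr_matrix()] in state `"log_zscored"` containing all
#'   `model$input_genes`.
#' @param patients optional patient subset (default all columns of `expr`).
#' @return an [expr_matrix()] (output_genes x patients, state `log_zscored`).
#' @export
predict_expression <- function(model, expr, patients = NULL) {
  stopifnot(inherits(model, "multitask_model"), inherits(expr, "expr_matrix"))
  patients <- patients %||% expr$patient_ids
  X <- design_for_genes(expr, model$input_genes, patients)
  out <- mlp_forward(model$layers, X)$out # patients x output genes
  expr_matrix(t(out), model$output_genes, patients, "log_zscored")
}

#' Per-gene Pearson correlation of predicted expression with a hazard vector
#'
#' Sign convention: positive means higher predicted expression associates with
#' higher direct-model hazard. Genes whose predictions have zero variance get
#' `NA` (undefined), not 0.
#'
#' @param pred predicted expression ([expr_matrix()], genes x patients).
#' @param direct_hazard named hazard vector covering the same patients.
#' @return named numeric vector, one Pearson r per output gene.
#' @export
expression_hazard_correlation <- function(pred, direct_hazard) {
  stopifnot(inherits(pred, "expr_matrix"))
  h <- direct_hazard[pred$patient_ids]
  if (anyNA(h)) stopf("hazard missing for some patients in the prediction")
  r <- apply(pred$values, 1L, function(v) {
    if (stats::sd(v) == 0 || stats::sd(h) == 0) NA_real_ else stats::cor(v, h)
  })
  stats::setNames(r, pred$gene_ids)
}
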