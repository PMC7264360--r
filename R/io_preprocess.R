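#' Expression matrix container
#'
#' A genes x patients numeric matrix plus identifier bookkeeping and a
#' transform-state flag. Raw matrices hold non-negative FPKM-like values and
#' may contain missing entries; models only ever see `log_zscored` matrices
#' with complete data.
#'
#' @param values numeric matrix, rows = genes, columns = patients.
#' @param gene_ids character vector of unique gene symbols (row names).
#' @param patient_ids character vector of unique patient identifiers.
#' @param transform_state one of `"raw"`, `"log"`, `"log_zscored"`.
#' @return an object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, gene_ids, patient_ids,
                        transform_state = c("raw", "log", "log_zscored")) {
  transform_state <- match.arg(transform_state)
  values <- as.matrix(values)
  if (nrow(values) != length(gene_ids)) {
    stopf("row count (%d) does not match gene_ids length (%d)",
          nrow(values), length(gene_ids))
  }
  if (ncol(values) != length(patient_ids)) {
    stopf("column count (%d) does not match patient_ids length (%d)",
          ncol(values), length(patient_ids))
  }
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g)) stopf("duplicated gene id(s): %s", paste(dup_g, collapse = ", "))
  dup_p <- unique(patient_ids[duplicated(patient_ids)])
  if (length(dup_p)) stopf("duplicated patient id(s): %s", paste(dup_p, collapse = ", "))
  if (transform_state == "raw" && any(values < 0, na.rm = TRUE)) {
    stopf("raw expression values must be >= 0")
  }
  dimnames(values) <- list(gene_ids, patient_ids)
  structure(
    list(values = values, gene_ids = as.character(gene_ids),
         patient_ids = as.character(patient_ids),
         transform_state = transform_state),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d patients [%s], %d missing\n",
              length(x$gene_ids), length(x$patient_ids), x$transform_state,
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read a genes x patients expression matrix from TSV
#'
#' First row holds patient identifiers, first column gene identifiers, cells
#' are numeric or empty (recorded as missing).
#'
#' @param path path to a tab-separated file.
#' @return an [expr_matrix()] in state `"raw"`.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, quote = "")
  if (ncol(raw) < 2L) stopf("expression file needs a gene column plus >=1 patient column")
  gene_ids <- raw[[1L]]
  patient_ids <- colnames(raw)[-1L]
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(vals) & !(cells == "" | cells == "NA"), arr.ind = TRUE)
  if (nrow(bad)) {
    stopf("non-numeric cell '%s' at gene row %d ('%s'), patient column '%s'",
          cells[bad[1, 1], bad[1, 2]], bad[1, 1], gene_ids[bad[1, 1]],
          patient_ids[bad[1, 2]])
  }
  expr_matrix(vals, gene_ids, patient_ids, "raw")
}

#' Write an expression matrix as TSV at full precision
#'
#' @param expr an [expr_matrix()].
#' @param path output file path.
#' @export
write_expression <- function(expr, path) {
  stopifnot(inherits(expr, "expr_matrix"))
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene", expr$patient_ids), collapse = "\t"), con)
  body <- vapply(seq_along(expr$gene_ids), function(i) {
    paste(c(expr$gene_ids[i], fmt(expr$values[i, ])), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read a clinical survival table
#'
#' Expects tab-separated columns `patient_id`, `time_days` (positive, days of
#' follow-up) and `event` (1/0 or true/false; 1 = death observed, 0 = censored
#' at `time_days`).
#'
#' @param path path to a TSV file.
#' @return a data frame of class `survival_outcomes` with columns
#'   `patient_id` (character), `time_days` (numeric) and `event` (logical).
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  need <- c("patient_id", "time_days", "event")
  miss <- setdiff(need, colnames(raw))
  if (length(miss)) stopf("clinical table missing column(s): %s", paste(miss, collapse = ", "))
  time <- suppressWarnings(as.numeric(raw$time_days))
  if (anyNA(time)) stopf("non-numeric time_days for patient %s",
                         raw$patient_id[which(is.na(time))[1]])
  ev_tok <- tolower(trimws(raw$event))
  ev <- ifelse(ev_tok %in% c("1", "true"), TRUE,
               ifelse(ev_tok %in% c("0", "false"), FALSE, NA))
  if (anyNA(ev)) stopf("unrecognized event token '%s' for patient %s",
                       raw$event[which(is.na(ev))[1]], raw$patient_id[which(is.na(ev))[1]])
  survival_outcomes(raw$patient_id, time, as.logical(ev))
}

#' Construct / validate a survival outcome table
#'
#' @param patient_id character identifiers, one per patient.
#' @param time_days positive follow-up times in days.
#' @param event logical; `TRUE` = death observed at `time_days`.
#' @return a `survival_outcomes` data frame.
#' @export
survival_outcomes <- function(patient_id, time_days, event) {
  patient_id <- as.character(patient_id)
  dup <- unique(patient_id[duplicated(patient_id)])
  if (length(dup)) stopf("duplicated patient id(s): %s", paste(dup, collapse = ", "))
  if (any(!is.finite(time_days)) || any(time_days <= 0)) {
    stopf("time_days must be finite and > 0 (offending patient: %s)",
          patient_id[which(!is.finite(time_days) | time_days <= 0)[1]])
  }
  stopifnot(is.logical(event), length(event) == length(patient_id),
            length(time_days) == length(patient_id), !anyNA(event))
  structure(
    data.frame(patient_id = patient_id, time_days = as.numeric(time_days),
               event = event, stringsAsFactors = FALSE),
    class = c("survival_outcomes", "data.frame")
  )
}

#' Write a survival outcome table as TSV
#' @param outcomes a `survival_outcomes` data frame.
#' @param path output path.
#' @export
write_clinical <- function(outcomes, path) {
  utils::write.table(
    data.frame(patient_id = outcomes$patient_id,
               time_days = sprintf("%.17g", outcomes$time_days),
               event = as.integer(outcomes$event)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a gene set
#' @param name set name.
#' @param genes character vector of gene symbols (unique, non-empty).
#' @return an object of class `gene_set`.
#' @export
gene_set <- function(name, genes) {
  genes <- as.character(genes)
  if (!length(genes)) stopf("gene set '%s' has an empty gene list", name)
  if (anyDuplicated(genes)) stopf("gene set '%s' has duplicated genes", name)
  structure(list(name = as.character(name), genes = genes), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: `name TAB description TAB gene TAB gene ...` per line. The
#' description field is discarded; repeated genes within a line are dropped
#' with a warning.
#'
#' @param path path to a GMT file.
#' @return a named list of [gene_set()] objects (possibly empty).
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) stopf("gene set '%s' has an empty gene list", parts[1])
    genes <- parts[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stopf("gene set '%s' has an empty gene list", parts[1])
    if (anyDuplicated(genes)) {
      warnf("gene set '%s': removed %d duplicated gene(s)",
            parts[1], sum(duplicated(genes)))
      genes <- unique(genes)
    }
    gene_set(parts[1], genes)
  })
  stats::setNames(sets, vapply(sets, `[[`, character(1), "name"))
}

#' Write gene sets to a GMT file
#' @param sets list of [gene_set()] objects.
#' @param path output path.
#' @param descriptions optional character vector of descriptions ("na" default).
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  lines <- vapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    d <- if (is.null(descriptions)) "na" else descriptions[i]
    paste(c(s$name, d, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Restrict a gene set to genes with complete expression data
#'
#' Keeps exactly the genes that are present in `expr` and have zero missing
#' values across all patients, preserving set order. This mirrors the usual
#' reduction of curated gene sets to the genes measured completely in the
#' cohort.
#'
#' @param set a [gene_set()].
#' @param expr an [expr_matrix()] in any transform state.
#' @return the filtered [gene_set()].
#' @export
filter_complete <- function(set, expr) {
  stopifnot(inherits(set, "gene_set"), inherits(expr, "expr_matrix"))
  present <- set$genes[set$genes %in% expr$gene_ids]
  keep <- present[rowSums(is.na(expr$values[present, , drop = FALSE])) == 0]
  if (!length(keep)) {
    stopf("gene set '%s': no gene has complete expression data", set$name)
  }
  gene_set(set$name, keep)
}

#' Per-gene scaling parameters estimated on a training subset
#'
#' Computes mean and population (n-denominator) standard deviation of
#' `log(1 + x)` per gene over the named training patients only, so held-out
#' patients never leak into the normalization.
#'
#' @param expr an [expr_matrix()] in state `"raw"`.
#' @param train_patients character vector of training patient ids.
#' @return a data frame of class `scaling_params` with columns `gene`, `mean`,
#'   `sd`, `constant` (logical flag for zero-variance genes, which must be
#'   dropped by the caller before [apply_scaling()]).
#' @export
fit_scaling <- function(expr, train_patients) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (expr$transform_state != "raw") stopf("fit_scaling expects a raw matrix")
  missing_p <- setdiff(train_patients, expr$patient_ids)
  if (length(missing_p)) stopf("unknown training patient(s): %s",
                               paste(missing_p, collapse = ", "))
  sub <- log1p(expr$values[, train_patients, drop = FALSE])
  mu <- rowMeans(sub)
  sd <- apply(sub, 1L, pop_sd)
  structure(
    data.frame(gene = expr$gene_ids, mean = mu, sd = ifelse(sd > 0, sd, NA_real_),
               constant = sd <= 0, stringsAsFactors = FALSE, row.names = NULL),
    class = c("scaling_params", "data.frame")
  )
}

#' Apply training-fold scaling to a raw expression matrix
#'
#' Each value becomes `(log1p(v) - mean_g) / sd_g` using the training-fold
#' parameters, applied to any patient set (train or test).
#'
#' @param expr an [expr_matrix()] in state `"raw"`.
#' @param params a `scaling_params` object from [fit_scaling()] covering all
#'   genes of `expr`; constant-flagged genes must have been dropped.
#' @return an [expr_matrix()] in state `"log_zscored"`.
#' @export
apply_scaling <- function(expr, params) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(params, "scaling_params"))
  if (expr$transform_state != "raw") stopf("apply_scaling expects a raw matrix")
  idx <- match(expr$gene_ids, params$gene)
  if (anyNA(idx)) stopf("no scaling parameters for gene(s): %s",
                        paste(expr$gene_ids[is.na(idx)], collapse = ", "))
  if (any(params$constant[idx])) {
    stopf("constant gene(s) must be dropped before scaling: %s",
          paste(expr$gene_ids[params$constant[idx]], collapse = ", "))
  }
  z <- (log1p(expr$values) - params$mean[idx]) / params$sd[idx]
  expr_matrix(z, expr$gene_ids, expr$patient_ids, "log_zscored")
}

#' Subset an expression matrix by genes and/or patients
#' @param expr an [expr_matrix()].
#' @param genes,patients identifiers to keep (NULL = all), order respected.
#' @return an [expr_matrix()] in the same transform state.
#' @export
subset_expr <- function(expr, genes = NULL, patients = NULL) {
  stopifnot(inherits(expr, "expr_matrix"))
  genes <- genes %||% expr$gene_ids
  patients <- patients %||% expr$patient_ids
  mg <- setdiff(genes, expr$gene_ids)
  if (length(mg)) stopf("gene(s) not in matrix: %s", paste(mg, collapse = ", "))
  mp <- setdiff(patients, expr$patient_ids)
  if (length(mp)) stopf("patient(s) not in matrix: %s", paste(mp, collapse = ", "))
  expr_matrix(expr$values[genes, patients, drop = FALSE], genes, patients,
              expr$transform_state)
}

#' Fit scaling on the training fold and scale the whole matrix
#'
#' Convenience wrapper used throughout cross-validation: estimates
#' [fit_scaling()] parameters on `train_patients`, drops genes that are
#' constant on the training fold, and returns the scaled matrix.
#'
#' @inheritParams fit_scaling
#' @return list with `expr` (log_zscored matrix, constant genes dropped),
#'   `params`, and `dropped` (character vector of constant genes).
#' @export
scale_with_train <- function(expr, train_patients) {
  params <- fit_scaling(expr, train_patients)
  dropped <- params$gene[params$constant]
  keep <- setdiff(expr$gene_ids, dropped)
  if (!length(keep)) stopf("all genes constant on the training fold")
  scaled <- apply_scaling(subset_expr(expr, genes = keep),
                          params[!params$constant, , drop = FALSE])
  list(expr = scaled, params = params, dropped = dropped)
}
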