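#' Negative log Cox partial likelihood (Breslow ties)
#'
#' For every observed death at time \eqn{t_i} the contribution is
#' \eqn{-[h_i - \log \sum_{j: t_j \ge t_i} e^{h_j}]}; the loss is the plain
#' sum over events (no division by the event count). Tied event times share
#' the full risk set (Breslow approximation). This is the training loss of the
#' survival networks and is invariant to adding a constant to all hazards.
#'
#' @param hazard numeric vector of log-hazards, aligned with `outcomes` rows
#'   (or named by patient id, in which case it is re-aligned).
#' @param outcomes a `survival_outcomes` data frame.
#' @return a single non-negative number.
#' @export
cox_loss <- function(hazard, outcomes) {
  h <- align_hazard(hazard, outcomes)
  if (!any(outcomes$event)) stopf("partial likelihood undefined: no events")
  ord <- order(outcomes$time_days, decreasing = TRUE)
  t_o <- outcomes$time_days[ord]
  e_o <- outcomes$event[ord]
  h_o <- h[ord]
  m <- max(h_o)
  # cumulative over descending time = sum over risk set {j : t_j >= t_i};
  # ties: every patient at the tied time is already included ahead of the
  # first event at that time because cumsum is taken over >= blocks below
  cs <- cumsum(exp(h_o - m))
  # for tied times all patients at that time must be in the risk set: take the
  # cumulative value at the LAST index of each tied block
  last_of_block <- ave(seq_along(t_o), t_o, FUN = max)
  risk <- m + log(cs[last_of_block])
  sum(risk[e_o] - h_o[e_o])
}

#' Gradient of [cox_loss()] with respect to each hazard entry
#'
#' @inheritParams cox_loss
#' @return numeric vector, same length and order as `hazard`.
#' @export
cox_loss_gradient <- function(hazard, outcomes) {
  h <- align_hazard(hazard, outcomes)
  if (!any(outcomes$event)) stopf("partial likelihood undefined: no events")
  n <- length(h)
  ord <- order(outcomes$time_days, decreasing = TRUE)
  t_o <- outcomes$time_days[ord]
  e_o <- outcomes$event[ord]
  h_o <- h[ord]
  m <- max(h_o)
  eh <- exp(h_o - m)
  cs <- cumsum(eh)
  last_of_block <- ave(seq_along(t_o), t_o, FUN = max)
  S <- cs[last_of_block] # sum_{t_j >= t_i} exp(h_j - m)
  # factor_k = sum over events i with t_i <= t_k of 1 / S_i
  inv_S <- ifelse(e_o, 1 / S, 0)
  # events with t_i <= t_k are those at position >= first index of k's block
  first_of_block <- ave(seq_along(t_o), t_o, FUN = min)
  tail_sum <- rev(cumsum(rev(inv_S)))
  factor <- tail_sum[first_of_block]
  g_o <- eh * factor - as.numeric(e_o)
  g <- numeric(n)
  g[ord] <- g_o
  g
}

# Align a (possibly named) hazard vector with the outcome rows.
align_hazard <- function(hazard, outcomes) {
  stopifnot(is.numeric(hazard))
  if (!is.null(names(hazard))) {
    idx <- match(outcomes$patient_id, names(hazard))
    if (anyNA(idx)) stopf("hazard missing for patient(s): %s",
                          paste(outcomes$patient_id[is.na(idx)], collapse = ", "))
    hazard <- hazard[idx]
  } else if (length(hazard) != nrow(outcomes)) {
    stopf("hazard length (%d) does not match outcomes (%d)",
          length(hazard), nrow(outcomes))
  }
  if (any(!is.finite(hazard))) stopf("hazard values must be finite")
  unname(hazard)
}
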