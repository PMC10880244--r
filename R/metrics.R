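# Basal metrics (Harrell's C-index, ROC-AUC) and the primary metric: the
# difference in squared scaled basal metrics (DSS) between the ICI and
# chemotherapy arms. Both basal metrics are rank statistics, so every
# downstream quantity is invariant under strictly monotone transforms of
# the model scores.

orient_scores <- function(scores, direction) {
  direction <- match.arg(direction, c("benefit_high", "benefit_low"))
  if (direction == "benefit_low") -scores else scores
}

#' Harrell's concordance index
#'
#' Fraction of comparable patient pairs whose predicted ordering matches
#' the observed survival ordering. A pair (i, j) with `t_i < t_j` is
#' comparable when patient i had the event; pairs with tied times are
#' comparable only when exactly one of the two had the event (that
#' patient is the shorter-lived one). Tied scores count 1/2. Scores are
#' oriented by `direction` so that larger oriented scores predict longer
#' survival.
#'
#' @param times follow-up times (months).
#' @param events event indicators (1 = event, 0 = censored).
#' @param scores per-patient predictions.
#' @param direction `"benefit_high"` or `"benefit_low"`.
#' @return concordance in \[0, 1\].
#' @export
concordance_index <- function(times, events, scores,
                              direction = "benefit_high") {
  stopifnot(length(times) == length(events),
            length(times) == length(scores))
  s <- orient_scores(scores, direction)
  dt <- outer(times, times, "<")            # dt[i,j]: t_i < t_j
  tie_t <- outer(times, times, "==")
  ev_i <- matrix(events == 1, length(times), length(times))
  comparable <- (dt & ev_i) |
    (tie_t & ev_i & t(!ev_i))               # tied time, only i has event
  npairs <- sum(comparable)
  if (npairs == 0) {
    icibench_error("icibench_value_error",
                   "no comparable pairs (all observations censored?)")
  }
  # i is the shorter-lived patient of each comparable pair; concordant
  # when the longer-lived patient j has the larger oriented score.
  s_lt <- outer(s, s, "<")                  # s_i < s_j
  s_eq <- outer(s, s, "==")
  (sum(comparable & s_lt) + 0.5 * sum(comparable & s_eq)) / npairs
}

#' ROC-AUC via the Mann-Whitney statistic
#'
#' Equals U / (n1 * n0) with mid-rank tie handling. `direction` declares
#' what large raw scores mean for the (bad-outcome) label: a
#' `benefit_low` model's large scores predict label 1, so its scores are
#' used as-is; a `benefit_high` model's scores are negated so that it is
#' credited for predicting label 0 (non-progression) correctly.
#'
#' @param labels 0/1 outcome labels (1 = progressive disease).
#' @param scores per-patient predictions.
#' @param direction `"benefit_high"` or `"benefit_low"`.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(labels, scores, direction = "benefit_low") {
  stopifnot(length(labels) == length(scores))
  keep <- !is.na(labels)
  labels <- labels[keep]
  scores <- scores[keep]
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    icibench_error("icibench_value_error",
                   "both outcome classes must be present")
  }
  s <- -orient_scores(scores, direction)    # oriented toward label 1
  r <- rank(s, ties.method = "average")
  u <- sum(r[labels == 1]) - n1 * (n1 + 1) / 2
  u / (n1 * n0)
}

#' Scaled basal metric: 2 * (BM - 0.5)
#'
#' Maps a chance-level basal metric to 0 and perfect (anti-)concordance
#' to +1 (-1).
#'
#' @param bm basal metric in \[0, 1\].
#' @return scaled value in \[-1, 1\].
#' @export
scaled_bm <- function(bm) {
  if (any(bm < 0 | bm > 1)) {
    icibench_error("icibench_value_error", "basal metric outside [0, 1]")
  }
  2 * (bm - 0.5)
}

#' Difference in squared scaled basal metrics (DSS)
#'
#' `scaled(bm_ici)^2 - scaled(bm_ctrl)^2`. Positive for models that
#' predict outcome specifically under checkpoint inhibition (in either
#' direction -- squaring credits anti-concordant predictors too), about 0
#' for prognostic models that perform equally in both arms, negative for
#' models informative only in the control arm.
#'
#' @param bm_ici,bm_ctrl per-arm basal metrics in \[0, 1\].
#' @return DSS in \[-1, 1\].
#' @export
dss <- function(bm_ici, bm_ctrl) {
  scaled_bm(bm_ici)^2 - scaled_bm(bm_ctrl)^2
}

#' Per-arm basal metrics for one endpoint
#'
#' Computes the endpoint's basal metric independently within each arm
#' (C-index for PFS/OS, ROC-AUC for BOR of progressive disease) using
#' only that arm's patients, plus the resulting DSS.
#'
#' @param dataset a [trial_dataset] with both arms present.
#' @param score a [model_score] covering every patient.
#' @param endpoint `"PFS"`, `"OS"` or `"BOR"`.
#' @return object of class `arm_basal_metrics` with fields `bm_ici`,
#'   `bm_ctrl`, `dss`, `metric_kind`, `n_ici`, `n_ctrl`.
#' @export
arm_basal_metrics <- function(dataset, score,
                              endpoint = c("PFS", "OS", "BOR")) {
  endpoint <- match.arg(endpoint)
  cl <- dataset$clinical
  if (!all(ARM_LEVELS %in% cl$arm)) {
    icibench_error("icibench_value_error",
                   "both trial arms must be present for evaluation")
  }
  rep_val <- validate_predictions(dataset, score)
  if (nrow(rep_val) > 0) {
    icibench_error("icibench_value_error", paste0(
      "predictions failed validation (", nrow(rep_val), " problem(s)); ",
      "see validate_predictions()"))
  }
  s <- score$scores[cl$patient_id]
  one_arm <- function(arm) {
    idx <- cl$arm == arm
    if (endpoint == "BOR") {
      roc_auc(cl$bor_pd[idx], s[idx], score$direction)
    } else {
      tcol <- if (endpoint == "PFS") cl$pfs_time else cl$os_time
      ecol <- if (endpoint == "PFS") cl$pfs_event else cl$os_event
      concordance_index(tcol[idx], ecol[idx], s[idx], score$direction)
    }
  }
  bm_ici <- one_arm("ICI")
  bm_ctrl <- one_arm("CHEMO")
  structure(list(
    bm_ici = bm_ici, bm_ctrl = bm_ctrl, dss = dss(bm_ici, bm_ctrl),
    metric_kind = if (endpoint == "BOR") "roc_auc" else "c_index",
    n_ici = sum(cl$arm == "ICI"), n_ctrl = sum(cl$arm == "CHEMO")
  ), class = "arm_basal_metrics")
}

#' @export
print.arm_basal_metrics <- function(x, ...) {
  cat(sprintf("arm_basal_metrics (%s): bm_ici = %.4f, bm_ctrl = %.4f, dss = %.4f\n",
              x$metric_kind, x$bm_ici, x$bm_ctrl, x$dss))
  invisible(x)
}
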