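# Bootstrap uncertainty, paired-bootstrap Bayes factors, the challenge
# ranking procedure, and Kaplan-Meier summaries for tertile-stratified
# survival reporting.

#' Bootstrap evaluation of one model
#'
#' Draws `B` bootstrap resamples of the dataset, stratified within arm so
#' every resample keeps the original arm sizes (DSS compares arms, so arm
#' imbalance across resamples would inflate its variance), and records
#' the per-arm basal metrics and DSS for each resample together with the
#' point estimates on the full data. Degenerate resamples (an arm with no
#' comparable pairs or a single outcome class) are redrawn and counted.
#'
#' @param dataset a [trial_dataset].
#' @param score a [model_score].
#' @param endpoint `"PFS"`, `"OS"` or `"BOR"`.
#' @param B number of resamples (>= 100).
#' @param seed integer seed; identical `(seed, B)` reproduce the draws.
#' @return object of class `evaluation_result` with `model_name`,
#'   `point` (bm_ici, bm_ctrl, dss), `draws` (B x 3 matrix), `seed`, `B`,
#'   `endpoint`, `n_redrawn`.
#' @export
bootstrap_evaluate <- function(dataset, score, endpoint, B = 1000,
                               seed = 1) {
  if (B < 100) {
    icibench_error("icibench_value_error", "B must be at least 100")
  }
  point <- arm_basal_metrics(dataset, score, endpoint)
  cl <- dataset$clinical
  idx_ici <- which(cl$arm == "ICI")
  idx_ctrl <- which(cl$arm == "CHEMO")
  s_all <- score$scores[cl$patient_id]

  one_bm <- function(idx) {
    if (endpoint == "BOR") {
      roc_auc(cl$bor_pd[idx], s_all[idx], score$direction)
    } else {
      tcol <- if (endpoint == "PFS") cl$pfs_time else cl$os_time
      ecol <- if (endpoint == "PFS") cl$pfs_event else cl$os_event
      concordance_index(tcol[idx], ecol[idx], s_all[idx], score$direction)
    }
  }

  set.seed(seed)
  draws <- matrix(NA_real_, B, 3,
                  dimnames = list(NULL, c("bm_ici", "bm_ctrl", "dss")))
  n_redrawn <- 0L
  for (b in seq_len(B)) {
    repeat {
      ri <- sample(idx_ici, length(idx_ici), replace = TRUE)
      rc <- sample(idx_ctrl, length(idx_ctrl), replace = TRUE)
      bm <- tryCatch(c(one_bm(ri), one_bm(rc)), icibench_error = function(e) NULL)
      if (!is.null(bm)) break
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > 100L * B) {
        icibench_error("icibench_value_error",
                       "bootstrap cannot find valid resamples")
      }
    }
    draws[b, ] <- c(bm[1], bm[2], dss(bm[1], bm[2]))
  }
  if (n_redrawn > 0) {
    message("bootstrap_evaluate: redrew ", n_redrawn,
            " degenerate resample(s)")
  }
  structure(list(
    model_name = score$model_name,
    point = c(bm_ici = point$bm_ici, bm_ctrl = point$bm_ctrl,
              dss = point$dss),
    draws = draws, seed = seed, B = B, endpoint = endpoint,
    n_redrawn = n_redrawn
  ), class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  q <- stats::quantile(x$draws[, "dss"], c(0.25, 0.75))
  cat(sprintf(
    "evaluation_result: %s (%s) dss = %.4f [IQR %.4f, %.4f], B = %d, seed = %d\n",
    x$model_name, x$endpoint, x$point["dss"], q[1], q[2], x$B, x$seed))
  invisible(x)
}

#' Paired-bootstrap Bayes factor
#'
#' Win-odds estimator on paired bootstrap draws: with
#' `w = #{i : a_i > b_i}` out of `B` (ties split 1/2),
#' `K = (w + 0.5) / (B - w + 0.5)`, capped at `2B`. `K > 3` is read as
#' decisive evidence that model a outperforms model b on the primary
#' metric.
#'
#' @param draws_a,draws_b equal-length numeric vectors of per-resample
#'   DSS values, paired by resample index (same dataset, B and seed).
#' @return positive real `K`.
#' @export
bayes_factor <- function(draws_a, draws_b) {
  if (length(draws_a) != length(draws_b)) {
    icibench_error("icibench_value_error",
                   "draw lists must be paired (equal length)")
  }
  B <- length(draws_a)
  w <- sum(draws_a > draws_b) + 0.5 * sum(draws_a == draws_b)
  k <- (w + 0.5) / (B - w + 0.5)
  min(k, 2 * B)
}

#' Challenge ranking procedure
#'
#' Eligibility requires outperforming the TMB baseline: Bayes factor
#' versus the reference `> 3`. Among eligible models the one with the
#' highest point DSS anchors the tie set: eligible models whose Bayes
#' factor relative to the anchor is `< 3` are considered tied with it.
#' Ties are broken on the ICI (nivolumab) arm basal metric; tied models
#' whose ICI-arm BM is within `tie_tol` of the best tie-break BM are
#' declared top performers. The default `tie_tol` is one bootstrap
#' standard error of the best tie-breaking model's ICI-arm BM.
#'
#' @param results list of [bootstrap_evaluate()] results (same dataset,
#'   endpoint, B and seed).
#' @param reference the TMB-baseline `evaluation_result`.
#' @param tie_tol numeric tolerance for "close to the best tie-breaking
#'   score"; `NULL` for the default.
#' @return object of class `ranking_result` with `table` (per-model DSS,
#'   K values, memberships), `eligible`, `tie_set`, `top_performers`,
#'   `tie_tol`.
#' @export
rank_models <- function(results, reference, tie_tol = NULL) {
  stopifnot(length(results) > 0)
  nm <- vapply(results, function(r) r$model_name, character(1))
  names(results) <- nm
  B <- vapply(results, function(r) r$B, numeric(1))
  if (length(unique(B)) != 1 || results[[1]]$B != reference$B) {
    icibench_error("icibench_value_error",
                   "all results must share the same B")
  }

  k_ref <- vapply(results, function(r) {
    bayes_factor(r$draws[, "dss"], reference$draws[, "dss"])
  }, numeric(1))
  eligible <- nm[k_ref > 3]

  tie_set <- character(0)
  top <- character(0)
  k_best <- stats::setNames(rep(NA_real_, length(nm)), nm)
  used_tol <- tie_tol
  if (length(eligible) > 0) {
    point_dss <- vapply(results[eligible], function(r) r$point["dss"],
                        numeric(1))
    best <- eligible[which.max(point_dss)]
    k_best[eligible] <- vapply(results[eligible], function(r) {
      bayes_factor(results[[best]]$draws[, "dss"], r$draws[, "dss"])
    }, numeric(1))
    tie_set <- eligible[k_best[eligible] < 3]
    tb <- vapply(results[tie_set], function(r) r$point["bm_ici"],
                 numeric(1))
    best_tb_model <- tie_set[which.max(tb)]
    if (is.null(used_tol)) {
      used_tol <- stats::sd(results[[best_tb_model]]$draws[, "bm_ici"])
    }
    top <- tie_set[tb >= max(tb) - used_tol]
  }

  tab <- data.frame(
    model = nm,
    dss = vapply(results, function(r) unname(r$point["dss"]), numeric(1)),
    bm_ici = vapply(results, function(r) unname(r$point["bm_ici"]),
                    numeric(1)),
    bm_ctrl = vapply(results, function(r) unname(r$point["bm_ctrl"]),
                     numeric(1)),
    k_vs_reference = unname(k_ref),
    k_vs_best = unname(k_best),
    eligible = nm %in% eligible,
    tied_with_best = nm %in% tie_set,
    top_performer = nm %in% top,
    stringsAsFactors = FALSE
  )
  tab <- tab[order(-tab$dss), ]
  rownames(tab) <- NULL
  structure(list(table = tab, eligible = eligible, tie_set = tie_set,
                 top_performers = top, tie_tol = used_tol,
                 reference = reference$model_name),
            class = "ranking_result")
}

#' @export
print.ranking_result <- function(x, ...) {
  cat("ranking_result (reference:", x$reference, ")\n")
  print(x$table, digits = 4)
  cat("top performers:",
      if (length(x$top_performers)) paste(x$top_performers, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' Kaplan-Meier median survival
#'
#' Product-limit estimate of median survival via [survival::survfit()].
#' When the curve sits exactly at 0.5 the median is the average of the
#' boundary times (so with no censoring it equals the plain sample
#' median); when the curve never reaches 0.5 the median is not reached
#' and `NA` is returned.
#'
#' @param times follow-up times.
#' @param events event indicators (1 = event).
#' @return median survival time, or `NA` ("not reached").
#' @export
km_median <- function(times, events) {
  stopifnot(length(times) >= 1)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  unname(stats::quantile(fit, probs = 0.5)$quantile)
}

#' Partition patients at the upper tertile of a model score
#'
#' `upper` holds patients whose score is at or above the cohort
#' upper-tertile threshold, `middle_lower` the rest; used for the
#' stratified Kaplan-Meier summaries of model performance.
#'
#' @param score a [model_score] (>= 3 patients).
#' @return list with character vectors `upper` and `middle_lower` and the
#'   numeric `threshold`.
#' @export
stratify_upper_tertile <- function(score) {
  v <- score$scores
  thr <- quantile_threshold(v, 2 / 3)
  upper <- names(v)[v >= thr]
  if (length(upper) == length(v)) {
    warning("all patients fall in the upper stratum (tied scores)")
  }
  list(upper = upper, middle_lower = setdiff(names(v), upper),
       threshold = thr)
}

#' Stratified median survival for a model score
#'
#' Convenience wrapper: splits the cohort at the score's upper tertile
#' and reports the Kaplan-Meier median of the chosen endpoint per arm and
#' stratum.
#'
#' @param dataset a [trial_dataset].
#' @param score a [model_score].
#' @param endpoint `"PFS"` or `"OS"`.
#' @return data.frame with arm, stratum, n, events, median (NA = not
#'   reached).
#' @export
km_by_stratum <- function(dataset, score, endpoint = c("PFS", "OS")) {
  endpoint <- match.arg(endpoint)
  cl <- dataset$clinical
  strat <- stratify_upper_tertile(score)
  tcol <- if (endpoint == "PFS") cl$pfs_time else cl$os_time
  ecol <- if (endpoint == "PFS") cl$pfs_event else cl$os_event
  rows <- list()
  for (arm in ARM_LEVELS) {
    for (grp in c("upper", "middle_lower")) {
      ids <- strat[[grp]]
      sel <- cl$arm == arm & cl$patient_id %in% ids
      if (!any(sel)) next
      rows[[length(rows) + 1]] <- data.frame(
        arm = arm, stratum = grp, n = sum(sel),
        events = sum(ecol[sel]),
        median = km_median(tcol[sel], ecol[sel]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
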