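# Reference implementations of the fully specified challenge models and
# the TMB / PD-L1 univariate baselines. Each dataset-level wrapper returns
# a model_score; the per-patient rules are exported separately so the
# published worked examples can be checked directly.

#' Cohort context for model thresholds
#'
#' All model cut points (tertiles, medians, 67th percentiles) and min-max
#' normalization bounds are computed on the cohort the model is scored
#' on, pooled across both arms.
#'
#' @param dataset a [trial_dataset].
#' @param proliferation,icr,panel optional [signature_score] objects used
#'   by models that need signature tertiles.
#' @return object of class `model_context`.
#' @export
model_context <- function(dataset, proliferation = NULL, icr = NULL,
                          panel = NULL) {
  cl <- dataset$clinical
  qt <- function(v, q) {
    if (all(is.na(v))) return(NA_real_)
    quantile_threshold(v, q)
  }
  minmax <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) return(c(NA_real_, NA_real_))
    range(v)
  }
  structure(list(
    tmb_tertile = qt(cl$tmb, 2 / 3),
    tmb_median = qt(cl$tmb, 0.5),
    tmb_p67 = qt(cl$tmb, 0.67),
    pdl1_median = qt(cl$pdl1, 0.5),
    pdl1_p67 = qt(cl$pdl1, 0.67),
    prolif_tertile = if (is.null(proliferation)) NA_real_ else
      quantile_threshold(proliferation$values, 2 / 3),
    icr_tertile = if (is.null(icr)) NA_real_ else
      quantile_threshold(icr$values, 2 / 3),
    tmb_range = minmax(cl$tmb),
    pdl1_range = minmax(cl$pdl1)
  ), class = "model_context")
}

#' Netphar decision-tree score
#'
#' TMB is binarized at 243 missense mutations (high if >= 243); PD-L1
#' only matters on the high branch: `Y = 10 * TMBbin + TMBbin * PD-L1`.
#' The low branch is deliberately conservative: every TMB-low patient
#' scores 0, and missing TMB falls to the low branch. Larger scores mean
#' better predicted benefit from checkpoint inhibition (`benefit_high`).
#'
#' @param tmb missense mutation count (may be `NA`, treated as low).
#' @param pdl1 PD-L1 percent; required.
#' @param tmb_cut TMB branching point (default 243).
#' @return numeric score(s).
#' @export
netphar_score <- function(tmb, pdl1, tmb_cut = 243) {
  if (any(is.na(pdl1))) {
    icibench_error("icibench_value_error",
                   "netphar_score requires PD-L1 for every patient")
  }
  tmb_bin <- as.numeric(!is.na(tmb) & tmb >= tmb_cut)
  10 * tmb_bin + tmb_bin * pdl1
}

#' I-MIRACLE three-level score
#'
#' TMB-high means TMB at or above the cohort upper tertile; when TMB is
#' missing, a proliferation signature score at or above its own upper
#' tertile stands in (the proliferation score correlates highly with TMB
#' in NSCLC). PD-L1-high means PD-L1 >= 50 percent; when PD-L1 is
#' missing, an immune (ICR) signature score at or above its upper tertile
#' stands in. Score 3 if both high, 1 if both low, 2 otherwise.
#'
#' @param tmb,pdl1 per-patient values (may be `NA` if the proxy exists).
#' @param proliferation,icr per-patient signature values aligned with
#'   `tmb`/`pdl1` (may be `NULL` when never needed).
#' @param ctx a [model_context] carrying the tertile thresholds.
#' @return integer score(s) in {1, 2, 3}.
#' @export
imiracle_score <- function(tmb, pdl1, proliferation = NULL, icr = NULL,
                           ctx) {
  n <- length(tmb)
  prolif <- if (is.null(proliferation)) rep(NA_real_, n) else proliferation
  icrv <- if (is.null(icr)) rep(NA_real_, n) else icr
  if (any(is.na(tmb) & is.na(prolif))) {
    icibench_error("icibench_value_error",
                   "patient with both TMB and proliferation score missing")
  }
  if (any(is.na(pdl1) & is.na(icrv))) {
    icibench_error("icibench_value_error",
                   "patient with both PD-L1 and ICR score missing")
  }
  tmb_high <- ifelse(!is.na(tmb), tmb >= ctx$tmb_tertile,
                     prolif >= ctx$prolif_tertile)
  pdl1_high <- ifelse(!is.na(pdl1), pdl1 >= 50, icrv >= ctx$icr_tertile)
  as.integer(1L + tmb_high + pdl1_high)
}

#' Aginome-Amoy rule-based score
#'
#' Patients split into three groups on the cohort medians: group 1
#' (PD-L1 below median), group 2 (PD-L1 at/above median, TMB below
#' median), group 3 (both at/above median), ranked group 3 > group 1 >
#' group 2. Within groups, min-max normalized TMB and PD-L1 combine as
#' `TMBn + 2*PDL1n` (group 3), `TMBn + PDL1n` (group 1) and
#' `TMBn - PDL1n` (group 2). Group offsets (+20 / +10 / 0) are arbitrary
#' rank-preserving constants enforcing the group ordering; only the
#' induced ranking matters for the rank-based basal metrics.
#'
#' @param tmb,pdl1 per-patient values; both required.
#' @param ctx a [model_context].
#' @return numeric score(s); higher = predicted responder.
#' @export
aginome_score <- function(tmb, pdl1, ctx) {
  if (any(is.na(tmb)) || any(is.na(pdl1))) {
    icibench_error("icibench_value_error",
                   "aginome_score requires TMB and PD-L1 for every patient")
  }
  norm <- function(v, rng) {
    if (!is.finite(rng[1]) || rng[2] == rng[1]) return(rep(0.5, length(v)))
    (v - rng[1]) / (rng[2] - rng[1])
  }
  tn <- norm(tmb, ctx$tmb_range)
  pn <- norm(pdl1, ctx$pdl1_range)
  group <- ifelse(pdl1 < ctx$pdl1_median, 1L,
                  ifelse(tmb < ctx$tmb_median, 2L, 3L))
  within <- ifelse(group == 3L, tn + 2 * pn,
                   ifelse(group == 1L, tn + pn, tn - pn))
  offset <- c(10, 0, 20)[group]
  offset + within
}

#' FICAN-OSCAR linear model score
#'
#' The published sparse linear model:
#' `Y = -0.693*PANEL - 0.357*isTMBhigh - 0.105*isMale - 0.198*isSquamous
#'  - 0.05*isSquamousAbove5PDL1 - 0.223*isEversmoker - 0.105*isECOG0`,
#' where PANEL is a single-sample enrichment score of a custom gene panel
#' and isTMBhigh uses the cohort TMB upper tertile (missing TMB counts as
#' low). All coefficients are negative, so smaller Y predicts better
#' checkpoint-inhibitor outcome (`benefit_low`).
#'
#' @param sex,histology,smoking,ecog covariates ("male"/"female",
#'   "squamous"/"nonsquamous", "ever"/"never", 0/1).
#' @param tmb,pdl1 per-patient values (`NA` TMB -> low; `NA` PD-L1 ->
#'   the squamous/PD-L1 interaction indicator is 0).
#' @param panel per-patient panel signature values.
#' @param ctx a [model_context].
#' @return numeric score(s).
#' @export
fican_oscar_score <- function(sex, histology, smoking, ecog, tmb, pdl1,
                              panel, ctx) {
  is_tmb_high <- as.numeric(!is.na(tmb) & tmb >= ctx$tmb_tertile)
  is_male <- as.numeric(sex == "male")
  is_squam <- as.numeric(histology == "squamous")
  is_squam_pdl1 <- as.numeric(is_squam == 1 & !is.na(pdl1) & pdl1 > 5)
  is_ever <- as.numeric(smoking == "ever")
  is_ecog0 <- as.numeric(ecog == 0)
  -0.693 * panel - 0.357 * is_tmb_high - 0.105 * is_male -
    0.198 * is_squam - 0.05 * is_squam_pdl1 - 0.223 * is_ever -
    0.105 * is_ecog0
}

#' DukeLKB1 six-feature model
#'
#' Features: TMB > 67th percentile indicator, PD-L1 > 67th percentile
#' indicator, and the means of histology-stratified z-scored expression
#' over four signatures (4-gene inflammatory, LKB1/STK11-loss, NRF2
#' activation, neuroendocrine differentiation). Expression is z-scored
#' separately within squamous and non-squamous tumors before averaging.
#' The combined score is a configurable weighted sum; the default weights
#' `(+1, +1, +1, -1, -1, -1)` treat immune/TMB/PD-L1 features as
#' benefit-associated and the three tumor-intrinsic programs as
#' resistance-associated.
#'
#' @param dataset a [trial_dataset] with histology for every patient.
#' @param inflammatory,lkb1_loss,nrf2,neuroendocrine [gene_set]s.
#' @param ctx a [model_context].
#' @param weights length-6 numeric weight vector.
#' @return list with `features` (patients x 6 matrix) and `score`
#'   (named numeric).
#' @export
dukelkb1_features <- function(dataset, inflammatory, lkb1_loss, nrf2,
                              neuroendocrine, ctx,
                              weights = c(1, 1, 1, -1, -1, -1)) {
  cl <- dataset$clinical
  if (any(is.na(cl$histology))) {
    icibench_error("icibench_value_error",
                   "dukelkb1 requires histology for every patient")
  }
  z <- zscore_genes(dataset$expression, strata = cl$histology)
  feats <- cbind(
    tmb_high = as.numeric(!is.na(cl$tmb) & cl$tmb > ctx$tmb_p67),
    pdl1_high = as.numeric(!is.na(cl$pdl1) & cl$pdl1 > ctx$pdl1_p67),
    inflammatory = signature_mean_score(z, inflammatory)$values,
    lkb1_loss = signature_mean_score(z, lkb1_loss)$values,
    nrf2 = signature_mean_score(z, nrf2)$values,
    neuroendocrine = signature_mean_score(z, neuroendocrine)$values
  )
  rownames(feats) <- cl$patient_id
  score <- drop(feats %*% weights)
  list(features = feats, score = score)
}

#' Univariate baseline model (raw TMB or PD-L1)
#'
#' The benchmarking baselines: the prediction is the raw variable value,
#' with cohort-median imputation of missing values.
#'
#' @param dataset a [trial_dataset].
#' @param variable `"TMB"` or `"PDL1"`.
#' @param subchallenge endpoint label for the returned score.
#' @return a [model_score] with direction `benefit_high`.
#' @export
baseline_score <- function(dataset, variable = c("TMB", "PDL1"),
                           subchallenge = "PFS") {
  variable <- match.arg(variable)
  cl <- dataset$clinical
  v <- if (variable == "TMB") cl$tmb else cl$pdl1
  if (all(is.na(v))) {
    icibench_error("icibench_value_error",
                   paste0(variable, " is entirely missing"))
  }
  v[is.na(v)] <- stats::median(v, na.rm = TRUE)
  names(v) <- cl$patient_id
  model_score(paste0("baseline_", tolower(variable)), subchallenge, v,
              "benefit_high")
}

MODEL_NAMES <- c("netphar", "imiracle", "aginome", "fican_oscar",
                 "dukelkb1", "baseline_tmb", "baseline_pdl1")

#' Score a dataset with a named model
#'
#' Dataset-level front end: computes the cohort context and any signature
#' scores the model needs, applies the model rule to every patient, and
#' returns a complete [model_score]. Gene sets are supplied as a named
#' list (names among `proliferation`, `icr`, `panel`, `inflammatory`,
#' `lkb1_loss`, `nrf2`, `neuroendocrine`) of [gene_set] objects or plain
#' character vectors.
#'
#' Netphar formally requires PD-L1; at the dataset level missing PD-L1 is
#' median-imputed (with a message) so a complete prediction vector can
#' always be submitted.
#'
#' @param dataset a [trial_dataset].
#' @param model one of `r paste(MODEL_NAMES, collapse = ", ")`.
#' @param subchallenge `"PFS"`, `"OS"` or `"BOR"`.
#' @param gene_sets named list of gene sets (see above).
#' @param dukelkb1_weights passed to [dukelkb1_features()].
#' @return a [model_score] covering every patient.
#' @export
score_model <- function(dataset, model, subchallenge = "PFS",
                        gene_sets = list(),
                        dukelkb1_weights = c(1, 1, 1, -1, -1, -1)) {
  model <- match.arg(model, MODEL_NAMES)
  cl <- dataset$clinical
  get_set <- function(nm) {
    gs <- gene_sets[[nm]]
    if (is.null(gs)) {
      icibench_error("icibench_value_error", paste0(
        "model '", model, "' needs gene set '", nm, "'"))
    }
    if (inherits(gs, "gene_set")) gs else gene_set(nm, gs)
  }
  sig <- function(nm) rank_enrichment_score(dataset$expression, get_set(nm))

  if (model == "baseline_tmb") {
    return(baseline_score(dataset, "TMB", subchallenge))
  }
  if (model == "baseline_pdl1") {
    return(baseline_score(dataset, "PDL1", subchallenge))
  }

  if (model == "netphar") {
    pdl1 <- cl$pdl1
    if (any(is.na(pdl1))) {
      message("netphar: median-imputing ", sum(is.na(pdl1)),
              " missing PD-L1 value(s)")
      pdl1[is.na(pdl1)] <- stats::median(pdl1, na.rm = TRUE)
    }
    s <- netphar_score(cl$tmb, pdl1)
    names(s) <- cl$patient_id
    return(model_score("netphar", subchallenge, s, "benefit_high"))
  }

  if (model == "imiracle") {
    prolif <- if (any(is.na(cl$tmb))) sig("proliferation") else NULL
    icr <- if (any(is.na(cl$pdl1))) sig("icr") else NULL
    ctx <- model_context(dataset, proliferation = prolif, icr = icr)
    s <- imiracle_score(cl$tmb, cl$pdl1,
                        proliferation = prolif$values[cl$patient_id],
                        icr = icr$values[cl$patient_id], ctx = ctx)
    s <- as.numeric(s)
    names(s) <- cl$patient_id
    return(model_score("imiracle", subchallenge, s, "benefit_high"))
  }

  if (model == "aginome") {
    tmb <- cl$tmb
    pdl1 <- cl$pdl1
    if (any(is.na(tmb)) || any(is.na(pdl1))) {
      message("aginome: median-imputing missing TMB/PD-L1 value(s)")
      tmb[is.na(tmb)] <- stats::median(tmb, na.rm = TRUE)
      pdl1[is.na(pdl1)] <- stats::median(pdl1, na.rm = TRUE)
    }
    tmp <- dataset
    tmp$clinical$tmb <- tmb
    tmp$clinical$pdl1 <- pdl1
    ctx <- model_context(tmp)
    s <- aginome_score(tmb, pdl1, ctx)
    names(s) <- cl$patient_id
    return(model_score("aginome", subchallenge, s, "benefit_high"))
  }

  if (model == "fican_oscar") {
    panel <- walk_enrichment_score(dataset$expression, get_set("panel"))
    ctx <- model_context(dataset)
    s <- fican_oscar_score(cl$sex, cl$histology, cl$smoking, cl$ecog,
                           cl$tmb, cl$pdl1,
                           panel$values[cl$patient_id], ctx)
    names(s) <- cl$patient_id
    return(model_score("fican_oscar", subchallenge, s, "benefit_low"))
  }

  # dukelkb1
  ctx <- model_context(dataset)
  res <- dukelkb1_features(dataset,
                           inflammatory = get_set("inflammatory"),
                           lkb1_loss = get_set("lkb1_loss"),
                           nrf2 = get_set("nrf2"),
                           neuroendocrine = get_set("neuroendocrine"),
                           ctx = ctx, weights = dukelkb1_weights)
  model_score("dukelkb1", subchallenge, res$score, "benefit_high")
}
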