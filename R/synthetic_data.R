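# Synthetic two-arm ICI-vs-chemotherapy trial generator. The generator
# produces the statistical structure the evaluation framework assumes --
# prognostic and predictive (treatment-interaction) biomarker effects on
# censored survival endpoints, a progressive-disease label, TMB and PD-L1
# coupled to latent expression factors through Gaussian copulas, and
# completely-at-random missingness -- so the whole pipeline can be
# exercised without restricted clinical-trial data.

#' Simulation configuration
#'
#' All generator parameters with defaults emulating a desk-scale NSCLC
#' checkpoint-inhibitor trial: 1:1 randomization, log-normal TMB (median
#' 150 missense mutations, log-sd 0.8) correlated 0.6 with a latent
#' proliferation factor, logit-normal PD-L1 correlated 0.5 with a latent
#' immune factor, exponential proportional-hazards PFS (baseline rate
#' 0.1/month), OS = PFS plus an independent exponential residual (rate
#' 0.08/month), administrative censoring at 24 months plus exponential
#' dropout (rate 0.02/month), and 10 percent missingness in TMB and
#' PD-L1.
#'
#' Effect coefficients act on the log hazard with a benefit convention:
#' positive `theta` means the ICI arm lives longer overall; positive
#' `beta_prog` means high-biomarker patients live longer in both arms
#' (prognostic); positive `beta_pred` means high-biomarker patients live
#' longer specifically under ICI (predictive). `gamma_prog`/`gamma_pred`
#' act analogously (with `alpha_bor` the intercept) on the log-odds of a
#' best overall response of progressive disease, signs flipped so that
#' benefit lowers the progression probability.
#'
#' @param n_patients cohort size.
#' @param allocation fraction randomized to the ICI arm.
#' @param n_genes total genes in the expression matrix.
#' @param blocks named list of signature blocks (`immune`,
#'   `proliferation`, `panel`), each `list(size =, loading =)`; blocks
#'   are disjoint, remaining genes are pure noise.
#' @param tmb_meanlog,tmb_sdlog log-normal TMB parameters (counts are
#'   rounded).
#' @param rho_tmb_prolif Gaussian-copula correlation between TMB and the
#'   proliferation factor.
#' @param pdl1_intercept,pdl1_scale logit-normal PD-L1 parameters
#'   (percent = 100 * plogis(intercept + scale * z)).
#' @param rho_pdl1_immune copula correlation between PD-L1 and the
#'   immune factor.
#' @param biomarker which standardized variable carries the outcome
#'   effects: `"tmb"`, `"pdl1"`, `"immune"` or `"proliferation"`.
#' @param theta,beta_prog,beta_pred log-hazard coefficients (see above).
#' @param lambda0 baseline PFS hazard (events/month).
#' @param lambda_res rate of the exponential OS - PFS residual.
#' @param censor_admin administrative censoring time (months).
#' @param censor_rate exponential dropout hazard (0 = none).
#' @param alpha_bor,gamma_prog,gamma_pred logistic parameters for the
#'   progressive-disease label.
#' @param miss_tmb,miss_pdl1 completely-at-random missingness fractions
#'   in \[0, 1).
#' @param seed master seed; all component substream seeds derive from it.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 500,
                              allocation = 0.5,
                              n_genes = 200,
                              blocks = list(
                                immune = list(size = 20, loading = 0.8),
                                proliferation = list(size = 20, loading = 0.8),
                                panel = list(size = 10, loading = 0.7)),
                              tmb_meanlog = log(150),
                              tmb_sdlog = 0.8,
                              rho_tmb_prolif = 0.6,
                              pdl1_intercept = -0.5,
                              pdl1_scale = 1.5,
                              rho_pdl1_immune = 0.5,
                              biomarker = c("tmb", "pdl1", "immune",
                                            "proliferation"),
                              theta = 0,
                              beta_prog = 0,
                              beta_pred = 0,
                              lambda0 = 0.1,
                              lambda_res = 0.08,
                              censor_admin = 24,
                              censor_rate = 0.02,
                              alpha_bor = -0.3,
                              gamma_prog = 0,
                              gamma_pred = 0,
                              miss_tmb = 0.1,
                              miss_pdl1 = 0.1,
                              seed = 1) {
  biomarker <- match.arg(biomarker)
  cfg <- list(
    n_patients = n_patients, allocation = allocation, n_genes = n_genes,
    blocks = blocks, tmb_meanlog = tmb_meanlog, tmb_sdlog = tmb_sdlog,
    rho_tmb_prolif = rho_tmb_prolif, pdl1_intercept = pdl1_intercept,
    pdl1_scale = pdl1_scale, rho_pdl1_immune = rho_pdl1_immune,
    biomarker = biomarker, theta = theta, beta_prog = beta_prog,
    beta_pred = beta_pred, lambda0 = lambda0, lambda_res = lambda_res,
    censor_admin = censor_admin, censor_rate = censor_rate,
    alpha_bor = alpha_bor, gamma_prog = gamma_prog,
    gamma_pred = gamma_pred, miss_tmb = miss_tmb, miss_pdl1 = miss_pdl1,
    seed = as.integer(seed)
  )
  validate_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) {
    if (!ok) icibench_error("icibench_config_error", msg)
  }
  chk(cfg$n_patients >= 4, "n_patients must be at least 4")
  chk(cfg$allocation > 0 && cfg$allocation < 1,
      "allocation must lie in (0, 1)")
  chk(cfg$tmb_sdlog > 0, "tmb_sdlog must be positive")
  chk(cfg$lambda0 > 0 && cfg$lambda_res > 0,
      "hazard rates must be positive")
  chk(cfg$censor_admin > 0, "censor_admin must be positive")
  chk(cfg$censor_rate >= 0, "censor_rate must be non-negative")
  chk(abs(cfg$rho_tmb_prolif) <= 1 && abs(cfg$rho_pdl1_immune) <= 1,
      "copula correlations must lie in [-1, 1]")
  chk(cfg$miss_tmb >= 0 && cfg$miss_tmb < 1 &&
        cfg$miss_pdl1 >= 0 && cfg$miss_pdl1 < 1,
      "missingness fractions must lie in [0, 1)")
  total <- sum(vapply(cfg$blocks, function(b) b$size, numeric(1)))
  chk(total <= cfg$n_genes,
      "signature blocks exceed the number of genes")
  invisible(TRUE)
}

# Named substreams: each generator component re-seeds with its own
# stream seed, so e.g. changing the missingness fraction never perturbs
# the covariate or outcome draws.
substream_seeds <- function(seed) {
  set.seed(seed)
  stats::setNames(sample.int(.Machine$integer.max - 1L, 5),
                  c("covariates", "expression", "outcomes",
                    "censoring", "missingness"))
}

#' Simulate a two-arm trial
#'
#' Draws a [trial_dataset] from a [simulation_config]: latent immune and
#' proliferation factors per patient, block-structured expression
#' (`loading * factor + N(0,1)` noise; non-signature genes pure noise),
#' TMB and PD-L1 coupled to the factors via Gaussian copulas, PFS from an
#' exponential proportional-hazards model with treatment, prognostic and
#' predictive terms, OS = PFS + independent exponential residual,
#' progressive disease from a logistic model, then censoring and
#' missingness. Identical seeds give identical datasets.
#'
#' @param config a [simulation_config].
#' @return list is a [trial_dataset] with an extra attribute `truth`
#'   holding the latent factors, the standardized biomarker, the gene
#'   sets of the signature blocks, and the substream seeds.
#' @export
simulate_trial <- function(config) {
  validate_config(config)
  cfg <- config
  n <- cfg$n_patients
  seeds <- substream_seeds(cfg$seed)
  ids <- sprintf("P%05d", seq_len(n))

  # -- covariates ----------------------------------------------------
  set.seed(seeds["covariates"])
  n_ici <- round(n * cfg$allocation)
  arm <- sample(c(rep("ICI", n_ici), rep("CHEMO", n - n_ici)))
  sex <- sample(c("male", "female"), n, replace = TRUE,
                prob = c(0.6, 0.4))
  histology <- sample(c("squamous", "nonsquamous"), n, replace = TRUE,
                      prob = c(0.25, 0.75))
  smoking <- sample(c("ever", "never"), n, replace = TRUE,
                    prob = c(0.85, 0.15))
  ecog <- sample(c(0, 1), n, replace = TRUE, prob = c(0.35, 0.65))
  immune <- stats::rnorm(n)
  prolif <- stats::rnorm(n)
  z_tmb <- cfg$rho_tmb_prolif * prolif +
    sqrt(1 - cfg$rho_tmb_prolif^2) * stats::rnorm(n)
  z_pdl1 <- cfg$rho_pdl1_immune * immune +
    sqrt(1 - cfg$rho_pdl1_immune^2) * stats::rnorm(n)
  tmb <- round(exp(cfg$tmb_meanlog + cfg$tmb_sdlog * z_tmb))
  pdl1 <- round(100 * stats::plogis(cfg$pdl1_intercept +
                                      cfg$pdl1_scale * z_pdl1), 1)

  # -- expression ----------------------------------------------------
  set.seed(seeds["expression"])
  expr <- matrix(stats::rnorm(cfg$n_genes * n), cfg$n_genes, n)
  block_names <- names(cfg$blocks)
  gene_ids <- sprintf("G%05d", seq_len(cfg$n_genes))
  gene_sets <- list()
  offset <- 0
  factors <- list(immune = immune, proliferation = prolif,
                  panel = immune)  # panel genes load on the immune factor
  for (bn in block_names) {
    blk <- cfg$blocks[[bn]]
    rows <- offset + seq_len(blk$size)
    fac <- factors[[bn]]
    if (is.null(fac)) fac <- stats::rnorm(n)
    expr[rows, ] <- expr[rows, ] + blk$loading * rep(fac, each = blk$size)
    gene_ids[rows] <- sprintf("%s_%03d", toupper(bn), seq_len(blk$size))
    gene_sets[[bn]] <- gene_set(bn, gene_ids[rows])
    offset <- offset + blk$size
  }
  rownames(expr) <- gene_ids
  colnames(expr) <- ids

  # -- outcomes ------------------------------------------------------
  set.seed(seeds["outcomes"])
  b <- switch(cfg$biomarker, tmb = z_tmb, pdl1 = z_pdl1,
              immune = immune, proliferation = prolif)
  ici <- as.numeric(arm == "ICI")
  lp <- cfg$theta * ici + cfg$beta_prog * b + cfg$beta_pred * b * ici
  hazard <- cfg$lambda0 * exp(-lp)
  pfs_raw <- stats::rexp(n, hazard)
  os_raw <- pfs_raw + stats::rexp(n, cfg$lambda_res)
  p_pd <- stats::plogis(cfg$alpha_bor - cfg$gamma_prog * b -
                          cfg$gamma_pred * b * ici)
  bor_pd <- stats::rbinom(n, 1, p_pd)

  # -- censoring -----------------------------------------------------
  set.seed(seeds["censoring"])
  cens <- rep(cfg$censor_admin, n)
  if (cfg$censor_rate > 0) {
    cens <- pmin(cens, stats::rexp(n, cfg$censor_rate))
  }
  pfs_time <- pmin(pfs_raw, cens)
  pfs_event <- as.numeric(pfs_raw <= cens)
  os_time <- pmin(os_raw, cens)
  os_event <- as.numeric(os_raw <= cens)

  clinical <- data.frame(
    patient_id = ids, arm = arm, sex = sex, histology = histology,
    smoking = smoking, ecog = ecog, tmb = tmb, pdl1 = pdl1,
    pfs_time = pfs_time, pfs_event = pfs_event,
    os_time = os_time, os_event = os_event, bor_pd = bor_pd,
    stringsAsFactors = FALSE)

  dataset <- trial_dataset(clinical, expr)
  dataset <- inject_missingness(dataset, cfg$miss_tmb, cfg$miss_pdl1,
                                seed = seeds["missingness"])
  attr(dataset, "truth") <- list(
    immune = stats::setNames(immune, ids),
    proliferation = stats::setNames(prolif, ids),
    biomarker = stats::setNames(b, ids),
    gene_sets = gene_sets,
    substream_seeds = seeds,
    config = cfg)
  dataset
}

#' Mask TMB / PD-L1 values completely at random
#'
#' Each patient's TMB (PD-L1) is masked independently with the given
#' fraction. Expression is always retained, so signature-based proxies
#' stay available for every patient.
#'
#' @param dataset a [trial_dataset].
#' @param tmb_fraction,pdl1_fraction masking probabilities in \[0, 1).
#' @param seed integer seed.
#' @return the masked [trial_dataset] (attributes preserved).
#' @export
inject_missingness <- function(dataset, tmb_fraction, pdl1_fraction,
                               seed = 1) {
  if (tmb_fraction >= 1 || pdl1_fraction >= 1 ||
      tmb_fraction < 0 || pdl1_fraction < 0) {
    icibench_error("icibench_config_error",
                   "missingness fractions must lie in [0, 1)")
  }
  n <- n_patients(dataset)
  set.seed(seed)
  if (tmb_fraction > 0) {
    dataset$clinical$tmb[stats::runif(n) < tmb_fraction] <- NA
  }
  if (pdl1_fraction > 0) {
    dataset$clinical$pdl1[stats::runif(n) < pdl1_fraction] <- NA
  }
  dataset
}

#' Named effect-scenario presets
#'
#' Four canonical configurations sharing the default generator
#' conditions and differing only in the outcome effects on the
#' standardized TMB biomarker:
#' \describe{
#'   \item{null}{no treatment, prognostic or predictive effect.}
#'   \item{prognostic_only}{`beta_prog = 1`, `beta_pred = 0`: the
#'     biomarker shifts survival identically in both arms.}
#'   \item{predictive_only}{`beta_prog = 0`, `beta_pred = 1`: the
#'     biomarker shifts survival only under ICI.}
#'   \item{mixed}{`beta_prog = 0.5`, `beta_pred = 0.7`.}
#' }
#' Non-null scenarios include a modest overall ICI benefit
#' (`theta = 0.2`). The logistic progression coefficients mirror the
#' survival coefficients.
#'
#' @param n_patients,n_genes problem size passed to every preset.
#' @param seed master seed passed to every preset.
#' @return named list of [simulation_config] objects.
#' @export
effect_scenarios <- function(n_patients = 500, n_genes = 200, seed = 1) {
  base <- function(...) {
    simulation_config(n_patients = n_patients, n_genes = n_genes,
                      biomarker = "tmb", seed = seed, ...)
  }
  list(
    null = base(),
    prognostic_only = base(theta = 0.2, beta_prog = 1, beta_pred = 0,
                           gamma_prog = 1, gamma_pred = 0),
    predictive_only = base(theta = 0.2, beta_prog = 0, beta_pred = 1,
                           gamma_prog = 0, gamma_pred = 1),
    mixed = base(theta = 0.2, beta_prog = 0.5, beta_pred = 0.7,
                 gamma_prog = 0.5, gamma_pred = 0.7)
  )
}
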