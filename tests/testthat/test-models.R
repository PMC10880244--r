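# Worked examples for the published decision rules, plus their
# structural invariants.

cohort_ctx <- function() {
  co <- toy_cohort()
  d <- toy_dataset()   # only used as a carrier for the clinical schema
  cl <- d$clinical[rep(1, nrow(co)), ]
  cl$patient_id <- co$patient_id
  cl$tmb <- co$tmb
  cl$pdl1 <- co$pdl1
  expr <- matrix(rnorm(3 * nrow(co)), 3,
                 dimnames = list(c("G1", "G2", "G3"), co$patient_id))
  model_context(trial_dataset(cl, expr))
}

test_that("netphar reproduces the published decision-tree examples", {
  expect_equal(netphar_score(100, 80), 0)   # conservative TMB-low branch
  expect_equal(netphar_score(243, 0), 10)   # boundary of the high branch
  expect_equal(netphar_score(300, 50), 60)
  expect_equal(netphar_score(NA, 90), 0)    # missing TMB -> low branch
  expect_error(netphar_score(300, NA), class = "icibench_value_error")
  # zero score iff TMB-low, for positive PD-L1
  tmb <- c(0, 100, 242, 243, 500, NA)
  s <- netphar_score(tmb, rep(30, 6))
  expect_identical(s == 0, !(!is.na(tmb) & tmb >= 243))
})

test_that("imiracle assigns categories 1/2/3 by the published rule", {
  ctx <- cohort_ctx()
  # cohort upper tertile of TMB(10..90) = 63.33
  expect_equal(imiracle_score(90, 60, ctx = ctx), 3L)
  expect_equal(imiracle_score(10, 10, ctx = ctx), 1L)
  expect_equal(imiracle_score(90, 10, ctx = ctx), 2L)
  expect_equal(imiracle_score(10, 60, ctx = ctx), 2L)
  # PD-L1 threshold is absolute (>= 50), not a cohort quantile
  expect_equal(imiracle_score(90, 50, ctx = ctx), 3L)
  expect_equal(imiracle_score(90, 49.9, ctx = ctx), 2L)
})

test_that("imiracle proxy rules replace missing TMB / PD-L1", {
  ctx <- cohort_ctx()
  ctx$prolif_tertile <- 0.5
  ctx$icr_tertile <- 0.25
  expect_equal(imiracle_score(NA, 60, proliferation = 0.9, ctx = ctx), 3L)
  expect_equal(imiracle_score(NA, 60, proliferation = 0.1, ctx = ctx), 2L)
  expect_equal(imiracle_score(90, NA, icr = 0.3, ctx = ctx), 3L)
  expect_equal(imiracle_score(90, NA, icr = 0.1, ctx = ctx), 2L)
  expect_error(imiracle_score(NA, 60, proliferation = NA, ctx = ctx),
               class = "icibench_value_error")
})

test_that("imiracle is monotone in TMB and PD-L1 and stays in {1,2,3}", {
  ctx <- cohort_ctx()
  grid <- expand.grid(tmb = seq(0, 100, 10), pdl1 = seq(0, 100, 10))
  s <- imiracle_score(grid$tmb, grid$pdl1, ctx = ctx)
  expect_true(all(s %in% 1:3))
  for (p in unique(grid$pdl1)) {
    expect_true(!is.unsorted(s[grid$pdl1 == p]))
  }
  for (t in unique(grid$tmb)) {
    expect_true(!is.unsorted(s[grid$tmb == t]))
  }
})

test_that("aginome groups and within-group formulas follow the rules", {
  ctx <- cohort_ctx()
  # PD-L1 below cohort median -> group 1 regardless of TMB
  expect_true(aginome_score(90, 0, ctx) >= 10)
  expect_true(aginome_score(90, 0, ctx) < 20)
  expect_true(aginome_score(10, 0, ctx) >= 10)
  # group 3 with TMB_norm = 1, PDL1_norm = 0.5: within-group 2.0, total 22
  ctx2 <- ctx
  ctx2$tmb_range <- c(0, 200)
  ctx2$pdl1_range <- c(0, 100)
  ctx2$tmb_median <- 100
  ctx2$pdl1_median <- 50
  expect_equal(aginome_score(200, 50, ctx2), 22)
  expect_error(aginome_score(NA, 50, ctx), class = "icibench_value_error")
})

test_that("aginome respects the strict group ordering 3 > 1 > 2", {
  set.seed(21)
  for (rep in 1:5) {
    tmb <- round(rlnorm(60, log(150), 0.8))
    pdl1 <- round(100 * plogis(rnorm(60)), 1)
    co <- toy_dataset()$clinical[rep(1, 60), ]
    co$patient_id <- sprintf("P%02d", 1:60)
    co$tmb <- tmb
    co$pdl1 <- pdl1
    expr <- matrix(rnorm(120), 2,
                   dimnames = list(c("G1", "G2"), co$patient_id))
    ctx <- model_context(trial_dataset(co, expr))
    s <- aginome_score(tmb, pdl1, ctx)
    grp <- ifelse(pdl1 < ctx$pdl1_median, 1L,
                  ifelse(tmb < ctx$tmb_median, 2L, 3L))
    if (any(grp == 3) && any(grp == 1)) {
      expect_gt(min(s[grp == 3]), max(s[grp == 1]))
    }
    if (any(grp == 1) && any(grp == 2)) {
      expect_gt(min(s[grp == 1]), max(s[grp == 2]))
    }
  }
})

test_that("fican-oscar reproduces the printed coefficients and is linear", {
  ctx <- cohort_ctx()
  base <- fican_oscar_score("female", "nonsquamous", "never", 1,
                            tmb = 10, pdl1 = 0, panel = 0, ctx = ctx)
  expect_equal(base, 0)
  expect_equal(fican_oscar_score("female", "nonsquamous", "never", 1,
                                 10, 0, panel = 1, ctx = ctx), -0.693)
  # male + eversmoker + ECOG0 + TMB-high, nonsquamous, panel 0
  expect_equal(fican_oscar_score("male", "nonsquamous", "ever", 0,
                                 90, 0, panel = 0, ctx = ctx), -0.790)
  # squamous with PD-L1 > 5 adds both histology terms
  expect_equal(fican_oscar_score("female", "squamous", "never", 1,
                                 10, 6, panel = 0, ctx = ctx),
               -0.198 - 0.05)
  expect_equal(fican_oscar_score("female", "squamous", "never", 1,
                                 10, 5, panel = 0, ctx = ctx), -0.198)
  # additivity over indicator-disjoint inputs
  a <- fican_oscar_score("male", "nonsquamous", "never", 1, 10, 0, 0, ctx)
  b <- fican_oscar_score("female", "nonsquamous", "ever", 1, 10, 0, 0, ctx)
  ab <- fican_oscar_score("male", "nonsquamous", "ever", 1, 10, 0, 0, ctx)
  expect_equal(a + b - base, ab)
})

test_that("dukelkb1 features follow the 67th-percentile and z-score rules", {
  d <- small_trial("null", n = 60, n_genes = 55, seed = 5)
  gs <- truth_gene_sets(d)
  ctx <- model_context(d)
  res <- dukelkb1_features(d, gs$inflammatory, gs$lkb1_loss, gs$nrf2,
                           gs$neuroendocrine, ctx)
  cl <- d$clinical
  tmb_known <- !is.na(cl$tmb)
  expect_identical(unname(res$features[tmb_known, "tmb_high"]),
                   as.numeric(cl$tmb[tmb_known] > ctx$tmb_p67))
  expect_true(all(res$features[!tmb_known, "tmb_high"] == 0))
  # constant expression -> all four signature features vanish
  d2 <- d
  d2$expression[] <- 3.14
  res2 <- dukelkb1_features(d2, gs$inflammatory, gs$lkb1_loss, gs$nrf2,
                            gs$neuroendocrine, ctx)
  expect_true(all(res2$features[, 3:6] == 0))
  # default weights: +immune/TMB/PD-L1, -tumor-intrinsic programs
  expect_equal(unname(res$score),
               unname(drop(res$features %*% c(1, 1, 1, -1, -1, -1))))
})

test_that("baseline models return the raw variable with median imputation", {
  d <- toy_dataset()
  s <- baseline_score(d, "TMB")
  expect_equal(unname(s$scores), c(100, 250, 400))  # B imputed at median
  s2 <- baseline_score(d, "PDL1")
  expect_equal(unname(s2$scores[1:2]), c(80, 5))
  expect_equal(unname(s2$scores[3]), median(c(80, 5)))
})

test_that("model scores are invariant to patient ordering", {
  d <- small_trial("mixed", n = 80, n_genes = 60, seed = 23)
  sets <- truth_gene_sets(d)
  perm <- sample(n_patients(d))
  d2 <- trial_dataset(d$clinical[perm, ], d$expression[, perm])
  for (m in c("imiracle", "aginome", "fican_oscar", "baseline_tmb")) {
    s1 <- suppressMessages(score_model(d, m, gene_sets = sets))
    s2 <- suppressMessages(score_model(d2, m, gene_sets = sets))
    expect_equal(s2$scores[names(s1$scores)], s1$scores,
                 tolerance = 1e-12, label = m)
  }
})
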