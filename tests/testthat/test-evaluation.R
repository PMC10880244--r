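fake_result <- function(name, dss_draws, bm_ici_draws = NULL,
                        point_dss = mean(dss_draws),
                        point_bm = mean(bm_ici_draws)) {
  B <- length(dss_draws)
  if (is.null(bm_ici_draws)) bm_ici_draws <- rep(0.6, B)
  draws <- cbind(bm_ici = bm_ici_draws, bm_ctrl = rep(0.5, B),
                 dss = dss_draws)
  structure(list(model_name = name,
                 point = c(bm_ici = point_bm, bm_ctrl = 0.5,
                           dss = point_dss),
                 draws = draws, seed = 1, B = B, endpoint = "PFS",
                 n_redrawn = 0L),
            class = "evaluation_result")
}

test_that("bootstrap evaluation is reproducible and arm-stratified", {
  d <- small_trial("predictive_only", n = 120, n_genes = 55, seed = 2)
  s <- score_model(d, "baseline_tmb")
  r1 <- bootstrap_evaluate(d, s, "PFS", B = 150, seed = 9)
  r2 <- bootstrap_evaluate(d, s, "PFS", B = 150, seed = 9)
  expect_identical(r1$draws, r2$draws)
  r3 <- bootstrap_evaluate(d, s, "PFS", B = 150, seed = 10)
  expect_false(identical(r1$draws, r3$draws))
  expect_equal(nrow(r1$draws), 150)
  expect_error(bootstrap_evaluate(d, s, "PFS", B = 50, seed = 1),
               class = "icibench_value_error")
})

test_that("constant scores give DSS = 0 in every bootstrap draw", {
  d <- small_trial("null", n = 80, n_genes = 55, seed = 6)
  const <- model_score("const", "PFS",
                       setNames(rep(2, n_patients(d)),
                                d$clinical$patient_id))
  r <- bootstrap_evaluate(d, const, "PFS", B = 100, seed = 4)
  expect_true(all(r$draws[, "dss"] == 0))
  expect_true(all(r$draws[, "bm_ici"] == 0.5))
})

test_that("a predictive signal puts the central half of DSS draws above zero", {
  d <- small_trial("predictive_only", n = 300, n_genes = 55, seed = 8)
  s <- score_model(d, "baseline_tmb")
  r <- bootstrap_evaluate(d, s, "PFS", B = 200, seed = 5)
  expect_gt(quantile(r$draws[, "dss"], 0.25), 0)
})

test_that("bayes factor matches the win-odds estimator", {
  expect_equal(bayes_factor(rep(1, 100), rep(0, 100)), 200)  # capped
  a <- c(rep(1, 75), rep(0, 25))
  b <- c(rep(0, 75), rep(1, 25))
  expect_equal(bayes_factor(a, b), 75.5 / 25.5)
  x <- rnorm(50)
  expect_equal(bayes_factor(x, x), 1)
  expect_error(bayes_factor(1:5, 1:4), class = "icibench_value_error")
})

test_that("reciprocal bayes factors multiply to one (uncapped)", {
  set.seed(12)
  for (i in 1:20) {
    a <- rnorm(500)
    b <- rnorm(500)
    k1 <- bayes_factor(a, b)
    k2 <- bayes_factor(b, a)
    if (k1 < 1000 && k2 < 1000) expect_equal(k1 * k2, 1)
  }
})

test_that("ranking applies eligibility, tie set and tie-breaking rules", {
  set.seed(3)
  B <- 500
  ref <- fake_result("baseline_tmb", rnorm(B, 0, 0.01),
                     rnorm(B, 0.55, 0.01))
  # decisively better than reference, clearly best
  strong <- fake_result("strong", rnorm(B, 0.2, 0.01),
                        rnorm(B, 0.72, 0.01))
  # also eligible, statistically tied with strong, near-equal tie-break
  twin <- fake_result("twin", strong$draws[, "dss"] + rnorm(B, 0, 0.02),
                      rnorm(B, 0.719, 0.01))
  # eligible but decisively worse than the best
  weak <- fake_result("weak", rnorm(B, 0.05, 0.01),
                      rnorm(B, 0.60, 0.01))
  # not eligible
  dud <- fake_result("dud", rnorm(B, -0.05, 0.01), rnorm(B, 0.5, 0.01))

  rk <- rank_models(list(strong, twin, weak, dud), ref)
  expect_setequal(rk$eligible, c("strong", "twin", "weak"))
  expect_setequal(rk$tie_set, c("strong", "twin"))
  expect_setequal(rk$top_performers, c("strong", "twin"))
  expect_true(all(rk$top_performers %in% rk$tie_set))
  expect_true(all(rk$tie_set %in% rk$eligible))

  # single decisive winner
  rk2 <- rank_models(list(strong, dud), ref)
  expect_identical(rk2$top_performers, "strong")

  # nobody beats the reference -> empty top-performer set, valid outcome
  rk3 <- rank_models(list(dud), ref)
  expect_identical(rk3$eligible, character(0))
  expect_identical(rk3$top_performers, character(0))
})

test_that("ranking memberships are nested on random inputs", {
  set.seed(14)
  B <- 300
  for (i in 1:10) {
    ref <- fake_result("ref", rnorm(B, 0, 0.05), rnorm(B, 0.55, 0.02))
    results <- lapply(1:4, function(k) {
      fake_result(paste0("m", k), rnorm(B, runif(1, -0.1, 0.25), 0.05),
                  rnorm(B, runif(1, 0.5, 0.75), 0.02))
    })
    rk <- rank_models(results, ref)
    expect_true(all(rk$top_performers %in% rk$tie_set))
    expect_true(all(rk$tie_set %in% rk$eligible))
  }
})

test_that("kaplan-meier medians match the product-limit estimate", {
  expect_equal(km_median(1:5, rep(1, 5)), 3)
  expect_true(is.na(km_median(c(2, 5, 7), c(0, 0, 0))))  # not reached
  # hand product-limit table: S(1) = 0.75, S(3) = 0.375 -> median 3
  km <- brute_km_survival(c(1, 2, 3, 4), c(1, 0, 1, 1))
  expect_equal(km$surv, c(0.75, 0.375, 0))
  expect_equal(km_median(c(1, 2, 3, 4), c(1, 0, 1, 1)), 3)
  # equals the plain sample median when nothing is censored
  set.seed(44)
  for (i in 1:20) {
    t <- sample(1:20, sample(3:9, 1), replace = TRUE)
    expect_equal(km_median(t, rep(1, length(t))), median(t))
  }
})

test_that("upper-tertile stratification partitions the cohort", {
  s <- model_score("m", "PFS", setNames(1:9, paste0("p", 1:9)))
  strat <- stratify_upper_tertile(s)
  expect_length(strat$upper, 3)
  expect_length(strat$middle_lower, 6)
  expect_setequal(c(strat$upper, strat$middle_lower), paste0("p", 1:9))

  tied <- model_score("m", "PFS", setNames(rep(4, 5), paste0("p", 1:5)))
  expect_warning(st <- stratify_upper_tertile(tied), "upper stratum")
  expect_length(st$upper, 5)

  # three-level scores: upper group is exactly the top category when its
  # prevalence is at most one third
  v <- c(rep(1, 3), rep(2, 3), rep(3, 3))
  s3 <- model_score("imiracle-like", "OS",
                    setNames(v, paste0("p", 1:9)))
  st3 <- stratify_upper_tertile(s3)
  expect_setequal(st3$upper, paste0("p", 7:9))
})

test_that("stratified KM summaries report per-arm medians", {
  d <- small_trial("predictive_only", n = 150, n_genes = 55, seed = 13)
  s <- score_model(d, "baseline_tmb")
  tab <- km_by_stratum(d, s, "PFS")
  expect_setequal(tab$arm, c("ICI", "CHEMO"))
  expect_setequal(unique(tab$stratum), c("upper", "middle_lower"))
  expect_true(all(tab$n > 0))
})
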