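test_that("GEE recovers noiseless generating laws to numerical tolerance", {
  tab <- simulate_cohort(cohort_params(n_subjects = 60, sd_subject_mm3 = 0,
                                       sd_eye_mm3 = 0, seed = 3))
  f1 <- gee_lm(onhv_mm3 ~ icp_cmH2O, tab)
  expect_equal(unname(coef(f1)), c(4.606, 0.136), tolerance = 1e-8)
  f2 <- gee_lm(bmdv_mm3 ~ icp_cmH2O, tab)
  expect_equal(unname(coef(f2)), c(2.100, -0.038), tolerance = 1e-8)
  # constant outcome: zero slope, intercept at the constant
  tab$const <- 3.3
  f3 <- gee_lm(const ~ icp_cmH2O, tab)
  expect_equal(unname(coef(f3)), c(3.3, 0), tolerance = 1e-10)
})

test_that("independence GEE equals OLS with the cluster sandwich of vcovCL", {
  tab <- simulate_cohort(cohort_params(n_subjects = 80, seed = 7))
  fit <- gee_lm(onhv_mm3 ~ icp_cmH2O + gccv_mm3, tab, corstr = "independence")
  ols <- lm(onhv_mm3 ~ icp_cmH2O + gccv_mm3, tab)
  expect_equal(coef(fit), coef(ols), tolerance = 1e-10)
  vc <- sandwich::vcovCL(ols, cluster = tab$subject_id, type = "HC0",
                         cadjust = FALSE)
  expect_equal(unname(vcov(fit)), unname(vc), tolerance = 1e-8)
})

test_that("robust GEE standard errors exceed naive OLS under strong clustering", {
  tab <- simulate_cohort(cohort_params(n_subjects = 150, sd_subject_mm3 = 1.5,
                                       sd_eye_mm3 = 0.05, seed = 21))
  fit <- gee_lm(onhv_mm3 ~ icp_cmH2O, tab)
  ols <- summary(lm(onhv_mm3 ~ icp_cmH2O, tab))$coefficients
  expect_gt(sqrt(vcov(fit)["icp_cmH2O", "icp_cmH2O"]),
            ols["icp_cmH2O", "Std. Error"])
  expect_gt(fit$alpha, 0.8)  # exchangeable correlation is detected
})

test_that("GEE slope estimates cover the truth across replicate cohorts", {
  hits <- 0
  for (seed in 1:100) {
    tab <- simulate_cohort(cohort_params(n_subjects = 500, seed = seed))
    tt <- model_terms(gee_lm(onhv_mm3 ~ icp_cmH2O, tab))
    row <- tt[tt$term == "icp_cmH2O", ]
    if (row$ci_low <= 0.136 && 0.136 <= row$ci_high) hits <- hits + 1
  }
  expect_gte(hits, 93)
})

test_that("GEE validates its inputs", {
  tab <- simulate_cohort(cohort_params(n_subjects = 10, seed = 1))
  expect_error(gee_lm(onhv_mm3 ~ icp_cmH2O, tab[tab$subject_id == "S001", ]),
               "clusters")
  tab$dup <- tab$icp_cmH2O
  expect_error(gee_lm(onhv_mm3 ~ icp_cmH2O + dup, tab), "singular")
})

test_that("one-eye regression keeps right eyes unless only the left exists", {
  tab <- data.frame(
    subject_id = c("a", "a", "b", "c", "c"),
    eye = c("OD", "OS", "OS", "OD", "OS"),
    icp_cmH2O = c(10, 10, 20, 30, 30),
    onhv_mm3 = c(5, 5.1, 7, 9, 9.2))
  one <- select_one_eye(tab)
  expect_identical(one$eye, c("OD", "OS", "OD"))
  fit <- one_eye_lm(onhv_mm3 ~ icp_cmH2O, tab)
  expect_equal(fit$r, 1, tolerance = 1e-9)          # perfectly linear
  expect_equal(unname(coef(fit)[2]), 0.2, tolerance = 1e-9)
  expect_error(one_eye_lm(onhv_mm3 ~ icp_cmH2O, tab[1:2, ]), "at least 3")
})

test_that("one-eye and all-eye univariable slopes agree within simulation error", {
  tab <- simulate_cohort(cohort_params(n_subjects = 400, seed = 9))
  gee <- model_terms(gee_lm(bmdv_mm3 ~ icp_cmH2O, tab))
  one <- model_terms(one_eye_lm(bmdv_mm3 ~ icp_cmH2O, tab))
  s_gee <- gee[gee$term == "icp_cmH2O", ]
  s_one <- one[one$term == "icp_cmH2O", ]
  expect_lt(abs(s_gee$coefficient - s_one$coefficient),
            2 * (s_gee$se + s_one$se))
  expect_lt(abs(s_one$coefficient - (-0.038)), 3 * s_one$se)
})

test_that("one-eye Pearson r is signed by the slope", {
  tab <- simulate_cohort(cohort_params(n_subjects = 50, sd_subject_mm3 = 0,
                                       sd_eye_mm3 = 0, seed = 2))
  expect_equal(one_eye_lm(bmdv_mm3 ~ icp_cmH2O, tab)$r, -1, tolerance = 1e-9)
  expect_equal(one_eye_lm(onhv_mm3 ~ icp_cmH2O, tab)$r, 1, tolerance = 1e-9)
})

test_that("pairwise correlation handles exact, null and degenerate cases", {
  tab <- simulate_cohort(cohort_params(n_subjects = 1000, seed = 13))
  tab$double_icp <- 2 * tab$icp_cmH2O
  expect_equal(pairwise_correlation(tab, "icp_cmH2O", "double_icp")$rho, 1)
  tab$neg <- -tab$icp_cmH2O
  expect_equal(pairwise_correlation(tab, "icp_cmH2O", "neg")$rho, -1)
  tab$noise <- rnorm(nrow(tab))  # independent of ICP
  r <- pairwise_correlation(tab, "icp_cmH2O", "noise", one_eye = FALSE)
  expect_lt(abs(r$rho), 0.1)
  tab$flat <- 1
  expect_error(pairwise_correlation(tab, "icp_cmH2O", "flat"), "zero variance")
})

test_that("gee_lm model methods behave like a standard fitted model", {
  tab <- simulate_cohort(cohort_params(n_subjects = 60, seed = 4))
  fit <- gee_lm(onhv_mm3 ~ icp_cmH2O, tab)
  expect_equal(unname(fitted(fit) + residuals(fit)), tab$onhv_mm3,
               tolerance = 1e-12)
  expect_equal(predict(fit), fitted(fit))
  nd <- data.frame(icp_cmH2O = c(10, 30))
  expect_equal(unname(diff(predict(fit, nd))), 20 * unname(coef(fit)[2]))
  ci <- confint(fit)
  expect_true(all(ci[, 1] <= coef(fit) & coef(fit) <= ci[, 2]))
  expect_output(print(summary(fit)), "Linear GEE")
})
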