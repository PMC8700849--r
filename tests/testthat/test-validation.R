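test_that("intercept-only logistic fit recovers the log odds", {
  y <- rep(c(1, 0), c(30, 70))
  fit <- fit_logistic(y)
  expect_equal(unname(fit$coef), log(30 / 70), tolerance = 1e-8)
  expect_lt(fit$loglik, 0)
})

test_that("a single binary covariate reproduces the 2x2 log odds ratio", {
  # table: exposed 40 cases / 60 controls, unexposed 20 / 80
  y <- rep(c(1, 0, 1, 0), c(40, 60, 20, 80))
  x <- rep(c(1, 1, 0, 0), c(40, 60, 20, 80))
  fit <- fit_logistic(y, data.frame(x = x))
  expect_equal(unname(fit$coef["x"]),
               log((40 * 80) / (60 * 20)), tolerance = 1e-8)
  expect_true(all(fit$se > 0))
  expect_true(all(fit$p >= 0 & fit$p <= 1))
})

test_that("separation raises an informative error", {
  y <- rep(c(0, 1), each = 20)
  x <- rep(c(0, 1), each = 20)
  expect_error(fit_logistic(y, data.frame(sep_var = x)), "sep_var")
  expect_error(fit_logistic(rep(1, 10)), "both classes")
})

test_that("Nagelkerke R2 follows its closed form and boundaries", {
  set.seed(50)
  x <- rnorm(300)
  y <- rbinom(300, 1, plogis(x))
  full <- fit_logistic(y, data.frame(x = x))
  null <- fit_logistic(y)
  r2 <- nagelkerke_r2(full, null)
  l1 <- full$loglik; l0 <- null$loglik; n <- 300
  expect_equal(r2, (1 - exp(2 * (l0 - l1) / n)) / (1 - exp(2 * l0 / n)))
  expect_equal(nagelkerke_r2(null, null), 0)
  expect_true(r2 >= 0 && r2 <= 1)
  # invariant to covariate rescaling
  full10 <- fit_logistic(y, data.frame(x = 10 * x))
  expect_equal(nagelkerke_r2(full10, null), r2, tolerance = 1e-8)
  expect_error(nagelkerke_r2(null, full), "nested")
})

test_that("AUC equals exhaustive pair counting, including ties", {
  scores <- c(1, 2, 2, 3, 0.5, 2)
  labels <- c(1, 1, 0, 1, 0, 0)
  a <- auc_delong(scores, labels)
  expect_equal(a$auc, auc_pairs(scores, labels))

  perf <- auc_delong(c(5, 6, 7, 1, 2, 3), c(1, 1, 1, 0, 0, 0))
  expect_equal(perf$auc, 1)

  set.seed(51)
  s <- rnorm(4000); y <- rbinom(4000, 1, 0.5)
  expect_lt(abs(auc_delong(s, y)$auc - 0.5), 0.04)
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(52)
  s <- rnorm(150); y <- rbinom(150, 1, plogis(s))
  a1 <- auc_delong(s, y)$auc
  expect_equal(auc_delong(exp(s), y)$auc, a1)
  expect_equal(auc_delong(s^3 + 2 * s, y)$auc, a1)
})

test_that("the DeLong interval matches pROC and shrinks with n", {
  skip_if_not_installed("pROC")
  set.seed(53)
  s <- round(rnorm(120), 1)
  y <- rbinom(120, 1, plogis(s))
  mine <- auc_delong(s, y)
  ref <- proc_auc_ci(s, y)
  expect_equal(mine$auc, unname(ref["auc"]), tolerance = 1e-12)
  expect_equal(mine$ci_low, unname(ref["lo"]), tolerance = 1e-10)
  expect_equal(mine$ci_high, unname(ref["hi"]), tolerance = 1e-10)

  width <- function(n, seed) {
    set.seed(seed)
    s <- rnorm(n); y <- rbinom(n, 1, plogis(s))
    a <- auc_delong(s, y)
    a$ci_high - a$ci_low
  }
  w_small <- mean(vapply(1:25, function(i) width(200, i), numeric(1)))
  w_large <- mean(vapply(1:25, function(i) width(3200, i), numeric(1)))
  expect_gt(w_small / w_large, 2.8)  # ~ sqrt(16) = 4 up to noise
  expect_lt(w_small / w_large, 5.5)
})

test_that("ROC curves are monotone with the right endpoints", {
  set.seed(54)
  s <- sample(rep(seq(-2, 2, by = 0.5), 12))
  y <- rbinom(length(s), 1, plogis(s))
  rc <- roc_curve(s, y)
  expect_equal(rc$sensitivity[1], 1)
  expect_equal(rc$specificity[1], 0)
  expect_equal(rc$sensitivity[nrow(rc)], 0)
  expect_equal(rc$specificity[nrow(rc)], 1)
  expect_true(all(diff(rc$sensitivity) <= 0))
  expect_true(all(diff(rc$specificity) >= 0))
  expect_error(roc_curve(s, rep(1, length(s))), "both classes")
})

test_that("decile odds ratios match the hand-computed 2x2 formula", {
  # 100 controls per decile; case counts planted per decile
  controls <- seq(0.5, 1000, by = 1)[1:1000]
  case_counts <- c(10, 5, 5, 5, 5, 5, 5, 5, 5, 40)
  case_scores <- unlist(lapply(1:10, function(k)
    rep(100 * k - 50, case_counts[k])))
  scores <- c(controls, case_scores)
  labels <- rep(c(0, 1), c(length(controls), length(case_scores)))
  tab <- decile_or(scores, labels)
  expect_equal(tab$n_control, rep(100L, 10))
  expect_equal(tab$n_case, as.integer(case_counts))
  expect_equal(tab$or[10], (40 * 100) / (10 * 100))
  se <- sqrt(1 / 40 + 1 / 100 + 1 / 10 + 1 / 100)
  expect_equal(tab$ci_low[10], exp(log(4) - qnorm(0.975) * se))
  expect_equal(tab$ci_high[10], exp(log(4) + qnorm(0.975) * se))
  expect_true(all(tab$ci_low[-1] <= tab$or[-1] &
                    tab$or[-1] <= tab$ci_high[-1]))
})

test_that("null scores give decile ORs near 1 and boundary ties drop low", {
  set.seed(55)
  s <- rnorm(5000); y <- rbinom(5000, 1, 0.3)
  tab <- decile_or(s, y)
  covered <- tab$ci_low[-1] <= 1 & tab$ci_high[-1] >= 1
  expect_gte(sum(covered), 8)

  # a score exactly on a decile boundary belongs to the lower decile
  ctrl <- 1:100
  cuts <- unname(quantile(ctrl, seq(0.1, 0.9, 0.1), type = 7))
  case_scores <- c(0.5, cuts, 100)   # boundary cases fall to deciles 1..9
  scores <- c(ctrl, case_scores)
  labels <- c(rep(0, 100), rep(1, length(case_scores)))
  dec <- decile_or(scores, labels)
  expect_equal(dec$n_case, c(2L, rep(1L, 8), 1L))
})

test_that("zero decile cells are an explicit error", {
  ctrl <- 1:100
  scores <- c(ctrl, rep(95, 5))   # cases only in the top decile
  labels <- c(rep(0, 100), rep(1, 5))
  expect_error(decile_or(scores, labels), "zero cell|reference")
  expect_error(decile_or(1:9, rep(c(0, 1), c(5, 4))), "10 controls")
})

test_that("onset-quartile membership follows type-7 quantile cuts", {
  aao <- 50:80
  co <- cohort_table(data.frame(
    id = sprintf("c%02d", seq_along(aao)),
    status = "case", sex = rep_len(c("F", "M"), length(aao)),
    age_at_sampling = 75,
    age_at_onset = aao,
    PC1 = sin(seq_along(aao)), PC2 = cos(seq_along(aao)),
    PC3 = sin(2 * seq_along(aao))))
  set.seed(56)
  scores <- setNames(rnorm(length(aao)), co$id)
  res <- aao_quartile_analysis(co, scores)
  # type-7 quartiles of 50..80 are 57.5 and 72.5
  expect_equal(unname(res$cuts), c(57.5, 72.5))
  expect_equal(res$n_q1, 8)   # onsets 50..57
  expect_equal(res$n_q4, 8)   # onsets 73..80
  expect_error(aao_quartile_analysis(co[1:5, ], scores), "at least 8")
})

test_that("strong negative onset slope lifts the quartile AUC above 0.5", {
  study <- simulate_prs_study(sim_config(
    n_cases = 500, n_controls = 800, n_snps = 50,
    aao_prs_slope = -4, seed = 57))
  fit <- prs_model(study$weights, study$panel, study$cohort)
  expect_gt(fit$aao$auc$auc, 0.6)
  # the score is higher in the early-onset quartile
  expect_gt(fit$aao$fit$coef[["prs"]], 0)
})
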