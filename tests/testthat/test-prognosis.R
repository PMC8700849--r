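toy_roc <- function() {
  # 5 informative points between the sentinels
  scores <- c(1, 2, 3, 4, 5, 6)
  labels <- c(0, 0, 1, 0, 1, 1)
  roc_curve(scores, labels)
}

test_that("costs = 1 reduces to the classic Youden point", {
  rc <- toy_roc()
  res <- weighted_youden_threshold(rc, costs = 1)
  youden <- rc$sensitivity + rc$specificity - 1
  expect_equal(res$sensitivity + res$specificity - 1, max(youden))
})

test_that("the weighted optimum matches brute force over curve points", {
  rc <- toy_roc()
  for (costs in c(1, 2, 3.5)) {
    res <- weighted_youden_threshold(rc, costs)
    obj <- costs * rc$sensitivity + rc$specificity
    expect_equal(res$objective, max(obj))
    best <- which(obj == max(obj))
    expect_equal(res$sensitivity, max(rc$sensitivity[best]))  # tie rule
  }
  expect_error(weighted_youden_threshold(rc, 0.5), ">= 1")
})

test_that("very large costs force sensitivity 1 below all case scores", {
  rc <- toy_roc()
  res <- weighted_youden_threshold(rc, costs = 1e6)
  expect_equal(res$sensitivity, 1)
  # among sensitivity-1 points the most specific one is kept, i.e. the
  # threshold just below the lowest case score (3 in the toy set)
  expect_lt(res$threshold, 3)
  expect_equal(res$specificity, 2 / 3)
})

test_that("the cost grid is monotone and consistent with single calls", {
  set.seed(80)
  z <- c(rnorm(400, 0.6), rnorm(800, 0))
  y <- rep(c(1, 0), c(400, 800))
  rc <- roc_curve(z, y)
  g <- cost_grid(rc, 1, 5, 0.01)
  expect_equal(nrow(g), 401)
  expect_true(all(diff(g$sensitivity) >= 0))
  expect_true(all(diff(g$specificity) <= 0))
  expect_gte(g$sensitivity[nrow(g)], g$sensitivity[1])
  # every reported operating point lies on the curve
  expect_true(all(paste(g$sensitivity, g$specificity) %in%
                    paste(rc$sensitivity, rc$specificity)))
  one <- weighted_youden_threshold(rc, 2.37)
  row <- g[abs(g$costs - 2.37) < 1e-9, ]
  expect_equal(row$sensitivity, one$sensitivity)
  expect_equal(row$specificity, one$specificity)

  single <- cost_grid(rc, 2, 2, 1)
  expect_equal(nrow(single), 1)
  expect_equal(single$sensitivity, weighted_youden_threshold(rc, 2)$sensitivity)
})

test_that("a constant score yields a flat grid", {
  rc <- roc_curve(c(1, 1, 1, 1), c(0, 1, 0, 1))
  g <- cost_grid(rc, 1, 5, 0.5)
  expect_true(all(g$sensitivity == g$sensitivity[1]))
  expect_true(all(g$specificity == g$specificity[1]))
})

test_that("the residual-incidence recursion matches the direct sum", {
  # 3-interval toy chain evaluated by hand through the printed expansion
  I <- c(0.01, 0.02, 0.03); D <- c(0.1, 0.2, 0.3)
  S <- (1 - D)^5
  hand <- I[1] + I[2] * S[1] * (1 - I[1]) +
    I[3] * S[1] * S[2] * (1 - I[1]) * (1 - I[2])
  expect_equal(residual_direct(I, D)[1], hand, tolerance = 1e-15)

  lt <- generate_life_table()
  res <- residual_lifetime_incidence(lt)
  expect_equal(res$residual, residual_direct(lt$incidence, lt$death_rate),
               tolerance = 1e-12)
  # the terminal open interval contributes its incidence once
  expect_equal(res$residual[10], lt$incidence[10])
})

test_that("with no deaths the single-interval chain passes through", {
  q <- 0.04
  lt <- life_table(c(rep(0, 9), q), rep(0, 10))
  res <- residual_lifetime_incidence(lt)
  expect_equal(res$residual, rep(q, 10))
  # zero death rates: residual at least any single interval's incidence
  lt2 <- generate_life_table(death_rate = rep(0, 10))
  res2 <- residual_lifetime_incidence(lt2)
  for (d in 1:10) {
    expect_gte(res2$residual[d] + 1e-15, max(lt2$incidence[d:10]))
  }
})

test_that("Bayes predictive values behave at the reference points", {
  pv <- predictive_values(0.5, 0.5, 0.2)
  expect_equal(pv$ppv, 0.2)
  expect_equal(pv$npv, 0.8)

  expect_equal(predictive_values(1, 0.4, 0.3)$npv, 1)
  expect_equal(predictive_values(0, 1, 0.05)$npv, 0.95)

  expect_error(predictive_values(1.2, 0.5, 0.1), "\\[0, 1\\]")
  expect_warning(pv0 <- predictive_values(0, 1, 0), "undefined")
  expect_true(is.na(pv0$ppv))
})

test_that("ppv rises and npv falls with incidence for informative tests", {
  p <- seq(0.001, 0.5, length.out = 50)
  pv <- predictive_values(0.8, 0.7, p)
  expect_true(all(diff(pv$ppv) > 0))
  expect_true(all(diff(pv$npv) < 0))
})

test_that("the prognosis report composes grid and incidence cell by cell", {
  set.seed(81)
  z <- c(rnorm(300, 0.7), rnorm(600))
  y <- rep(c(1, 0), c(300, 600))
  rc <- roc_curve(z, y)
  g <- cost_grid(rc, 1, 5, 1)
  res <- residual_lifetime_incidence(generate_life_table())
  rep5 <- prognosis_report(g, res, costs = 1:5)
  expect_equal(nrow(rep5), 50)
  for (i in sample(nrow(rep5), 5)) {
    pv <- predictive_values(rep5$sensitivity[i], rep5$specificity[i],
                            rep5$residual[i])
    expect_equal(rep5$ppv[i], pv$ppv)
    expect_equal(rep5$npv[i], pv$npv)
  }
  # residual incidence decreasing in age means ppv non-increasing
  sub <- rep5[rep5$costs == 1, ]
  expect_true(all(diff(sub$ppv[order(-sub$residual)]) <= 1e-15))
  expect_error(prognosis_report(g, res, costs = 7), "not on the grid")
})
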