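#' Logistic regression with Wald tests
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares via [stats::glm()], convergence tolerance 1e-10, at most 100
#' iterations) with per-coefficient Wald z statistics and two-sided p
#' values. Non-convergence or (quasi-)complete separation raises an
#' error naming the offending covariate rather than returning an
#' unusable fit.
#'
#' @param outcome binary vector (0/1, logical, or two-level factor).
#' @param covariates `data.frame` or matrix of covariate columns, or
#'   `NULL` for an intercept-only model.
#' @return A list of class `"logistic_fit"`: `coef`, `se`, `z`, `p`,
#'   `loglik`, `n`, `fitted`, `converged` and the underlying `glm`.
#' @export
fit_logistic <- function(outcome, covariates = NULL) {
  y <- to_binary(outcome)
  if (length(unique(y)) < 2) {
    stop("outcome must contain both classes", call. = FALSE)
  }
  if (is.null(covariates)) {
    dat <- data.frame(.y = y)
    form <- .y ~ 1
  } else {
    dat <- as.data.frame(covariates)
    dat$.y <- y
    form <- stats::as.formula(paste(".y ~",
      paste(sprintf("`%s`", setdiff(names(dat), ".y")), collapse = " + ")))
  }
  fit <- suppressWarnings(
    stats::glm(form, family = stats::binomial(), data = dat,
               control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  )
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("design not full rank: coefficient for ",
         names(cf)[is.na(cf)][1], " is not estimable", call. = FALSE)
  }
  se <- sqrt(diag(stats::vcov(fit)))
  big <- abs(cf) > 15 & names(cf) != "(Intercept)"
  if (!fit$converged || any(big)) {
    off <- if (any(big)) names(cf)[big][1] else names(cf)[which.max(abs(cf))]
    stop("logistic regression did not converge (possible separation); ",
         "check covariate ", off, call. = FALSE)
  }
  z <- cf / se
  structure(list(
    coef = cf, se = se, z = z, p = 2 * stats::pnorm(-abs(z)),
    loglik = as.numeric(stats::logLik(fit)), n = length(y),
    fitted = stats::fitted(fit), converged = fit$converged, glm = fit
  ), class = "logistic_fit")
}

to_binary <- function(outcome) {
  if (is.factor(outcome)) outcome <- as.integer(outcome) - 1L
  if (is.character(outcome)) {
    if (all(outcome %in% c("case", "control"))) {
      outcome <- as.integer(outcome == "case")
    } else stop("cannot interpret character outcome", call. = FALSE)
  }
  y <- as.numeric(outcome)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary", call. = FALSE)
  y
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic fit (n = ", x$n, ", logLik = ",
      format(x$loglik, digits = 6), ")\n", sep = "")
  print(data.frame(coef = x$coef, se = x$se, z = x$z, p = x$p))
  invisible(x)
}

#' @export
coef.logistic_fit <- function(object, ...) object$coef

#' @export
logLik.logistic_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coef), class = "logLik")
}

#' Nagelkerke pseudo-R-squared
#'
#' Cox-Snell R2 = 1 - exp(2 (l0 - l1) / n), rescaled by its maximum
#' 1 - exp(2 l0 / n), where l1 and l0 are the log-likelihoods of the
#' full and null model on the same outcome.
#'
#' @param full,null nested [fit_logistic()] objects (same outcome, same
#'   n; `null` nested in `full`).
#' @return A value in \[0, 1\].
#' @export
nagelkerke_r2 <- function(full, null) {
  stopifnot(inherits(full, "logistic_fit"), inherits(null, "logistic_fit"))
  if (full$n != null$n) stop("models fitted on different n", call. = FALSE)
  l1 <- full$loglik; l0 <- null$loglik; n <- full$n
  if (l1 < l0 - 1e-8) {
    stop("full-model log-likelihood below null: models are not nested",
         call. = FALSE)
  }
  cs <- 1 - exp(2 * (l0 - l1) / n)
  cs_max <- 1 - exp(2 * l0 / n)
  if (cs_max <= 0) return(0)
  min(1, cs / cs_max)
}

## ---- ROC / AUC -------------------------------------------------------------

#' ROC curve and AUC with DeLong confidence interval
#'
#' The ROC curve is evaluated at thresholds placed at midpoints between
#' consecutive distinct scores, with -Inf/+Inf sentinels; an individual
#' is test-positive when their score exceeds the threshold. The AUC is
#' the Mann-Whitney U statistic scaled to \[0, 1\] with ties counted
#' one half, i.e. the probability that a random case outscores a random
#' control. The 95% confidence interval uses the DeLong placement
#' variance.
#'
#' @param scores numeric scores.
#' @param labels binary labels (1/`"case"` = positive class).
#' @return `roc_and_auc()` returns `list(roc, auc)`; `roc_curve()` a
#'   `data.frame` of class `"roc_curve"` (`threshold`, `sensitivity`,
#'   `specificity`); `auc_delong()` a list of class `"auc_estimate"`
#'   (`auc`, `se`, `ci_low`, `ci_high`, `method`, `n_case`, `n_control`).
#' @export
roc_and_auc <- function(scores, labels) {
  y <- to_binary(labels)
  check_two_classes(y)
  list(roc = roc_curve(scores, y), auc = auc_delong(scores, y))
}

check_two_classes <- function(y) {
  if (length(unique(y)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  invisible(y)
}

#' @rdname roc_and_auc
#' @export
roc_curve <- function(scores, labels) {
  y <- to_binary(labels)
  check_two_classes(y)
  stopifnot(length(scores) == length(y), all(is.finite(scores)))
  u <- sort(unique(scores))
  thr <- c(-Inf, (u[-length(u)] + u[-1]) / 2, Inf)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  # cumulative counts of scores <= u[k], per class
  tab1 <- cumsum(tabulate(match(scores[y == 1], u), length(u)))
  tab0 <- cumsum(tabulate(match(scores[y == 0], u), length(u)))
  # positive test means score > threshold; the midpoint after u[k]
  # classifies exactly the scores above u[k] as positive
  out <- data.frame(threshold = thr,
                    sensitivity = c(1, (n1 - tab1) / n1),
                    specificity = c(0, tab0 / n0))
  class(out) <- c("roc_curve", "data.frame")
  out
}

#' @rdname roc_and_auc
#' @param conf_level confidence level for the DeLong interval.
#' @export
auc_delong <- function(scores, labels, conf_level = 0.95) {
  y <- to_binary(labels)
  check_two_classes(y)
  x1 <- scores[y == 1]; x0 <- scores[y == 0]
  n1 <- length(x1); n0 <- length(x0)
  r <- rank(c(x1, x0))           # midranks handle ties as 1/2
  r1 <- r[seq_len(n1)]; r0 <- r[n1 + seq_len(n0)]
  auc <- (sum(r1) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # DeLong placements from midranks
  v10 <- (r1 - rank(x1)) / n0                 # per-case placement
  v01 <- 1 - (r0 - rank(x0)) / n1             # per-control placement
  s10 <- if (n1 > 1) stats::var(v10) else NA_real_
  s01 <- if (n0 > 1) stats::var(v01) else NA_real_
  se <- sqrt(s10 / n1 + s01 / n0)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- if (is.finite(se)) c(auc - zq * se, auc + zq * se) else c(NA, NA)
  structure(list(auc = auc, se = se,
                 ci_low = max(0, min(ci[1], auc)),
                 ci_high = min(1, max(ci[2], auc)),
                 method = "delong", conf_level = conf_level,
                 n_case = n1, n_control = n0),
            class = "auc_estimate")
}

#' @export
print.auc_estimate <- function(x, ...) {
  cat(sprintf("AUC %.4f [%.4f, %.4f] (%s, %d cases / %d controls)\n",
              x$auc, x$ci_low, x$ci_high, x$method, x$n_case, x$n_control))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, add = FALSE, col = "steelblue", ...) {
  fpr <- 1 - x$specificity
  o <- order(fpr, x$sensitivity)
  if (add) {
    graphics::lines(fpr[o], x$sensitivity[o], col = col, ...)
  } else {
    graphics::plot(fpr[o], x$sensitivity[o], type = "l", col = col,
                   xlab = "1 - specificity", ylab = "sensitivity",
                   xlim = c(0, 1), ylim = c(0, 1), ...)
    graphics::abline(0, 1, lty = 3, col = "grey")
  }
  invisible(x)
}

## ---- decile odds ratios ----------------------------------------------------

#' Decile odds ratios against the lowest score decile
#'
#' Cut points are the 10%..90% quantiles (type 7) of the score among
#' controls; every individual is binned into half-open intervals that
#' are right-closed, so a score tied with a boundary falls in the lower
#' decile. For each decile k = 2..10, the odds ratio versus decile 1 is
#' the 2x2 cross-product ratio with a Wald 95% confidence interval
#' exp(log OR +/- 1.96 sqrt(sum of reciprocal cell counts)).
#'
#' @param scores numeric scores.
#' @param labels binary labels (1/`"case"` = case).
#' @param conf_level confidence level.
#' @return A `data.frame` of class `"decile_or"`: per decile the score
#'   range, case/control counts, OR and CI (decile 1 is the reference,
#'   OR 1).
#' @export
decile_or <- function(scores, labels, conf_level = 0.95) {
  y <- to_binary(labels)
  check_two_classes(y)
  ctrl <- scores[y == 0]
  if (length(ctrl) < 10) stop("need at least 10 controls", call. = FALSE)
  cuts <- stats::quantile(ctrl, probs = seq(0.1, 0.9, by = 0.1), type = 7,
                          names = FALSE)
  dec <- cut(scores, breaks = c(-Inf, cuts, Inf), labels = FALSE,
             right = TRUE)
  n_case <- tabulate(dec[y == 1], 10)
  n_ctrl <- tabulate(dec[y == 0], 10)
  if (any(c(n_case[1], n_ctrl[1]) == 0)) {
    stop("empty cell in the reference decile; continuity corrections are ",
         "out of scope", call. = FALSE)
  }
  if (any(n_case == 0 | n_ctrl == 0)) {
    stop("zero cell in decile ", which(n_case == 0 | n_ctrl == 0)[1],
         "; continuity corrections are out of scope", call. = FALSE)
  }
  or <- (n_case * n_ctrl[1]) / (n_case[1] * n_ctrl)
  se <- sqrt(1 / n_case + 1 / n_ctrl + 1 / n_case[1] + 1 / n_ctrl[1])
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- data.frame(
    decile = 1:10,
    cut_low = c(-Inf, cuts), cut_high = c(cuts, Inf),
    n_case = n_case, n_control = n_ctrl,
    or = or,
    ci_low = exp(log(or) - zq * se),
    ci_high = exp(log(or) + zq * se)
  )
  out$or[1] <- 1
  out$ci_low[1] <- NA_real_
  out$ci_high[1] <- NA_real_
  class(out) <- c("decile_or", "data.frame")
  out
}

## ---- age-at-onset quartile analysis ---------------------------------------

#' Discrimination between early- and late-onset cases
#'
#' Cases are split at the quartiles of age-at-onset (type-7 quantiles);
#' only the lowest (AAO <= Q1 cut) and highest (AAO > Q3 cut) quartiles
#' are retained. Early-onset membership is regressed on the score plus
#' sex and PC1-PC3 (age at sampling excluded), and the score's ROC/AUC
#' for early vs late onset is computed.
#'
#' @param cohort a [cohort_table()]; only cases with a recorded
#'   age-at-onset are used.
#' @param scores a `prs_scores` object or a named numeric vector of
#'   standardized scores.
#' @return A list of class `"aao_analysis"`: `fit` (a `logistic_fit`),
#'   `roc`, `auc`, the quartile `cuts`, and `n_q1`, `n_q4`.
#' @export
aao_quartile_analysis <- function(cohort, scores) {
  stopifnot(inherits(cohort, "prs_cohort"))
  s <- score_vector(scores)
  cases <- cohort[cohort$status == "case" & !is.na(cohort$age_at_onset), ,
                  drop = FALSE]
  if (nrow(cases) < 8) {
    stop("need at least 8 cases with age-at-onset, got ", nrow(cases),
         call. = FALSE)
  }
  q <- stats::quantile(cases$age_at_onset, c(0.25, 0.75), type = 7,
                       names = FALSE)
  early <- cases$age_at_onset <= q[1]
  late <- cases$age_at_onset > q[2]
  sub <- cases[early | late, , drop = FALSE]
  outcome <- as.integer(sub$age_at_onset <= q[1])
  sv <- s[match(sub$id, names(s))]
  if (anyNA(sv)) stop("case without a score", call. = FALSE)
  covars <- data.frame(prs = sv, sex = as.integer(sub$sex == "M"),
                       PC1 = sub$PC1, PC2 = sub$PC2, PC3 = sub$PC3)
  fit <- fit_logistic(outcome, covars)
  ra <- roc_and_auc(sv, outcome)
  structure(list(fit = fit, roc = ra$roc, auc = ra$auc, cuts = q,
                 n_q1 = sum(early), n_q4 = sum(late)),
            class = "aao_analysis")
}

score_vector <- function(scores) {
  if (inherits(scores, "prs_scores")) {
    stats::setNames(scores$standardized, scores$id)
  } else {
    stopifnot(is.numeric(scores), !is.null(names(scores)))
    scores
  }
}

#' @export
print.aao_analysis <- function(x, ...) {
  cat(sprintf("Age-at-onset quartile analysis: Q1 (<= %.1f y, n = %d) vs Q4 (> %.1f y, n = %d)\n",
              x$cuts[1], x$n_q1, x$cuts[2], x$n_q4))
  print(x$auc)
  invisible(x)
}
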