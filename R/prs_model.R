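#' Fit a PRS evaluation model to a case-control cohort
#'
#' The one-stop fitting function of the package. Given a published
#' variant weight table, an allele-dosage panel and a phenotype cohort,
#' it
#' \enumerate{
#'   \item matches the score variants to the panel (position + allele
#'     set, MAF and info-score filters),
#'   \item computes the raw weighted-dosage score and standardizes it
#'     against the control distribution (control mean 0, SD 1),
#'   \item fits the case-control logistic regression of status on the
#'     standardized score adjusted for sex, age at sampling and PC1-PC3,
#'     together with the covariate-only and intercept-only reductions
#'     and their Nagelkerke pseudo-R-squared,
#'   \item computes the score's ROC curve and AUC with a DeLong 95%
#'     confidence interval,
#'   \item computes decile odds ratios against the lowest control
#'     decile, and
#'   \item when enough cases carry an age-at-onset, the early- vs
#'     late-onset quartile analysis (logistic fit without age, plus the
#'     score's Q1-vs-Q4 AUC).
#' }
#'
#' @param weights a [weight_table()].
#' @param panel a [dosage_panel()].
#' @param cohort a [cohort_table()]; IDs must be present in the panel.
#' @param maf_min,info_min variant filters passed to [match_variants()].
#' @param missing missing-dosage policy passed to [compute_prs()].
#' @return An object of class `"prs_model"` with components `match`,
#'   `scores`, `fit` (full logistic), `fit_covariates` (without the
#'   score), `fit_null` (intercept only), `r2` (pseudo-R2 with and
#'   without the score), `roc`, `auc`, `deciles`, `aao` (or `NULL`),
#'   `cohort`, and `call`. Supports `print()`, `summary()`, `coef()`,
#'   `predict()`, `plot()`, `residuals()` and `simulate()`.
#' @examples
#' study <- simulate_prs_study(sim_config(n_cases = 150, n_controls = 350,
#'                                        n_snps = 50, seed = 42))
#' fit <- prs_model(study$weights, study$panel, study$cohort)
#' fit
#' coef(fit)["prs"]
#' @export
prs_model <- function(weights, panel, cohort, maf_min = 0.01,
                      info_min = 0.7, missing = c("mean", "drop")) {
  stopifnot(inherits(weights, "prs_weights"),
            inherits(panel, "dosage_panel"),
            inherits(cohort, "prs_cohort"))
  missing <- match.arg(missing)
  idx <- match(cohort$id, panel$ids)
  if (anyNA(idx)) {
    stop("cohort individual ", cohort$id[is.na(idx)][1],
         " not present in the dosage panel", call. = FALSE)
  }

  match_rep <- match_variants(weights, panel, maf_min = maf_min,
                              info_min = info_min)
  attr(match_rep, "weights") <- weights
  raw <- compute_prs(panel, weights, match_rep, missing = missing,
                     controls = cohort$id[cohort$status == "control"])
  scores <- standardize_scores(raw, cohort)

  z <- scores$standardized[match(cohort$id, scores$id)]
  y <- as.integer(cohort$status == "case")
  covars <- data.frame(prs = z,
                       sex = as.integer(cohort$sex == "M"),
                       age_at_sampling = cohort$age_at_sampling,
                       PC1 = cohort$PC1, PC2 = cohort$PC2, PC3 = cohort$PC3)
  fit_full <- fit_logistic(y, covars)
  fit_cov <- fit_logistic(y, covars[setdiff(names(covars), "prs")])
  fit_null <- fit_logistic(y, NULL)
  r2 <- c(with_prs = nagelkerke_r2(fit_full, fit_null),
          without_prs = nagelkerke_r2(fit_cov, fit_null))

  ra <- roc_and_auc(z, y)
  deciles <- decile_or(z, y)
  aao <- NULL
  n_aao <- sum(cohort$status == "case" & !is.na(cohort$age_at_onset))
  if (n_aao >= 8) {
    aao <- aao_quartile_analysis(cohort, scores)
  }

  structure(list(
    match = match_rep, scores = scores,
    fit = fit_full, fit_covariates = fit_cov, fit_null = fit_null,
    r2 = r2, roc = ra$roc, auc = ra$auc, deciles = deciles, aao = aao,
    cohort = cohort, missing = missing, call = match.call()
  ), class = "prs_model")
}

#' @export
print.prs_model <- function(x, ...) {
  cat("PRS evaluation model\n")
  cat("  variants: ", sum(x$match$matched), " matched of ",
      nrow(x$match), " requested\n", sep = "")
  cat("  cohort:   ", sum(x$cohort$status == "case"), " cases / ",
      sum(x$cohort$status == "control"), " controls\n", sep = "")
  cat(sprintf("  AUC:      %.3f [%.3f, %.3f] (DeLong 95%% CI)\n",
              x$auc$auc, x$auc$ci_low, x$auc$ci_high))
  cat(sprintf("  per-SD log-OR: %.3f (Wald p = %.3g)\n",
              x$fit$coef[["prs"]], x$fit$p[["prs"]]))
  invisible(x)
}

#' @export
summary.prs_model <- function(object, ...) {
  x <- object
  out <- list(
    n = nrow(x$cohort),
    n_case = sum(x$cohort$status == "case"),
    n_control = sum(x$cohort$status == "control"),
    n_snps = sum(x$match$matched),
    auc = x$auc,
    r2 = x$r2,
    prs_coef = x$fit$coef[["prs"]],
    prs_se = x$fit$se[["prs"]],
    prs_p = x$fit$p[["prs"]],
    coefficients = data.frame(coef = x$fit$coef, se = x$fit$se,
                              z = x$fit$z, p = x$fit$p),
    deciles = x$deciles,
    aao = x$aao
  )
  class(out) <- "summary.prs_model"
  out
}

#' @export
print.summary.prs_model <- function(x, ...) {
  cat("PRS evaluation summary\n")
  cat(sprintf("  n = %d (%d cases, %d controls), %d score variants\n",
              x$n, x$n_case, x$n_control, x$n_snps))
  cat(sprintf("  AUC (case-control)      %.3f [%.3f, %.3f]\n",
              x$auc$auc, x$auc$ci_low, x$auc$ci_high))
  cat(sprintf("  Nagelkerke R2 with PRS  %.3f\n", x$r2[["with_prs"]]))
  cat(sprintf("  Nagelkerke R2 w/o PRS   %.3f\n", x$r2[["without_prs"]]))
  cat(sprintf("  PRS log-OR per SD       %.3f (SE %.3f, Wald p %.3g)\n",
              x$prs_coef, x$prs_se, x$prs_p))
  if (!is.null(x$aao)) {
    cat(sprintf("  AAO Q1-vs-Q4 AUC        %.3f [%.3f, %.3f]\n",
                x$aao$auc$auc, x$aao$auc$ci_low, x$aao$auc$ci_high))
  }
  or <- x$deciles
  cat(sprintf("  decile OR range         %.2f (2nd) .. %.2f (10th)\n",
              or$or[2], or$or[10]))
  invisible(x)
}

#' @export
coef.prs_model <- function(object, ...) object$fit$coef

#' Score new individuals with a fitted PRS model
#'
#' Applies the stored variant match and control-based standardization
#' parameters to a new dosage panel; with `type = "response"` and a
#' cohort, returns fitted disease probabilities from the logistic model.
#'
#' @param object a [prs_model()].
#' @param panel a new [dosage_panel()]; defaults to the training scores.
#' @param cohort covariates for `type = "response"`.
#' @param type `"score"` (standardized score), `"raw"`, or
#'   `"response"`.
#' @param ... unused.
#' @return Named numeric vector.
#' @export
predict.prs_model <- function(object, panel = NULL, cohort = NULL,
                              type = c("score", "raw", "response"), ...) {
  type <- match.arg(type)
  if (is.null(panel)) {
    raw <- stats::setNames(object$scores$raw, object$scores$id)
  } else {
    raw <- compute_prs(panel, weights_from_match(object), missing = object$missing)
  }
  if (type == "raw") return(raw)
  z <- stats::setNames(apply_standardization(raw, object$scores), names(raw))
  if (type == "score") return(z)
  if (is.null(cohort)) cohort <- object$cohort
  cf <- object$fit$coef
  idx <- match(names(z), cohort$id)
  if (anyNA(idx)) stop("individual without covariates", call. = FALSE)
  eta <- cf[["(Intercept)"]] + cf[["prs"]] * z +
    cf[["sex"]] * (cohort$sex[idx] == "M") +
    cf[["age_at_sampling"]] * cohort$age_at_sampling[idx] +
    cf[["PC1"]] * cohort$PC1[idx] + cf[["PC2"]] * cohort$PC2[idx] +
    cf[["PC3"]] * cohort$PC3[idx]
  stats::setNames(stats::plogis(eta), names(z))
}

# the model keeps its weight table reachable through the call; store it
# explicitly instead so prediction does not rely on the caller's frame
weights_from_match <- function(object) {
  attr(object$match, "weights")
}

#' @export
residuals.prs_model <- function(object, type = "deviance", ...) {
  stats::residuals(object$fit$glm, type = type)
}

#' Simulate case-control status from the fitted model
#'
#' Draws Bernoulli status vectors from the fitted per-individual disease
#' probabilities of the full logistic model.
#'
#' @param object a [prs_model()].
#' @param nsim number of replicate status vectors.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return A `data.frame` with `nsim` columns of 0/1 status draws.
#' @export
simulate.prs_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- object$fit$fitted
  out <- as.data.frame(replicate(nsim, stats::rbinom(length(p), 1L, p)))
  names(out) <- paste0("sim_", seq_len(nsim))
  rownames(out) <- object$cohort$id
  out
}

#' @export
plot.prs_model <- function(x, which = c("roc", "density"), ...) {
  which <- match.arg(which)
  if (which == "roc") {
    plot(x$roc, main = sprintf("AUC %.3f [%.3f, %.3f]", x$auc$auc,
                               x$auc$ci_low, x$auc$ci_high), ...)
  } else {
    z <- x$scores$standardized[match(x$cohort$id, x$scores$id)]
    is_case <- x$cohort$status == "case"
    dc <- stats::density(z[is_case]); dk <- stats::density(z[!is_case])
    graphics::plot(dk, col = "steelblue", main = "standardized PRS",
                   xlab = "PRS (control SD units)",
                   ylim = range(dc$y, dk$y), ...)
    graphics::lines(dc, col = "firebrick")
    graphics::legend("topright", c("controls", "cases"), bty = "n",
                     col = c("steelblue", "firebrick"), lty = 1)
  }
  invisible(x)
}
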