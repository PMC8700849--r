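#' Optimal threshold under a weighted Youden index
#'
#' Selects the ROC curve point maximizing `costs * sensitivity +
#' specificity`, where `costs` is the relative severity of a false
#' negative compared to a false positive. At `costs = 1` this is the
#' classic Youden point (the additive constant does not move the
#' argmax). Exact ties are broken towards higher sensitivity, i.e. the
#' lower threshold.
#'
#' @param roc a [roc_curve()].
#' @param costs weight of sensitivity, >= 1.
#' @return A list `threshold`, `sensitivity`, `specificity`,
#'   `objective`.
#' @export
weighted_youden_threshold <- function(roc, costs = 1) {
  stopifnot(inherits(roc, "roc_curve"))
  if (!nrow(roc)) stop("empty ROC curve", call. = FALSE)
  if (!is.finite(costs) || costs < 1) {
    stop("costs must be a finite weight >= 1", call. = FALSE)
  }
  obj <- costs * roc$sensitivity + roc$specificity
  # rows are ordered by increasing threshold (decreasing sensitivity),
  # so the first maximum is the highest-sensitivity tie
  i <- which.max(obj)
  list(threshold = roc$threshold[i],
       sensitivity = roc$sensitivity[i],
       specificity = roc$specificity[i],
       objective = obj[i])
}

#' Weighted Youden thresholds over a grid of cost values
#'
#' Evaluates [weighted_youden_threshold()] at every grid value
#' `c_min + i * step` (endpoints inclusive; grid values built by
#' integer indexing to avoid floating-point drift over the default
#' 40001 points). Sensitivity must be non-decreasing and specificity
#' non-increasing in the costs; this monotonicity is checked on the
#' result.
#'
#' @param roc a [roc_curve()].
#' @param c_min,c_max,step grid limits and spacing (defaults 1, 5,
#'   0.0001).
#' @return A `data.frame` of class `"cost_grid"`: `costs`, `threshold`,
#'   `sensitivity`, `specificity`, `objective`.
#' @export
cost_grid <- function(roc, c_min = 1, c_max = 5, step = 1e-4) {
  stopifnot(inherits(roc, "roc_curve"))
  if (step <= 0) stop("step must be positive", call. = FALSE)
  n <- floor(round((c_max - c_min) / step, 8))
  costs <- c_min + (0:n) * step
  sens <- roc$sensitivity
  spec <- roc$specificity
  idx <- integer(length(costs))
  for (i in seq_along(costs)) {
    idx[i] <- which.max(costs[i] * sens + spec)
  }
  out <- data.frame(costs = costs,
                    threshold = roc$threshold[idx],
                    sensitivity = sens[idx],
                    specificity = spec[idx],
                    objective = costs * sens[idx] + spec[idx])
  if (is.unsorted(out$sensitivity) ||
      is.unsorted(rev(out$specificity))) {
    stop("internal error: cost grid violates monotonicity", call. = FALSE)
  }
  class(out) <- c("cost_grid", "data.frame")
  out
}

#' Residual lifetime incidence from a life table
#'
#' For an individual who is disease-free at the start of interval
#' \[d, d+4\], the probability of developing the disease before death is
#' accumulated over the remaining 5-year intervals: each later
#' interval's incidence is discounted by all earlier interval survival
#' probabilities `S = (1 - D)^5` (D the annual death rate) and all
#' earlier disease-free probabilities `(1 - I)`. The open-ended last
#' interval \[95+\] contributes its incidence once, with no further
#' survival weighting. Implemented as the backward recursion
#' `R_k = I_k + S_k (1 - I_k) R_{k+1}`, `R_10 = I_10`, which telescopes
#' into the direct sum.
#'
#' @param table a [life_table()].
#' @return A `data.frame` of class `"residual_incidence"`: per starting
#'   interval the `incidence`, `death_rate`, 5-year `survival` factor
#'   and the `residual` lifetime incidence.
#' @export
residual_lifetime_incidence <- function(table) {
  if (!inherits(table, "life_table")) table <- validate_life_table_frame(table)
  I <- table$incidence
  S <- (1 - table$death_rate)^5
  k <- length(I)
  R <- numeric(k)
  R[k] <- I[k]
  for (i in (k - 1):1) R[i] <- I[i] + S[i] * (1 - I[i]) * R[i + 1]
  out <- data.frame(interval = table$interval,
                    age_start = table$age_start,
                    incidence = I, death_rate = table$death_rate,
                    survival = S, residual = R)
  class(out) <- c("residual_incidence", "data.frame")
  out
}

#' Positive and negative predictive values by Bayes' formula
#'
#' `ppv = sens p / (sens p + (1 - spec)(1 - p))` and
#' `npv = spec (1 - p) / (spec (1 - p) + (1 - sens) p)`, where `p` is
#' the pre-test probability of disease — here the residual lifetime
#' incidence of the individual's age group rather than a cross-sectional
#' prevalence. A degenerate 0/0 denominator yields `NA` (undefined),
#' not 0.
#'
#' @param sensitivity,specificity test characteristics in \[0, 1\].
#' @param incidence pre-test disease probability (vectorized).
#' @return A `data.frame` with columns `incidence`, `ppv`, `npv`.
#' @export
predictive_values <- function(sensitivity, specificity, incidence) {
  args <- c(sensitivity = sensitivity, specificity = specificity)
  if (any(!is.finite(args)) || any(args < 0) || any(args > 1)) {
    stop("sensitivity and specificity must lie in [0, 1]", call. = FALSE)
  }
  if (any(!is.finite(incidence)) || any(incidence < 0) || any(incidence > 1)) {
    stop("incidence must lie in [0, 1]", call. = FALSE)
  }
  p <- as.numeric(incidence)
  ppv_num <- sensitivity * p
  ppv_den <- ppv_num + (1 - specificity) * (1 - p)
  npv_num <- specificity * (1 - p)
  npv_den <- npv_num + (1 - sensitivity) * p
  ppv <- ifelse(ppv_den > 0, ppv_num / ppv_den, NA_real_)
  npv <- ifelse(npv_den > 0, npv_num / npv_den, NA_real_)
  if (anyNA(c(ppv, npv))) {
    warning("predictive value undefined (0/0 denominator)", call. = FALSE)
  }
  data.frame(incidence = p, ppv = ppv, npv = npv)
}

#' Age- and cost-specific predictive values of a score threshold
#'
#' Combines the operating points of a cost grid (at selected cost
#' levels) with the residual lifetime incidence of each age group: for
#' every age group x cost level cell, the ppv and npv from Bayes'
#' formula with the age group's residual lifetime incidence as the
#' pre-test probability.
#'
#' @param grid a [cost_grid()].
#' @param residual a [residual_lifetime_incidence()] result.
#' @param costs cost levels to report (default integers 1..5); each must
#'   be present in the grid.
#' @return A `data.frame` of class `"prognosis_table"` in long format:
#'   `age_group`, `costs`, `sensitivity`, `specificity`, `residual`,
#'   `ppv`, `npv`.
#' @export
prognosis_report <- function(grid, residual, costs = 1:5) {
  stopifnot(inherits(grid, "cost_grid"),
            inherits(residual, "residual_incidence"))
  rows <- vapply(costs, function(cc) {
    i <- which(abs(grid$costs - cc) < 1e-9)
    if (!length(i)) stop("cost level ", cc, " not on the grid",
                         call. = FALSE)
    i[1]
  }, integer(1))
  out <- do.call(rbind, lapply(seq_along(costs), function(k) {
    i <- rows[k]
    pv <- predictive_values(grid$sensitivity[i], grid$specificity[i],
                            residual$residual)
    data.frame(age_group = residual$interval,
               costs = costs[k],
               sensitivity = grid$sensitivity[i],
               specificity = grid$specificity[i],
               residual = residual$residual,
               ppv = pv$ppv, npv = pv$npv,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("prognosis_table", "data.frame")
  out
}

#' @export
print.prognosis_table <- function(x, digits = 3, ...) {
  cat("Predictive values by age group and cost level\n")
  wide <- stats::reshape(
    as.data.frame(x)[c("age_group", "costs", "ppv", "npv")],
    idvar = "age_group", timevar = "costs", direction = "wide")
  print(format(wide, digits = digits), row.names = FALSE)
  invisible(x)
}
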