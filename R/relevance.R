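# per-variant score contributions: n x m matrix with column j equal to
# weight_j * oriented dosage_j (mean-imputed), so that the full raw
# score is rowSums and any sub-score is a row sum over a column subset
contribution_matrix <- function(panel, weights, match = NULL,
                                missing = "mean", controls = NULL) {
  if (is.null(match)) match <- match_variants(weights, panel)
  eff <- effect_dosages(panel, weights, match)
  d <- eff$dosages
  if (anyNA(d)) {
    if (missing == "mean") {
      rows <- if (is.null(controls)) seq_len(nrow(d)) else
        which(panel$ids %in% controls)
      freq <- colMeans(d[rows, , drop = FALSE], na.rm = TRUE) / 2
      for (j in which(colSums(is.na(d)) > 0)) d[is.na(d[, j]), j] <- 2 * freq[j]
    } else {
      d[is.na(d)] <- 0
    }
  }
  contrib <- sweep(d, 2, eff$weights, `*`)
  key <- paste(panel$variants$chrom, panel$variants$pos,
               sep = ":")[match$panel_col[eff$keep]]
  colnames(contrib) <- key
  list(contrib = contrib, key = key,
       chrom = panel$variants$chrom[match$panel_col[eff$keep]],
       pos = panel$variants$pos[match$panel_col[eff$keep]])
}

#' Leave-one-out AUC per score variant ("AUC-SNP" values)
#'
#' For each variant j in the active set, the AUC of the score computed
#' without j. Sub-scores are row sums over a precomputed per-variant
#' contribution matrix (weight times oriented, mean-imputed dosage), so
#' no re-matching or re-orientation happens per candidate; summing the
#' retained columns afresh (rather than subtracting j's contribution
#' from the total) keeps exact score ties exact, so the AUC equals
#' full rescoring bit for bit. An explicit-rescoring oracle verifies
#' this in the test suite.
#'
#' @param panel a [dosage_panel()].
#' @param weights a [weight_table()].
#' @param labels binary labels aligned with the panel's individuals.
#' @param active_set optional character vector of `chrom:pos` keys (or
#'   integer indices into the matched set); defaults to all matched
#'   variants.
#' @param match optional precomputed [match_variants()] report.
#' @return Named numeric vector of leave-one-out AUCs, one per active
#'   variant, names `chrom:pos`.
#' @export
leave_one_out_auc <- function(panel, weights, labels, active_set = NULL,
                              match = NULL) {
  y <- to_binary(labels)
  check_two_classes(y)
  cm <- contribution_matrix(panel, weights, match)
  act <- resolve_active(cm$key, active_set)
  out <- vapply(act, function(j) {
    auc_delong(rowSums(cm$contrib[, setdiff(act, j), drop = FALSE]), y)$auc
  }, numeric(1))
  names(out) <- cm$key[act]
  out
}

resolve_active <- function(key, active_set) {
  if (is.null(active_set)) return(seq_along(key))
  if (is.character(active_set)) {
    idx <- match(active_set, key)
    if (anyNA(idx)) stop("unknown variant key: ",
                         active_set[is.na(idx)][1], call. = FALSE)
    idx
  } else {
    as.integer(active_set)
  }
}

#' Greedy backward elimination of score variants by AUC decline
#'
#' Starting from all matched variants, repeatedly removes the variant
#' whose exclusion lowers the residual score's AUC the most (steepest
#' decline), recomputing the candidate AUCs over the remaining set at
#' every step, until the DeLong 95% confidence interval of the residual
#' AUC first includes 0.5. The removed variants, in order, are the
#' "most relevant" set. Ties in the steepest decline are broken by
#' genomic (chromosome, position) order so reruns are identical. If the
#' interval never includes 0.5, elimination stops with a single variant
#' left and the result is flagged `exhausted`.
#'
#' @param panel a [dosage_panel()].
#' @param weights a [weight_table()].
#' @param labels binary labels aligned with the panel's individuals.
#' @param alpha significance level of the stopping interval (0.05 gives
#'   the 95% CI).
#' @param max_removals optional cap on the number of eliminations.
#' @param recompute if `TRUE` (default) candidate AUCs are recomputed
#'   over the remaining set each iteration (full greedy); if `FALSE`
#'   the initial leave-one-out ranking is reused (static ranking).
#' @param match optional precomputed [match_variants()] report.
#' @return A list of class `"prs_relevance"`: `removed` (data.frame in
#'   removal order with the residual AUC and CI after each step),
#'   `loo_auc` (initial leave-one-out AUC per variant), `full_auc`
#'   (AUC of the complete score), `stopped` (CI included 0.5),
#'   `exhausted`, `alpha`, `key`, `chrom`, `pos`.
#' @export
greedy_auc_elimination <- function(panel, weights, labels, alpha = 0.05,
                                   max_removals = Inf, recompute = TRUE,
                                   match = NULL) {
  y <- to_binary(labels)
  check_two_classes(y)
  cm <- contribution_matrix(panel, weights, match)
  m <- length(cm$key)
  if (m < 1) stop("no matched variants", call. = FALSE)
  ord <- genomic_order(cm$chrom, cm$pos)  # genomic order for tie-breaks
  contrib <- cm$contrib[, ord, drop = FALSE]
  key <- cm$key[ord]; chrom <- cm$chrom[ord]; pos <- cm$pos[ord]

  conf <- 1 - alpha
  # exact subset scores: summing retained columns afresh preserves score
  # ties exactly, so results match explicit rescoring bit for bit
  sub_score <- function(idx) rowSums(contrib[, idx, drop = FALSE])
  full <- auc_delong(sub_score(seq_len(m)), y, conf_level = conf)
  loo0 <- vapply(seq_len(m), function(j)
    auc_delong(sub_score(setdiff(seq_len(m), j)), y)$auc, numeric(1))
  names(loo0) <- key

  removed <- integer(0)
  res_auc <- numeric(0); res_lo <- numeric(0); res_hi <- numeric(0)
  stopped <- includes_half(full)
  exhausted <- FALSE
  active <- seq_len(m)
  cand <- loo0                            # candidate AUCs over active set

  while (!stopped && length(removed) < max_removals) {
    if (length(active) == 1L) { exhausted <- TRUE; break }
    j <- active[which.min(cand[active])]  # first minimum = genomic order
    active <- setdiff(active, j)
    a <- auc_delong(sub_score(active), y, conf_level = conf)
    removed <- c(removed, j)
    res_auc <- c(res_auc, a$auc)
    res_lo <- c(res_lo, a$ci_low); res_hi <- c(res_hi, a$ci_high)
    if (includes_half(a)) { stopped <- TRUE; break }
    if (recompute) {
      cand[active] <- vapply(active, function(k)
        auc_delong(sub_score(setdiff(active, k)), y)$auc, numeric(1))
    }
  }
  if (!stopped && length(active) == 1L) exhausted <- TRUE
  if (exhausted) {
    warning("residual AUC confidence interval never included 0.5; ",
            "stopped with one variant left", call. = FALSE)
  }

  structure(list(
    removed = data.frame(
      step = seq_along(removed),
      chrom = chrom[removed], pos = pos[removed], key = key[removed],
      residual_auc = res_auc, ci_low = res_lo, ci_high = res_hi,
      stringsAsFactors = FALSE),
    loo_auc = loo0, full_auc = full,
    stopped = stopped, exhausted = exhausted, alpha = alpha,
    key = key, chrom = chrom, pos = pos
  ), class = "prs_relevance")
}

# numeric chromosomes sort numerically, then X/Y/MT etc. lexically
genomic_order <- function(chrom, pos) {
  num <- suppressWarnings(as.numeric(chrom))
  order(is.na(num), num, chrom, pos)
}

includes_half <- function(a) {
  is.finite(a$ci_low) && is.finite(a$ci_high) &&
    a$ci_low <= 0.5 && a$ci_high >= 0.5
}

#' @export
print.prs_relevance <- function(x, ...) {
  cat("Greedy AUC-based variant elimination\n")
  cat(sprintf("  full-score AUC %.4f [%.4f, %.4f]\n",
              x$full_auc$auc, x$full_auc$ci_low, x$full_auc$ci_high))
  cat("  most relevant variants removed:", nrow(x$removed),
      "of", length(x$key), "\n")
  if (x$exhausted) cat("  (stopping interval never included 0.5)\n")
  invisible(x)
}

#' Rank variants by leave-one-out AUC with relevance classes
#'
#' Variants are sorted ascending by their leave-one-out AUC (a low
#' value means removing the variant hurts discrimination most) and
#' labelled by a four-way class combining membership in the greedy
#' most-relevant set with an external genome-wide-significance
#' annotation: `"both"`, `"gs_only"`, `"most_relevant_only"`,
#' `"neither"`.
#'
#' @param result a [greedy_auc_elimination()] result.
#' @param gs_keys optional character vector of `chrom:pos` keys flagged
#'   genome-wide significant.
#' @return A `data.frame` of class `"relevance_ranking"`: `rank`, `key`,
#'   `chrom`, `pos`, `auc_snp`, `most_relevant`, `gs`, `class`, with a
#'   `counts` attribute giving the per-class totals.
#' @export
rank_table <- function(result, gs_keys = NULL) {
  stopifnot(inherits(result, "prs_relevance"))
  mr <- result$key %in% result$removed$key
  gs <- if (is.null(gs_keys)) rep(FALSE, length(result$key)) else
    result$key %in% gs_keys
  cls <- ifelse(mr & gs, "both",
         ifelse(gs, "gs_only",
         ifelse(mr, "most_relevant_only", "neither")))
  o <- order(result$loo_auc, result$chrom, result$pos)
  out <- data.frame(
    rank = seq_along(o),
    key = result$key[o], chrom = result$chrom[o], pos = result$pos[o],
    auc_snp = unname(result$loo_auc[o]),
    most_relevant = mr[o], gs = gs[o], class = cls[o],
    stringsAsFactors = FALSE
  )
  counts <- table(factor(cls, levels = c("both", "gs_only",
                                         "most_relevant_only", "neither")))
  attr(out, "counts") <- counts
  class(out) <- c("relevance_ranking", "data.frame")
  out
}

#' @export
plot.relevance_ranking <- function(x, ...) {
  cols <- c(both = "black", gs_only = "blue",
            most_relevant_only = "red", neither = "goldenrod")
  graphics::plot(x$rank, x$auc_snp, col = cols[x$class], pch = 20,
                 xlab = "rank by leave-one-out AUC",
                 ylab = "AUC without the variant", ...)
  graphics::legend("bottomright", legend = names(cols), col = cols,
                   pch = 20, bty = "n", cex = 0.8)
  invisible(x)
}
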