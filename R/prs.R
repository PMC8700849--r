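#' Match score variants to a dosage panel
#'
#' A weight-table variant matches iff its (chromosome, position) key is
#' present in the panel, its allele pair equals the panel's \{ref, alt\}
#' as a set, and it passes the minor-allele-frequency filter (and the
#' imputation info-score filter when the panel carries an `info` column).
#' The report records, per matched variant, whether the effect allele is
#' the panel alt allele (orientation `"alt"`, dosage used as is) or the
#' panel ref allele (orientation `"ref"`, dosage used as `2 - d`).
#' Strand-ambiguous pairs (A/T, C/G) are matched as-is with a warning;
#' no frequency-based strand flipping is attempted.
#'
#' @param weights a [weight_table()].
#' @param panel a [dosage_panel()].
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param info_min minimum info score, applied only when the panel has an
#'   `info` column (default 0.7).
#' @return A `data.frame` of class `"match_report"`, one row per
#'   requested variant, with columns `chrom`, `pos`, `matched`, `reason`
#'   (`matched` | `absent` | `allele-mismatch` | `maf-filtered` |
#'   `info-filtered`), `orientation` (`alt`/`ref`/`NA`) and `panel_col`
#'   (column index into the panel's dosage matrix).
#' @export
match_variants <- function(weights, panel, maf_min = 0.01, info_min = 0.7) {
  stopifnot(inherits(weights, "prs_weights"), inherits(panel, "dosage_panel"))
  wkey <- paste(weights$chrom, weights$pos, sep = ":")
  pkey <- paste(panel$variants$chrom, panel$variants$pos, sep = ":")
  idx <- match(wkey, pkey)

  n <- nrow(weights)
  reason <- rep("matched", n)
  orientation <- rep(NA_character_, n)

  absent <- is.na(idx)
  reason[absent] <- "absent"

  ok <- !absent
  pref <- panel$variants$ref[idx]
  palt <- panel$variants$alt[idx]
  same_set <- ok &
    ((weights$effect_allele == palt & weights$other_allele == pref) |
     (weights$effect_allele == pref & weights$other_allele == palt))
  reason[ok & !same_set] <- "allele-mismatch"

  maf <- pmin(panel$variants$af[idx], 1 - panel$variants$af[idx])
  low_maf <- same_set & !is.na(maf) & maf < maf_min
  reason[low_maf] <- "maf-filtered"

  if ("info" %in% names(panel$variants)) {
    info <- panel$variants$info[idx]
    low_info <- same_set & !low_maf & !is.na(info) & info < info_min
    reason[low_info] <- "info-filtered"
  }

  matched <- reason == "matched"
  orientation[matched] <- ifelse(weights$effect_allele[matched] == palt[matched],
                                 "alt", "ref")

  ambig <- matched &
    paste0(pmin(weights$effect_allele, weights$other_allele),
           pmax(weights$effect_allele, weights$other_allele)) %in% c("AT", "CG")
  if (any(ambig)) {
    warning(sum(ambig), " strand-ambiguous (A/T or C/G) variant(s) matched ",
            "as-is; no strand flipping attempted", call. = FALSE)
  }

  out <- data.frame(
    chrom = weights$chrom, pos = weights$pos,
    matched = matched, reason = reason, orientation = orientation,
    panel_col = ifelse(matched, idx, NA_integer_),
    stringsAsFactors = FALSE
  )
  class(out) <- c("match_report", "data.frame")
  out
}

#' @export
print.match_report <- function(x, ...) {
  cat("Variant matching:", nrow(x), "requested,", sum(x$matched),
      "matched,", sum(!x$matched), "omitted\n")
  if (any(!x$matched)) {
    tab <- table(x$reason[!x$matched])
    for (r in names(tab)) cat("  ", r, ": ", tab[[r]], "\n", sep = "")
  }
  invisible(x)
}

# oriented effect-allele dosage matrix (n x m_matched) and the aligned
# weight vector; missing dosages are left NA here
effect_dosages <- function(panel, weights, match = NULL) {
  if (is.null(match)) match <- match_variants(weights, panel, maf_min = 0)
  keep <- which(match$matched)
  if (!length(keep)) stop("zero matched variants", call. = FALSE)
  d <- panel$dosages[, match$panel_col[keep], drop = FALSE]
  flip <- match$orientation[keep] == "ref"
  if (any(flip)) d[, flip] <- 2 - d[, flip, drop = FALSE]
  list(dosages = d, weights = weights$weight[keep], keep = keep)
}

#' Compute raw polygenic risk scores
#'
#' The raw score of an individual is the sum over matched variants of
#' the per-allele weight times the effect-allele dosage (the panel
#' dosage when the effect allele is the panel alt allele, `2 - dosage`
#' when it is the ref allele).
#'
#' Missing dosages are handled by the `missing` policy: `"mean"`
#' (default) substitutes twice the effect-allele frequency observed in
#' the panel's non-missing dosages — restricted to the individuals named
#' in `controls` when given — and `"drop"` omits the variant from that
#' individual's sum.
#'
#' @param panel a [dosage_panel()].
#' @param weights a [weight_table()].
#' @param match a [match_variants()] report derived from these inputs;
#'   computed with default filters when omitted.
#' @param missing `"mean"` or `"drop"`.
#' @param controls optional IDs of control individuals used for the
#'   mean-imputation frequency.
#' @return Named numeric vector of raw scores, one per panel individual.
#' @export
compute_prs <- function(panel, weights, match = NULL,
                        missing = c("mean", "drop"), controls = NULL) {
  missing <- match.arg(missing)
  if (is.null(match)) match <- match_variants(weights, panel)
  eff <- effect_dosages(panel, weights, match)
  d <- eff$dosages
  if (anyNA(d)) {
    if (missing == "mean") {
      rows <- if (is.null(controls)) seq_len(nrow(d)) else
        which(panel$ids %in% controls)
      freq <- colMeans(d[rows, , drop = FALSE], na.rm = TRUE) / 2
      for (j in which(colSums(is.na(d)) > 0)) {
        d[is.na(d[, j]), j] <- 2 * freq[j]
      }
    } else {
      d[is.na(d)] <- 0
    }
  }
  scores <- as.numeric(d %*% eff$weights)
  names(scores) <- panel$ids
  scores
}

#' Standardize raw scores against the control distribution
#'
#' Subtracts the control mean and divides by the control standard
#' deviation (sample convention, denominator n - 1). The parameters are
#' stored so the same transformation can be applied to new individuals
#' via [apply_standardization()].
#'
#' @param raw named numeric vector of raw scores (names = individual IDs).
#' @param cohort a [cohort_table()] giving case/control status.
#' @return A `data.frame` of class `"prs_scores"` with columns `id`,
#'   `raw`, `standardized`, carrying attributes `center` and `scale`.
#' @export
standardize_scores <- function(raw, cohort) {
  stopifnot(inherits(cohort, "prs_cohort"))
  idx <- match(cohort$id, names(raw))
  if (anyNA(idx)) {
    stop("cohort individual ", cohort$id[is.na(idx)][1],
         " has no score", call. = FALSE)
  }
  ctrl <- raw[idx[cohort$status == "control"]]
  if (length(ctrl) < 2) stop("need at least 2 controls", call. = FALSE)
  s <- stats::sd(ctrl)
  if (s == 0) stop("control scores have zero standard deviation",
                   call. = FALSE)
  m <- mean(ctrl)
  out <- data.frame(id = names(raw), raw = as.numeric(raw),
                    standardized = (as.numeric(raw) - m) / s,
                    stringsAsFactors = FALSE)
  attr(out, "center") <- m
  attr(out, "scale") <- s
  class(out) <- c("prs_scores", "data.frame")
  out
}

#' @rdname standardize_scores
#' @param scores a `prs_scores` object holding stored parameters.
#' @export
apply_standardization <- function(raw, scores) {
  (as.numeric(raw) - attr(scores, "center")) / attr(scores, "scale")
}
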