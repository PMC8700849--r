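# independent oracles used across the suite; all deliberately naive

# AUC by exhaustive case-control pair counting, ties worth one half
auc_pairs <- function(scores, labels) {
  xc <- scores[labels == 1]
  xk <- scores[labels == 0]
  cmp <- outer(xc, xk, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# residual lifetime incidence by direct evaluation of the telescoping
# sum: each interval's incidence times all earlier survival factors and
# all earlier disease-free factors
residual_direct <- function(incidence, death_rate) {
  S <- (1 - death_rate)^5
  k <- length(incidence)
  vapply(seq_len(k), function(d) {
    total <- 0
    for (j in d:k) {
      term <- incidence[j]
      if (j > d) {
        term <- term * prod(S[d:(j - 1)]) * prod(1 - incidence[d:(j - 1)])
      }
      total <- total + term
    }
    total
  }, numeric(1))
}

# naive rescoring of a weight subset against a panel, one variant at a
# time, no shared code with the package's contribution decomposition
rescore_naive <- function(wtab, panel) {
  s <- rep(0, length(panel$ids))
  for (i in seq_len(nrow(wtab))) {
    k <- which(panel$variants$chrom == wtab$chrom[i] &
                 panel$variants$pos == wtab$pos[i])
    d <- panel$dosages[, k]
    if (wtab$effect_allele[i] == panel$variants$ref[k]) d <- 2 - d
    s <- s + wtab$weight[i] * d
  }
  s
}

proc_auc_ci <- function(scores, labels) {
  r <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
  ci <- suppressWarnings(pROC::ci.auc(r, method = "delong"))
  c(auc = as.numeric(pROC::auc(r)), lo = ci[1], hi = ci[3])
}

# full greedy backward elimination by explicit rescoring, stopping when
# the DeLong 95% CI of the residual AUC includes 0.5 (pROC machinery)
greedy_naive <- function(wtab, panel, labels) {
  active <- seq_len(nrow(wtab))
  ord <- order(is.na(suppressWarnings(as.numeric(wtab$chrom))),
               suppressWarnings(as.numeric(wtab$chrom)),
               wtab$chrom, wtab$pos)
  active <- ord
  removed <- integer(0)
  full <- proc_auc_ci(rescore_naive(wtab, panel), labels)
  if (full["lo"] <= 0.5 && full["hi"] >= 0.5) {
    return(list(removed = integer(0), exhausted = FALSE))
  }
  repeat {
    if (length(active) == 1L) {
      return(list(removed = removed, exhausted = TRUE))
    }
    cand <- vapply(active, function(j) {
      proc_auc_ci(rescore_naive(wtab[setdiff(active, j), , drop = FALSE],
                                panel), labels)["auc"]
    }, numeric(1))
    j <- active[which.min(cand)]
    active <- setdiff(active, j)
    removed <- c(removed, j)
    ci <- proc_auc_ci(rescore_naive(wtab[active, , drop = FALSE], panel),
                      labels)
    if (ci["lo"] <= 0.5 && ci["hi"] >= 0.5) {
      return(list(removed = removed, exhausted = FALSE))
    }
  }
}

# small random study instance for property tests
random_instance <- function(n_snps, n_ind, seed, effect_sd = 0.3) {
  set.seed(seed)
  mafs <- runif(n_snps, 0.1, 0.5)
  panel <- generate_genotypes(mafs, n_ind, seed = seed + 1)
  wtab <- weight_table(panel$variants$chrom, panel$variants$pos,
                       panel$variants$alt, panel$variants$ref,
                       rnorm(n_snps, 0, effect_sd))
  z <- rescore_naive(wtab, panel)
  z <- (z - mean(z)) / max(sd(z), 1e-12)
  y <- rbinom(n_ind, 1, plogis(0.8 * z))
  list(panel = panel, weights = wtab, labels = y)
}
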