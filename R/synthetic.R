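#' Configuration for the synthetic PRS study generator
#'
#' Bundles every tunable of the generator. The defaults reproduce the
#' shape and discrimination level of a typical single-disease PRS
#' validation study: 1914 cases, 4464 controls, a 1743-variant score, a
#' per-SD log-odds ratio of 0.57 for the true standardized score (which
#' yields a case-control AUC of about 0.65 under case-control sampling),
#' and an age-at-onset that decreases by 1.3 years per PRS standard
#' deviation (Q1-vs-Q4 onset-quartile AUC of about 0.59).
#'
#' @param n_cases,n_controls target numbers of cases and controls.
#' @param n_snps number of score variants.
#' @param maf_range range the per-variant minor allele frequencies are
#'   drawn from, within (0, 0.5].
#' @param effect_mean,effect_sd mean and SD of the per-variant log-odds
#'   weights.
#' @param large_frac fraction of variants given a "large" effect.
#' @param large_mult SD multiplier for the large-effect variants.
#' @param intercept baseline log-odds of disease at reference covariates.
#' @param prs_beta log-odds ratio per standard deviation of the true PRS.
#' @param sex_effect additional log-odds for males.
#' @param age_effect log-odds per year of age at sampling (centred at the
#'   midpoint of `age_range`).
#' @param age_range sampling-age range, years (uniform).
#' @param aao_mean,aao_sd mean and SD of case age-at-onset, years.
#' @param aao_prs_slope change in mean age-at-onset per PRS standard
#'   deviation, years (negative: high-score cases have earlier onset).
#' @param seed integer master seed; per-stage child seeds are derived
#'   from it so stages can be regenerated independently.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_cases = 1914L, n_controls = 4464L,
                       n_snps = 1743L, maf_range = c(0.05, 0.5),
                       effect_mean = 0, effect_sd = 0.02,
                       large_frac = 0.02, large_mult = 5,
                       intercept = stats::qlogis(0.25), prs_beta = 0.57,
                       sex_effect = 0.35, age_effect = 0.02,
                       age_range = c(40, 80),
                       aao_mean = 62, aao_sd = 10, aao_prs_slope = -1.3,
                       seed = 1L) {
  cfg <- list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    n_snps = as.integer(n_snps), maf_range = as.numeric(maf_range),
    effect_mean = effect_mean, effect_sd = effect_sd,
    large_frac = large_frac, large_mult = large_mult,
    intercept = intercept, prs_beta = prs_beta,
    sex_effect = sex_effect, age_effect = age_effect,
    age_range = as.numeric(age_range),
    aao_mean = aao_mean, aao_sd = aao_sd, aao_prs_slope = aao_prs_slope,
    seed = as.integer(seed)
  )
  with(cfg, {
    stopifnot(n_cases > 0, n_controls > 0, n_snps > 0,
              length(maf_range) == 2, maf_range[1] > 0,
              maf_range[2] <= 0.5, maf_range[1] <= maf_range[2],
              effect_sd >= 0, large_frac >= 0, large_frac <= 1,
              aao_sd >= 0, age_range[1] < age_range[2])
  })
  class(cfg) <- "sim_config"
  cfg
}

# deterministic fan-out of a master seed into per-stage child seeds,
# kept below 2^31 so they are valid R integer seeds
child_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate Hardy-Weinberg genotype dosages
#'
#' Each dosage is the sum of two independent allele draws with success
#' probability equal to the variant's alt-allele frequency, i.e. genotype
#' counts follow Hardy-Weinberg proportions. Optionally, light uniform
#' noise can be added and clipped to \[0, 2\] to emulate fractional
#' imputed dosages.
#'
#' @param mafs vector of alt-allele frequencies, each in (0, 0.5].
#' @param n_individuals number of individuals.
#' @param seed integer seed; the output is reproducible given it.
#' @param dosage_noise if `TRUE`, add uniform noise of half-width
#'   `noise_sd` and clip to \[0, 2\] (default off: integer allele counts).
#' @param noise_sd half-width of the dosage noise.
#' @param variants optional variant metadata to attach; generated
#'   (chromosomes cycling 1..22, distinct positions, random alleles) when
#'   omitted.
#' @return A [dosage_panel()].
#' @export
generate_genotypes <- function(mafs, n_individuals, seed = 1L,
                               dosage_noise = FALSE, noise_sd = 0.05,
                               variants = NULL) {
  mafs <- as.numeric(mafs)
  if (any(mafs <= 0 | mafs > 0.5)) {
    stop("allele frequencies must lie in (0, 0.5]", call. = FALSE)
  }
  if (n_individuals <= 0) stop("n_individuals must be positive", call. = FALSE)
  m <- length(mafs)
  set.seed(seed)
  dos <- matrix(stats::rbinom(n_individuals * m, 2L, rep(mafs, each = n_individuals)),
                nrow = n_individuals, ncol = m)
  dos <- dos * 1.0
  if (dosage_noise) {
    dos[] <- pmin(2, pmax(0, dos + stats::runif(length(dos), -noise_sd, noise_sd)))
  }
  if (is.null(variants)) {
    bases <- c("A", "C", "G", "T")
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    ref <- sample(bases, m, replace = TRUE)
    # avoid strand-ambiguous (complementary) pairs in generated panels
    alt <- vapply(ref, function(b) sample(setdiff(bases, c(b, comp[[b]])), 1L), "")
    variants <- data.frame(
      chrom = as.character(rep_len(1:22, m)),
      pos = 10000L + 137L * seq_len(m),
      ref = ref, alt = unname(alt),
      af = colMeans(dos) / 2,
      stringsAsFactors = FALSE
    )
  } else {
    variants$af <- colMeans(dos) / 2
  }
  dosage_panel(dos, variants, sprintf("ind%05d", seq_len(n_individuals)))
}

# draw per-variant log-odds weights; a fraction gets an inflated SD
generate_weights_for <- function(panel, config, seed) {
  set.seed(seed)
  m <- nrow(panel$variants)
  sds <- rep(config$effect_sd, m)
  n_large <- round(config$large_frac * m)
  if (n_large > 0) sds[sample.int(m, n_large)] <- config$effect_sd * config$large_mult
  w <- stats::rnorm(m, config$effect_mean, sds)
  # orient a fraction of entries to the panel ref allele so downstream
  # allele re-orientation is exercised; the oriented score is unchanged
  flip <- stats::runif(m) < 0.2
  weight_table(
    chrom = panel$variants$chrom,
    pos = panel$variants$pos,
    effect_allele = ifelse(flip, panel$variants$ref, panel$variants$alt),
    other_allele = ifelse(flip, panel$variants$alt, panel$variants$ref),
    weight = ifelse(flip, -w, w)
  )
}

#' Assign phenotypes to a genotyped panel
#'
#' Disease status is drawn from a logistic model whose linear predictor is
#' `intercept + prs_beta * z + sex_effect * male + age_effect * (age - mid)`
#' where `z` is the true PRS (the weighted effect-allele dosage sum)
#' standardized over the panel. Case age-at-onset is normal with mean
#' `aao_mean + aao_prs_slope * z` and SD `aao_sd`. Sex is Bernoulli(1/2),
#' sampling age uniform over `age_range`, and PC1-PC3 are standard-normal
#' noise covariates.
#'
#' @param panel a [dosage_panel()].
#' @param weights the true [weight_table()] driving liability.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return A list with elements `cohort` (a [cohort_table()]) and `truth`
#'   (true weights, per-variant frequencies, raw and standardized
#'   liability, status and age-at-onset).
#' @export
generate_cohort <- function(panel, weights, config, seed = config$seed) {
  if (!length(panel$ids)) stop("empty dosage panel", call. = FALSE)
  n <- length(panel$ids)
  eff <- effect_dosages(panel, weights)
  raw <- as.numeric(eff$dosages %*% eff$weights)
  z <- if (stats::sd(raw) > 0) (raw - mean(raw)) / stats::sd(raw) else raw * 0
  set.seed(seed)
  sex <- ifelse(stats::rbinom(n, 1L, 0.5) == 1L, "M", "F")
  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  mid <- mean(config$age_range)
  eta <- config$intercept + config$prs_beta * z +
    config$sex_effect * (sex == "M") + config$age_effect * (age - mid)
  p <- stats::plogis(eta)
  status <- ifelse(stats::rbinom(n, 1L, p) == 1L, "case", "control")
  aao <- rep(NA_real_, n)
  ncase <- sum(status == "case")
  if (ncase > 0) {
    aao[status == "case"] <- stats::rnorm(
      ncase, config$aao_mean + config$aao_prs_slope * z[status == "case"],
      config$aao_sd)
  }
  cohort <- cohort_table(data.frame(
    id = panel$ids, status = status, sex = sex,
    age_at_sampling = round(age, 1), age_at_onset = round(aao, 1),
    PC1 = stats::rnorm(n), PC2 = stats::rnorm(n), PC3 = stats::rnorm(n),
    stringsAsFactors = FALSE
  ))
  truth <- list(
    true_weights = eff$weights,
    true_mafs = panel$variants$af,
    liability_raw = raw,
    liability_z = z,
    model_prob = p,
    assigned_status = status,
    assigned_aao = aao
  )
  list(cohort = cohort, truth = truth)
}

#' Packaged default disease life table
#'
#' @description
#' A life table of ten 5-year intervals \[50-54\]..\[95+\] with a
#' late-onset incidence profile that rises to a peak around 80 and an
#' age-increasing annual death rate. It is a synthetic stand-in
#' calibrated only in magnitude: the implied residual lifetime incidence
#' is about 1.9% at age 50, falling to 0.2% in the open-ended last
#' interval, the scale typical of Parkinson's disease claims-data rates.
#'
#' @param incidence,death_rate optional replacement profiles (length 10).
#' @param age_start first age of the first interval.
#' @return A [life_table()].
#' @export
generate_life_table <- function(incidence = NULL, death_rate = NULL,
                                age_start = 50) {
  if (is.null(incidence)) {
    incidence <- c(0.0007, 0.0012, 0.0020, 0.0030, 0.0040,
                   0.0047, 0.0047, 0.0040, 0.0030, 0.0020)
  }
  if (is.null(death_rate)) {
    death_rate <- c(0.004, 0.006, 0.009, 0.014, 0.022,
                    0.035, 0.055, 0.090, 0.150, 0.250)
  }
  life_table(incidence, death_rate, age_start = age_start)
}

#' Simulate a complete synthetic PRS validation study
#'
#' Runs the full generator: per-variant frequencies and true weights,
#' Hardy-Weinberg genotypes for a population pool, logistic phenotype
#' assignment, then case-control subsampling to the configured quota.
#' The master seed fans out into independent child seeds for the
#' frequency/weight, genotype, phenotype and subsampling stages.
#'
#' @param config a [sim_config()].
#' @return A list of class `"prs_study"`: `weights`, `panel`, `cohort`,
#'   `truth`, `life_table`, `config`.
#' @export
simulate_prs_study <- function(config = sim_config()) {
  seeds <- child_seeds(config$seed, 4L)
  set.seed(seeds[1])
  mafs <- stats::runif(config$n_snps, config$maf_range[1], config$maf_range[2])

  # pool large enough that both quotas are met with high probability
  p_guess <- stats::plogis(config$intercept)
  n_pool <- ceiling(1.35 * max(config$n_cases / p_guess,
                               config$n_controls / (1 - p_guess)))
  panel <- generate_genotypes(mafs, n_pool, seed = seeds[2])
  weights <- generate_weights_for(panel, config, seed = seeds[1])
  gen <- generate_cohort(panel, weights, config, seed = seeds[3])

  status <- gen$cohort$status
  if (sum(status == "case") < config$n_cases ||
      sum(status == "control") < config$n_controls) {
    stop("population pool of ", n_pool, " produced ",
         sum(status == "case"), " cases / ", sum(status == "control"),
         " controls; fewer than the configured quota", call. = FALSE)
  }
  set.seed(seeds[4])
  keep <- c(sample(which(status == "case"), config$n_cases),
            sample(which(status == "control"), config$n_controls))
  keep <- sort(keep)

  panel <- dosage_panel(panel$dosages[keep, , drop = FALSE],
                        panel$variants, panel$ids[keep])
  panel$variants$af <- colMeans(panel$dosages) / 2
  dimnames(panel$dosages) <- list(panel$ids,
                                  paste(panel$variants$chrom,
                                        panel$variants$pos, sep = ":"))
  cohort <- gen$cohort[keep, , drop = FALSE]
  rownames(cohort) <- NULL
  class(cohort) <- c("prs_cohort", "data.frame")
  truth <- lapply(gen$truth, function(v)
    if (length(v) == n_pool) v[keep] else v)

  structure(list(weights = weights, panel = panel, cohort = cohort,
                 truth = truth, life_table = generate_life_table(),
                 config = config),
            class = "prs_study")
}

#' @export
print.prs_study <- function(x, ...) {
  cat("Synthetic PRS study:",
      sum(x$cohort$status == "case"), "cases /",
      sum(x$cohort$status == "control"), "controls,",
      nrow(x$weights), "score variants (seed", x$config$seed, ")\n")
  invisible(x)
}

#' Write the four study input files plus the ground truth
#'
#' Emits `weights.tsv`, `dosages.tsv` (or `dosages.vcf`), `cohort.csv`,
#' `life_table.csv` and `truth.json` into `dir`.
#'
#' @param study a `prs_study` from [simulate_prs_study()].
#' @param dir output directory (created if needed).
#' @param dosage_format `"tsv"` or `"vcf"`.
#' @return The directory path, invisibly.
#' @export
write_study_inputs <- function(study, dir, dosage_format = c("tsv", "vcf")) {
  stopifnot(inherits(study, "prs_study"))
  dosage_format <- match.arg(dosage_format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_weights(study$weights, file.path(dir, "weights.tsv"))
  write_dosages(study$panel,
                file.path(dir, paste0("dosages.", dosage_format)),
                format = dosage_format)
  write_cohort(study$cohort, file.path(dir, "cohort.csv"))
  write_life_table(study$life_table, file.path(dir, "life_table.csv"))
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
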