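#' Construct a variant weight table
#'
#' A variant weight table describes a published polygenic risk score: one row
#' per variant with its genomic position, the effect allele whose dosage is
#' counted, the other allele, and the per-allele log-odds weight.
#'
#' @param chrom character vector of chromosome labels.
#' @param pos integer vector of 1-based base-pair positions.
#' @param effect_allele,other_allele single-base alleles (A, C, G or T).
#' @param weight numeric log-odds weight per copy of the effect allele.
#' @return A `data.frame` of class `"prs_weights"` with one row per variant.
#' @export
weight_table <- function(chrom, pos, effect_allele, other_allele, weight) {
  x <- data.frame(
    chrom = as.character(chrom),
    pos = as.integer(pos),
    effect_allele = toupper(as.character(effect_allele)),
    other_allele = toupper(as.character(other_allele)),
    weight = as.numeric(weight),
    stringsAsFactors = FALSE
  )
  validate_weight_table(x)
}

validate_weight_table <- function(x) {
  bases <- c("A", "C", "G", "T")
  if (any(is.na(x$pos)) || any(x$pos <= 0)) {
    stop("variant positions must be positive integers (row ",
         which(is.na(x$pos) | x$pos <= 0)[1], ")", call. = FALSE)
  }
  bad <- !(x$effect_allele %in% bases) | !(x$other_allele %in% bases)
  if (any(bad)) {
    stop("malformed allele in row ", which(bad)[1],
         ": alleles must be one of A, C, G, T", call. = FALSE)
  }
  same <- x$effect_allele == x$other_allele
  if (any(same)) {
    stop("effect and other allele identical in row ", which(same)[1],
         call. = FALSE)
  }
  key <- paste(x$chrom, x$pos, sep = ":")
  if (anyDuplicated(key)) {
    stop("duplicate (chromosome, position) key in row ",
         which(duplicated(key))[1], ": ", key[duplicated(key)][1],
         call. = FALSE)
  }
  if (any(!is.finite(x$weight))) {
    stop("non-finite weight in row ", which(!is.finite(x$weight))[1],
         call. = FALSE)
  }
  rownames(x) <- NULL
  class(x) <- c("prs_weights", "data.frame")
  x
}

#' Construct an allele-dosage panel
#'
#' Holds an individuals x variants matrix of alternate-allele dosages in
#' \[0, 2\] (fractional after imputation; `NA` marks a missing genotype)
#' together with per-variant metadata. Dosages always count the panel's
#' alt allele; re-orientation towards a weight table's effect allele is
#' done at scoring time.
#'
#' @param dosages numeric matrix, individuals in rows, variants in columns.
#' @param variants `data.frame` with columns `chrom`, `pos`, `ref`, `alt`,
#'   `af` (alt-allele frequency) and optionally `info` (imputation info
#'   score).
#' @param ids character vector of individual identifiers (one per row).
#' @return An object of class `"dosage_panel"`.
#' @export
dosage_panel <- function(dosages, variants, ids) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  ids <- as.character(ids)
  if (nrow(dosages) != length(ids)) {
    stop("dosage matrix has ", nrow(dosages), " rows but ", length(ids),
         " individual IDs", call. = FALSE)
  }
  if (ncol(dosages) != nrow(variants)) {
    stop("dosage matrix has ", ncol(dosages), " columns but ",
         nrow(variants), " variant metadata rows", call. = FALSE)
  }
  if (anyDuplicated(ids)) stop("duplicate individual IDs", call. = FALSE)
  needed <- c("chrom", "pos", "ref", "alt", "af")
  miss <- setdiff(needed, names(variants))
  if (length(miss)) {
    stop("variant metadata lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  rng <- range(dosages, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2)) {
    stop("dosage outside [0, 2] (range ", rng[1], "..", rng[2], ")",
         call. = FALSE)
  }
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  rownames(variants) <- NULL
  key <- paste(variants$chrom, variants$pos, sep = ":")
  if (anyDuplicated(key)) {
    stop("duplicate variant (chromosome, position): ",
         key[duplicated(key)][1], call. = FALSE)
  }
  dimnames(dosages) <- list(ids, key)
  structure(
    list(dosages = dosages, variants = variants, ids = ids),
    class = "dosage_panel"
  )
}

#' @export
print.dosage_panel <- function(x, ...) {
  cat("Dosage panel:", length(x$ids), "individuals x",
      nrow(x$variants), "variants\n")
  nmiss <- sum(is.na(x$dosages))
  if (nmiss) cat("  missing dosages:", nmiss, "\n")
  invisible(x)
}

#' @export
dim.dosage_panel <- function(x) dim(x$dosages)

#' Construct a phenotype cohort table
#'
#' One row per individual: case/control status, sex, age at sampling,
#' age at onset (cases only) and the first three principal components
#' used as ancestry covariates.
#'
#' @param x `data.frame` with columns `id`, `status` (`"case"`/`"control"`),
#'   `sex` (`"F"`/`"M"`), `age_at_sampling`, `age_at_onset` (NA for
#'   controls), `PC1`, `PC2`, `PC3`.
#' @return A `data.frame` of class `"prs_cohort"`.
#' @export
cohort_table <- function(x) {
  needed <- c("id", "status", "sex", "age_at_sampling", "age_at_onset",
              "PC1", "PC2", "PC3")
  miss <- setdiff(needed, names(x))
  if (length(miss)) {
    stop("cohort lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  x$id <- as.character(x$id)
  x$status <- as.character(x$status)
  x$sex <- as.character(x$sex)
  if (anyDuplicated(x$id)) {
    stop("duplicate individual ID: ", x$id[duplicated(x$id)][1],
         call. = FALSE)
  }
  bad <- !(x$status %in% c("case", "control"))
  if (any(bad)) {
    stop("row ", which(bad)[1],
         ": status must be 'case' or 'control', got '",
         x$status[bad][1], "'", call. = FALSE)
  }
  bad <- !(x$sex %in% c("F", "M"))
  if (any(bad)) {
    stop("row ", which(bad)[1], ": sex must be 'F' or 'M'", call. = FALSE)
  }
  ctrl_aao <- x$status == "control" & !is.na(x$age_at_onset)
  if (any(ctrl_aao)) {
    stop("row ", which(ctrl_aao)[1],
         ": control carries an age-at-onset", call. = FALSE)
  }
  rownames(x) <- NULL
  class(x) <- c("prs_cohort", "data.frame")
  x
}

#' Construct a life table of 5-year age intervals
#'
#' Ten contiguous 5-year intervals from \[50-54\] to \[95+\], each with the
#' probability `incidence` of disease onset within the interval and the
#' annual probability `death_rate` of dying within the interval. These are
#' the inputs of the residual lifetime incidence recursion (see
#' [residual_lifetime_incidence()]).
#'
#' @param incidence numeric vector of 10 interval incidence probabilities.
#' @param death_rate numeric vector of 10 annual death probabilities.
#' @param age_start first age of the first interval (default 50).
#' @return A `data.frame` of class `"life_table"` with columns `interval`,
#'   `age_start`, `incidence`, `death_rate`.
#' @export
life_table <- function(incidence, death_rate, age_start = 50) {
  if (length(incidence) != 10L || length(death_rate) != 10L) {
    stop("life table must have exactly 10 intervals, got ",
         length(incidence), " incidence and ", length(death_rate),
         " death-rate values", call. = FALSE)
  }
  if (any(!is.finite(incidence)) || any(incidence < 0) || any(incidence > 1)) {
    stop("interval incidence probabilities must lie in [0, 1]",
         call. = FALSE)
  }
  if (any(!is.finite(death_rate)) || any(death_rate < 0) || any(death_rate > 1)) {
    stop("annual death probabilities must lie in [0, 1]", call. = FALSE)
  }
  starts <- age_start + 5L * (0:9)
  labels <- c(paste(starts[1:9], starts[1:9] + 4L, sep = "-"),
              paste0(starts[10], "+"))
  x <- data.frame(
    interval = labels,
    age_start = starts,
    incidence = as.numeric(incidence),
    death_rate = as.numeric(death_rate),
    stringsAsFactors = FALSE
  )
  class(x) <- c("life_table", "data.frame")
  x
}

validate_life_table_frame <- function(x) {
  needed <- c("interval", "age_start", "incidence", "death_rate")
  miss <- setdiff(needed, names(x))
  if (length(miss)) {
    stop("life table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(x) != 10L) {
    stop("life table must cover exactly 10 intervals [50-54]..[95+], got ",
         nrow(x), " rows", call. = FALSE)
  }
  x <- x[order(x$age_start), , drop = FALSE]
  if (any(diff(x$age_start) != 5L)) {
    stop("life-table intervals are not contiguous 5-year bins",
         call. = FALSE)
  }
  life_table(x$incidence, x$death_rate, age_start = x$age_start[1])
}

## ---- readers and writers ---------------------------------------------------

#' Read and write a variant weight table (tab-separated)
#'
#' The on-disk format is tab-separated text with header columns
#' `chrom`, `pos`, `effect_allele`, `other_allele`, `weight`.
#'
#' @param path file path.
#' @return `read_weights()` returns a validated [weight_table()];
#'   `write_weights()` returns `path` invisibly.
#' @export
read_weights <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE,
                         colClasses = "character")
  needed <- c("chrom", "pos", "effect_allele", "other_allele", "weight")
  miss <- setdiff(needed, names(x))
  if (length(miss)) {
    stop("weight file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  x$pos <- as.integer(x$pos)
  x$weight <- as.numeric(x$weight)
  validate_weight_table(x[needed])
}

#' @rdname read_weights
#' @param x a [weight_table()].
#' @export
write_weights <- function(x, path) {
  stopifnot(inherits(x, "prs_weights"))
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write an allele-dosage panel
#'
#' Two on-disk formats are supported. The tab-separated layout is
#' variant-major: header columns `chrom`, `pos`, `ref`, `alt`, `af`,
#' optionally `info`, then one column per individual ID holding dosages;
#' missing dosages are the literal token `NA`. The VCF layout carries
#' dosages in a per-genotype `DS` FORMAT field (missing: `.`) and the
#' alt-allele frequency in an `AF` INFO field; reading uses the vcfR
#' parser.
#'
#' @param path file path.
#' @param format `"tsv"` or `"vcf"`.
#' @return `read_dosages()` returns a [dosage_panel()].
#' @export
read_dosages <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") read_dosages_tsv(path) else read_dosages_vcf(path)
}

read_dosages_tsv <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- intersect(c("chrom", "pos", "ref", "alt", "af", "info"),
                         names(x))
  if (!all(c("chrom", "pos", "ref", "alt", "af") %in% meta_cols)) {
    stop("dosage file ", path,
         " lacks metadata columns chrom/pos/ref/alt/af", call. = FALSE)
  }
  id_cols <- setdiff(names(x), meta_cols)
  if (!length(id_cols)) stop("dosage file has no individual columns",
                             call. = FALSE)
  mat <- t(as.matrix(x[id_cols]))
  storage.mode(mat) <- "double"
  bad <- which(!is.na(mat) & (mat < 0 | mat > 2), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("dosage outside [0, 2] at variant row ", bad[1, 2],
         ", individual ", id_cols[bad[1, 1]], call. = FALSE)
  }
  dosage_panel(mat, x[meta_cols], id_cols)
}

read_dosages_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (!any(grepl("DS", vcf@gt[, "FORMAT"]))) {
    stop("VCF ", path, " has no per-genotype DS dosage field",
         call. = FALSE)
  }
  ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  fix <- vcfR::getFIX(vcf)
  af <- suppressWarnings(as.numeric(sub(".*AF=([^;]+).*", "\\1",
                                        vcf@fix[, "INFO"])))
  variants <- data.frame(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    alt = fix[, "ALT"],
    af = af,
    stringsAsFactors = FALSE
  )
  mat <- t(ds)
  bad <- which(!is.na(mat) & (mat < 0 | mat > 2), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("dosage outside [0, 2] in VCF record ", bad[1, 2], call. = FALSE)
  }
  dosage_panel(mat, variants, colnames(ds))
}

#' @rdname read_dosages
#' @param x a [dosage_panel()].
#' @export
write_dosages <- function(x, path, format = c("tsv", "vcf")) {
  stopifnot(inherits(x, "dosage_panel"))
  format <- match.arg(format)
  if (format == "tsv") {
    out <- cbind(x$variants, as.data.frame(t(x$dosages)))
    names(out) <- c(names(x$variants), x$ids)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    write_dosages_vcf(x, path)
  }
  invisible(path)
}

write_dosages_vcf <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Alt allele frequency\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Alt allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$ids), collapse = "\t")
  ), con)
  v <- x$variants
  ds <- t(x$dosages)                 # variants x individuals
  ds_chr <- format(ds, trim = TRUE, digits = 6)
  ds_chr[is.na(ds)] <- "."
  lines <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS",
                 paste0("AF=", format(v$af, trim = TRUE, digits = 6)),
                 "DS",
                 apply(ds_chr, 1, paste, collapse = "\t"),
                 sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read and write a phenotype cohort (CSV)
#'
#' Columns: `id`, `status` (case/control), `sex` (F/M), `age_at_sampling`,
#' `age_at_onset` (empty for controls), `PC1`, `PC2`, `PC3`.
#'
#' @param path file path.
#' @return `read_cohort()` returns a validated [cohort_table()].
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  cohort_table(x)
}

#' @rdname read_cohort
#' @param x a [cohort_table()].
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "prs_cohort"))
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read and write a life table (CSV)
#'
#' Columns: `interval` (label), `age_start`, `incidence`, `death_rate`;
#' exactly ten contiguous 5-year intervals from \[50-54\] to \[95+\].
#'
#' @param path file path.
#' @return `read_life_table()` returns a validated [life_table()].
#' @export
read_life_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_life_table_frame(x)
}

#' @rdname read_life_table
#' @param x a [life_table()].
#' @export
write_life_table <- function(x, path) {
  stopifnot(inherits(x, "life_table"))
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
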