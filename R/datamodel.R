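#' Construct a trait table
#'
#' A trait table holds quantitative phenotype measurements for a set of
#' subjects: an `n x m` numeric matrix with unique subject identifiers on
#' the rows and trait names on the columns.  All downstream machinery
#' (covariate adjustment, standardization, the pleiotropy test) consumes
#' this container.
#'
#' @param values Numeric matrix or data frame, subjects in rows, traits in
#'   columns.  No missing values are allowed; filter incomplete rows first.
#' @param subject_ids Character vector of unique subject identifiers
#'   (defaults to rownames of `values`).
#' @param trait_names Character vector of trait names (defaults to
#'   colnames of `values`).
#' @return An object of class `trait_table`: the numeric matrix with
#'   subject ids as rownames and trait names as colnames.
#' @export
trait_table <- function(values, subject_ids = rownames(values),
                        trait_names = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 2L) stop("a trait table needs at least 2 subjects")
  if (ncol(values) < 1L) stop("a trait table needs at least 1 trait")
  if (is.null(subject_ids)) subject_ids <- as.character(seq_len(nrow(values)))
  subject_ids <- as.character(subject_ids)
  if (anyDuplicated(subject_ids))
    stop("duplicate subject id: ",
         paste(unique(subject_ids[duplicated(subject_ids)]), collapse = ", "))
  if (is.null(trait_names)) trait_names <- paste0("trait", seq_len(ncol(values)))
  if (anyNA(values)) stop("trait table contains missing values; drop incomplete rows first")
  dimnames(values) <- list(subject_ids, trait_names)
  structure(values, class = c("trait_table", "matrix", "array"))
}

#' Construct a genotype table
#'
#' Genotype codes count copies of the per-SNP minor allele: 0, 1 or 2,
#' with `NA` for missing calls.  The minor allele is defined among the
#' non-missing calls of each SNP; [genotype_table()] re-orients any column
#' whose coded allele turns out to be the major one, so that the stored
#' allele frequency never exceeds 0.5.
#'
#' @param codes Numeric matrix, subjects in rows, SNPs in columns, entries
#'   in `{0, 1, 2, NA}`.
#' @param subject_ids,snp_ids Row/column identifiers (default: dimnames).
#' @param map Optional data frame of marker metadata with columns
#'   `snp_id`, `chrom`, `position` (physical position, Mb).
#' @return An object of class `genotype_table`: the integer code matrix
#'   with a `map` attribute.
#' @export
genotype_table <- function(codes, subject_ids = rownames(codes),
                           snp_ids = colnames(codes), map = NULL) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  bad <- !(codes %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  if (is.null(subject_ids)) subject_ids <- as.character(seq_len(nrow(codes)))
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(codes)))
  subject_ids <- as.character(subject_ids)
  if (anyDuplicated(subject_ids)) stop("duplicate subject id in genotype table")
  dimnames(codes) <- list(subject_ids, as.character(snp_ids))
  # orient every column toward the minor allele
  for (j in seq_len(ncol(codes))) {
    x <- codes[, j]
    af <- mean(x, na.rm = TRUE) / 2
    if (is.finite(af) && af > 0.5) codes[, j] <- 2L - x
  }
  if (!is.null(map)) {
    map <- as.data.frame(map)
    stopifnot("snp_id" %in% names(map))
    map <- map[match(colnames(codes), map$snp_id), , drop = FALSE]
  }
  structure(codes, map = map, class = c("genotype_table", "matrix", "array"))
}

#' Read a phenotype/covariate table from delimited text
#'
#' Reads a tab-delimited file with a header row and one row per subject,
#' keeps the named trait columns (plus any named covariates), and drops
#' subjects with a missing value in any requested column.  The number of
#' dropped rows is reported via `message()`.
#'
#' @param path Path to a TSV file.  Missing values are coded `NA`.
#' @param trait_names Character vector of trait column names to extract.
#' @param covariate_names Optional covariate column names (e.g. `"age"`,
#'   `"sex"`) that must also be complete.
#' @param id_col Name of the subject identifier column (default first
#'   column).
#' @return A list with elements `traits` (a [trait_table()]) and
#'   `covariates` (a data frame of the requested covariate columns with
#'   rownames = subject ids, or `NULL`).
#' @export
read_trait_table <- function(path, trait_names, covariate_names = NULL,
                             id_col = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (is.null(id_col)) id_col <- names(df)[1L]
  wanted <- c(trait_names, covariate_names)
  missing_cols <- setdiff(c(id_col, wanted), names(df))
  if (length(missing_cols))
    stop("column(s) not found in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df[[id_col]]))
    stop("duplicate subject id in ", path)
  keep <- stats::complete.cases(df[, wanted, drop = FALSE])
  if (any(!keep))
    message(sum(!keep), " subject(s) dropped for missing trait/covariate values")
  df <- df[keep, , drop = FALSE]
  tt <- trait_table(as.matrix(df[, trait_names, drop = FALSE]),
                    subject_ids = df[[id_col]])
  cov <- NULL
  if (!is.null(covariate_names)) {
    cov <- df[, covariate_names, drop = FALSE]
    rownames(cov) <- df[[id_col]]
  }
  list(traits = tt, covariates = cov)
}

#' Read genotypes from a matrix TSV or a VCF
#'
#' The matrix dialect is a TSV with subjects in rows (first column =
#' subject id) and one column of 0/1/2/NA codes per SNP; an optional
#' sidecar map file (`snp_id`, `chrom`, `position`) supplies marker
#' coordinates.  VCF input uses the GT field of biallelic records
#' (phased and unphased genotypes are treated identically); multiallelic
#' records and malformed GT fields are skipped with a warning.  In both
#' cases codes are re-oriented so they count the minor allele.
#'
#' @param path Input file.
#' @param format `"matrix-tsv"` or `"vcf"`.
#' @param map_path Optional sidecar map TSV for the matrix dialect.
#' @return A [genotype_table()].
#' @export
read_genotypes <- function(path, format = c("matrix-tsv", "vcf"),
                           map_path = NULL) {
  format <- match.arg(format)
  if (format == "matrix-tsv") {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(df[[1L]])
    codes <- as.matrix(df[, -1L, drop = FALSE])
    map <- NULL
    if (!is.null(map_path)) {
      map <- utils::read.delim(map_path, stringsAsFactors = FALSE)
    }
    return(genotype_table(codes, subject_ids = ids, map = map))
  }
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(vcf)
  multi <- grepl(",", alt)
  if (any(multi)) {
    warning(sum(multi), " multiallelic record(s) skipped")
    vcf <- vcf[!multi, ]
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  # rows = SNPs, cols = subjects; count ALT alleles per call
  count_alt <- function(g) {
    if (is.na(g)) return(NA_integer_)
    al <- strsplit(g, "[/|]")[[1L]]
    if (length(al) != 2L || !all(al %in% c("0", "1"))) return(NA_integer_)
    sum(al == "1")
  }
  codes <- apply(gt, c(1L, 2L), count_alt)
  bad <- is.na(codes) & !is.na(gt)
  if (any(bad)) warning(sum(bad), " malformed GT call(s) set to missing")
  pos <- as.numeric(vcfR::getPOS(vcf))
  map <- data.frame(snp_id = rownames(codes),
                    chrom = vcfR::getCHROM(vcf),
                    position = pos / 1e6)  # report in Mb
  genotype_table(t(codes), map = map)
}

#' Adjust traits for age and sex
#'
#' Each trait is regressed on an intercept, AGE, AGE squared and SEX by
#' least squares; the residuals become the adjusted traits used in
#' association testing.  Residual columns have mean zero and are
#' orthogonal to the fitted covariate design.
#'
#' @param traits A [trait_table()].
#' @param covariates Data frame aligned with `traits` containing columns
#'   `age` (years) and `sex` (binary indicator).
#' @return A `trait_table` of residuals with the same dimnames.
#' @export
adjust_traits <- function(traits, covariates) {
  stopifnot(nrow(traits) == nrow(covariates))
  if (!all(c("age", "sex") %in% names(covariates)))
    stop("covariates must contain 'age' and 'sex' columns")
  age <- as.numeric(covariates$age)
  sex <- as.numeric(covariates$sex)
  if (stats::var(age) == 0) stop("age has zero variance")
  X <- cbind(1, age, age^2, sex)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warning("constant covariate column dropped from adjustment design")
  }
  if (nrow(X) <= qrX$rank) stop("too few subjects for the adjustment design")
  resid <- qr.resid(qrX, unclass(traits))
  trait_table(resid, subject_ids = rownames(traits),
              trait_names = colnames(traits))
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditioning on the observed allele counts: the
#' p-value is the sum of the conditional probabilities of every
#' heterozygote count (with the same parity as the minor-allele total)
#' whose probability does not exceed that of the observed configuration.
#' No mid-p correction is applied.
#'
#' @param counts Integer vector of length 3:
#'   `(n_hom_minor, n_het, n_hom_major)`.
#' @return The exact p-value in `(0, 1]`.
#' @export
#' @examples
#' hwe_exact_test(c(1, 45, 1150))  # ~0.37
hwe_exact_test <- function(counts) {
  counts <- as.integer(round(counts))
  if (length(counts) != 3L || any(counts < 0L))
    stop("counts must be three non-negative integers")
  n <- sum(counts)
  if (n < 1L) stop("all genotype counts are zero")
  n_minor <- 2L * counts[1L] + counts[2L]
  n_major <- 2L * counts[3L] + counts[2L]
  if (n_minor > n_major) {  # orient toward the rarer allele
    counts <- rev(counts)
    tmp <- n_minor; n_minor <- n_major; n_major <- tmp
  }
  if (n_minor == 0L) return(1)
  hets <- seq.int(n_minor %% 2L, n_minor, by = 2L)
  # log conditional probability of each feasible heterozygote count
  logp <- vapply(hets, function(h) {
    aa <- (n_minor - h) %/% 2L
    bb <- n - aa - h
    lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
      h * log(2) + lfactorial(n_minor) + lfactorial(n_major) -
      lfactorial(2L * n)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- match(counts[2L], hets)
  if (is.na(obs)) stop("heterozygote count inconsistent with allele totals")
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

#' Per-SNP genotype summaries
#'
#' Tabulates genotype counts, minor allele frequency and the exact
#' Hardy-Weinberg p-value for every SNP of a genotype table, using the
#' non-missing calls of each marker.
#'
#' @param genotypes A [genotype_table()].
#' @return Data frame with columns `snp_id`, `n_hom_minor`, `n_het`,
#'   `n_hom_major`, `maf`, `hwe_p`.
#' @export
snp_summary <- function(genotypes) {
  codes <- unclass(genotypes)
  out <- lapply(seq_len(ncol(codes)), function(j) {
    x <- codes[, j]
    x <- x[!is.na(x)]
    cnt <- c(sum(x == 2L), sum(x == 1L), sum(x == 0L))
    tot <- sum(cnt)
    maf <- if (tot > 0) (2 * cnt[1L] + cnt[2L]) / (2 * tot) else NA_real_
    data.frame(snp_id = colnames(codes)[j],
               n_hom_minor = cnt[1L], n_het = cnt[2L], n_hom_major = cnt[3L],
               maf = maf,
               hwe_p = if (tot > 0) hwe_exact_test(cnt) else NA_real_)
  })
  do.call(rbind, out)
}

#' Quality-control filter on minor allele frequency and Hardy-Weinberg
#'
#' Removes SNPs with minor allele frequency at or below `maf_min` or an
#' exact Hardy-Weinberg p-value at or below `hwe_min` — the usual
#' pre-association cleaning step.
#'
#' @param genotypes A [genotype_table()].
#' @param maf_min MAF threshold (SNPs with `maf <= maf_min` are removed).
#' @param hwe_min HWE p-value threshold (`hwe_p <= hwe_min` removed).
#' @return List with `genotypes` (the filtered table) and `summary` (the
#'   full [snp_summary()] data frame with a logical `pass` column).
#' @export
qc_filter <- function(genotypes, maf_min = 0.01, hwe_min = 1e-5) {
  summ <- snp_summary(genotypes)
  summ$pass <- !is.na(summ$maf) & summ$maf > maf_min & summ$hwe_p > hwe_min
  keep <- summ$snp_id[summ$pass]
  if (!length(keep)) message("no SNPs survive QC")
  map <- attr(genotypes, "map")
  if (!is.null(map)) map <- map[map$snp_id %in% keep, , drop = FALSE]
  gt <- genotype_table(unclass(genotypes)[, keep, drop = FALSE], map = map)
  list(genotypes = gt, summary = summ)
}

#' Genetic-model design encodings of a genotype vector
#'
#' Translates minor-allele-count codes into regression design columns for
#' the four classical inheritance models: `GEN` treats genotype as a
#' three-level factor (two indicator columns, code 0 as reference), `ADD`
#' uses the allele count itself, `DOM` indicates carriers of at least one
#' minor allele, and `REC` indicates minor-allele homozygotes.
#'
#' @param codes Integer vector with values in `{0, 1, 2}` (missing values
#'   must already be removed).
#' @param model One of `"GEN"`, `"ADD"`, `"DOM"`, `"REC"`.
#' @return Numeric matrix with one row per subject: two columns for `GEN`,
#'   one otherwise.
#' @export
encode_genotype <- function(codes, model = c("GEN", "ADD", "DOM", "REC")) {
  model <- match.arg(toupper(model), c("GEN", "ADD", "DOM", "REC"))
  codes <- as.integer(codes)
  if (anyNA(codes) || !all(codes %in% 0:2))
    stop("codes must be 0, 1 or 2 with no missing values")
  switch(model,
    GEN = cbind(het = as.numeric(codes == 1L),
                hom = as.numeric(codes == 2L)),
    ADD = cbind(add = as.numeric(codes)),
    DOM = cbind(dom = as.numeric(codes >= 1L)),
    REC = cbind(rec = as.numeric(codes == 2L)))
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", nrow(x), "subjects x", ncol(x), "SNPs\n")
  if (!is.null(attr(x, "map"))) cat("  with marker map\n")
  invisible(x)
}

#' @export
print.trait_table <- function(x, ...) {
  cat("trait_table:", nrow(x), "subjects x", ncol(x), "traits (",
      paste(colnames(x), collapse = ", "), ")\n")
  invisible(x)
}
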