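#' Single-trait association test
#'
#' Classical linear-regression association test for one quantitative
#' trait: the marker design is compared against the nested
#' intercept-plus-covariates model, and the deviance difference scaled by
#' the full-model dispersion is referred to a chi-squared distribution
#' with as many degrees of freedom as the marker contributes.  This is
#' the per-trait building block of the single-trait comparators (SATN
#' without, SATB with Bonferroni adjustment).
#'
#' @param trait Numeric vector of trait values.
#' @param marker_design Matrix from [encode_genotype()].
#' @param covariate_design Optional covariate matrix (no intercept).
#' @param n_traits Number of traits in the family, used for the
#'   Bonferroni-adjusted p-value `min(1, n_traits * p)`.
#' @param trait_name Label carried into the result.
#' @return Object of class `single_trait_result`: list with
#'   `trait_name`, `statistic`, `df`, `p_value`, `p_bonferroni`,
#'   `degenerate`.
#' @export
single_trait_test <- function(trait, marker_design, covariate_design = NULL,
                              n_traits = 1L, trait_name = "trait") {
  marker_design <- as.matrix(marker_design)
  if (!is.null(covariate_design)) covariate_design <- as.matrix(covariate_design)
  fit <- .lrt_deviance(as.numeric(trait), marker_design, covariate_design)
  if (fit$degenerate) {
    p <- 1
    stat <- 0
    df <- 0L
  } else {
    stat <- fit$stat
    df <- fit$df
    p <- stats::pchisq(stat, df, lower.tail = FALSE)
  }
  structure(list(trait_name = trait_name, statistic = stat, df = df,
                 p_value = p, p_bonferroni = min(1, n_traits * p),
                 degenerate = fit$degenerate),
            class = "single_trait_result")
}

#' Single-trait tests for every trait of a table
#'
#' Runs [single_trait_test()] per trait against one marker and returns a
#' tidy data frame, with the Bonferroni family size set to the number of
#' traits.
#'
#' @param traits A [trait_table()] or numeric matrix.
#' @param codes Genotype codes 0/1/2 aligned with the trait rows.
#' @param model Genetic model for [encode_genotype()].
#' @param covariate_design Optional covariate matrix.
#' @return Data frame: `trait`, `model`, `statistic`, `df`, `p`,
#'   `p_bonferroni`.
#' @export
single_trait_scan <- function(traits, codes, model = "ADD",
                              covariate_design = NULL) {
  Y <- as.matrix(unclass(traits))
  md <- encode_genotype(codes, model)
  m <- ncol(Y)
  rows <- lapply(seq_len(m), function(j) {
    r <- single_trait_test(Y[, j], md, covariate_design, n_traits = m,
                           trait_name = colnames(Y)[j] %||% paste0("trait", j))
    data.frame(trait = r$trait_name, model = model, statistic = r$statistic,
               df = r$df, p = r$p_value, p_bonferroni = r$p_bonferroni)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rejection decisions with and without Bonferroni adjustment
#'
#' Given per-trait p-values for one marker, flags each trait as rejected
#' at level `alpha` without adjustment (SATN) and at `alpha / m` with
#' Bonferroni adjustment (SATB); the any-trait decisions are the OR over
#' traits.  The SATB rejection set is always a subset of the SATN set.
#'
#' @param p_values Numeric vector of per-trait p-values.
#' @param alpha Family-wise significance level (default 0.05).
#' @return List with `satn` and `satb` (logical per-trait flags) and
#'   `satn_any`, `satb_any`.
#' @export
satb_decision <- function(p_values, alpha = 0.05) {
  m <- length(p_values)
  satn <- p_values <= alpha
  satb <- p_values <= alpha / m
  list(satn = satn, satb = satb,
       satn_any = any(satn), satb_any = any(satb))
}

#' @export
print.single_trait_result <- function(x, ...) {
  cat(sprintf("single-trait test [%s]: stat = %.4f on %d df; p = %.4g (Bonferroni %.4g)\n",
              x$trait_name, x$statistic, x$df, x$p_value, x$p_bonferroni))
  invisible(x)
}
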