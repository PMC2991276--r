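#' Sample genotype codes at a Hardy-Weinberg locus
#'
#' Draws independent minor-allele-count codes with
#' `P(2) = maf^2`, `P(1) = 2 maf (1 - maf)`, `P(0) = (1 - maf)^2`,
#' i.e. a biallelic locus in Hardy-Weinberg proportions.  Uses the
#' current R random number generator state.
#'
#' @param maf Minor allele frequency, strictly in `(0, 1)`.
#' @param n Number of subjects.
#' @return Integer vector of codes in `{0, 1, 2}`.
#' @export
sample_hwe_genotypes <- function(maf, n) {
  if (!is.numeric(maf) || maf <= 0 || maf >= 1)
    stop("maf must lie strictly between 0 and 1")
  stats::rbinom(n, 2L, maf)
}

#' Haplotype frequencies for two linked biallelic loci
#'
#' Given minor allele frequencies `p1` (marker) and `q1` (QTL) and an
#' allelic correlation `r`, computes `D = r * sqrt(p1 (1-p1) q1 (1-q1))`
#' and the four joint haplotype frequencies
#' `f(A1B1) = p1 q1 + D`, `f(A1B2) = p1 (1-q1) - D`,
#' `f(A2B1) = (1-p1) q1 - D`, `f(A2B2) = (1-p1)(1-q1) + D`,
#' where allele 1 is the minor allele at each locus.
#'
#' @param p1 Minor allele frequency of the tested marker.
#' @param q1 Minor allele frequency of the QTL.
#' @param r Allelic correlation coefficient in `[-1, 1]`.
#' @return Object of class `haplotype_freqs`: list with the four
#'   frequencies `f_A1B1`, `f_A1B2`, `f_A2B1`, `f_A2B2`, plus `D`, `r`,
#'   `p1`, `q1`.
#' @export
haplotype_frequencies <- function(p1, q1, r) {
  stopifnot(p1 > 0, p1 < 1, q1 > 0, q1 < 1, abs(r) <= 1)
  D <- r * sqrt(p1 * (1 - p1) * q1 * (1 - q1))
  f <- c(f_A1B1 = p1 * q1 + D,
         f_A1B2 = p1 * (1 - q1) - D,
         f_A2B1 = (1 - p1) * q1 - D,
         f_A2B2 = (1 - p1) * (1 - q1) + D)
  neg <- f < -1e-12
  if (any(neg))
    stop("infeasible r: negative haplotype frequency for ",
         paste(names(f)[neg], collapse = ", "))
  f <- pmax(f, 0)
  structure(c(as.list(f), list(D = D, r = r, p1 = p1, q1 = q1)),
            class = "haplotype_freqs")
}

#' Sample a linked marker given QTL genotypes
#'
#' For each of a subject's two QTL alleles, the linked marker allele is
#' drawn from the conditional distribution `P(A | B) = f(AB) / f(B)`;
#' the marker code is the number of minor marker alleles.  Both loci are
#' in Hardy-Weinberg proportions, and at `r = 1` the marker reproduces
#' the QTL genotype exactly.
#'
#' @param qtl_codes Integer QTL codes in `{0, 1, 2}` (minor-allele
#'   counts).
#' @param hapfreqs A [haplotype_frequencies()] object.
#' @return Integer vector of marker codes.
#' @export
sample_marker_given_qtl <- function(qtl_codes, hapfreqs) {
  q1 <- hapfreqs$q1
  pA_given_B1 <- min(1, max(0, hapfreqs$f_A1B1 / q1))        # P(minor | QTL minor)
  pA_given_B2 <- min(1, max(0, hapfreqs$f_A1B2 / (1 - q1)))  # P(minor | QTL major)
  n <- length(qtl_codes)
  # per subject: qtl_codes minor alleles and 2 - qtl_codes major alleles
  a_from_minor <- stats::rbinom(n, qtl_codes, pA_given_B1)
  a_from_major <- stats::rbinom(n, 2L - qtl_codes, pA_given_B2)
  a_from_minor + a_from_major
}

#' Simulation scenario configuration
#'
#' Bundles the generating-model parameters for the four simulation
#' designs used to characterize the pleiotropy test:
#' \describe{
#'   \item{1}{Two traits driven directly by one QTL:
#'     `Y_i = U_i + X b + E_i`, `E ~ N(0, 2^2)`, QTL MAF 0.2,
#'     `U = (0, 50)`; `b` varies from 0 to 1.}
#'   \item{2}{As scenario 1 with `b = 1` fixed, but the returned tested
#'     marker is a separate locus (MAF 0.2) in LD with the QTL at
#'     allelic correlation `r`.}
#'   \item{3}{Two traits with a second QTL and an environmental
#'     covariate: `Y_i = U_i + X b + Q c + W d + E_i`, `c = d = 4`,
#'     `W ~ N(0, 1)`, `E ~ N(0, 0.5^2)`; `b` varies from 0 to 4.}
#'   \item{4}{`n_traits` (2-10) copies of the scenario-3 trait law with
#'     `b = 2.5` and independent residuals; `U_i = (i - 1) * 50`.}
#' }
#' The per-dataset sample size defaults to `n = 100`.
#'
#' @param scenario Integer 1-4.
#' @param n Subjects per dataset.
#' @param b Tested-QTL additive effect (scenarios 1, 3; fixed at 1 and
#'   2.5 in scenarios 2 and 4).
#' @param r LD correlation between marker and QTL (scenario 2).
#' @param n_traits Number of traits (scenario 4).
#' @param qtl_maf,marker_maf Minor allele frequencies (default 0.2).
#' @param c_effect,d_effect Second-QTL and environmental effects
#'   (default 4, scenarios 3-4).
#' @param sigma Residual standard deviation (default 2 for scenarios
#'   1-2, 0.5 for 3-4).
#' @return Object of class `scenario_config` (a named list).
#' @export
scenario_config <- function(scenario, n = 100L, b = 0, r = 0, n_traits = 2L,
                            qtl_maf = 0.2, marker_maf = 0.2,
                            c_effect = 4, d_effect = 4, sigma = NULL) {
  scenario <- as.integer(scenario)
  if (!scenario %in% 1:4) stop("scenario must be 1, 2, 3 or 4")
  if (n < 10L) stop("n must be at least 10")
  if (is.null(sigma)) sigma <- if (scenario <= 2L) 2 else 0.5
  if (scenario == 2L) b <- 1
  if (scenario == 4L) b <- 2.5
  if (scenario == 4L && !(n_traits >= 2L && n_traits <= 10L))
    stop("scenario 4 uses between 2 and 10 traits")
  if (scenario != 4L) n_traits <- 2L
  structure(list(scenario = scenario, n = as.integer(n), b = b, r = r,
                 n_traits = as.integer(n_traits), qtl_maf = qtl_maf,
                 marker_maf = marker_maf, c_effect = c_effect,
                 d_effect = d_effect, sigma = sigma,
                 U = (seq_len(n_traits) - 1) * 50),
            class = "scenario_config")
}

#' Simulate one dataset under a scenario configuration
#'
#' Generates a trait table and the tested-marker genotype codes from the
#' generating models of [scenario_config()], using the current RNG state
#' (set a seed beforehand for reproducibility).  In scenario 2 the traits
#' are driven by the QTL but the returned `marker` is the LD-linked
#' locus; in all other scenarios the tested marker is the causal QTL
#' itself (null when `b = 0`).
#'
#' @param config A [scenario_config()].
#' @return List with `traits` (a [trait_table()]), `marker` (integer
#'   codes of the tested marker), `qtl` (the causal locus; identical to
#'   `marker` outside scenario 2), and `config`.
#' @export
simulate_scenario <- function(config) {
  if (!inherits(config, "scenario_config"))
    stop("config must be built with scenario_config()")
  n <- config$n
  m <- config$n_traits
  X <- sample_hwe_genotypes(config$qtl_maf, n)
  marker <- X
  if (config$scenario == 2L) {
    hf <- haplotype_frequencies(config$marker_maf, config$qtl_maf, config$r)
    marker <- sample_marker_given_qtl(X, hf)
  }
  base <- config$b * X
  if (config$scenario >= 3L) {
    Q <- sample_hwe_genotypes(config$qtl_maf, n)
    W <- stats::rnorm(n)
    base <- base + config$c_effect * Q + config$d_effect * W
  }
  Y <- matrix(stats::rnorm(n * m, sd = config$sigma), n, m) + base
  Y <- sweep(Y, 2L, config$U, "+")
  colnames(Y) <- paste0("Y", seq_len(m))
  list(traits = trait_table(Y), marker = as.integer(marker),
       qtl = as.integer(X), config = config)
}

#' Fraction of between-trait correlation contributed by the tested QTL
#'
#' For the two-QTL-plus-environment trait law
#' `Y = U + X b + Q c + W d + E`, the between-trait covariance is
#' `b^2 var(X) + c^2 var(Q) + d^2 var(W)` and the share attributable to
#' the tested QTL is
#' `P(b) = b^2 var(X) / (b^2 var(X) + c^2 var(Q) + d^2 var(W))`.
#' With MAF-0.2 Hardy-Weinberg loci (`var = 2 * 0.2 * 0.8 = 0.32`), a
#' standard-normal environment and `c = d = 4`, this reduces to
#' `0.32 b^2 / (0.32 b^2 + 21.12)`.
#'
#' @param b Tested-QTL effect.
#' @param c_effect,d_effect Second-QTL and environmental effects.
#' @param var_x,var_q Genotype variances of the two loci.
#' @param var_w Variance of the environmental covariate.
#' @return The contributed fraction in `[0, 1)`.
#' @export
#' @examples
#' prop_correlation_contributed(4)    # ~0.195
#' prop_correlation_contributed(2.5)  # ~0.087
prop_correlation_contributed <- function(b, c_effect = 4, d_effect = 4,
                                         var_x = 0.32, var_q = 0.32,
                                         var_w = 1) {
  stopifnot(var_x >= 0, var_q >= 0, var_w >= 0)
  denom <- b^2 * var_x + c_effect^2 * var_q + d_effect^2 * var_w
  if (denom == 0) stop("zero denominator: no variance source")
  b^2 * var_x / denom
}

#' Write a simulated dataset to delimited text
#'
#' Writes the trait table (TSV with a subject id column), the tested
#' marker as a one-SNP genotype matrix TSV, and a YAML echo of the
#' configuration, so a simulated dataset round-trips through
#' [read_trait_table()] and [read_genotypes()].
#'
#' @param dataset Output of [simulate_scenario()].
#' @param prefix Output path prefix; writes `<prefix>_traits.tsv`,
#'   `<prefix>_geno.tsv`, `<prefix>_config.yaml`.
#' @return Invisibly, the three file paths.
#' @export
write_simulated_dataset <- function(dataset, prefix) {
  tt <- dataset$traits
  tf <- paste0(prefix, "_traits.tsv")
  gf <- paste0(prefix, "_geno.tsv")
  cf <- paste0(prefix, "_config.yaml")
  df <- data.frame(subject_id = rownames(tt), unclass(tt),
                   check.names = FALSE)
  utils::write.table(df, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  gdf <- data.frame(subject_id = rownames(tt), marker = dataset$marker)
  utils::write.table(gdf, gf, sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(unclass(dataset$config), cf)
  invisible(c(traits = tf, genotypes = gf, config = cf))
}
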