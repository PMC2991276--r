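# Independent oracles used across test files.

# Enumeration oracle for the exact Hardy-Weinberg test: list every
# feasible heterozygote count for the observed allele totals, compute
# each configuration's conditional probability up to a constant as
# 2^h / (n_AA! n_Aa! n_aa!), normalize, and sum the probabilities not
# exceeding that of the observed configuration.
hwe_enumeration_oracle <- function(counts) {
  n <- sum(counts)
  n_minor <- 2 * counts[1] + counts[2]
  n_major <- 2 * counts[3] + counts[2]
  if (n_minor > n_major) {
    counts <- rev(counts)
    n_minor <- 2 * counts[1] + counts[2]
  }
  if (n_minor == 0) return(1)
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  lw <- sapply(hets, function(h) {
    aa <- (n_minor - h) / 2
    bb <- n - aa - h
    h * log(2) - lfactorial(aa) - lfactorial(h) - lfactorial(bb)
  })
  pr <- exp(lw - max(lw))
  pr <- pr / sum(pr)
  obs <- pr[hets == counts[2]]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# Generic linear-model LRT-type oracle through the lm() formula
# interface: deviance difference of nested vs full fit, scaled by the
# full model's unbiased dispersion, i.e. the same statistic computed by
# an entirely separate code path.
lm_lrt_oracle <- function(y, marker, covar = NULL) {
  df_full <- if (is.null(covar)) data.frame(y = y, marker)
             else data.frame(y = y, marker, covar)
  full <- lm(y ~ ., data = df_full)
  nested <- if (is.null(covar)) lm(y ~ 1)
            else lm(y ~ ., data = data.frame(y = y, covar))
  phi <- deviance(full) / df.residual(full)
  list(stat = (deviance(nested) - deviance(full)) / phi,
       df = df.residual(nested) - df.residual(full))
}

# Deterministic small trait matrix with a given correlation structure.
make_correlated_traits <- function(n, sigma, seed = 1) {
  set.seed(seed)
  L <- chol(sigma)
  Y <- matrix(rnorm(n * ncol(sigma)), n) %*% L
  trait_table(Y, trait_names = paste0("T", seq_len(ncol(sigma))))
}
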