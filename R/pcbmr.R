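#' Standardize traits to mean zero and unit sample variance
#'
#' Column-wise `(Y - mean) / sd` with the sample (n-1) standard deviation.
#' Standardization makes the covariance and correlation matrices of the
#' traits coincide, so the principal-component decomposition is unit-free.
#' The means and variances are stored for the reverse transformation of
#' component-scale effect estimates.
#'
#' @param traits A [trait_table()] or numeric matrix (subjects x traits).
#' @return Object of class `standardized_traits`: the standardized matrix
#'   with attributes `mean` and `var` (per-trait).
#' @export
standardize <- function(traits) {
  Y <- as.matrix(unclass(traits))
  mu <- colMeans(Y)
  v <- apply(Y, 2L, stats::var)
  if (any(v == 0)) {
    nm <- colnames(Y)[v == 0]
    if (is.null(nm)) nm <- which(v == 0)
    stop("trait has zero variance: ", paste(nm, collapse = ", "))
  }
  Ys <- sweep(sweep(Y, 2L, mu), 2L, sqrt(v), "/")
  structure(Ys, mean = mu, var = v,
            class = c("standardized_traits", "matrix", "array"))
}

#' Eigendecomposition of the trait correlation matrix
#'
#' Decomposes the sample correlation matrix of the standardized traits as
#' `rho = Gamma Lambda Gamma^T`.  Eigenpairs are ordered by decreasing
#' eigenvalue; each eigenvector's sign is fixed so that its
#' largest-magnitude entry is positive (ties broken by the first trait
#' index), which pins down otherwise arbitrary score signs.
#'
#' @param standardized Output of [standardize()].
#' @return Object of class `eigen_system`: list with `correlation`
#'   (m x m), `vectors` (orthonormal columns), `values` (descending).
#' @export
eigendecompose <- function(standardized) {
  rho <- stats::cor(unclass(standardized))
  if (any(!is.finite(rho))) stop("non-finite trait correlations")
  e <- eigen(rho, symmetric = TRUE)
  G <- e$vectors
  for (j in seq_len(ncol(G))) {
    i <- which.max(abs(G[, j]))  # which.max takes the first index on ties
    if (G[i, j] < 0) G[, j] <- -G[, j]
  }
  rownames(G) <- colnames(rho)
  structure(list(correlation = rho, vectors = G, values = e$values),
            class = "eigen_system")
}

#' Select canonical variables at a variance-explained threshold
#'
#' Keeps the smallest number `k` of leading principal components whose
#' eigenvalues sum to at least a fraction `theta` of the total trait
#' variance (`m`, for a correlation matrix), and forms the canonical
#' variable scores `z = Y^S Gamma_(1..k)`.  Components with numerically
#' zero eigenvalues (< 1e-10) are never retained.  Score columns are
#' mutually uncorrelated with sample variance equal to their eigenvalue.
#'
#' @param eigensystem Output of [eigendecompose()].
#' @param standardized Output of [standardize()] (same data).
#' @param theta Variance-explained threshold in `(0, 1]` (default 0.8,
#'   i.e. the retained components explain at least 80% of variation).
#' @return Object of class `canonical_set`: list with `k`, `theta`,
#'   `loadings` (m x k), `values` (length k), `scores` (n x k),
#'   `explained_fraction`, and the trait `mean`/`var` carried over for
#'   reverse transformation.
#' @export
select_canonical <- function(eigensystem, standardized, theta = 0.8) {
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0 || theta > 1)
    stop("theta must be a single value in (0, 1]")
  lam <- eigensystem$values
  m <- length(lam)
  cumfrac <- cumsum(lam) / m
  k <- which(cumfrac >= theta - 1e-12)[1L]
  if (is.na(k)) k <- m
  k <- max(1L, min(k, sum(lam > 1e-10)))
  G <- eigensystem$vectors[, seq_len(k), drop = FALSE]
  z <- unclass(standardized) %*% G
  colnames(z) <- paste0("z", seq_len(k))
  structure(list(k = k, theta = theta, loadings = G,
                 values = lam[seq_len(k)], scores = z,
                 explained_fraction = cumfrac[k],
                 mean = attr(standardized, "mean"),
                 var = attr(standardized, "var")),
            class = "canonical_set")
}

# Least-squares LRT-type deviance comparison of full vs nested design.
# Returns the statistic (RSS_nested - RSS_full) / phi_hat, the marker
# degrees of freedom actually contributed, and a degeneracy flag.
# phi_hat = RSS_full / (n - p_full), the unbiased full-model dispersion.
.lrt_deviance <- function(y, marker, covar = NULL) {
  n <- length(y)
  ones <- rep(1, n)
  X0 <- if (is.null(covar) || ncol(covar) == 0L) cbind(ones) else cbind(ones, covar)
  f0 <- stats::lm.fit(X0, y)
  rss0 <- sum(f0$residuals^2)
  X1 <- cbind(X0, marker)
  f1 <- stats::lm.fit(X1, y)
  rss1 <- sum(f1$residuals^2)
  df <- f1$rank - f0$rank
  # marker coefficients sit after the ncol(X0) baseline columns; aliased
  # (rank-dropped) columns come back NA from lm.fit
  bmark <- f1$coefficients[seq.int(ncol(X0) + 1L, length.out = ncol(marker))]
  if (df < 1L || n - f1$rank < 1L)
    return(list(stat = 0, df = 0L, phi = NA_real_, degenerate = TRUE,
                beta = bmark))
  phi <- rss1 / (n - f1$rank)
  stat <- if (phi > 0) max(0, (rss0 - rss1) / phi) else Inf
  list(stat = stat, df = df, phi = phi, degenerate = FALSE, beta = bmark)
}

#' Pleiotropy test by principal-component-based multivariate regression
#'
#' Tests the joint null hypothesis that a marker has no effect on any
#' retained canonical variable.  For each component `i`, a full linear
#' model (intercept + marker design + covariates) and a nested model
#' (intercept + covariates) are fitted by least squares, and the
#' component statistic is the deviance difference scaled by the
#' full-model dispersion estimate,
#' `T_i = (RSS_nested - RSS_full) / phi_i` with
#' `phi_i = RSS_full / (n - p_full)`.  Because the canonical variables
#' are mutually uncorrelated, `T = sum(T_i)` is referred to a chi-squared
#' distribution with `k * (marker design columns)` degrees of freedom.
#'
#' Rank-deficient marker designs (e.g. a monomorphic marker, or one
#' collinear with the covariates) lose the degenerate columns and the
#' degrees of freedom shrink accordingly; a marker contributing no rank
#' at all yields `p = 1` with `degenerate = TRUE`.
#'
#' @param canonical A [select_canonical()] result.
#' @param marker_design Numeric matrix from [encode_genotype()], rows
#'   aligned with the canonical scores.
#' @param covariate_design Optional numeric matrix of covariates (no
#'   intercept column; one is always included).
#' @return Object of class `pcbmr_result`: list with `T`, `per_component`
#'   (the `T_i`), `df`, `p_value`, `dispersions`, `beta` (k x marker-cols
#'   effect estimates on the component scale), and `degenerate`.
#' @export
pcbmr_test <- function(canonical, marker_design, covariate_design = NULL) {
  z <- canonical$scores
  k <- canonical$k
  marker_design <- as.matrix(marker_design)
  if (nrow(marker_design) != nrow(z))
    stop("marker design rows do not match canonical scores")
  if (!is.null(covariate_design)) covariate_design <- as.matrix(covariate_design)
  Ti <- numeric(k)
  phi <- numeric(k)
  beta <- matrix(NA_real_, k, ncol(marker_design),
                 dimnames = list(colnames(z), colnames(marker_design)))
  df_marker <- NA_integer_
  degenerate <- FALSE
  for (i in seq_len(k)) {
    fit <- .lrt_deviance(z[, i], marker_design, covariate_design)
    Ti[i] <- fit$stat
    phi[i] <- fit$phi
    if (fit$degenerate) degenerate <- TRUE
    df_marker <- fit$df
    beta[i, ] <- fit$beta
  }
  df <- k * df_marker
  if (df < 1L || degenerate) {
    out <- list(T = 0, per_component = Ti, df = 0L, p_value = 1,
                dispersions = phi, beta = beta, k = k, degenerate = TRUE,
                reduced_df = TRUE)
  } else {
    T <- sum(Ti)
    out <- list(T = T, per_component = Ti, df = df,
                p_value = stats::pchisq(T, df, lower.tail = FALSE),
                dispersions = phi, beta = beta, k = k, degenerate = FALSE,
                reduced_df = df_marker < ncol(marker_design))
  }
  class(out) <- "pcbmr_result"
  out
}

#' Map component-scale effects back to the original traits
#'
#' Effects estimated on the canonical-variable scale are linear
#' combinations of standardized-trait effects.  Given per-component
#' effect estimates `beta_i`, the implied effect on original trait `j` is
#' `sd_j * sum_i loadings[j, i] * beta_i`.
#'
#' @param canonical A [select_canonical()] result (carries the loadings
#'   and the original trait standard deviations).
#' @param beta Numeric vector of length `k`: one effect per retained
#'   component (e.g. a column of `pcbmr_result$beta`).
#' @return Named numeric vector of per-trait effects on the original
#'   trait scale.
#' @export
reverse_transform <- function(canonical, beta) {
  beta <- as.numeric(beta)
  if (length(beta) != canonical$k)
    stop("beta length must equal the number of retained components (k = ",
         canonical$k, ")")
  eff_std <- drop(canonical$loadings %*% beta)
  eff <- eff_std * sqrt(canonical$var)
  names(eff) <- rownames(canonical$loadings)
  eff
}

#' One-call pleiotropy test on a trait table
#'
#' Convenience wrapper: standardize, eigendecompose, select canonical
#' variables at `theta`, and run [pcbmr_test()] for one marker under one
#' genetic model.
#'
#' @param traits A [trait_table()] (typically covariate-adjusted).
#' @param codes Genotype codes 0/1/2 aligned with the trait rows.
#' @param model Genetic model passed to [encode_genotype()].
#' @param theta Variance-explained threshold for [select_canonical()].
#' @param covariate_design Optional covariate matrix.
#' @return A `pcbmr_result` (with the `canonical_set` attached as
#'   attribute `canonical`).
#' @export
pcbmr <- function(traits, codes, model = "GEN", theta = 0.8,
                  covariate_design = NULL) {
  s <- standardize(traits)
  cs <- select_canonical(eigendecompose(s), s, theta = theta)
  res <- pcbmr_test(cs, encode_genotype(codes, model), covariate_design)
  attr(res, "canonical") <- cs
  res
}

#' Per-SNP pleiotropy scan
#'
#' Runs the pleiotropy test for every SNP of a genotype table against a
#' common set of traits.  Canonical variables are constructed once from
#' all subjects; each marker is tested on its complete-case subjects
#' (subjects missing that genotype are dropped for that marker only, and
#' the marker is re-encoded on the remaining calls).
#'
#' @param traits A [trait_table()] (typically covariate-adjusted).
#' @param genotypes A [genotype_table()] with matching subject ids.
#' @param model Genetic model (single string).
#' @param theta Variance-explained threshold.
#' @return Data frame with one row per SNP: `snp_id`, `position`,
#'   `model`, `k`, `T`, `df`, `p`, `neg_log10_p`, `degenerate`.
#' @export
pcbmr_scan <- function(traits, genotypes, model = "GEN", theta = 0.8) {
  common <- intersect(rownames(traits), rownames(genotypes))
  if (!length(common)) stop("no overlapping subjects between traits and genotypes")
  tt <- trait_table(unclass(traits)[common, , drop = FALSE])
  codes <- unclass(genotypes)[common, , drop = FALSE]
  s <- standardize(tt)
  es <- eigendecompose(s)
  cs <- select_canonical(es, s, theta = theta)
  map <- attr(genotypes, "map")
  rows <- lapply(seq_len(ncol(codes)), function(j) {
    x <- codes[, j]
    ok <- !is.na(x)
    if (sum(ok) < 3L || length(unique(x[ok])) < 2L) {
      res <- list(T = 0, df = 0L, p_value = 1, degenerate = TRUE)
    } else {
      cs_j <- cs
      cs_j$scores <- cs$scores[ok, , drop = FALSE]
      res <- pcbmr_test(cs_j, encode_genotype(x[ok], model))
    }
    pos <- if (!is.null(map)) map$position[match(colnames(codes)[j], map$snp_id)] else NA_real_
    data.frame(snp_id = colnames(codes)[j], position = pos, model = model,
               k = cs$k, T = res$T, df = res$df, p = res$p_value,
               neg_log10_p = -log10(max(res$p_value, .Machine$double.xmin)),
               degenerate = res$degenerate)
  })
  do.call(rbind, rows)
}

#' @export
print.pcbmr_result <- function(x, ...) {
  cat("PCBMR pleiotropy test\n")
  cat(sprintf("  k = %d canonical variable(s); T = %.4f on %d df; p = %.4g\n",
              x$k, x$T, x$df, x$p_value))
  if (x$degenerate) cat("  (degenerate marker design)\n")
  invisible(x)
}

#' @export
print.canonical_set <- function(x, ...) {
  cat(sprintf("canonical_set: k = %d of %d components (%.1f%% of variance, theta = %g)\n",
              x$k, nrow(x$loadings), 100 * x$explained_fraction, x$theta))
  invisible(x)
}
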