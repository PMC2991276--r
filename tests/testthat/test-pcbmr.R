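test_that("standardization yields exact zero-mean unit-variance columns", {
  Y <- trait_table(cbind(a = c(1, 4, 6, 9), b = c(10, 10, 30, 50)))
  s <- standardize(Y)
  expect_lt(max(abs(colMeans(s))), 1e-12)
  expect_equal(unname(apply(unclass(s), 2, var)), c(1, 1), tolerance = 1e-12)
  # hand formula on the toy matrix
  expect_equal(unclass(s)[, "a"], (c(1, 4, 6, 9) - 5) / sd(c(1, 4, 6, 9)),
               ignore_attr = TRUE)
  expect_error(standardize(trait_table(cbind(a = c(1, 2, 3), b = c(5, 5, 5)))),
               "b")
})

test_that("eigendecomposition reconstructs the correlation matrix", {
  # 2x2 closed form: eigenvalues 1 + r and 1 - r
  r <- 0.6
  Y <- make_correlated_traits(2000, matrix(c(1, r, r, 1), 2), seed = 5)
  es <- eigendecompose(standardize(Y))
  rhat <- es$correlation[1, 2]
  expect_equal(es$values, c(1 + rhat, 1 - rhat), tolerance = 1e-10)
  # random 5-trait reconstruction within 1e-8
  sigma <- crossprod(matrix(rnorm(25), 5)) + diag(5)
  Y5 <- make_correlated_traits(200, cov2cor(sigma), seed = 9)
  es5 <- eigendecompose(standardize(Y5))
  G <- es5$vectors
  expect_lt(max(abs(G %*% diag(es5$values) %*% t(G) - es5$correlation)), 1e-8)
  expect_lt(max(abs(crossprod(G) - diag(5))), 1e-8)
  expect_equal(sum(es5$values), 5, tolerance = 1e-10)
  # sign convention: largest-magnitude loading of each eigenvector positive
  for (j in 1:5) expect_gt(G[which.max(abs(G[, j])), j], 0)
})

test_that("canonical selection honours the variance-explained threshold", {
  s <- standardize(make_correlated_traits(500, matrix(c(1, .97, .97, 1), 2),
                                          seed = 2))
  es <- eigendecompose(s)
  # eigenvalues ~ (1.97, 0.03): one component explains >= 80%
  cs <- select_canonical(es, s, theta = 0.8)
  expect_equal(cs$k, 1L)
  expect_gte(cs$explained_fraction, 0.8)
  # theta = 1 retains everything
  cs2 <- select_canonical(es, s, theta = 1)
  expect_equal(cs2$k, 2L)
  expect_error(select_canonical(es, s, theta = 0), "theta")
  expect_error(select_canonical(es, s, theta = 1.2), "theta")
  # score variance equals the eigenvalue; scores uncorrelated
  v <- apply(cs2$scores, 2, var)
  expect_equal(unname(v), es$values, tolerance = 1e-10)
  expect_lt(abs(cor(cs2$scores)[1, 2]), 1e-8)
})

test_that("weakly correlated traits keep all components, near-collinear keep one", {
  set.seed(31)
  k_weak <- k_strong <- integer(30)
  for (i in 1:30) {
    ds1 <- simulate_scenario(scenario_config(1, b = 0.5))
    ds3 <- simulate_scenario(scenario_config(3, b = 2))
    s1 <- standardize(ds1$traits); s3 <- standardize(ds3$traits)
    k_weak[i] <- select_canonical(eigendecompose(s1), s1)$k
    k_strong[i] <- select_canonical(eigendecompose(s3), s3)$k
  }
  expect_true(all(k_weak == 2L))
  expect_true(all(k_strong == 1L))
})

test_that("with k = 1 the pleiotropy statistic equals the generic lm oracle", {
  set.seed(123)
  for (i in 1:50) {
    n <- sample(30:80, 1)
    codes <- rbinom(n, 2, runif(1, 0.15, 0.45))
    if (length(unique(codes)) < 2) next
    y <- rnorm(n) + runif(1, -1, 1) * codes
    model <- sample(c("GEN", "ADD", "DOM", "REC"), 1)
    md <- encode_genotype(codes, model)
    covar <- if (i %% 2 == 0) cbind(age = rnorm(n)) else NULL
    tt <- trait_table(cbind(y = y, ycopy = y * 2 + 3))  # perfectly correlated
    s <- standardize(tt)
    cs <- select_canonical(eigendecompose(s), s)
    expect_equal(cs$k, 1L)
    res <- pcbmr_test(cs, md, covar)
    oracle <- lm_lrt_oracle(cs$scores[, 1], md, covar)
    if (oracle$df == 0) next
    expect_equal(res$T, oracle$stat, tolerance = 1e-9)
    expect_equal(res$df, oracle$df)
  }
})

test_that("T is non-negative and invariant to affine trait rescaling", {
  set.seed(77)
  for (i in 1:20) {
    ds <- simulate_scenario(scenario_config(1, b = runif(1)))
    res1 <- pcbmr(ds$traits, ds$marker, model = "ADD")
    Y2 <- sweep(sweep(unclass(ds$traits), 2, c(3.7, 0.01), "*"), 2, c(-5, 100), "+")
    res2 <- pcbmr(trait_table(Y2), ds$marker, model = "ADD")
    expect_gte(res1$T, 0)
    expect_equal(res1$T, res2$T, tolerance = 1e-8)
    expect_equal(res1$p_value, res2$p_value, tolerance = 1e-8)
  }
})

test_that("with uncorrelated traits, T is the sum of per-trait statistics", {
  # When the traits are mutually uncorrelated the canonical variables
  # coincide with the standardized traits (identity loadings), and the
  # joint statistic decomposes into the per-trait single-regression
  # statistics computed independently.
  set.seed(15)
  n <- 150
  codes <- rbinom(n, 2, 0.3)
  y1 <- rnorm(n) + 0.4 * codes
  y2 <- resid(lm(rnorm(n) - 0.3 * codes ~ y1)) + 0.1 * codes
  Y0 <- trait_table(cbind(t1 = y1, t2 = y2))
  s <- standardize(Y0)
  cs <- structure(list(k = 2L, theta = 1, loadings = diag(2),
                       values = c(1, 1), scores = unclass(s),
                       explained_fraction = 1,
                       mean = attr(s, "mean"), var = attr(s, "var")),
                  class = "canonical_set")
  md <- encode_genotype(codes, "ADD")
  res <- pcbmr_test(cs, md)
  st <- sapply(1:2, function(j) lm_lrt_oracle(unclass(s)[, j], md)$stat)
  expect_equal(res$T, sum(st), tolerance = 1e-8)
  expect_equal(res$df, 2L)
})

test_that("squared correlations of all scores with any trait sum to one", {
  Y <- make_correlated_traits(300, cov2cor(crossprod(matrix(rnorm(16), 4)) + diag(4)),
                              seed = 21)
  s <- standardize(Y)
  cs <- select_canonical(eigendecompose(s), s, theta = 1)
  r2 <- cor(cs$scores, unclass(s))^2
  expect_equal(unname(colSums(r2)), rep(1, 4), tolerance = 1e-8)
})

test_that("null p-values are uniform and degenerate markers give p = 1", {
  set.seed(99)
  pvals <- replicate(600, {
    ds <- simulate_scenario(scenario_config(1, n = 100, b = 0))
    if (length(unique(ds$marker)) < 2) return(NA_real_)
    pcbmr(ds$traits, ds$marker, model = "ADD")$p_value
  })
  pvals <- pvals[!is.na(pvals)]
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
  # constant marker: degenerate flag, p = 1
  tt <- make_correlated_traits(50, diag(2), seed = 1)
  res <- pcbmr(tt, rep(1L, 50), model = "ADD")
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)
})

test_that("reverse transformation maps component effects to trait scale", {
  # single trait: effect times the trait sd
  y <- rnorm(80, sd = 3)
  tt <- trait_table(cbind(a = y, b = rnorm(80)))
  s <- standardize(tt)
  cs <- select_canonical(eigendecompose(s), s, theta = 1)
  expect_equal(unname(reverse_transform(cs, c(0, 0))), c(0, 0))
  expect_error(reverse_transform(cs, 1), "k = 2")
  # simulate-and-recover: near-collinear traits, effect b recovered per trait
  set.seed(55)
  b_true <- 2
  eff <- replicate(40, {
    ds <- simulate_scenario(scenario_config(3, n = 400, b = b_true))
    res <- pcbmr(ds$traits, ds$marker, model = "ADD")
    cs <- attr(res, "canonical")
    reverse_transform(cs, res$beta[, 1])
  })
  expect_equal(mean(eff), b_true, tolerance = 3 * sd(eff) / sqrt(length(eff)))
})
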