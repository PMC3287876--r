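test_that("build_sigma produces the documented correlation structures", {
  expect_identical(build_sigma(3, "identity"), diag(1, 3))
  expect_equal(build_sigma(2, "exchangeable", rho = 0.1),
               matrix(c(1, 0.1, 0.1, 1), 2))
  blocky <- build_sigma(4, "exchangeable", rho = 0.1, block_sizes = c(2, 2))
  expect_equal(blocky[1:2, 3:4], matrix(0, 2, 2))
  expect_equal(blocky[1, 2], 0.1)
  expect_error(build_sigma(2, "exchangeable", rho = 1), "singular")
  expect_error(build_sigma(4, "exchangeable", block_sizes = c(2, 3)),
               "sum")
})

test_that("a prior-only (all-zero) column gives Q = y'y and zero penalty", {
  y <- c(-1.5, -0.5, 0.5, 1.5)
  expect_warning(
    ev <- log_marginal_likelihood(y, matrix(0, 4, 1), prior_spec(lambda = 1)),
    "all-zero")
  expect_equal(ev$q_gamma, sum(y^2), tolerance = 1e-12)
  expect_equal(ev$log_det_penalty, 0, tolerance = 1e-12)
  expect_equal(ev$log_marginal, -(4 / 2) * log(sum(y^2)), tolerance = 1e-12)
})

test_that("closed-form evidence ratios match direct numerical integration", {
  set.seed(101)
  for (i in 1:6) {
    n <- sample(4:6, 1)
    y <- rnorm(n)
    y <- y - mean(y)
    k1 <- sample(1:2, 1)
    k2 <- sample(1:2, 1)
    lam <- runif(1, 0.5, 2)
    X1 <- matrix(rnorm(n * k1), n, k1)
    X2 <- matrix(rnorm(n * k2), n, k2)
    s1 <- build_sigma(k1, "exchangeable", rho = 0.2)
    s2 <- diag(1, k2)
    pr <- prior_spec(lambda = lam, m = 1)
    d_closed <- log_marginal_likelihood(y, X1, pr, s1)$log_marginal -
      log_marginal_likelihood(y, X2, pr, s2)$log_marginal
    d_oracle <- oracle_log_marginal(y, X1, lam, s1) -
      oracle_log_marginal(y, X2, lam, s2)
    expect_lt(abs(exp(d_closed - d_oracle) - 1), 1e-3)
  }
})

test_that("augmented-QR route agrees with explicit normal equations", {
  set.seed(77)
  for (i in 1:30) {
    n <- sample(10:50, 1)
    k <- sample(1:10, 1)
    y <- rnorm(n); y <- y - mean(y)
    X <- scale(matrix(rnorm(n * k), n, k), scale = FALSE)
    lam <- runif(1, 0.3, 3)
    sig <- build_sigma(k, "exchangeable", rho = runif(1, 0, 0.5))
    ev <- log_marginal_likelihood(y, X, prior_spec(lambda = lam), sig)
    ref <- naive_evidence(y, X, lam, sig)
    expect_equal(ev$q_gamma, ref$q_gamma, tolerance = 1e-8)
    expect_equal(ev$log_marginal, ref$log_marginal, tolerance = 1e-8)
  }
})

test_that("evidence is invariant under consistent column permutation", {
  set.seed(5)
  n <- 20
  y <- rnorm(n); y <- y - mean(y)
  X <- matrix(rnorm(n * 3), n, 3)
  sig <- build_sigma(3, "exchangeable", rho = 0.1, block_sizes = c(2, 1))
  perm <- c(3, 1, 2)
  ev1 <- log_marginal_likelihood(y, X, prior_spec(), sig)
  ev2 <- log_marginal_likelihood(y, X[, perm], prior_spec(),
                                 sig[perm, perm])
  expect_equal(ev1$log_marginal, ev2$log_marginal, tolerance = 1e-10)
})

test_that("as lambda shrinks the prior pulls Q toward y'y for every model", {
  set.seed(6)
  n <- 30
  y <- rnorm(n); y <- y - mean(y)
  X <- scale(matrix(rnorm(n * 3), n, 3), scale = FALSE)
  lams <- c(1, 0.1, 0.01, 0.001)
  qs <- vapply(lams, function(l)
    log_marginal_likelihood(y, X, prior_spec(lambda = l))$q_gamma,
    numeric(1))
  expect_true(all(diff(abs(qs - sum(y^2))) < 0))
  expect_equal(qs[4], sum(y^2), tolerance = 1e-4)
})

test_that("size-penalized prior multiplies posterior odds by e^(-dk/2)", {
  ev_k3 <- structure(list(log_marginal = -12.3, k = 3L, n = 100L),
                     class = "model_evidence")
  ev_k1 <- structure(list(log_marginal = -12.3, k = 1L, n = 100L),
                     class = "model_evidence")
  pr_u <- prior_spec(model_prior = "uniform")
  pr_s <- prior_spec(model_prior = "size_penalized")
  expect_equal(log_model_posterior(ev_k3, pr_u),
               log_model_posterior(ev_k1, pr_u))
  expect_equal(exp(log_model_posterior(ev_k3, pr_s) -
                     log_model_posterior(ev_k1, pr_s)),
               exp(-1))
  pr_b <- prior_spec(model_prior = "size_penalized",
                     size_penalty = "bic_log_n")
  expect_equal(log_model_posterior(ev_k3, pr_b) -
                 log_model_posterior(ev_k1, pr_b), -log(100))
})

test_that("count_model_space is exact and refuses what it cannot count", {
  expect_identical(count_model_space(4, 2), 6)
  expect_identical(count_model_space(10, 0), 1)
  expect_identical(count_model_space(10, 10), 1)
  expect_equal(count_model_space(24478, 3), choose(24478, 3))
  expect_identical(count_model_space(50, 3), count_model_space(50, 47))
  expect_error(count_model_space(4, 5), "m <= p")
  expect_error(count_model_space(24487, 600), "exact integer range")
})

test_that("prior inclusion equals the binomial-coefficient ratio m/p", {
  for (p in c(7, 20)) for (m in c(1, 3)) {
    expect_equal(prior_inclusion(p, m),
                 count_model_space(p - 1, m - 1) / count_model_space(p, m))
  }
})

test_that("exhaustive enumeration normalizes and finds a planted model", {
  set.seed(12)
  g <- random_genotypes(60, 4, seed = 12)
  y <- rnorm(60); y <- y - mean(y)
  exh <- exhaustive_posterior(y, snp_provider(g), 4, 2,
                              prior_spec(m = 2))
  expect_identical(nrow(exh), 6L)
  expect_equal(sum(exh$posterior), 1, tolerance = 1e-12)

  # strong planted signal on factors {1, 2}: effects 10x the noise sd
  Xc <- center_columns(g, 1:2)
  y2 <- drop(Xc %*% c(10, 10)) + rnorm(60)
  y2 <- y2 - mean(y2)
  exh2 <- exhaustive_posterior(y2, snp_provider(g), 4, 2, prior_spec(m = 2))
  expect_identical(sort(exh2$active[[which.max(exh2$posterior)]]), 1:2)

  expect_error(exhaustive_posterior(y, snp_provider(g), 24478, 3,
                                    prior_spec(m = 3)),
               "MCMC")
})

test_that("a duplicated candidate column does not break the enumeration", {
  g <- random_genotypes(40, 3, seed = 4)
  vals <- cbind(unclass(g), unclass(g)[, 3])
  colnames(vals) <- c(colnames(g), "dup")
  gdup <- genotype_matrix(vals)
  y <- rnorm(40); y <- y - mean(y)
  exh <- exhaustive_posterior(y, snp_provider(gdup), 4, 2, prior_spec(m = 2))
  expect_equal(sum(exh$posterior), 1, tolerance = 1e-12)
  expect_true(all(is.finite(exh$log_posterior)))
})
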