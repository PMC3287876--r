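make_gene_fixture <- function(n = 60, sizes = c(3, 5, 1, 2), seed = 70) {
  p <- sum(sizes)
  g <- random_genotypes(n, p, seed = seed)
  genes <- sprintf("G%02d", rep(seq_along(sizes), sizes))
  list(g = g, map = gene_map(setNames(genes, colnames(g))), sizes = sizes)
}

test_that("gene designs stack the centered columns of every active gene", {
  fx <- make_gene_fixture()
  d <- build_gene_design(c("G01", "G02"), fx$map, fx$g)
  expect_identical(d$k, 3L + 5L)
  expect_identical(unname(d$block_sizes), c(3L, 5L))
  expect_lt(max(abs(colMeans(d$columns))), 1e-10)
  # single 1-variant gene reduces to the SNP design of that variant
  d1 <- build_gene_design("G03", fx$map, fx$g)
  v <- names(fx$map)[as.character(fx$map) == "G03"]
  expect_equal(unname(d1$columns), unname(center_columns(fx$g, v)))
  expect_error(build_gene_design("NOPE", fx$map, fx$g), "unknown gene")
})

test_that("evidence is invariant to gene activation order", {
  fx <- make_gene_fixture()
  y <- rnorm(60); y <- y - mean(y)
  pr <- prior_spec(m = 2)
  ev <- function(genes) {
    d <- build_gene_design(genes, fx$map, fx$g)
    sig <- build_sigma(d$k, "exchangeable", 0.1, d$block_sizes)
    log_marginal_likelihood(y, d$columns, pr, sig)$log_marginal
  }
  expect_equal(ev(c("G01", "G04")), ev(c("G04", "G01")), tolerance = 1e-10)
})

test_that("SNP-run gene summary divides mean posterior by the m/p prior", {
  fx <- make_gene_fixture()
  probs <- rep(0, sum(fx$sizes))
  probs[1:2] <- c(0.4, 0.0)   # the first two variants sit in G01
  snp_sum <- make_summary(probs, ids = colnames(fx$g), m = 10)
  snp_sum$m <- 10L; snp_sum$p <- 24487L
  tab <- gene_summary_from_snp_run(snp_sum, fx$map)
  g1 <- tab[tab$gene_id == "G01", ]
  expect_equal(g1$mean_posterior, 0.4 / 3)
  expect_equal(g1$posterior_prior_ratio, (0.4 / 3) / (10 / 24487))
  # all variants exactly at prior level -> ratio 1; all zero -> ratio 0
  at_prior <- make_summary(rep(10 / 24487, sum(fx$sizes)),
                           ids = colnames(fx$g), m = 10)
  at_prior$m <- 10L; at_prior$p <- 24487L
  tab2 <- gene_summary_from_snp_run(at_prior, fx$map)
  expect_equal(tab2$posterior_prior_ratio, rep(1, nrow(tab2)))
  expect_equal(tab[tab$gene_id == "G03", "posterior_prior_ratio"], 0)
})

test_that("worked two-variant example reproduces the defining arithmetic", {
  probs <- c(0.4, 0.0)
  snp_sum <- make_summary(probs, ids = c("v1", "v2"), m = 10)
  snp_sum$m <- 10L; snp_sum$p <- 24487L
  map <- gene_map(c(v1 = "GENE", v2 = "GENE"))
  tab <- gene_summary_from_snp_run(snp_sum, map)
  expect_equal(tab$posterior_prior_ratio, 0.2 / (10 / 24487))
  expect_equal(round(tab$posterior_prior_ratio, 1), 489.7)
})

test_that("gene screening finds the gene that carries the signal", {
  set.seed(80)
  sizes <- c(2, 3, 1, 2, 4, 1, 2, 3, 1, 1)
  fx <- make_gene_fixture(n = 90, sizes = sizes, seed = 80)
  causal <- names(fx$map)[as.character(fx$map) == "G02"]  # 3-variant gene
  y <- drop(center_columns(fx$g, causal) %*% c(1.2, 1.0, 0.8)) + rnorm(90)
  pr <- prior_spec(m = 3, model_prior = "size_penalized")
  res <- run_gene_screen(fx$g, y, fx$map, pr, n_iter = 10000,
                         burn_in = 1000, seed = 4)
  expect_gt(res$probabilities[["G02"]], 0.9)
  # sampler marginals agree with exhaustive enumeration over gene sets
  y0 <- y - mean(y)
  exh <- exhaustive_posterior(y0, gene_provider(fx$g, fx$map),
                              length(sizes), 3, pr)
  em <- exhaustive_marginals(exh, length(sizes))
  expect_lt(max(abs(res$probabilities - em)), 0.05)
  expect_equal(sum(res$probabilities), 3, tolerance = 1e-9)
})

test_that("duplicated genes split the posterior they would hold alone", {
  g <- random_genotypes(80, 3, seed = 81)
  y <- drop(center_columns(g, 1) * 2) + rnorm(80)
  y <- y - mean(y)
  vals <- cbind(unclass(g), unclass(g)[, 1])
  colnames(vals) <- c("V1", "V2", "V3", "V1dup")
  gdup <- genotype_matrix(vals)
  map3 <- gene_map(c(V1 = "GA", V2 = "GB", V3 = "GC"))
  map4 <- gene_map(c(V1 = "GA", V2 = "GB", V3 = "GC", V1dup = "GD"))
  pr <- prior_spec(m = 1, model_prior = "size_penalized")
  exh3 <- exhaustive_posterior(y, gene_provider(g, map3), 3, 1, pr)
  exh4 <- exhaustive_posterior(y, gene_provider(gdup, map4), 4, 1, pr)
  m3 <- exhaustive_marginals(exh3, 3)
  m4 <- exhaustive_marginals(exh4, 4)
  # GA and its duplicate GD share what GA held alone
  expect_equal(m4[1] + m4[4], m3[1], tolerance = 0.05)
  expect_equal(m4[1], m4[4], tolerance = 1e-6)
})

test_that("with singleton genes and a uniform prior, gene mode is SNP mode", {
  n <- 50; p <- 6
  g <- random_genotypes(n, p, seed = 82)
  colnames(g) <- sprintf("V%02d", 1:p)   # sorted gene ids follow columns
  map <- gene_map(setNames(sprintf("G%02d", 1:p), colnames(g)))
  y <- drop(center_columns(g, 1:2) %*% c(1, 0.7)) + rnorm(n)
  pr <- prior_spec(m = 2, model_prior = "uniform")
  snp <- run_chain(g, y, pr, factor_mode = "snp", n_iter = 3000,
                   burn_in = 200, seed = 11)
  gen <- run_chain(g, y, pr, factor_mode = "gene", gene_map = map,
                   n_iter = 3000, burn_in = 200, seed = 11)
  expect_identical(snp$visits, gen$visits)
  expect_equal(unname(marginal_inclusion(snp)$probabilities),
               unname(marginal_inclusion(gen)$probabilities))
})

test_that("gene mode demands a complete variant-to-gene map", {
  fx <- make_gene_fixture()
  partial <- gene_map(unclass(fx$map)[-1])
  expect_error(run_chain(fx$g, rnorm(60), prior_spec(m = 2),
                         factor_mode = "gene", gene_map = partial,
                         n_iter = 10, seed = 1),
               "unmapped")
})
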