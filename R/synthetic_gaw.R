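# Synthetic mini-exome replicates with known causal truth, emulating the
# shape of a GAW17-style study: ~700 unrelated individuals, a few hundred
# to a few thousand genes with highly variable variant counts, a strongly
# rare-skewed allele-frequency spectrum, a small number of causal variants
# clustered in few genes with effects in [0.13, 1.35] on a unit-noise
# trait, three covariates (Smoke, Age, Sex), and an optional
# smoking-by-gene interaction.  Sites are sampled independently (binomial
# in the allele frequency); an optional within-gene LD generator via a
# shared latent haplotype factor is provided for robustness checks.

#' Configuration for the synthetic replicate generator
#'
#' Defaults describe one fixed set of study conditions: 697 individuals,
#' 200 genes with log-series(0.93) variant counts (about 1,000 variants in
#' total), truncated scaled-Beta(0.3, 2.5) minor-allele frequencies
#' floored at one copy per sample, and 10 causal variants in 3 genes with
#' effects spanning 0.13-1.35 against unit noise.
#'
#' @param preset \code{"default"} as above; \code{"tiny"} for fast smoke
#'   tests (80 individuals, 12 genes); \code{"gaw17_scale"} for a full-size
#'   run (3,205 genes, 39 causal variants in 9 genes).
#' @param ... named fields overriding the preset (see
#'   \code{\link{simulate_genotypes}} and \code{\link{simulate_trait}} for
#'   their meaning): \code{n_individuals}, \code{n_genes},
#'   \code{gene_size_theta}, \code{maf_shape1}, \code{maf_shape2},
#'   \code{maf_floor}, \code{causal_spec} (list of groups, each with
#'   \code{n}, \code{effects}, and optional \code{mafs}),
#'   \code{effect_range}, \code{noise_sd}, \code{smoke_prev},
#'   \code{age_range}, \code{covariate_coefs}, \code{interaction}
#'   (\code{NULL} or \code{list(gene = <causal group index>, multiplier)}),
#'   \code{ld_rho} (\code{NULL} for independent sites).
#' @return list of class \code{"synthetic_config"}.
#' @export
synthetic_config <- function(preset = c("default", "tiny", "gaw17_scale"),
                             ...) {
  preset <- match.arg(preset)
  base <- list(
    n_individuals = 697L,
    n_genes = 200L,
    gene_size_theta = 0.93,
    maf_shape1 = 0.3,
    maf_shape2 = 2.5,
    maf_floor = 1 / (2 * 697),
    causal_spec = list(
      list(n = 5L, effects = c(1.35, 1.25, 1.15, 1.00, 0.85),
           mafs = c(0.02, 0.06, 0.005, 0.10, 0.30)),
      list(n = 3L, effects = c(0.70, 0.55, 0.40),
           mafs = c(0.012, 0.08, 0.16)),
      list(n = 2L, effects = c(0.25, 0.13),
           mafs = c(0.003, 0.001))),
    effect_range = c(0.13, 1.35),
    noise_sd = 1,
    smoke_prev = 0.3,
    age_range = c(30L, 70L),
    covariate_coefs = c(Smoke = 0.5, Age = 0.02, Sex = 0.2),
    interaction = NULL,
    ld_rho = NULL)
  if (preset == "tiny") {
    base$n_individuals <- 80L
    base$n_genes <- 12L
    base$gene_size_theta <- 0.8
    base$maf_floor <- 1 / (2 * 80)
    base$causal_spec <- list(
      list(n = 2L, effects = c(1.0, 0.8), mafs = c(0.2, 0.3)))
  } else if (preset == "gaw17_scale") {
    base$n_genes <- 3205L
    # 39 causal variants in 9 genes; effects spread over the declared range
    sizes <- c(11L, 8L, 5L, 4L, 3L, 3L, 2L, 2L, 1L)
    eff <- seq(1.35, 0.13, length.out = 39)
    at <- 0L
    base$causal_spec <- lapply(sizes, function(s) {
      g <- list(n = s, effects = eff[at + seq_len(s)], mafs = NULL)
      at <<- at + s
      g
    })
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(base))
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  # whole-value replacement (modifyList would merge nested lists)
  base[names(dots)] <- dots
  cfg <- base
  for (grp in cfg$causal_spec) {
    if (length(grp$effects) != grp$n)
      stop("causal group: effects length must equal n")
    if (any(grp$effects < cfg$effect_range[1] - 1e-12) ||
        any(grp$effects > cfg$effect_range[2] + 1e-12))
      stop("causal effects outside the declared effect range [",
           cfg$effect_range[1], ", ", cfg$effect_range[2], "]")
    if (!is.null(grp$mafs) && length(grp$mafs) != grp$n)
      stop("causal group: mafs length must equal n")
  }
  structure(cfg, class = "synthetic_config")
}

# Log-series distribution on {1, 2, ...}: P(k) proportional to theta^k / k.
# Heavy right tail gives the "few huge genes, many single-variant genes"
# shape of exome variant counts.
.rlogseries <- function(n, theta, kmax = 2000L) {
  k <- seq_len(kmax)
  pk <- theta^k / k
  sample.int(kmax, n, replace = TRUE, prob = pk)
}

# Truncated scaled-Beta MAF spectrum: maf = qbeta(u, a, b)/2 with u drawn
# uniformly above the floor's quantile.  cdf available in closed form for
# distributional tests.
.rmaf <- function(n, shape1, shape2, floor_) {
  lo <- pbeta(2 * floor_, shape1, shape2)
  0.5 * qbeta(runif(n, lo, 1), shape1, shape2)
}

#' CDF of the generator's MAF spectrum
#'
#' @param q quantiles.
#' @param config a \code{\link{synthetic_config}}.
#' @return cumulative probabilities of the truncated scaled-Beta spectrum.
#' @export
pmaf_spectrum <- function(q, config) {
  lo <- pbeta(2 * config$maf_floor, config$maf_shape1, config$maf_shape2)
  pmin(pmax((pbeta(2 * q, config$maf_shape1, config$maf_shape2) - lo) /
              (1 - lo), 0), 1)
}

#' Simulate genotypes and a gene map
#'
#' Gene variant counts are log-series; per-variant allele frequencies come
#' from the rare-skewed spectrum (causal variants may have fixed
#' frequencies from the causal plan); genotypes are binomial(2, maf) per
#' individual, independent across sites unless \code{ld_rho} requests the
#' shared within-gene haplotype factor.  Variants monomorphic in the
#' realized sample are redrawn, mirroring sites ascertained by observed
#' polymorphism.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @param seed optional integer; when NULL the current RNG state is used.
#' @return list with \code{genotypes} (\code{\link{genotype_matrix}}),
#'   \code{gene_map}, \code{maf_params} (the drawn frequency of every
#'   variant) and \code{causal} (data.frame variant_id, gene_id, effect,
#'   maf).
#' @export
simulate_genotypes <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_individuals
  sizes <- .rlogseries(config$n_genes, config$gene_size_theta)

  # host each causal group in the lowest-index unused gene big enough
  groups <- config$causal_spec
  need <- vapply(groups, `[[`, integer(1), "n")
  host <- integer(length(groups))
  used <- logical(config$n_genes)
  for (gi in order(-need)) {
    ok <- which(!used & sizes >= need[gi])
    if (!length(ok))
      stop("no gene large enough to host a causal group of ", need[gi],
           " variants; increase n_genes or gene sizes")
    host[gi] <- ok[1]
    used[ok[1]] <- TRUE
  }

  gene_ids <- sprintf("GENE%04d", seq_len(config$n_genes))
  variant_gene <- rep(seq_len(config$n_genes), sizes)
  p <- length(variant_gene)
  variant_ids <- unlist(lapply(seq_len(config$n_genes), function(i)
    sprintf("%s_V%02d", gene_ids[i], seq_len(sizes[i]))), use.names = FALSE)

  maf <- .rmaf(p, config$maf_shape1, config$maf_shape2, config$maf_floor)
  causal_rows <- list()
  for (gi in seq_along(groups)) {
    grp <- groups[[gi]]
    cols <- which(variant_gene == host[gi])[seq_len(grp$n)]
    if (!is.null(grp$mafs)) maf[cols] <- grp$mafs
    causal_rows[[gi]] <- data.frame(variant_id = variant_ids[cols],
                                    gene_id = gene_ids[host[gi]],
                                    effect = grp$effects,
                                    maf = maf[cols])
  }
  causal <- do.call(rbind, causal_rows)

  draw <- function(cols) {
    if (is.null(config$ld_rho)) {
      matrix(rbinom(n * length(cols), 2L, rep(maf[cols], each = n)),
             n, length(cols))
    } else {
      # shared latent haplotype factor per gene block, Gaussian copula
      out <- matrix(0L, n, length(cols))
      r <- config$ld_rho
      for (hap in 1:2) {
        w <- rnorm(n)
        z <- sqrt(r) * w + sqrt(1 - r) * matrix(rnorm(n * length(cols)),
                                                n, length(cols))
        out <- out + (z < rep(qnorm(maf[cols]), each = n))
      }
      out
    }
  }

  vals <- matrix(0L, n, p)
  for (g in seq_len(config$n_genes)) {
    cols <- which(variant_gene == g)
    vals[, cols] <- draw(cols)
  }
  # ascertainment: redraw sites that came out monomorphic
  for (tries in 1:50) {
    mono <- which(colSums(vals) == 0L | colSums(vals) == 2L * n)
    if (!length(mono)) break
    vals[, mono] <- draw(mono)
  }
  if (length(mono <- which(colSums(vals) == 0L | colSums(vals) == 2L * n)))
    vals[1, mono] <- 1L   # force one heterozygote at pathologically rare sites

  g <- genotype_matrix(vals, variant_ids = variant_ids,
                       individual_ids = sprintf("IND%04d", seq_len(n)))
  list(genotypes = g,
       gene_map = gene_map(setNames(gene_ids[variant_gene], variant_ids)),
       maf_params = setNames(maf, variant_ids),
       causal = causal)
}

#' Simulate the quantitative trait
#'
#' trait = sum(effect_j * minor-allele count_j) + covariate part +
#' optional smoking-by-gene-burden interaction + Gaussian noise.  The four
#' parts are returned separately and sum to the trait exactly.
#'
#' @param genotypes a \code{\link{genotype_matrix}}.
#' @param causal data.frame with \code{variant_id}, \code{gene_id},
#'   \code{effect} (as produced by \code{\link{simulate_genotypes}}).
#' @param config a \code{\link{synthetic_config}}.
#' @param seed optional integer.
#' @return list with \code{pheno} (data.frame: individual_id, trait,
#'   Smoke, Age, Sex) and \code{truth} (causal table, causal gene ids,
#'   per-gene expected variance explained, trait decomposition).
#' @export
simulate_trait <- function(genotypes, causal, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(genotypes)
  miss <- setdiff(causal$variant_id, colnames(genotypes))
  if (length(miss))
    stop("causal variants absent from genotypes: ",
         paste(head(miss, 5), collapse = ", "))
  Xc <- unclass(genotypes)[, causal$variant_id, drop = FALSE]
  storage.mode(Xc) <- "double"
  genetic <- unname(drop(Xc %*% causal$effect))

  smoke <- rbinom(n, 1L, config$smoke_prev)
  age <- sample(seq(config$age_range[1], config$age_range[2]), n,
                replace = TRUE)
  sex <- rbinom(n, 1L, 0.5)
  cc <- config$covariate_coefs
  covariate <- cc[["Smoke"]] * smoke + cc[["Age"]] * age + cc[["Sex"]] * sex

  interaction <- numeric(n)
  if (!is.null(config$interaction)) {
    gene_idx <- config$interaction$gene
    grp_gene <- unique(causal$gene_id)[gene_idx]
    burden <- rowSums(Xc[, causal$gene_id == grp_gene, drop = FALSE])
    interaction <- config$interaction$multiplier * smoke * burden
  }

  noise <- rnorm(n, 0, config$noise_sd)
  trait <- genetic + covariate + interaction + noise

  maf_real <- compute_maf(genotypes)[causal$variant_id]
  var_exp <- causal$effect^2 * 2 * maf_real * (1 - maf_real)
  gene_var <- sort(tapply(var_exp, causal$gene_id, sum), decreasing = TRUE)

  list(pheno = data.frame(individual_id = rownames(genotypes),
                          trait = trait, Smoke = smoke, Age = age,
                          Sex = sex),
       truth = list(causal = causal,
                    causal_genes = unique(causal$gene_id),
                    gene_variance_explained = gene_var,
                    strongest_gene = names(gene_var)[1],
                    decomposition = list(genetic = genetic,
                                         covariate = covariate,
                                         interaction = interaction,
                                         noise = noise)))
}

#' Simulate one full replicate
#'
#' @param config a \code{\link{synthetic_config}}.
#' @param seed integer seed; the replicate is fully reproducible from it.
#' @return list of class \code{"bfs_replicate"} with \code{genotypes},
#'   \code{gene_map}, \code{maf_params}, \code{pheno}, \code{truth},
#'   \code{config}, \code{seed}.
#' @export
simulate_replicate <- function(config = synthetic_config(), seed = 1L) {
  set.seed(seed)
  gen <- simulate_genotypes(config)
  tr <- simulate_trait(gen$genotypes, gen$causal, config)
  structure(c(gen[c("genotypes", "gene_map", "maf_params")], tr,
              list(config = config, seed = as.integer(seed))),
            class = "bfs_replicate")
}

#' @export
print.bfs_replicate <- function(x, ...) {
  cat("bfs_replicate: ", nrow(x$genotypes), " individuals, ",
      ncol(x$genotypes), " variants in ",
      length(attr(x$gene_map, "gene_sizes")), " genes, ",
      nrow(x$truth$causal), " causal variants in ",
      length(x$truth$causal_genes), " genes (seed ", x$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Write a replicate to plain-text files
#'
#' Emits the genotype TSV, gene-map TSV and phenotype TSV consumed by the
#' loaders, plus the causal truth as JSON.
#'
#' @param replicate a \code{"bfs_replicate"}.
#' @param dir output directory (created if needed).
#' @return named character vector of the four file paths.
#' @export
write_dataset <- function(replicate, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genotypes = file.path(dir, "genotypes.tsv"),
             gene_map = file.path(dir, "gene_map.tsv"),
             pheno = file.path(dir, "phenotypes.tsv"),
             truth = file.path(dir, "truth.json"))
  write_genotypes(replicate$genotypes, paths[["genotypes"]])
  write_gene_map(replicate$gene_map, paths[["gene_map"]])
  write.table(replicate$pheno, paths[["pheno"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(list(causal = replicate$truth$causal,
                            causal_genes = replicate$truth$causal_genes,
                            strongest_gene = replicate$truth$strongest_gene,
                            seed = replicate$seed),
                       paths[["truth"]], auto_unbox = TRUE, digits = NA)
  paths
}
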