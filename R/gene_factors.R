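# Gene-as-factor mode: all variants of a gene enter or leave the model
# together.  Model designs then have varying column counts, so the
# size-penalized prior (proportional to exp(-k/2), k = number of
# regression coefficients) is used to offset the advantage large genes
# would otherwise get.  Gene-level statements can also be derived from a
# SNP-level run by averaging variant posteriors within each gene.

#' Design matrix for a set of active genes
#'
#' @param active_genes character vector of gene ids (the m active genes).
#' @param gene_map a \code{\link{gene_map}}.
#' @param genotypes a \code{\link{genotype_matrix}}.
#' @return An object of class \code{"gene_model_design"}: list with
#'   \code{columns} (centered design, one column per variant of every
#'   active gene, blocks ordered by gene then variant), \code{k},
#'   \code{block_sizes}, \code{active_genes}, \code{variant_ids}.
#' @export
build_gene_design <- function(active_genes, gene_map, genotypes) {
  unknown <- setdiff(active_genes, unique(as.character(gene_map)))
  if (length(unknown))
    stop("unknown gene(s): ", paste(unknown, collapse = ", "))
  assign_ <- as.character(gene_map[colnames(genotypes)])
  vars <- lapply(active_genes, function(g) colnames(genotypes)[which(assign_ == g)])
  if (any(lengths(vars) == 0L))
    stop("gene(s) with no genotyped variants: ",
         paste(active_genes[lengths(vars) == 0L], collapse = ", "))
  ids <- unlist(vars, use.names = FALSE)
  structure(list(columns = center_columns(genotypes, ids),
                 k = length(ids),
                 block_sizes = lengths(vars),
                 active_genes = active_genes,
                 variant_ids = ids),
            class = "gene_model_design")
}

#' Gene-level summary derived from a SNP-level run
#'
#' For each gene, the mean marginal posterior probability over its
#' variants is compared with the per-variant prior inclusion probability,
#' which is m/p under the uniform model prior over size-m models.
#'
#' @param snp_summary an \code{"inclusion_summary"} from a SNP-mode chain.
#' @param gene_map a \code{\link{gene_map}} covering every summarized
#'   variant.
#' @param m,p model size and variant count; default from the summary.
#' @return data.frame with columns \code{gene_id}, \code{n_variants},
#'   \code{mean_posterior}, \code{posterior_prior_ratio}, sorted by
#'   decreasing ratio.
#' @export
gene_summary_from_snp_run <- function(snp_summary, gene_map,
                                      m = snp_summary$m,
                                      p = snp_summary$p) {
  probs <- snp_summary$probabilities
  mapped <- names(probs) %in% names(gene_map)
  if (!all(mapped))
    stop("variants missing from gene map: ",
         paste(head(names(probs)[!mapped], 5), collapse = ", "))
  genes <- as.character(gene_map[names(probs)])
  mean_post <- tapply(probs, genes, mean)
  nv <- tapply(probs, genes, length)
  empty <- setdiff(unique(as.character(gene_map)), names(mean_post))
  if (length(empty))
    warning("gene(s) with no summarized variants excluded: ",
            paste(head(empty, 5), collapse = ", "), call. = FALSE)
  prior_per_variant <- m / p
  out <- data.frame(gene_id = names(mean_post),
                    n_variants = as.integer(nv),
                    mean_posterior = as.numeric(mean_post),
                    posterior_prior_ratio = as.numeric(mean_post) / prior_per_variant,
                    row.names = NULL)
  out[order(-out$posterior_prior_ratio, out$gene_id), , drop = FALSE]
}

#' Gene-level screening by MCMC
#'
#' Convenience wrapper around \code{\link{run_chain}} with
#' \code{factor_mode = "gene"}.  The supplied prior should normally use
#' \code{model_prior = "size_penalized"}: gene models have as many
#' coefficients as their genes have variants, and the exp(-k/2) prior
#' keeps large genes from being favored purely for their parameter count.
#'
#' @inheritParams run_chain
#' @return An \code{"inclusion_summary"} over genes, with the underlying
#'   \code{"bfs_chain"} attached as attribute \code{"chain"}.
#' @export
run_gene_screen <- function(genotypes, response, gene_map,
                            prior = prior_spec(m = 3,
                                               model_prior = "size_penalized"),
                            n_iter = 10000L, burn_in = 1000L, seed = 1L,
                            cache_max = 1e5) {
  chain <- run_chain(genotypes, response, prior, factor_mode = "gene",
                     gene_map = gene_map, n_iter = n_iter, burn_in = burn_in,
                     seed = seed, cache_max = cache_max)
  out <- marginal_inclusion(chain)
  attr(out, "chain") <- chain
  out
}
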