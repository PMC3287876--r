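# Metropolis-Hastings over the restricted model space.  States are sorted
# index sets of exactly m active factors; the proposal swaps one random
# active factor for one random inactive factor, which is symmetric
# (q = 1/(m (p - m)) both ways), so the acceptance probability is the bare
# posterior ratio min{exp(delta log posterior), 1}.  Marginal inclusion
# probabilities are visit counts: every post-burn-in iteration contributes
# its state, repeats included.

#' Swap proposal over fixed-size factor sets
#'
#' Replaces one uniformly chosen active factor with one uniformly chosen
#' inactive factor; the returned state differs from the input in exactly
#' two positions.
#'
#' @param state sorted integer vector of active factor indices.
#' @param p total number of candidate factors.
#' @return sorted integer vector of the same length.
#' @export
propose_swap <- function(state, p) {
  m <- length(state)
  if (m >= p) stop("no inactive factor to swap in (m = p)")
  if (m < 1L) stop("no active factor to swap out")
  drop_at <- sample.int(m, 1L)
  inactive <- seq_len(p)[-state]
  add <- inactive[sample.int(p - m, 1L)]
  sort.int(c(state[-drop_at], add))
}

#' One Metropolis-Hastings accept/reject step
#'
#' Accepts the proposal with probability min\{exp(delta), 1\} where delta
#' is the difference of unnormalized log posteriors (model prior
#' included).  A non-finite proposal log posterior is treated as -Inf and
#' auto-rejected.
#'
#' @param state current factor set.
#' @param proposal proposed factor set.
#' @param log_posterior_fn function(active_indices) -> unnormalized log
#'   posterior.
#' @return the chosen state, with attribute \code{"accepted"} (logical).
#' @export
mh_step <- function(state, proposal, log_posterior_fn) {
  lp_cur <- log_posterior_fn(state)
  lp_prop <- log_posterior_fn(proposal)
  delta <- lp_prop - lp_cur
  accepted <- is.finite(lp_prop) && (delta >= 0 || log(runif(1L)) < delta)
  out <- if (accepted) proposal else state
  attr(out, "accepted") <- accepted
  out
}

# Shared sampler core.  log_post_fn is evaluated once per distinct model
# (bounded cache, flushed when full).  RNG: one seed governs the initial
# state, every proposal, and every acceptance draw, so a chain is
# bit-reproducible from (data, prior, n_iter, burn_in, seed).
.mh_engine <- function(log_post_fn, p, m, n_iter, burn_in, seed,
                       cache_max = 1e5, audit = FALSE) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  cache <- new.env(hash = TRUE, parent = emptyenv())
  cache_n <- 0L
  lp_of <- function(idx) {
    key <- paste(idx, collapse = ".")
    v <- cache[[key]]
    if (is.null(v)) {
      v <- log_post_fn(idx)
      if (!is.finite(v)) v <- -Inf
      if (cache_n >= cache_max) {
        rm(list = ls(cache, all.names = TRUE), envir = cache)
        cache_n <<- 0L
      }
      assign(key, v, envir = cache)
      cache_n <<- cache_n + 1L
    }
    v
  }

  active <- sort.int(sample.int(p, m))
  cur_lp <- lp_of(active)
  visits <- matrix(0L, nrow = n_iter, ncol = m)
  n_accept <- 0L
  total <- burn_in + n_iter
  audit_rows <- if (audit) vector("character", total)
  init_state <- active

  for (j in seq_len(total)) {
    prop <- propose_swap(active, p)
    prop_lp <- lp_of(prop)
    delta <- prop_lp - cur_lp
    accepted <- is.finite(prop_lp) &&
      (delta >= 0 || log(runif(1L)) < delta)
    if (accepted) {
      active <- prop
      cur_lp <- prop_lp
      if (j > burn_in) n_accept <- n_accept + 1L
    }
    if (j > burn_in) visits[j - burn_in, ] <- active
    if (audit)
      audit_rows[j] <- paste(j - burn_in, paste(prop, collapse = ","),
                             sprintf("%.10g", delta), as.integer(accepted),
                             sep = "\t")
  }

  list(visits = visits, n_accept = n_accept, init_state = init_state,
       audit_rows = audit_rows)
}

#' Run a factor-screening MCMC chain
#'
#' Samples models of exactly \code{prior$m} active factors.  In SNP mode
#' each variant is a factor and every model has m design columns.  In gene
#' mode each gene is a factor; a model's design holds the centered columns
#' of every variant in its m active genes, so the column count k varies
#' between models and the size-penalized model prior (see
#' \code{\link{prior_spec}}) is the appropriate choice.
#'
#' @param genotypes a \code{\link{genotype_matrix}}.
#' @param response the covariate-adjusted trait: a
#'   \code{\link{residualize}} result or a numeric vector (centered
#'   internally if not already mean zero).
#' @param prior a \code{\link{prior_spec}}; \code{prior$m} is the model
#'   size.
#' @param factor_mode \code{"snp"} or \code{"gene"}.
#' @param gene_map required in gene mode; every genotyped variant must be
#'   mapped.
#' @param n_iter post-burn-in chain length; defaults to 100000 in SNP mode
#'   and 10000 in gene mode.
#' @param burn_in discarded initial iterations (default 1000).
#' @param seed integer seed; the chain is bit-reproducible given the seed.
#' @param cache_max maximum number of distinct models kept in the evidence
#'   cache (flushed when full).
#' @param audit_file optional path; writes a gzipped TSV with one row per
#'   iteration (iteration, proposed set, delta log posterior, accepted)
#'   from which the chain can be replayed with
#'   \code{\link{replay_chain_audit}}.
#' @return An object of class \code{"bfs_chain"}: list with \code{visits}
#'   (n_iter x m integer matrix of active factor indices), \code{n_accept},
#'   \code{acceptance_rate}, \code{factor_ids}, \code{factor_mode},
#'   \code{m}, \code{p}, \code{n_iter}, \code{burn_in}, \code{seed},
#'   \code{prior}.
#' @export
run_chain <- function(genotypes, response, prior = prior_spec(),
                      factor_mode = c("snp", "gene"), gene_map = NULL,
                      n_iter = NULL, burn_in = 1000L, seed = 1L,
                      cache_max = 1e5, audit_file = NULL) {
  factor_mode <- match.arg(factor_mode)
  y <- if (inherits(response, "residual_trait")) response$values
       else as.numeric(response)
  if (length(y) != nrow(genotypes))
    stop("response length does not match number of genotyped individuals")
  y <- y - mean(y)
  if (is.null(n_iter))
    n_iter <- if (factor_mode == "snp") 100000L else 10000L
  if (n_iter < 1L) stop("n_iter must be >= 1")
  m <- prior$m

  Gc <- center_columns(genotypes, seq_len(ncol(genotypes)))
  if (any(colSums(Gc != 0) == 0L))
    warning("monomorphic variant(s) present; their design columns are all ",
            "zero and carry no evidence", call. = FALSE)

  if (factor_mode == "snp") {
    p <- ncol(genotypes)
    factor_ids <- colnames(genotypes)
    if (m >= p) stop("model size m must be smaller than the number of variants")
    # fixed k = m: precompute the prior square-root block once
    sigma <- build_sigma(m, prior$sigma_structure, prior$rho)
    root <- .sigma_inv_root(sigma, m)
    log_post_fn <- function(idx) {
      ev <- .evidence_qr(y, Gc[, idx, drop = FALSE], prior$lambda,
                         root$C, root$logdet_sigma)
      log_model_posterior(ev, prior)
    }
  } else {
    if (is.null(gene_map)) stop("gene mode requires a gene_map")
    unmapped <- setdiff(colnames(genotypes), names(gene_map))
    if (length(unmapped))
      stop("gene mode requires every variant to be mapped to a gene; ",
           "unmapped: ", paste(head(unmapped, 5), collapse = ", "))
    factor_ids <- sort(unique(as.character(gene_map[colnames(genotypes)])))
    p <- length(factor_ids)
    if (m >= p) stop("model size m must be smaller than the number of genes")
    gene_cols <- lapply(factor_ids, function(g)
      which(as.character(gene_map[colnames(genotypes)]) == g))
    log_post_fn <- function(idx) {
      cols <- unlist(gene_cols[idx], use.names = FALSE)
      k <- length(cols)
      bs <- lengths(gene_cols[idx])
      sigma <- build_sigma(k, prior$sigma_structure, prior$rho,
                           block_sizes = bs)
      root <- .sigma_inv_root(sigma, k)
      ev <- .evidence_qr(y, Gc[, cols, drop = FALSE], prior$lambda,
                         root$C, root$logdet_sigma)
      log_model_posterior(ev, prior)
    }
  }

  res <- .mh_engine(log_post_fn, p, m, n_iter, burn_in, seed,
                    cache_max = cache_max, audit = !is.null(audit_file))
  if (!is.null(audit_file)) {
    con <- gzfile(audit_file, "w")
    writeLines(c(paste0("#init\t", paste(res$init_state, collapse = ",")),
                 paste("iteration", "proposed", "delta_log_posterior",
                       "accepted", sep = "\t"),
                 res$audit_rows), con)
    close(con)
  }
  structure(list(visits = res$visits, n_accept = res$n_accept,
                 acceptance_rate = res$n_accept / n_iter,
                 factor_ids = factor_ids, factor_mode = factor_mode,
                 m = m, p = p, n_iter = n_iter, burn_in = as.integer(burn_in),
                 seed = as.integer(seed), prior = prior),
            class = "bfs_chain")
}

#' @export
print.bfs_chain <- function(x, ...) {
  cat("bfs_chain (", x$factor_mode, " mode): ", x$n_iter,
      " iterations after ", x$burn_in, " burn-in, m = ", x$m, " of p = ",
      x$p, " factors, acceptance rate ",
      signif(x$acceptance_rate, 3), ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Replay a chain from its audit log
#'
#' Reconstructs the post-burn-in visit sequence from the gzipped audit TSV
#' written by \code{\link{run_chain}}, so any report can be regenerated
#' without re-running the sampler.
#'
#' @param path audit file path.
#' @return integer visit matrix as in a \code{"bfs_chain"}.
#' @export
replay_chain_audit <- function(path) {
  lines <- readLines(path)
  init <- as.integer(strsplit(sub("^#init\t", "", lines[1]), ",")[[1]])
  rows <- read.delim(textConnection(lines[-1]),
                     colClasses = c("integer", "character", "numeric",
                                    "integer"))
  m <- length(init)
  post <- rows$iteration >= 1L
  visits <- matrix(0L, sum(post), m)
  active <- init
  at <- 0L
  for (r in seq_len(nrow(rows))) {
    if (rows$accepted[r] == 1L)
      active <- as.integer(strsplit(rows$proposed[r], ",")[[1]])
    if (rows$iteration[r] >= 1L) {
      at <- at + 1L
      visits[at, ] <- active
    }
  }
  visits
}

#' Marginal posterior inclusion probabilities from a chain
#'
#' The probability for factor i is the fraction of post-burn-in iterations
#' whose model includes i; the probabilities sum to m by construction.
#'
#' @param chain a \code{"bfs_chain"}, or a bare integer visit matrix.
#' @param p number of candidate factors (taken from the chain when given).
#' @param factor_ids optional factor names.
#' @return An object of class \code{"inclusion_summary"}: list with
#'   \code{probabilities} (length p), \code{factor_ids}, \code{m},
#'   \code{p}, \code{n_iter}.
#' @export
marginal_inclusion <- function(chain, p = NULL, factor_ids = NULL) {
  if (inherits(chain, "bfs_chain")) {
    visits <- chain$visits
    p <- chain$p
    factor_ids <- chain$factor_ids
    m <- chain$m
  } else {
    visits <- chain
    if (is.null(p)) stop("p is required when passing a bare visit matrix")
    m <- ncol(visits)
  }
  if (nrow(visits) == 0L) stop("empty chain")
  counts <- tabulate(visits, nbins = p)
  probs <- counts / nrow(visits)
  if (is.null(factor_ids)) factor_ids <- as.character(seq_len(p))
  structure(list(probabilities = setNames(probs, factor_ids),
                 factor_ids = factor_ids, m = as.integer(m),
                 p = as.integer(p), n_iter = nrow(visits)),
            class = "inclusion_summary")
}

#' @export
print.inclusion_summary <- function(x, n = 10L, ...) {
  cat("inclusion_summary: p = ", x$p, ", m = ", x$m, ", ", x$n_iter,
      " iterations\nTop factors:\n", sep = "")
  ord <- order(-x$probabilities, x$factor_ids)
  print(round(x$probabilities[ord[seq_len(min(n, x$p))]], 4))
  invisible(x)
}

#' Two-chain convergence diagnostic
#'
#' Correlation between the marginal inclusion probabilities of two chains
#' run with different seeds; values near 1 suggest both chains explored
#' the same posterior.  Diagnostic only - no threshold is enforced.
#'
#' @param summary_a,summary_b \code{"inclusion_summary"} objects over the
#'   same factors.
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @return correlation in [-1, 1].
#' @export
convergence_check <- function(summary_a, summary_b,
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (summary_a$p != summary_b$p ||
      !identical(summary_a$factor_ids, summary_b$factor_ids))
    stop("summaries are not over the same factor set")
  a <- summary_a$probabilities
  b <- summary_b$probabilities
  if (sd(a) == 0 || sd(b) == 0)
    stop("degenerate run: an inclusion vector has zero variance")
  cor(a, b, method = method)
}
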