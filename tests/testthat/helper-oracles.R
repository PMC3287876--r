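# Independent reference computations used to check the closed-form
# evidence path, plus small fixture builders.  Nothing here touches the
# package's QR route.

# Marginal likelihood by direct integration: sigma^2 integrated
# analytically (inverse-gamma), then adaptive numerical quadrature over
# beta (nested infinite-range integrate for k = 2).  Includes all
# constants:
#   p(y) = |Lambda|^(-1/2) pi^(-(n+k)/2) Gamma((n+k)/2)
#          * int A(beta)^(-(n+k)/2) dbeta,
#   A(beta) = ||y - X beta||^2 + beta' Lambda^(-1) beta.
oracle_log_marginal <- function(y, X, lambda, sigma) {
  X <- as.matrix(X)
  n <- length(y)
  k <- ncol(X)
  Lambda <- lambda^2 * sigma
  Li <- solve(Lambda)
  pow <- (n + k) / 2
  dens <- function(beta) {
    r <- y - X %*% beta
    exp(-pow * log(sum(r * r) + drop(crossprod(beta, Li %*% beta))))
  }
  I <- if (k == 1L) {
    integrate(function(b) vapply(b, dens, numeric(1)), -Inf, Inf,
              rel.tol = 1e-10, subdivisions = 1000L)$value
  } else if (k == 2L) {
    inner <- function(b1)
      integrate(function(b2) vapply(b2, function(v) dens(c(b1, v)),
                                    numeric(1)),
                -Inf, Inf, rel.tol = 1e-9, subdivisions = 500L)$value
    integrate(function(b1) vapply(b1, inner, numeric(1)), -Inf, Inf,
              rel.tol = 1e-8, subdivisions = 500L)$value
  } else stop("oracle supports k <= 2")
  -0.5 * as.numeric(determinant(Lambda)$modulus) - pow * log(pi) +
    lgamma(pow) + log(I)
}

# Evidence by explicit normal equations (no QR anywhere): Q from
# y'y - y'X (X'X + Lambda^-1)^-1 X'y, determinants directly.
naive_evidence <- function(y, X, lambda, sigma) {
  X <- as.matrix(X)
  Lambda <- lambda^2 * sigma
  M <- crossprod(X) + solve(Lambda)
  xty <- crossprod(X, y)
  q <- sum(y^2) - drop(crossprod(xty, solve(M, xty)))
  logdet <- as.numeric(determinant(M)$modulus) +
    as.numeric(determinant(Lambda)$modulus)
  list(q_gamma = q,
       log_marginal = -0.5 * logdet - (length(y) / 2) * log(q))
}

# Minimal VCF fixture: gts is a variants x samples character matrix of GT
# strings ("0/0", "0/1", "1/1", "./.").
write_test_vcf <- function(path, gts, ref = "A", alt = "C") {
  samples <- colnames(gts)
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(gts)))
  ids <- rownames(gts)
  if (is.null(ids)) ids <- paste0("var", seq_len(nrow(gts)))
  ref <- rep_len(ref, nrow(gts))
  alt <- rep_len(alt, nrow(gts))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(gts)), function(i)
    paste(c("1", i, ids[i], ref[i], alt[i], ".", "PASS", ".", "GT",
            gts[i, ]), collapse = "\t"), character(1))
  writeLines(c(header, body), path)
  path
}

# Inclusion summary built directly from a probability vector.
make_summary <- function(probs, ids = sprintf("F%02d", seq_along(probs)),
                         m = round(sum(probs))) {
  structure(list(probabilities = stats::setNames(probs, ids),
                 factor_ids = ids, m = as.integer(m),
                 p = length(probs), n_iter = NA_integer_),
            class = "inclusion_summary")
}

# Small polymorphic genotype matrix with reproducible content.
random_genotypes <- function(n, p, maf = 0.3, seed = 1) {
  set.seed(seed)
  repeat {
    vals <- matrix(rbinom(n * p, 2, maf), n, p)
    if (all(colSums(vals) > 0 & colSums(vals) < 2 * n)) break
  }
  genotype_matrix(vals)
}

# Centered-column design provider over a genotype matrix (SNP mode).
snp_provider <- function(g) function(idx) center_columns(g, idx)

# Gene-mode design provider: factors are gene ids in sorted order.
gene_provider <- function(g, map) {
  genes <- sort(unique(as.character(map)))
  function(idx) {
    d <- build_gene_design(genes[idx], map, g)
    out <- d$columns
    attr(out, "block_sizes") <- d$block_sizes
    out
  }
}

# Total-variation distance between chain visit frequencies and an
# exhaustive posterior over the same model space.
visit_tv_distance <- function(chain, exh) {
  key <- vapply(exh$active, paste, character(1), collapse = ".")
  freq <- table(apply(chain$visits, 1, paste, collapse = "."))
  emp <- stats::setNames(numeric(length(key)), key)
  emp[names(freq)] <- as.numeric(freq) / chain$n_iter
  0.5 * sum(abs(emp - exh$posterior))
}
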