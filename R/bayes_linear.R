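# Closed-form model evidence for fixed-size linear models under the
# conjugate prior
#
#   y = X beta + eps,   eps ~ N(0, sigma^2 I)
#   beta | sigma^2 ~ N(0, sigma^2 lambda^2 Sigma),   p(sigma^2) ~ 1/sigma^2
#
# Integrating out beta and sigma^2 gives, up to a constant shared by all
# models on the same data,
#
#   p(y | gamma) propto |lambda^2 Sigma|^(-1/2)
#                       |X'X + (lambda^2 Sigma)^(-1)|^(-1/2)
#                       Q(gamma)^(-n/2)
#
# with Q(gamma) = y'y - y'X (X'X + (lambda^2 Sigma)^(-1))^(-1) X'y.  Both
# Q and the determinant come from one QR decomposition of the augmented
# design Xt = rbind(X, C / lambda) with C'C = Sigma^(-1) against the
# augmented response yt = c(y, 0_k): Q is the residual sum of squares and
# |Xt'Xt| is the squared product of the R diagonal.  Everything is kept in
# log space; with n in the hundreds, Q^(-n/2) underflows otherwise.

#' Prior specification for factor screening
#'
#' @param lambda positive scale of the effect-size prior.  The default 1
#'   suits effects on the order of the trait's residual standard deviation.
#' @param m number of active factors per model (fixed model size).
#' @param sigma_structure \code{"identity"} (no prior correlation between
#'   effects) or \code{"exchangeable"} (constant correlation \code{rho}
#'   between effects of variants within the same gene).
#' @param rho within-block prior correlation, in [0, 1); used only for the
#'   exchangeable structure.
#' @param model_prior \code{"uniform"} (all models of size m equally
#'   likely; appropriate when every model has the same parameter count) or
#'   \code{"size_penalized"} (prior proportional to exp(-k/2) with k the
#'   number of regression coefficients; the BIC-style penalty used when
#'   genes of unequal size are the factors).
#' @param size_penalty penalty form for \code{"size_penalized"}:
#'   \code{"half_k"} is exp(-k/2); \code{"bic_log_n"} is the
#'   exp(-(k/2) log n) variant, provided for comparison and off by default.
#' @return An object of class \code{"prior_spec"}.
#' @export
prior_spec <- function(lambda = 1, m = 10,
                       sigma_structure = c("identity", "exchangeable"),
                       rho = 0.1,
                       model_prior = c("uniform", "size_penalized"),
                       size_penalty = c("half_k", "bic_log_n")) {
  sigma_structure <- match.arg(sigma_structure)
  model_prior <- match.arg(model_prior)
  size_penalty <- match.arg(size_penalty)
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0)
    stop("lambda must be a single positive number")
  if (m < 1L || m != round(m)) stop("m must be a positive integer")
  if (sigma_structure == "exchangeable" && (rho < 0 || rho >= 1))
    stop("rho must be in [0, 1) to keep the prior covariance positive definite")
  structure(list(lambda = lambda, m = as.integer(m),
                 sigma_structure = sigma_structure, rho = rho,
                 model_prior = model_prior, size_penalty = size_penalty),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("prior_spec: lambda = ", x$lambda, ", m = ", x$m,
      ", Sigma = ", x$sigma_structure,
      if (x$sigma_structure == "exchangeable") paste0(" (rho = ", x$rho, ")"),
      ", model prior = ", x$model_prior, "\n", sep = "")
  invisible(x)
}

#' Prior covariance structure Sigma for a model's coefficients
#'
#' @param k number of design columns.
#' @param structure \code{"identity"} or \code{"exchangeable"}.
#' @param rho within-block correlation for the exchangeable structure.
#' @param block_sizes integer vector summing to \code{k}; each block (one
#'   per active gene) gets 1 on the diagonal and \code{rho} off-diagonal,
#'   with zero correlation across blocks.  Defaults to a single block.
#' @return k x k symmetric positive-definite matrix.
#' @export
build_sigma <- function(k, structure = c("identity", "exchangeable"),
                        rho = 0.1, block_sizes = NULL) {
  structure <- match.arg(structure)
  if (structure == "identity") return(diag(1, k))
  if (rho < 0 || rho >= 1)
    stop("rho must be in [0, 1): rho >= 1 gives a singular prior")
  if (is.null(block_sizes)) block_sizes <- k
  if (sum(block_sizes) != k)
    stop("block sizes must sum to the number of design columns")
  sig <- matrix(0, k, k)
  at <- 0L
  for (b in block_sizes) {
    idx <- at + seq_len(b)
    sig[idx, idx] <- rho
    at <- at + b
  }
  diag(sig) <- 1
  sig
}

#' Log marginal likelihood of one model (augmented-QR route)
#'
#' @param y centered response vector (covariate residuals).
#' @param X n x k matrix of centered design columns for the model's active
#'   factors.
#' @param prior a \code{\link{prior_spec}} (its \code{lambda} is used).
#' @param sigma k x k symmetric positive-definite prior correlation matrix;
#'   defaults to the identity.
#' @param warn_degenerate warn when a design column is all zero (e.g. a
#'   monomorphic variant).  Such columns are permitted: the proper prior
#'   keeps the augmented regression full rank.
#' @return An object of class \code{"model_evidence"}: list with
#'   \code{log_marginal} (up to a model-independent constant),
#'   \code{q_gamma}, \code{log_det_penalty}, \code{k}, \code{n}.
#' @export
log_marginal_likelihood <- function(y, X, prior = prior_spec(),
                                    sigma = NULL, warn_degenerate = TRUE) {
  X <- as.matrix(X)
  n <- length(y)
  k <- ncol(X)
  if (n < 1L || k < 1L) stop("need n >= 1 observations and k >= 1 columns")
  if (nrow(X) != n) stop("nrow(X) must equal length(y)")
  if (all(y == 0)) stop("response is identically zero")
  if (is.null(sigma)) sigma <- diag(1, k)
  if (warn_degenerate && any(colSums(X != 0) == 0L))
    warning("design contains all-zero column(s); evidence is prior-dominated ",
            "for those coefficients", call. = FALSE)
  root <- .sigma_inv_root(sigma, k)   # C with C'C = Sigma^(-1)
  .evidence_qr(y, X, prior$lambda, root$C, root$logdet_sigma)
}

# Cholesky-based C with C'C = Sigma^(-1); also returns log|Sigma|.
.sigma_inv_root <- function(sigma, k) {
  sigma <- as.matrix(sigma)
  if (!isTRUE(all.equal(sigma, t(sigma), tolerance = 1e-10)))
    stop("sigma must be symmetric")
  R <- tryCatch(chol(sigma),
                error = function(e) stop("sigma is not positive definite",
                                         call. = FALSE))
  list(C = t(backsolve(R, diag(1, k))),        # R^{-T}, lower triangular
       logdet_sigma = 2 * sum(log(diag(R))))
}

# Core evidence computation shared with the sampler: one QR of the
# augmented design.
.evidence_qr <- function(y, X, lambda, C, logdet_sigma) {
  n <- length(y)
  k <- ncol(X)
  Xt <- rbind(X, C / lambda)
  yt <- c(y, numeric(k))
  fit <- .lm.fit(Xt, yt)
  q_gamma <- sum(fit$residuals^2)
  rdiag <- diag(fit$qr)[seq_len(k)]
  logdet_xtx <- 2 * sum(log(abs(rdiag)))
  logdet_lambda_sigma <- 2 * k * log(lambda) + logdet_sigma
  log_det_penalty <- -0.5 * (logdet_lambda_sigma + logdet_xtx)
  structure(list(log_marginal = log_det_penalty - (n / 2) * log(q_gamma),
                 q_gamma = q_gamma,
                 log_det_penalty = log_det_penalty,
                 k = k, n = n),
            class = "model_evidence")
}

#' @export
print.model_evidence <- function(x, ...) {
  cat("model_evidence: k = ", x$k, ", n = ", x$n,
      ", log marginal (rel.) = ", signif(x$log_marginal, 8),
      ", Q = ", signif(x$q_gamma, 8), "\n", sep = "")
  invisible(x)
}

#' Log posterior (unnormalized) of a model
#'
#' Adds the log model prior to the log marginal likelihood.  Under the
#' uniform prior the marginal is returned unchanged; under the
#' size-penalized prior the model contributes an extra -k/2 (or
#' -(k/2) log n for the \code{"bic_log_n"} variant), with k the number of
#' regression coefficients.  Only differences between models matter.
#'
#' @param evidence a \code{"model_evidence"}.
#' @param prior a \code{\link{prior_spec}}.
#' @return single numeric, up to the same shared constant as the marginal.
#' @export
log_model_posterior <- function(evidence, prior) {
  lp <- evidence$log_marginal
  if (prior$model_prior == "size_penalized") {
    pen <- switch(prior$size_penalty,
                  half_k = evidence$k / 2,
                  bic_log_n = (evidence$k / 2) * log(evidence$n))
    lp <- lp - pen
  }
  lp
}

#' Exact size of the restricted model space
#'
#' The number of models with exactly m of p factors active, choose(p, m),
#' by an exact integer recurrence (each partial product is itself a
#' binomial coefficient, so every division is exact).  Errors out beyond
#' 2^53, where double-precision integers lose exactness.
#'
#' @param p number of candidate factors.
#' @param m model size.
#' @return exact count as a numeric integer.
#' @export
count_model_space <- function(p, m) {
  if (m < 0 || m > p) stop("need 0 <= m <= p")
  m <- min(m, p - m)
  acc <- 1
  for (i in seq_len(m)) {
    acc <- acc * (p - m + i) / i
    if (acc > 2^53)
      stop("choose(", p, ", ", m, ") exceeds the exact integer range of ",
           "double precision")
  }
  acc
}

#' Prior marginal inclusion probability under the uniform model prior
#'
#' With all choose(p, m) size-m models equally likely a priori, the prior
#' probability that any given factor is active is
#' choose(p-1, m-1) / choose(p, m) = m / p; the simplified form avoids
#' evaluating binomial coefficients that overflow exact integer range.
#'
#' @param p number of candidate factors.
#' @param m model size.
#' @return m / p.
#' @export
prior_inclusion <- function(p, m) {
  if (m < 0 || m > p) stop("need 0 <= m <= p")
  m / p
}

#' Exhaustive posterior over the restricted model space
#'
#' Enumerates all choose(p, m) models, computes each model's evidence and
#' prior, and normalizes.  Intended as the exact reference for small
#' problems; refuses spaces larger than \code{cap} (use the MCMC sampler
#' instead).
#'
#' @param y centered response vector.
#' @param design_provider function(active_indices) returning the centered
#'   design matrix for that factor set; may attach an integer attribute
#'   \code{"block_sizes"} (one entry per active factor) for the
#'   exchangeable prior structure.
#' @param p number of candidate factors.
#' @param m model size.
#' @param prior a \code{\link{prior_spec}}.
#' @param cap refuse enumeration when choose(p, m) exceeds this.
#' @return data.frame with one row per model: list-column \code{active}
#'   (integer vectors), \code{log_posterior}, and normalized
#'   \code{posterior} summing to 1.
#' @export
exhaustive_posterior <- function(y, design_provider, p, m,
                                 prior = prior_spec(m = m), cap = 1e6) {
  n_models <- count_model_space(p, m)
  if (n_models > cap)
    stop("model space has ", format(n_models, big.mark = ","),
         " models (> cap ", format(cap, scientific = TRUE),
         "); use the MCMC sampler (run_chain) instead")
  sets <- combn(p, m, simplify = FALSE)
  lp <- vapply(sets, function(idx) {
    X <- design_provider(idx)
    bs <- attr(X, "block_sizes")
    sig <- build_sigma(ncol(X), prior$sigma_structure, prior$rho,
                       block_sizes = bs)
    ev <- log_marginal_likelihood(y, X, prior, sig, warn_degenerate = FALSE)
    log_model_posterior(ev, prior)
  }, numeric(1))
  post <- exp(lp - max(lp))
  post <- post / sum(post)
  out <- data.frame(model = seq_along(sets))
  out$active <- sets
  out$log_posterior <- lp
  out$posterior <- post
  out
}

#' Exact marginal inclusion probabilities from an exhaustive posterior
#'
#' @param exh result of \code{\link{exhaustive_posterior}}.
#' @param p number of candidate factors.
#' @return numeric vector of length p summing to m.
#' @export
exhaustive_marginals <- function(exh, p) {
  probs <- numeric(p)
  for (r in seq_len(nrow(exh)))
    probs[exh$active[[r]]] <- probs[exh$active[[r]]] + exh$posterior[r]
  probs
}
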