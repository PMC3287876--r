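# Two-stage covariate adjustment: the trait is regressed on the covariates
# once, up front, and the residuals serve as the response for all variant
# models.  Both the residuals and the centered genotype columns then have
# mean zero, so the variant models need no intercept.  Gene-by-environment
# interactions are deliberately not adjusted for; power against a factor
# acting only through such an interaction is reduced.

#' Remove covariate effects from a quantitative trait
#'
#' Ordinary least squares of the trait on an intercept plus the covariate
#' columns; the residuals are returned as the response for screening.
#'
#' @param trait numeric vector.
#' @param covariates numeric matrix with \code{length(trait)} rows; may
#'   have zero columns (intercept-only regression, i.e. mean-centering).
#' @return An object of class \code{"residual_trait"}: list with
#'   \code{values} (residual vector, mean 0 and orthogonal to every
#'   covariate) and \code{r_squared_covariates}.
#' @export
residualize <- function(trait, covariates = NULL) {
  y <- as.numeric(trait)
  n <- length(y)
  if (is.null(covariates)) covariates <- matrix(numeric(0), n, 0)
  covariates <- as.matrix(covariates)
  if (nrow(covariates) != n)
    stop("covariate rows (", nrow(covariates),
         ") do not match trait length (", n, ")")
  c_ <- ncol(covariates)
  if (n <= c_ + 1L)
    stop("need more observations than covariates plus intercept")
  design <- cbind(`(Intercept)` = 1, covariates)
  fit <- lm.fit(design, y)
  if (fit$rank < ncol(design)) {
    dropped <- colnames(design)[is.na(fit$coefficients)]
    stop("covariate matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  res <- unname(fit$residuals)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(res^2) / tss else 0
  structure(list(values = res, r_squared_covariates = r2),
            class = "residual_trait")
}

#' @export
print.residual_trait <- function(x, ...) {
  cat("residual_trait: n = ", length(x$values),
      ", covariate R^2 = ", signif(x$r_squared_covariates, 4), "\n", sep = "")
  invisible(x)
}
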