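# Input handling: genotype matrices, gene maps, phenotype/covariate tables.
#
# Conventions: genotypes are minor-allele counts in {0,1,2}, one row per
# individual, one column per variant.  All tables are reconciled by
# individual id, never by row position.  Missing genotypes are a hard
# error: no silent imputation.

#' Construct a genotype matrix of minor-allele counts
#'
#' @param values integer matrix, individuals x variants, entries in
#'   \{0, 1, 2\} (minor-allele counts; no missing values).
#' @param variant_ids character vector of distinct variant identifiers,
#'   one per column.
#' @param individual_ids character vector of distinct individual
#'   identifiers, one per row.
#' @return An object of class \code{"genotype_matrix"}: the integer matrix
#'   with dimnames set.
#' @export
genotype_matrix <- function(values, variant_ids = colnames(values),
                            individual_ids = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(variant_ids))
    variant_ids <- paste0("V", seq_len(ncol(values)))
  if (is.null(individual_ids))
    individual_ids <- paste0("I", seq_len(nrow(values)))
  if (nrow(values) < 2L)
    stop("a genotype matrix needs at least 2 individuals")
  if (anyNA(values))
    stop("missing genotypes are not allowed; found NA at ",
         paste(which(is.na(values))[1], collapse = ","))
  if (!all(values %in% c(0L, 1L, 2L)))
    stop("genotype entries must be minor-allele counts in {0, 1, 2}")
  if (anyDuplicated(variant_ids))
    stop("variant ids must be distinct")
  if (anyDuplicated(individual_ids))
    stop("individual ids must be distinct")
  storage.mode(values) <- "integer"
  dimnames(values) <- list(individual_ids, variant_ids)
  class(values) <- c("genotype_matrix", "matrix", "array")
  values
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix: ", nrow(x), " individuals x ", ncol(x),
      " variants\n", sep = "")
  invisible(x)
}

#' Load genotypes from TSV or VCF
#'
#' TSV layout: tab-separated with a header row of variant ids and a first
#' column of individual ids; entries are minor-allele counts 0/1/2.  VCF
#' input uses the GT field only; sites must be biallelic and fully called.
#' For VCF the minor allele is decided per site from the sample allele
#' frequency, with a frequency tie (0.5) counting ALT as minor, so the
#' loaded counts are invariant under REF/ALT label swaps.
#'
#' @param path file path.
#' @param format \code{"tsv"} or \code{"vcf"}.
#' @return A \code{\link{genotype_matrix}}.
#' @export
load_genotypes <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format, tsv = .load_genotypes_tsv(path), vcf = .load_genotypes_vcf(path))
}

.load_genotypes_tsv <- function(path) {
  tab <- read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2L)
    stop("genotype TSV parse error: need an individual-id column plus ",
         ">= 1 variant column in ", path)
  ids <- tab[[1]]
  mat <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.integer(mat), nrow(mat), ncol(mat)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop("genotype TSV parse error at line ", bad[1] + 1L, " (individual ",
         ids[bad[1]], ", variant ", colnames(mat)[bad[2]],
         "): value ", dQuote(mat[bad[1], bad[2]]),
         " is not a genotype count; missing genotypes are not supported")
  }
  genotype_matrix(num, variant_ids = colnames(mat), individual_ids = ids)
}

.load_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))   # single-record VCFs come back as a bare vector
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L) stop("VCF contains no variant records: ", path)
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi))
    stop("multiallelic site not supported: ",
         fix[which(multi)[1], "CHROM"], ":", fix[which(multi)[1], "POS"],
         " (split or drop multiallelic records upstream)")
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt)))
    gt <- matrix(gt, nrow = nrow(fix), dimnames = list(NULL, names(gt)))
  # alt dosage per genotype string; any missing allele is an error
  core <- sub(":.*$", "", gt)
  miss <- is.na(core) | grepl("\\.", core)
  if (any(miss)) {
    bad <- which(miss, arr.ind = TRUE)[1, ]
    stop("missing genotype at ", fix[bad[1], "CHROM"], ":",
         fix[bad[1], "POS"], " sample ", colnames(gt)[bad[2]],
         "; missing genotypes are not supported")
  }
  alleles <- strsplit(core, "[/|]")
  nall <- lengths(alleles)
  if (any(nall != 2L))
    stop("non-diploid genotype encountered (",
         core[which(nall != 2L)[1]], ")")
  flat <- unlist(alleles)
  if (!all(flat %in% c("0", "1")))
    stop("unexpected allele index in GT field: ",
         setdiff(unique(flat), c("0", "1"))[1])
  alt_dose <- matrix(colSums(matrix(flat == "1", nrow = 2L)),
                     nrow = nrow(gt), ncol = ncol(gt))
  n <- ncol(gt)   # samples are columns in VCF
  alt_freq <- rowSums(alt_dose) / (2 * n)
  # minor allele per site from the sample itself; tie counts ALT as minor
  minor <- alt_dose
  flip <- alt_freq > 0.5
  minor[flip, ] <- 2L - alt_dose[flip, , drop = FALSE]
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  genotype_matrix(t(minor), variant_ids = ids, individual_ids = colnames(gt))
}

#' Write a genotype matrix to TSV
#'
#' Inverse of \code{\link{load_genotypes}} with \code{format = "tsv"}:
#' writing then reloading reproduces the matrix exactly.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param path output file path.
#' @export
write_genotypes <- function(g, path) {
  df <- data.frame(individual_id = rownames(g), unclass(g),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a variant-to-gene map
#'
#' @param path TSV with columns \code{variant_id} and \code{gene_id}.
#' @return An object of class \code{"gene_map"}: a named character vector
#'   (variant id -> gene id) with a \code{gene_sizes} attribute.
#' @export
load_gene_map <- function(path) {
  tab <- read.delim(path, colClasses = "character")
  need <- c("variant_id", "gene_id")
  if (!all(need %in% names(tab)))
    stop("gene map must have columns variant_id and gene_id; found: ",
         paste(names(tab), collapse = ", "))
  gene_map(setNames(tab$gene_id, tab$variant_id))
}

#' Construct a gene map from a named vector
#'
#' @param assignment named character vector: names are variant ids, values
#'   are gene ids; every variant maps to exactly one gene.
#' @return A \code{"gene_map"} object.
#' @export
gene_map <- function(assignment) {
  if (is.null(names(assignment)) || anyDuplicated(names(assignment)))
    stop("gene map assignment must be named by distinct variant ids")
  assignment <- setNames(as.character(assignment), names(assignment))
  structure(assignment,
            gene_sizes = table(assignment),
            class = "gene_map")
}

#' @export
print.gene_map <- function(x, ...) {
  gs <- attr(x, "gene_sizes")
  cat("gene_map: ", length(x), " variants in ", length(gs), " genes",
      " (sizes ", min(gs), "-", max(gs), ")\n", sep = "")
  invisible(x)
}

#' Write a gene map to TSV
#' @param map a \code{"gene_map"}.
#' @param path output file path.
#' @export
write_gene_map <- function(map, path) {
  write.table(data.frame(variant_id = names(map), gene_id = as.character(map)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a phenotype/covariate table aligned to a genotype matrix
#'
#' Rows are matched to the genotype matrix by \code{individual_id}, never
#' by position; every genotyped individual must be present.
#'
#' @param path TSV with columns \code{individual_id}, the trait column, and
#'   covariate columns.
#' @param genotypes a \code{\link{genotype_matrix}} giving the individual
#'   order to reconcile against.
#' @param trait name of the trait column (default \code{"trait"}).
#' @param covariates character vector of covariate column names; default
#'   all remaining numeric columns.
#' @return list with \code{trait} (numeric vector) and \code{covariates}
#'   (numeric matrix, possibly 0 columns), ordered like \code{genotypes}.
#' @export
load_phenotypes <- function(path, genotypes, trait = "trait",
                            covariates = NULL) {
  tab <- read.delim(path, check.names = FALSE)
  if (!"individual_id" %in% names(tab))
    stop("phenotype table must have an individual_id column")
  if (!trait %in% names(tab))
    stop("trait column ", dQuote(trait), " not found")
  idx <- match(rownames(genotypes), as.character(tab$individual_id))
  if (anyNA(idx))
    stop("phenotypes missing for individuals: ",
         paste(head(rownames(genotypes)[is.na(idx)], 5), collapse = ", "))
  tab <- tab[idx, , drop = FALSE]
  if (is.null(covariates))
    covariates <- setdiff(names(tab), c("individual_id", trait))
  cov <- as.matrix(tab[, covariates, drop = FALSE])
  storage.mode(cov) <- "double"
  y <- as.numeric(tab[[trait]])
  if (anyNA(y) || anyNA(cov))
    stop("phenotype table contains missing values")
  list(trait = y, covariates = cov)
}

#' Minor allele frequencies
#'
#' MAF is the per-variant count of minor-allele copies divided by twice the
#' number of diploid individuals; always in [0, 0.5].
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @return numeric vector, one value per variant, named by variant id.
#' @export
compute_maf <- function(g) {
  n2 <- 2 * nrow(g)
  copies <- colSums(g)
  pmin(copies, n2 - copies) / n2
}

#' Mean-centered design columns for a set of variants
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param selection variant indices or ids; column order of the result
#'   follows the selection order.
#' @return numeric matrix, individuals x selected variants, each column
#'   with mean 0.
#' @export
center_columns <- function(g, selection) {
  if (length(selection) == 0L) stop("empty variant selection")
  if (is.character(selection)) {
    miss <- setdiff(selection, colnames(g))
    if (length(miss))
      stop("unknown variant id(s): ", paste(head(miss, 5), collapse = ", "))
    selection <- match(selection, colnames(g))
  }
  x <- unclass(g)[, selection, drop = FALSE]
  storage.mode(x) <- "double"
  sweep(x, 2L, colMeans(x), "-")
}
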