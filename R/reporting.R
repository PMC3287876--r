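# Screening reports: ranked per-factor tables, posterior-threshold counts,
# top-k membership across replicates, and the realized false-positive
# discovery rate against known truth.  Ranking ties are broken by factor
# id so every report is deterministic.

#' Ranked per-factor screening report
#'
#' @param summary an \code{"inclusion_summary"}.
#' @param maf optional named numeric vector of minor-allele frequencies
#'   (SNP mode).
#' @param gene_map optional \code{\link{gene_map}} to annotate variants
#'   with their gene.
#' @param truth optional character vector of truly associated factor ids;
#'   adds a \code{causal} column and threshold false-positive rates.
#' @param thresholds posterior cutoffs for the threshold table.
#' @param top_k how many leading factors count as "top" in the summary.
#' @return list of class \code{"screen_report"}: \code{factors}
#'   (data.frame id, gene, maf, posterior, rank, causal), \code{thresholds}
#'   (data.frame threshold, n_flagged, and when truth is known
#'   true_positives, false_positives, false_positive_rate), \code{top_k},
#'   \code{top_ids}.
#' @export
screen_report <- function(summary, maf = NULL, gene_map = NULL,
                          truth = NULL, thresholds = c(0.5, 0.1),
                          top_k = 20L) {
  probs <- summary$probabilities
  ids <- summary$factor_ids
  ord <- order(-probs, ids)
  rank <- integer(length(ids))
  rank[ord] <- seq_along(ids)
  tab <- data.frame(id = ids,
                    gene = if (!is.null(gene_map))
                      as.character(gene_map[ids]) else NA_character_,
                    maf = if (!is.null(maf)) unname(maf[ids]) else NA_real_,
                    posterior = unname(probs),
                    rank = rank,
                    row.names = NULL)
  if (!is.null(truth)) tab$causal <- tab$id %in% truth
  tab <- tab[order(tab$rank), , drop = FALSE]

  thr <- data.frame(threshold = sort(thresholds, decreasing = TRUE))
  thr$n_flagged <- vapply(thr$threshold,
                          function(t) sum(probs > t), integer(1))
  if (!is.null(truth)) {
    fdr <- lapply(thr$threshold, function(t)
      fdr_at_threshold(summary, truth, t))
    thr$true_positives <- vapply(fdr, `[[`, numeric(1), "true_positives")
    thr$false_positives <- vapply(fdr, `[[`, numeric(1), "false_positives")
    thr$false_positive_rate <- vapply(fdr, function(f)
      if (is.null(f$rate)) NA_real_ else f$rate, numeric(1))
  }
  top_k <- min(top_k, length(ids))
  structure(list(factors = tab, thresholds = thr, top_k = top_k,
                 top_ids = tab$id[seq_len(top_k)]),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, n = 10L, ...) {
  cat("screen_report (top ", min(n, nrow(x$factors)), " of ",
      nrow(x$factors), " factors):\n", sep = "")
  print(head(x$factors, n), row.names = FALSE)
  cat("\nposterior thresholds:\n")
  print(x$thresholds, row.names = FALSE)
  invisible(x)
}

#' Top-k membership counts across replicates
#'
#' For each factor, in how many replicates it ranks within the top k by
#' marginal posterior probability.  Ties at the k-th rank are broken by
#' factor id, so membership is deterministic.
#'
#' @param summaries list of \code{"inclusion_summary"} objects over the
#'   same factor set, one per replicate.
#' @param k top-list size.
#' @return data.frame with \code{id} and \code{appearances}, factors that
#'   never appear omitted, sorted by decreasing appearances then id.
#' @export
top_k_membership <- function(summaries, k = 20L) {
  if (!length(summaries)) stop("no summaries given")
  ids <- summaries[[1]]$factor_ids
  for (s in summaries)
    if (!identical(s$factor_ids, ids))
      stop("summaries are not over the same factor set")
  if (k > length(ids)) stop("k exceeds the number of factors")
  counts <- setNames(integer(length(ids)), ids)
  for (s in summaries) {
    ord <- order(-s$probabilities, ids)
    top <- ids[ord[seq_len(k)]]
    counts[top] <- counts[top] + 1L
  }
  out <- data.frame(id = names(counts), appearances = as.integer(counts),
                    row.names = NULL)
  out <- out[out$appearances > 0L, , drop = FALSE]
  out[order(-out$appearances, out$id), , drop = FALSE]
}

#' Realized false-positive discovery rate at a posterior cutoff
#'
#' Among factors whose marginal posterior exceeds the threshold, the
#' fraction not in the causal truth set: FP / (FP + TP).  This is the
#' realized false-discovery proportion at the cutoff given known
#' simulation truth, not an expected FDR in the multiple-testing sense.
#'
#' @param summary an \code{"inclusion_summary"}.
#' @param truth character vector of truly associated factor ids.
#' @param threshold posterior cutoff in (0, 1).
#' @return list with \code{true_positives}, \code{false_positives}, and
#'   \code{rate} (NULL when nothing is flagged).
#' @export
fdr_at_threshold <- function(summary, truth, threshold) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0, 1)")
  flagged <- summary$factor_ids[summary$probabilities > threshold]
  tp <- sum(flagged %in% truth)
  fp <- length(flagged) - tp
  list(true_positives = tp, false_positives = fp,
       rate = if (tp + fp == 0L) NULL else fp / (tp + fp))
}
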