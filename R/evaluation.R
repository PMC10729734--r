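#' Area under the ROC curve of a drug ranking
#'
#' Computed in the exact Mann-Whitney form,
#' \eqn{P(score_{pos} > score_{neg}) + \frac{1}{2} P(tie)}, via midranks; no
#' curve interpolation is involved.
#'
#' @param scores Named numeric vector of per-drug scores.
#' @param positives Character vector of drug ids labeled positive; ids absent
#'   from \code{scores} are dropped with a message.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, positives) {
  if (is.null(names(scores))) stop("scores must be named by drug id")
  positives <- unique(positives)
  known <- positives %in% names(scores)
  if (any(!known))
    message(sum(!known), " positive drug(s) absent from the scored universe",
            " were dropped")
  positives <- positives[known]
  is_pos <- names(scores) %in% positives
  n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
  if (n_pos == 0L || n_neg == 0L)
    stop("AUROC needs at least one positive and one negative drug")
  rk <- rank(scores)       # midranks handle ties exactly
  (sum(rk[is_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Overlap of the top k drugs of two rankings
#'
#' @param ranking_a,ranking_b Character vectors of drug ids ordered best
#'   first, over the same universe.
#' @param k Number of top drugs to compare (default 50).
#' @return Size of the intersection of the two top-k sets.
#' @export
topk_overlap <- function(ranking_a, ranking_b, k = 50L) {
  if (!setequal(ranking_a, ranking_b))
    stop("the two rankings must cover the same drug universe")
  if (k > length(ranking_a)) stop("k exceeds the size of the drug universe")
  length(intersect(ranking_a[seq_len(k)], ranking_b[seq_len(k)]))
}

#' Rank correlation between two score vectors
#'
#' Spearman by default (Pearson available), with a two-sided p-value.
#'
#' @param scores_a,scores_b Numeric vectors over the same drugs, aligned by
#'   name when both are named, by position otherwise.
#' @param method "spearman" (default) or "pearson".
#' @return List with \code{coefficient} and \code{p_value}.
#' @export
rank_correlation <- function(scores_a, scores_b, method = "spearman") {
  if (length(scores_a) != length(scores_b))
    stop("score vectors differ in length")
  if (length(scores_a) < 3L) stop("need at least 3 drugs")
  if (!is.null(names(scores_a)) && !is.null(names(scores_b))) {
    if (!setequal(names(scores_a), names(scores_b)))
      stop("score vectors cover different drugs")
    scores_b <- scores_b[names(scores_a)]
  }
  ct <- stats::cor.test(scores_a, scores_b, method = method,
                        exact = FALSE, alternative = "two.sided")
  list(coefficient = unname(ct$estimate), p_value = ct$p.value)
}

#' Read a plain-text list of true-positive drugs
#'
#' One drug id per line; blank lines ignored.
#'
#' @param path Path to the text file.
#' @return Character vector of drug ids.
#' @export
read_positive_drugs <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x)])
}

#' Evaluate a drug result table against a true-positive list
#'
#' @param results A \code{DrugResultTable} (see \code{\link{rank_drugs}}).
#' @param positives Character vector of positive drug ids.
#' @param k Top-k used for the overlap count reported against the table's
#'   own ranking head (default 50, capped at the universe size).
#' @return List with \code{auroc}, \code{n_positives_used}, \code{k},
#'   \code{topk_hits} (positives within the top k).
#' @export
evaluate_ranking <- function(results, positives, k = 50L) {
  scores <- stats::setNames(results$centrality_score, results$drug_id)
  a <- auroc(scores, positives)
  k <- min(k, nrow(results))
  top <- results$drug_id[order(results$rank)][seq_len(k)]
  list(auroc = a,
       n_positives_used = sum(positives %in% results$drug_id),
       k = k,
       topk_hits = sum(top %in% positives))
}
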