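#' Bootstrap null distribution of drug centrality scores
#'
#' The drug/gene-set overlap structure is held fixed while the gene-level DE
#' scores are resampled with replacement from the observed pool and
#' reassigned to genes; the bipartite weights, similarity projection,
#' column normalization, and restarting walk are then rebuilt from scratch
#' for each replicate. Drugs isolated in a replicate (possible when the
#' resampled scores zero out an overlap) receive centrality 0 in that row,
#' which keeps the matrix rectangular and is conservative for the empirical
#' p-value. Each replicate draws from its own sub-seed derived from
#' \code{seed}, so results do not depend on execution order.
#'
#' @param cat A \code{\link{drug_target_catalog}} (already size-filtered).
#' @param sets A \code{\link{gene_set_collection}} (already size-filtered).
#' @param de A \code{DEProfile} or named DE-score vector.
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Integer master seed.
#' @param r,tol,max_iter Passed to \code{\link{random_walk_restart}}; must
#'   match the observed run.
#' @return A \code{B x n_drugs} matrix of class \code{NullScores}; columns
#'   are named by drug id.
#' @export
bootstrap_null <- function(cat, sets, de, B = 1000L, seed = 1L,
                           r = 0.9, tol = 1e-10, max_iter = 10000L) {
  if (B < 1L) stop("B must be >= 1")
  scores <- de_score_vector(de)
  skel <- bipartite_skeleton(cat, sets, names(scores))
  pool <- unname(scores)
  n_gene <- length(pool)
  drug_ids <- skel$drug_ids
  null <- matrix(0, nrow = B, ncol = length(drug_ids),
                 dimnames = list(NULL, drug_ids))
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, B)
  for (k in seq_len(B)) {
    set.seed(sub_seeds[k])
    star <- pool[sample.int(n_gene, n_gene, replace = TRUE)]
    W <- weights_from_scores(skel, star)
    A <- tcrossprod(W)
    diag(A) <- 0
    cs <- colSums(A)
    keep <- cs > 0
    if (!any(keep)) next  # fully isolated replicate: all centralities 0
    # A is symmetric with zero diagonal, so a zero column is a zero row too;
    # dropping isolated drugs leaves the remaining column sums positive
    Ak <- A[keep, keep, drop = FALSE]
    Tm <- sweep(Ak, 2L, cs[keep], "/")
    v <- random_walk_restart(Tm, r = r, tol = tol, max_iter = max_iter)$v
    null[k, keep] <- v
  }
  class(null) <- c("NullScores", class(null))
  null
}

#' Empirical p-values from a bootstrap null
#'
#' For drug i, \eqn{p_i = \#\{k : v^{*k}_i \ge v_i\} / B}: the fraction of
#' null replicates whose centrality is at least the observed one (ties count
#' against the drug). With \code{pseudocount = TRUE} the estimator
#' \eqn{(\#\{\cdot\} + 1)/(B + 1)} is used instead, which avoids exact zeros.
#'
#' @param observed A \code{CentralityVector} (or named numeric vector).
#' @param null A \code{NullScores} matrix with drug-id column names.
#' @param pseudocount Use the add-one estimator (default FALSE).
#' @return Named vector of p-values for the observed drugs.
#' @export
empirical_pvalues <- function(observed, null, pseudocount = FALSE) {
  v <- if (inherits(observed, "CentralityVector")) observed$v else observed
  if (is.null(names(v)) || is.null(colnames(null)))
    stop("observed scores and null matrix must both carry drug ids")
  if (!all(names(v) %in% colnames(null)))
    stop("drug ids of observed scores not all present in null matrix: ",
         paste(setdiff(names(v), colnames(null)), collapse = ", "))
  nm <- null[, names(v), drop = FALSE]
  B <- nrow(nm)
  counts <- colSums(nm >= rep(v, each = B))
  if (pseudocount) (counts + 1) / (B + 1) else counts / B
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, order-preserving with the input
#' and clipped at 1.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Vector of adjusted values, same order and names as \code{p}.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must be finite and in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Assemble the ranked drug result table
#'
#' Ranks drugs by descending centrality (ties broken by drug id) and flags
#' candidates whose FDR is strictly below the threshold.
#'
#' @param v A \code{CentralityVector} or named numeric vector of centrality
#'   scores.
#' @param p Named or aligned vector of empirical p-values (may be NULL when
#'   no permutations were run).
#' @param fdr Adjusted p-values aligned with \code{p} (may be NULL).
#' @param threshold Candidate cutoff on FDR (strict \code{<}); default 0.1.
#' @param drug_names Optional named character vector of display names.
#' @return Data frame of class \code{DrugResultTable} with columns drug_id,
#'   drug_name, centrality_score, p_value, fdr, rank, candidate; sorted by
#'   rank.
#' @export
rank_drugs <- function(v, p = NULL, fdr = NULL, threshold = 0.1,
                       drug_names = NULL) {
  scores <- if (inherits(v, "CentralityVector")) v$v else v
  ids <- names(scores)
  if (is.null(ids)) stop("centrality scores must be named by drug id")
  if (!is.null(p) && length(p) != length(scores))
    stop("length of p-values does not match the number of drugs")
  if (!is.null(fdr) && length(fdr) != length(scores))
    stop("length of FDR values does not match the number of drugs")
  nm <- if (is.null(drug_names)) stats::setNames(ids, ids)
        else {
          out <- as.character(drug_names[ids])
          out[is.na(out)] <- ids[is.na(out)]
          stats::setNames(out, ids)
        }
  ord <- order(-scores, ids)
  tab <- data.frame(
    drug_id = ids[ord],
    drug_name = unname(nm[ids[ord]]),
    centrality_score = unname(scores[ord]),
    p_value = if (is.null(p)) NA_real_ else unname(p[ord]),
    fdr = if (is.null(fdr)) NA_real_ else unname(fdr[ord]),
    rank = seq_along(ord),
    stringsAsFactors = FALSE
  )
  tab$candidate <- if (is.null(fdr)) NA else tab$fdr < threshold
  class(tab) <- c("DrugResultTable", "data.frame")
  tab
}
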