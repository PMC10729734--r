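#' Run the full drug-prioritization pipeline
#'
#' Orchestrates the four stages: (1) per-gene DE scoring of the case/control
#' expression data, (2) construction of the DE-weighted drug/gene-set
#' bipartite network, (3) projection onto the drug-drug functional
#' similarity matrix, and (4) random-walk-with-restart centrality with a
#' gene-level bootstrap null, empirical p-values, and BH FDR. Drugs isolated
#' in the observed network are reported with centrality 0 and p-value 1.
#'
#' @param expression An \code{\link{expression_dataset}}.
#' @param catalog A \code{\link{drug_target_catalog}} (size-filtered).
#' @param sets A \code{\link{gene_set_collection}} (size-filtered).
#' @param restart Restart probability (default 0.9).
#' @param tol Walk convergence tolerance (default 1e-10).
#' @param max_iter Walk iteration cap (default 10000).
#' @param n_perm Bootstrap replicates for the null (default 1000); 0 skips
#'   significance estimation and leaves p/FDR columns as NA.
#' @param seed Master seed for the bootstrap.
#' @param fdr_threshold Candidate cutoff, strict \code{fdr <} (default 0.1).
#' @param normalize Z-score normalize expression first (default TRUE).
#' @param var_equal,symmetric,pseudocount Passed through to
#'   \code{\link{compute_de_scores}} and \code{\link{empirical_pvalues}}.
#' @return A list of class \code{DrugSimRun} with elements \code{de},
#'   \code{bipartite}, \code{similarity}, \code{transition},
#'   \code{centrality}, \code{null} (or NULL), \code{results} (a
#'   \code{DrugResultTable}), and \code{config} (the resolved parameters).
#' @export
run_pipeline <- function(expression, catalog, sets,
                         restart = 0.9, tol = 1e-10, max_iter = 10000L,
                         n_perm = 1000L, seed = 1L, fdr_threshold = 0.1,
                         normalize = TRUE, var_equal = FALSE,
                         symmetric = FALSE, pseudocount = FALSE) {
  ds <- if (normalize) zscore_normalize(expression) else expression
  de <- compute_de_scores(ds, var_equal = var_equal, symmetric = symmetric)
  bw <- build_bipartite(catalog, sets, de)
  sim <- project_similarity(bw)
  tm <- column_normalize(sim)
  cv <- random_walk_restart(tm, r = restart, tol = tol, max_iter = max_iter)

  p <- fdr <- NULL
  null <- NULL
  all_ids <- sort(c(names(cv$v), tm$removed))
  v_all <- stats::setNames(numeric(length(all_ids)), all_ids)
  v_all[names(cv$v)] <- cv$v

  if (n_perm > 0L) {
    null <- bootstrap_null(catalog, sets, de, B = n_perm, seed = seed,
                           r = restart, tol = tol, max_iter = max_iter)
    p_walked <- empirical_pvalues(cv, null, pseudocount = pseudocount)
    p <- stats::setNames(rep(1, length(all_ids)), all_ids)
    p[names(p_walked)] <- p_walked
    fdr <- bh_fdr(p)
  } else {
    warning("n_perm = 0: skipping significance estimation")
  }

  results <- rank_drugs(v_all, p = p, fdr = fdr, threshold = fdr_threshold,
                        drug_names = catalog$drug_names)
  structure(list(
    de = de, bipartite = bw, similarity = sim, transition = tm,
    centrality = cv, null = null, results = results,
    config = list(restart = restart, tol = tol, max_iter = max_iter,
                  n_perm = n_perm, seed = seed,
                  fdr_threshold = fdr_threshold, normalize = normalize,
                  var_equal = var_equal, symmetric = symmetric,
                  pseudocount = pseudocount,
                  n_drugs = length(catalog$targets),
                  n_sets = length(sets$sets),
                  n_isolated = length(tm$removed))),
    class = "DrugSimRun")
}

#' @export
print.DrugSimRun <- function(x, ...) {
  cfg <- x$config
  cat("DrugSimRun:", cfg$n_drugs, "drugs,", cfg$n_sets, "gene sets;",
      cfg$n_isolated, "isolated;",
      if (is.null(x$null)) "no permutations"
      else paste0(nrow(x$null), " bootstrap replicates"), "\n")
  n_cand <- sum(x$results$candidate, na.rm = TRUE)
  cat("  candidates at FDR <", cfg$fdr_threshold, ":", n_cand, "\n")
  invisible(x)
}
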