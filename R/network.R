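#' Jaccard index of two gene sets
#'
#' @param d,g Character vectors of gene ids (duplicates ignored).
#' @return \eqn{|d \cap g| / |d \cup g|}, a value in [0, 1].
#' @export
jaccard <- function(d, g) {
  d <- unique(d); g <- unique(g)
  u <- length(union(d, g))
  if (u == 0L) stop("Jaccard index undefined: both sets are empty")
  length(intersect(d, g)) / u
}

# median of a nonempty numeric vector; avoids stats::median dispatch overhead
# in the bootstrap inner loop
fast_median <- function(x) {
  n <- length(x)
  if (n == 1L) return(x)
  h <- n %/% 2L
  if (n %% 2L == 1L) sort(x, partial = h + 1L)[h + 1L]
  else { s <- sort(x, partial = c(h, h + 1L)); (s[h] + s[h + 1L]) / 2 }
}

#' Disease-contextual weight of a drug/gene-set edge
#'
#' The weight is the Jaccard index of the full target set and gene set
#' multiplied by the median DE score of the genes common to both that have a
#' measured DE value. Overlap genes without a measured DE score are excluded
#' from the median; when no overlap gene is measured, or the overlap is
#' empty, the weight is 0 and no edge exists.
#'
#' @param d Drug target set (character vector of gene ids).
#' @param g Gene set (character vector).
#' @param de A \code{DEProfile} or named DE-score vector.
#' @return Nonnegative edge weight.
#' @export
edge_weight <- function(d, g, de) {
  scores <- de_score_vector(de)
  ov <- intersect(unique(d), unique(g))
  if (!length(ov)) return(0)
  measured <- ov[ov %in% names(scores)]
  if (!length(measured)) return(0)
  jaccard(d, g) * unname(fast_median(scores[measured]))
}

# Precompute the DE-independent skeleton of the bipartite network: which
# (drug, gene-set) pairs overlap, their Jaccard factor, and the indices of
# their measured overlap genes in `universe`. The skeleton is constant across
# bootstrap replicates; only the DE scores change.
bipartite_skeleton <- function(cat, sets, universe) {
  stopifnot(inherits(cat, "DrugTargetCatalog"),
            inherits(sets, "GeneSetCollection"))
  drug_ids <- names(cat$targets)
  set_ids <- names(sets$sets)
  gene_pos <- stats::setNames(seq_along(universe), universe)
  set_idx <- lapply(sets$sets, function(g) {
    i <- gene_pos[g]; as.integer(i[!is.na(i)])
  })
  set_size <- lengths(sets$sets)
  pair_drug <- integer(0); pair_set <- integer(0)
  pair_j <- numeric(0); pair_genes <- list()
  k <- 0L
  for (a in seq_along(drug_ids)) {
    tg <- cat$targets[[a]]
    tg_idx <- gene_pos[tg]
    tg_idx <- as.integer(tg_idx[!is.na(tg_idx)])
    n_t <- length(tg)
    for (j in seq_along(set_ids)) {
      ov <- intersect(tg_idx, set_idx[[j]])
      if (!length(ov)) next
      # Jaccard over the full, unrestricted sets
      n_ov_full <- length(intersect(tg, sets$sets[[j]]))
      if (!n_ov_full) next
      k <- k + 1L
      pair_drug[k] <- a
      pair_set[k] <- j
      pair_j[k] <- n_ov_full / (n_t + set_size[j] - n_ov_full)
      pair_genes[[k]] <- ov
    }
  }
  list(drug_ids = drug_ids, set_ids = set_ids,
       pair_drug = pair_drug, pair_set = pair_set,
       pair_j = pair_j, pair_genes = pair_genes,
       universe = universe)
}

# Fill the bipartite weight matrix from a skeleton and a DE-score vector
# aligned with skeleton$universe.
weights_from_scores <- function(skel, scores) {
  W <- matrix(0, length(skel$drug_ids), length(skel$set_ids),
              dimnames = list(skel$drug_ids, skel$set_ids))
  np <- length(skel$pair_drug)
  if (np) {
    w <- vapply(skel$pair_genes,
                function(ix) fast_median(scores[ix]), numeric(1))
    W[cbind(skel$pair_drug, skel$pair_set)] <- skel$pair_j * w
  }
  W
}

#' Build the drug/gene-set bipartite weight matrix
#'
#' Rows are drugs, columns are gene sets; entry (a, j) is
#' \code{\link{edge_weight}} of drug a's targets and set j's genes under the
#' supplied DE profile.
#'
#' @param cat A \code{\link{drug_target_catalog}}.
#' @param sets A \code{\link{gene_set_collection}}.
#' @param de A \code{DEProfile} or named DE-score vector.
#' @return An object of class \code{BipartiteWeights}: list with \code{W}
#'   (drugs x sets matrix), \code{drug_ids}, \code{set_ids}.
#' @export
build_bipartite <- function(cat, sets, de) {
  scores <- de_score_vector(de)
  skel <- bipartite_skeleton(cat, sets, names(scores))
  W <- weights_from_scores(skel, unname(scores))
  structure(list(W = W, drug_ids = skel$drug_ids, set_ids = skel$set_ids),
            class = "BipartiteWeights")
}

#' Project the bipartite network onto drugs
#'
#' The drug-drug functional similarity matrix is \eqn{A = W W^T} with the
#' diagonal set to 0 (self-links removed), so \eqn{A_{ab}} is the sum over
#' shared gene sets of the products of the two drugs' edge weights.
#'
#' @param bw A \code{BipartiteWeights}.
#' @return An object of class \code{DrugSimilarityMatrix}: list with the
#'   symmetric nonnegative matrix \code{A} and \code{drug_ids}.
#' @export
project_similarity <- function(bw) {
  W <- if (inherits(bw, "BipartiteWeights")) bw$W else bw
  if (nrow(W) < 2L) stop("projection needs at least 2 drugs")
  A <- tcrossprod(W)
  diag(A) <- 0
  structure(list(A = A, drug_ids = rownames(W)),
            class = "DrugSimilarityMatrix")
}

#' @export
print.DrugSimilarityMatrix <- function(x, ...) {
  n <- nrow(x$A)
  cat("DrugSimilarityMatrix:", n, "drugs,",
      sum(x$A[upper.tri(x$A)] > 0), "edges\n")
  invisible(x)
}
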