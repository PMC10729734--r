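#' Column-normalize a drug similarity matrix into a transition matrix
#'
#' Each entry is divided by its column sum so that columns sum to 1 and
#' \code{T[a, b]} is the probability the walker moves from drug b to drug a.
#' Isolated drugs (zero row and column) would make the normalization
#' undefined and cannot receive propagation evidence; they are removed and
#' reported in the \code{removed} element.
#'
#' @param sim A \code{DrugSimilarityMatrix}.
#' @return An object of class \code{TransitionMatrix}: list with the
#'   column-stochastic matrix \code{T}, \code{drug_ids}, and \code{removed}
#'   (ids of isolated drugs).
#' @export
column_normalize <- function(sim) {
  A <- if (inherits(sim, "DrugSimilarityMatrix")) sim$A else sim
  cs <- colSums(A)
  isolated <- cs == 0
  if (all(isolated)) stop("all drugs are isolated; no network to normalize")
  removed <- rownames(A)[isolated]
  A <- A[!isolated, !isolated, drop = FALSE]
  Tm <- sweep(A, 2L, colSums(A), "/")
  structure(list(T = Tm, drug_ids = rownames(Tm), removed = removed),
            class = "TransitionMatrix")
}

#' Random walk with restart
#'
#' Iterates \eqn{v^{t+1} = (1 - r) T v^t + r v^0} from the uniform seed
#' \eqn{v^0 = 1/N} until the L1 difference between successive vectors falls
#' below \code{tol}. The fixed point is the eigenvector-centrality-style
#' score of each drug: the stationary probability that the restarting walker
#' occupies the node.
#'
#' @param tm A \code{TransitionMatrix} (or bare column-stochastic matrix).
#' @param r Restart probability in (0, 1]; default 0.9.
#' @param tol L1 convergence tolerance; default 1e-10.
#' @param max_iter Iteration cap; non-convergence is reported via the
#'   \code{converged} flag and a warning, not an error.
#' @return An object of class \code{CentralityVector}: list with named
#'   probability vector \code{v}, \code{iterations}, \code{converged}.
#' @export
random_walk_restart <- function(tm, r = 0.9, tol = 1e-10, max_iter = 10000L) {
  Tm <- if (inherits(tm, "TransitionMatrix")) tm$T else tm
  stopifnot(r > 0, r <= 1)
  n <- nrow(Tm)
  v0 <- rep(1 / n, n)
  v <- v0
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    v_new <- (1 - r) * as.vector(Tm %*% v) + r * v0
    if (sum(abs(v_new - v)) < tol) {
      v <- v_new
      converged <- TRUE
      break
    }
    v <- v_new
  }
  if (!converged)
    warning("random walk did not converge within ", max_iter, " iterations")
  structure(list(v = stats::setNames(v, rownames(Tm)),
                 iterations = iter, converged = converged),
            class = "CentralityVector")
}

#' Closed-form stationary solution of the restarting walk
#'
#' Solves the fixed-point equation of the restart iteration directly:
#' \eqn{v = r (I - (1 - r) T)^{-1} v^0} with the uniform seed. Serves as an
#' analytic cross-check for \code{\link{random_walk_restart}}.
#'
#' @inheritParams random_walk_restart
#' @return A \code{CentralityVector} with \code{iterations = 0}.
#' @export
closed_form_stationary <- function(tm, r = 0.9) {
  Tm <- if (inherits(tm, "TransitionMatrix")) tm$T else tm
  stopifnot(r > 0, r <= 1)
  n <- nrow(Tm)
  v0 <- rep(1 / n, n)
  v <- solve(diag(n) - (1 - r) * Tm, r * v0)
  structure(list(v = stats::setNames(as.vector(v), rownames(Tm)),
                 iterations = 0L, converged = TRUE),
            class = "CentralityVector")
}

#' @export
print.CentralityVector <- function(x, ...) {
  cat("CentralityVector:", length(x$v), "drugs;",
      if (x$converged) paste0("converged in ", x$iterations, " iterations")
      else "NOT converged", "\n")
  invisible(x)
}
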