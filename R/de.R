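#' Z-score normalize an expression dataset
#'
#' Standardizes each gene row to mean 0 and unit (n-1) standard deviation
#' across all samples. Constant rows, which carry no between-sample
#' information, become all-zero rows.
#'
#' @param ds An \code{\link{expression_dataset}}.
#' @return The dataset with standardized values.
#' @export
zscore_normalize <- function(ds) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  x <- ds$values
  mu <- rowMeans(x)
  xc <- x - mu
  sd <- sqrt(rowSums(xc^2) / (ncol(x) - 1L))
  zero <- sd == 0 | !is.finite(sd)
  sd[zero] <- 1
  out <- xc / sd
  out[zero, ] <- 0
  ds$values <- out
  ds
}

# Vectorized two-sample t-test over the rows of x.
# Returns two-sided p-values; rows constant in both groups get p = 1,
# rows with zero pooled spread but different means get p = 0 (clamped later).
row_ttest_p <- function(x, case, control, var_equal = FALSE) {
  x1 <- x[, case, drop = FALSE]
  x2 <- x[, control, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1L)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1L)
  if (var_equal) {
    sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep.int(n1 + n2 - 2L, nrow(x))
  } else {
    se2 <- v1 / n1 + v2 / n2
    se <- sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  }
  tstat <- (m1 - m2) / se
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  degenerate <- se == 0 | !is.finite(se)
  if (any(degenerate)) {
    same <- degenerate & (m1 == m2)
    p[degenerate] <- 0     # zero spread, different means: maximal evidence
    p[same] <- 1           # identical constant rows: no evidence
  }
  unname(p)
}

#' Per-gene differential-expression scores
#'
#' For every gene a two-tailed t-test compares case versus control samples.
#' The p-value is mapped to a z-score through the inverse normal cdf,
#' \eqn{z = \Phi^{-1}(1 - p)}, and the DE score is \eqn{|z|}: the larger the
#' score, the more strongly the gene is transcriptionally dysregulated.
#' p-values are clamped to \code{[1e-300, 1 - 1e-16]} before the quantile
#' transform so z stays finite. Note that under this printed transform a
#' p-value near 1 also yields a large (negative) z and hence a large DE
#' score; set \code{symmetric = TRUE} for the conventional two-tailed
#' transform \eqn{z = \Phi^{-1}(1 - p/2)} instead.
#'
#' @param ds An \code{\link{expression_dataset}} (normalize first with
#'   \code{\link{zscore_normalize}} if desired; the t-test is invariant to
#'   per-gene affine rescaling, so this choice does not alter DE scores).
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @param symmetric Use \eqn{z = \Phi^{-1}(1 - p/2)} instead of the default
#'   \eqn{z = \Phi^{-1}(1 - p)}.
#' @param clamp Length-2 numeric: lower/upper clamp for p before the
#'   quantile transform.
#' @return A data frame of class \code{DEProfile} with columns
#'   \code{gene}, \code{p}, \code{z}, \code{de_score}.
#' @export
compute_de_scores <- function(ds, var_equal = FALSE, symmetric = FALSE,
                              clamp = c(1e-300, 1 - 1e-16)) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  case <- ds$group == "case"
  control <- ds$group == "control"
  if (sum(case) < 2L || sum(control) < 2L)
    stop("both groups need at least 2 samples for the t-test")
  p <- row_ttest_p(ds$values, case, control, var_equal = var_equal)
  pc <- pmin(pmax(p, clamp[1L]), clamp[2L])
  z <- if (symmetric) stats::qnorm(pc / 2, lower.tail = FALSE)
       else stats::qnorm(pc, lower.tail = FALSE)
  out <- data.frame(gene = rownames(ds$values), p = p, z = z,
                    de_score = abs(z), stringsAsFactors = FALSE)
  class(out) <- c("DEProfile", "data.frame")
  out
}

#' Extract named DE scores from a DE profile
#'
#' @param de A \code{DEProfile} or an already-named numeric vector.
#' @return Named numeric vector of nonnegative DE scores.
#' @export
de_score_vector <- function(de) {
  if (is.numeric(de) && !is.null(names(de))) return(de)
  stopifnot(inherits(de, "DEProfile"))
  stats::setNames(de$de_score, de$gene)
}

#' Write a DE profile to TSV
#'
#' @param de A \code{DEProfile}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_de_profile <- function(de, path) {
  stopifnot(inherits(de, "DEProfile"))
  out <- data.frame(gene = de$gene, p = signif(de$p, 6),
                    z = signif(de$z, 6), de_score = signif(de$de_score, 6))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
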