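#' Specification of a synthetic case/control drug-repurposing benchmark
#'
#' Describes a self-contained benchmark with a planted disease-contextual
#' signal. Every drug is built by the same rule: it anchors on a few random
#' gene sets and draws its targets from their member genes, so that each
#' drug has genuine functional-set overlap. The "true" drugs are an
#' arbitrary designation; the disease signal is planted purely in the
#' expression data by shifting the case-group mean of the genes belonging to
#' the true drugs' anchor sets (padded with random genes up to
#' \code{frac_dysregulated}). With \code{effect_size = 0} true and decoy
#' drugs are therefore statistically exchangeable by construction, and with
#' a positive effect the signal reaches the true drugs only through the
#' bipartite drug/gene-set path the pipeline actually exercises.
#'
#' @param n_genes Number of genes (default 2000).
#' @param n_samples_per_group Samples per group (default 20).
#' @param n_drugs Number of drugs (default 100).
#' @param n_gene_sets Number of gene sets (default 300).
#' @param n_true_drugs Number of planted true drugs (default 5).
#' @param effect_size Case-group mean shift, in SD units, for dysregulated
#'   genes (default 2.5).
#' @param frac_dysregulated Minimum fraction of genes shifted (default
#'   0.15); the dysregulated pool always contains every anchor-set gene of
#'   the true drugs and is padded with random genes up to this fraction.
#' @param n_anchor_sets Gene sets each drug anchors on (default 2).
#' @param target_size_range Inclusive range of drug target-set sizes
#'   (default 5..30; capped at the anchor-gene pool size, and within the
#'   catalog filter bounds 4..499).
#' @param set_size_range Inclusive range of gene-set sizes (default 8..40;
#'   within the collection filter bounds 6..99).
#' @param seed Master seed; all randomness flows from it through named
#'   substreams so components can be regenerated independently.
#' @return A list of class \code{BenchmarkSpec}.
#' @export
benchmark_spec <- function(n_genes = 2000L, n_samples_per_group = 20L,
                           n_drugs = 100L, n_gene_sets = 300L,
                           n_true_drugs = 5L, effect_size = 2.5,
                           frac_dysregulated = 0.15, n_anchor_sets = 2L,
                           target_size_range = c(5L, 30L),
                           set_size_range = c(8L, 40L), seed = 1L) {
  spec <- list(n_genes = as.integer(n_genes),
               n_samples_per_group = as.integer(n_samples_per_group),
               n_drugs = as.integer(n_drugs),
               n_gene_sets = as.integer(n_gene_sets),
               n_true_drugs = as.integer(n_true_drugs),
               effect_size = effect_size,
               frac_dysregulated = frac_dysregulated,
               n_anchor_sets = as.integer(n_anchor_sets),
               target_size_range = as.integer(target_size_range),
               set_size_range = as.integer(set_size_range),
               seed = as.integer(seed))
  if (spec$n_drugs < 2L) stop("need at least 2 drugs")
  if (spec$n_true_drugs > spec$n_drugs)
    stop("n_true_drugs exceeds n_drugs")
  if (spec$n_samples_per_group < 2L)
    stop("need at least 2 samples per group")
  if (spec$n_anchor_sets < 1L || spec$n_anchor_sets > spec$n_gene_sets)
    stop("n_anchor_sets must be in 1..n_gene_sets")
  if (spec$target_size_range[1L] < 4L || spec$target_size_range[2L] > 499L)
    stop("target_size_range must lie within the catalog filter bounds 4..499")
  if (spec$set_size_range[1L] < 6L || spec$set_size_range[2L] > 99L)
    stop("set_size_range must lie within the gene-set filter bounds 6..99")
  if (spec$set_size_range[2L] > spec$n_genes)
    stop("gene-set sizes exceed the number of genes")
  if (spec$n_anchor_sets * spec$set_size_range[1L] <
      spec$target_size_range[1L])
    stop("anchor pools can be smaller than the minimum target-set size")
  if (round(spec$frac_dysregulated * spec$n_genes) < spec$set_size_range[2L])
    stop("frac_dysregulated too small for the requested set sizes")
  class(spec) <- "BenchmarkSpec"
  spec
}

#' Generate a synthetic benchmark bundle
#'
#' Expression is standard normal noise; the dysregulated genes get a mean
#' shift of \code{effect_size} in the case group. Gene sets sample the whole
#' gene universe; each drug draws its targets from the union of its
#' \code{n_anchor_sets} randomly assigned anchor sets. The dysregulated pool
#' is the union of the true drugs' anchor-set genes, padded with random
#' genes up to \code{frac_dysregulated}. All emitted objects pass the
#' read-time size filters, and the bundle is a deterministic function of the
#' seed.
#'
#' @param spec A \code{\link{benchmark_spec}}.
#' @return A list of class \code{BenchmarkBundle} with elements
#'   \code{expression} (an \code{ExpressionDataset}), \code{catalog},
#'   \code{sets}, \code{true_drugs} (character vector),
#'   \code{dysregulated_genes}, and \code{spec}.
#' @export
generate_benchmark <- function(spec = benchmark_spec()) {
  stopifnot(inherits(spec, "BenchmarkSpec"))
  set.seed(spec$seed)
  sub <- sample.int(.Machine$integer.max - 1L, 3L)  # sets, catalog, expression

  gene_ids <- sprintf("g%05d", seq_len(spec$n_genes))

  # gene sets: uniform draws from the whole universe
  set.seed(sub[1L])
  set_ids <- sprintf("GS%04d", seq_len(spec$n_gene_sets))
  sizes <- sample(seq(spec$set_size_range[1L], spec$set_size_range[2L]),
                  spec$n_gene_sets, replace = TRUE)
  sets <- lapply(sizes, function(s) sample(gene_ids, s))
  names(sets) <- set_ids

  # drugs: one construction rule for all; targets drawn from the union of
  # each drug's anchor sets
  set.seed(sub[2L])
  drug_ids <- sprintf("D%04d", seq_len(spec$n_drugs))
  tsizes <- sample(seq(spec$target_size_range[1L],
                       spec$target_size_range[2L]),
                   spec$n_drugs, replace = TRUE)
  anchors <- lapply(seq_len(spec$n_drugs), function(a)
    sample.int(spec$n_gene_sets, spec$n_anchor_sets))
  targets <- lapply(seq_len(spec$n_drugs), function(a) {
    pool <- unique(unlist(sets[anchors[[a]]], use.names = FALSE))
    sample(pool, min(tsizes[a], length(pool)))
  })
  names(targets) <- drug_ids
  catalog <- drug_target_catalog(
    targets, stats::setNames(paste0("compound_", tolower(drug_ids)),
                             drug_ids))

  # disease signal: dysregulate the true drugs' anchor-set genes, padded
  # with random genes up to the requested fraction
  true_ids <- drug_ids[seq_len(spec$n_true_drugs)]
  anchor_genes <- unique(unlist(
    sets[unique(unlist(anchors[seq_len(spec$n_true_drugs)]))],
    use.names = FALSE))
  n_dys <- max(round(spec$frac_dysregulated * spec$n_genes),
               length(anchor_genes))
  pad <- setdiff(gene_ids, anchor_genes)
  set.seed(sub[3L])
  dys_genes <- c(anchor_genes,
                 sample(pad, n_dys - length(anchor_genes)))

  # expression: baseline N(0,1), case-group shift on dysregulated genes
  n_s <- spec$n_samples_per_group
  x <- matrix(stats::rnorm(spec$n_genes * 2L * n_s), nrow = spec$n_genes,
              dimnames = list(gene_ids,
                              c(sprintf("case_%03d", seq_len(n_s)),
                                sprintf("ctrl_%03d", seq_len(n_s)))))
  group <- rep(c("case", "control"), each = n_s)
  x[dys_genes, group == "case"] <-
    x[dys_genes, group == "case"] + spec$effect_size
  expression <- expression_dataset(x, group)

  desc <- stats::setNames(
    ifelse(vapply(sets, function(g) any(g %in% anchor_genes), logical(1)),
           "contains_dysregulated", "null_set"), set_ids)

  structure(list(expression = expression, catalog = catalog,
                 sets = gene_set_collection(sets, desc),
                 true_drugs = true_ids,
                 dysregulated_genes = dys_genes,
                 spec = spec),
            class = "BenchmarkBundle")
}

#' Write a benchmark bundle as pipeline-ready files
#'
#' Emits the exact formats the readers consume: \code{expression.tsv},
#' \code{phenotype.tsv} (labels "case"/"control"), \code{drug_targets.tsv},
#' \code{gene_sets.gmt}, and \code{true_drugs.txt}.
#'
#' @param bundle A \code{BenchmarkBundle}.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the five file paths, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "BenchmarkBundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             phenotype = file.path(dir, "phenotype.tsv"),
             targets = file.path(dir, "drug_targets.tsv"),
             gene_sets = file.path(dir, "gene_sets.gmt"),
             true_drugs = file.path(dir, "true_drugs.txt"))

  x <- bundle$expression$values
  expr <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                     stringsAsFactors = FALSE)
  utils::write.table(expr, paths["expression"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  ph <- data.frame(sample_id = colnames(x),
                   label = as.character(bundle$expression$group))
  utils::write.table(ph, paths["phenotype"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  tg <- bundle$catalog$targets
  dt <- data.frame(
    drug_id = rep(names(tg), lengths(tg)),
    drug_name = rep(unname(bundle$catalog$drug_names[names(tg)]),
                    lengths(tg)),
    target_gene = unlist(tg, use.names = FALSE))
  utils::write.table(dt, paths["targets"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  gmt <- vapply(names(bundle$sets$sets), function(id) {
    paste(c(id, bundle$sets$descriptions[[id]], bundle$sets$sets[[id]]),
          collapse = "\t")
  }, character(1))
  writeLines(gmt, paths["gene_sets"])

  writeLines(bundle$true_drugs, paths["true_drugs"])
  invisible(paths)
}
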