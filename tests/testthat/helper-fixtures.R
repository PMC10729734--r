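# Small in-code fixtures shared across test files.

# gene x sample matrix with named dims
tiny_matrix <- function(n_genes = 5, n_case = 3, n_control = 3, seed = 42) {
  set.seed(seed)
  x <- matrix(rnorm(n_genes * (n_case + n_control)), nrow = n_genes,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              c(sprintf("case_%d", seq_len(n_case)),
                                sprintf("ctrl_%d", seq_len(n_control)))))
  x
}

tiny_dataset <- function(n_genes = 5, n_case = 3, n_control = 3, seed = 42) {
  x <- tiny_matrix(n_genes, n_case, n_control, seed)
  expression_dataset(x, rep(c("case", "control"), c(n_case, n_control)))
}

# write expression + phenotype TSVs; returns the two paths
write_expression_files <- function(x, labels,
                                   dir = withr::local_tempdir(.local_envir = parent.frame()),
                                   case_label = "case",
                                   control_label = "control") {
  mp <- file.path(dir, "expr.tsv")
  pp <- file.path(dir, "pheno.tsv")
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE)
  write.table(df, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample_id = colnames(x), label = labels),
              pp, sep = "\t", quote = FALSE, row.names = FALSE)
  list(matrix = mp, phenotype = pp)
}

write_targets_file <- function(targets, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  p <- file.path(dir, "targets.tsv")
  df <- data.frame(drug_id = rep(names(targets), lengths(targets)),
                   target_gene = unlist(targets, use.names = FALSE))
  write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  p
}

write_gmt_file <- function(sets, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  p <- file.path(dir, "sets.gmt")
  writeLines(vapply(names(sets), function(id)
    paste(c(id, "desc", sets[[id]]), collapse = "\t"), character(1)), p)
  p
}

# random drug/set/DE instance for oracle loops
random_instance <- function(n_drugs, n_sets, n_genes, seed) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  targets <- lapply(seq_len(n_drugs), function(i)
    sample(genes, sample(4:8, 1)))
  names(targets) <- sprintf("D%02d", seq_len(n_drugs))
  sets <- lapply(seq_len(n_sets), function(i)
    sample(genes, sample(6:10, 1)))
  names(sets) <- sprintf("S%02d", seq_len(n_sets))
  de <- setNames(abs(rnorm(n_genes)), genes)
  list(cat = drug_target_catalog(targets),
       sets = gene_set_collection(sets), de = de)
}

# random column-stochastic matrix with zero diagonal
random_transition <- function(n, seed) {
  set.seed(seed)
  A <- matrix(runif(n * n), n, n)
  A <- A + t(A)            # symmetric like a similarity projection
  diag(A) <- 0
  dimnames(A) <- list(sprintf("D%03d", seq_len(n)),
                      sprintf("D%03d", seq_len(n)))
  sweep(A, 2, colSums(A), "/")
}

# independent BH step-up oracle: sort ascending, p(i)*m/i, cumulative min
# from the largest rank down, mapped back to input order
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}
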