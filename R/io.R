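#' Construct an expression dataset
#'
#' Bundles a gene-by-sample expression matrix with a binary case/control
#' phenotype. This is the container every downstream step consumes.
#'
#' @param values Numeric matrix, genes in rows (rownames are gene ids),
#'   samples in columns (colnames are sample ids).
#' @param group Character or factor of length \code{ncol(values)} with values
#'   \code{"case"} or \code{"control"}, aligned with the columns.
#' @return An object of class \code{ExpressionDataset}: a list with elements
#'   \code{values} and \code{group} (a factor with levels control, case).
#' @export
expression_dataset <- function(values, group) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids in expression matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in expression matrix")
  group <- as.character(group)
  if (length(group) != ncol(values))
    stop("`group` length must equal the number of samples")
  if (!all(group %in% c("case", "control")))
    stop("`group` entries must be 'case' or 'control'")
  tab <- table(factor(group, levels = c("control", "case")))
  if (any(tab < 2))
    stop("each of the case and control groups needs at least 2 samples")
  structure(
    list(values = values,
         group = factor(group, levels = c("control", "case"))),
    class = "ExpressionDataset"
  )
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat("ExpressionDataset:", nrow(x$values), "genes x", ncol(x$values),
      "samples (", sum(x$group == "case"), "case /",
      sum(x$group == "control"), "control )\n")
  invisible(x)
}

#' Read an expression matrix and its phenotype file
#'
#' The matrix file is a TSV whose first column holds gene ids and whose header
#' row holds sample ids. The phenotype file is a two-column TSV (header
#' required) mapping sample id to a group label. Samples whose label matches
#' neither \code{case_label} nor \code{control_label} are dropped; a matrix
#' sample absent from the phenotype file is an error. Duplicate gene rows are
#' collapsed by their mean, a deterministic, order-independent rule.
#'
#' @param matrix_path Path to the expression TSV.
#' @param phenotype_path Path to the two-column phenotype TSV.
#' @param case_label,control_label Labels in the phenotype file to treat as
#'   case and control.
#' @return An \code{\link{expression_dataset}}.
#' @export
read_expression <- function(matrix_path, phenotype_path,
                            case_label = "case", control_label = "control") {
  mat <- utils::read.delim(matrix_path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(mat) < 2) stop("expression matrix needs a gene column and >=1 sample")
  genes <- trimws(as.character(mat[[1L]]))
  x <- as.matrix(mat[, -1L, drop = FALSE])
  storage.mode(x) <- "double"
  rownames(x) <- genes

  ph <- utils::read.delim(phenotype_path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(ph) < 2) stop("phenotype file must have two columns (sample, label)")
  ph_sample <- trimws(as.character(ph[[1L]]))
  ph_label <- trimws(as.character(ph[[2L]]))

  missing <- setdiff(colnames(x), ph_sample)
  if (length(missing))
    stop("sample(s) missing from phenotype file: ",
         paste(missing, collapse = ", "))

  label <- ph_label[match(colnames(x), ph_sample)]
  keep <- label %in% c(case_label, control_label)
  x <- x[, keep, drop = FALSE]
  group <- ifelse(label[keep] == case_label, "case", "control")

  # collapse duplicate gene rows by mean
  if (anyDuplicated(rownames(x))) {
    counts <- table(rownames(x))
    x <- rowsum(x, group = rownames(x), reorder = FALSE)
    x <- x / as.vector(counts[rownames(x)])
  }
  expression_dataset(x, group)
}

#' Construct a drug-target catalog
#'
#' @param targets Named list; each element is a character vector of target
#'   gene ids for one drug (names are drug ids).
#' @param drug_names Optional named character vector of human-readable drug
#'   names; defaults to the drug ids.
#' @return An object of class \code{DrugTargetCatalog}.
#' @export
drug_target_catalog <- function(targets, drug_names = NULL) {
  if (is.null(names(targets)) || anyDuplicated(names(targets)))
    stop("`targets` must be a uniquely named list")
  targets <- lapply(targets, function(g) unique(trimws(as.character(g))))
  if (is.null(drug_names)) {
    drug_names <- stats::setNames(names(targets), names(targets))
  } else {
    drug_names <- stats::setNames(as.character(drug_names[names(targets)]),
                                  names(targets))
    drug_names[is.na(drug_names)] <- names(targets)[is.na(drug_names)]
  }
  structure(list(targets = targets, drug_names = drug_names),
            class = "DrugTargetCatalog")
}

#' @export
print.DrugTargetCatalog <- function(x, ...) {
  sz <- lengths(x$targets)
  cat("DrugTargetCatalog:", length(x$targets), "drugs; target-set sizes",
      min(sz), "-", max(sz), "\n")
  invisible(x)
}

#' Read a drug-target TSV and apply the target-count filter
#'
#' Expects a header row and columns \code{drug_id}, optionally
#' \code{drug_name}, and \code{target_gene}, one row per (drug, target) pair.
#' Duplicate pairs are deduplicated. Drugs are retained only when their
#' target-set size lies in \code{[min_size, max_size]}; the defaults encode
#' the convention of keeping drugs with more than 3 but fewer than 500
#' targets, which avoids degenerate and promiscuous target sets.
#'
#' @param path Path to the TSV.
#' @param min_size,max_size Inclusive bounds on target-set size.
#' @return A \code{\link{drug_target_catalog}}.
#' @export
read_drug_targets <- function(path, min_size = 4L, max_size = 499L) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  cn <- tolower(names(tab))
  id_col <- which(cn == "drug_id")
  gene_col <- which(cn == "target_gene")
  name_col <- which(cn == "drug_name")
  if (!length(id_col) || !length(gene_col))
    stop("drug-target file needs 'drug_id' and 'target_gene' columns")
  ids <- trimws(as.character(tab[[id_col]]))
  genes <- trimws(as.character(tab[[gene_col]]))
  keep <- !duplicated(paste0(ids, "\r", genes))
  ids <- ids[keep]; genes <- genes[keep]
  targets <- split(genes, ids)
  sz <- lengths(targets)
  targets <- targets[sz >= min_size & sz <= max_size]
  if (!length(targets))
    stop("no drugs remain after the target-set size filter [",
         min_size, ", ", max_size, "]")
  drug_names <- NULL
  if (length(name_col)) {
    nm <- trimws(as.character(tab[[name_col]]))[keep]
    drug_names <- tapply(nm, ids[seq_along(nm)], `[`, 1L)
  }
  drug_target_catalog(targets, drug_names)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (names are set ids).
#' @param descriptions Optional named character vector of set descriptions.
#' @return An object of class \code{GeneSetCollection}.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("`sets` must be a uniquely named list")
  sets <- lapply(sets, function(g) unique(trimws(as.character(g))))
  if (is.null(descriptions))
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  structure(list(sets = sets,
                 descriptions = stats::setNames(
                   as.character(descriptions[names(sets)]), names(sets))),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  sz <- lengths(x$sets)
  cat("GeneSetCollection:", length(x$sets), "sets; sizes",
      min(sz), "-", max(sz), "\n")
  invisible(x)
}

#' Read a GMT gene-set file and apply the size filter
#'
#' Standard GMT: one set per line, tab-separated fields
#' \code{set_id<TAB>description<TAB>gene1<TAB>gene2...}. Sets are retained
#' only when their size lies in \code{[min_size, max_size]}; the defaults
#' keep sets with more than 5 and fewer than 100 genes, avoiding overly
#' narrow or broad functional categories.
#'
#' @param path Path to the GMT file.
#' @param min_size,max_size Inclusive bounds on set size.
#' @return A \code{\link{gene_set_collection}}.
#' @export
read_gene_sets <- function(path, min_size = 6L, max_size = 99L) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("malformed GMT line ", bad[1L], ": fewer than 3 tab-separated fields")
  ids <- vapply(fields, function(f) trimws(f[1L]), character(1))
  desc <- vapply(fields, function(f) trimws(f[2L]), character(1))
  sets <- lapply(fields, function(f) unique(trimws(f[-(1:2)])))
  names(sets) <- ids
  sz <- lengths(sets)
  keep <- sz >= min_size & sz <= max_size
  if (!any(keep))
    stop("no gene sets remain after the size filter [", min_size, ", ",
         max_size, "]")
  gene_set_collection(sets[keep], stats::setNames(desc, ids)[keep])
}

#' Write a drug result table to TSV
#'
#' Columns: drug_id, drug_name, centrality_score, p_value, fdr, rank; rows
#' sorted by descending centrality with ties broken by drug_id. Numeric
#' columns are printed to 6 significant digits.
#'
#' @param table A drug result data frame as produced by
#'   \code{\link{rank_drugs}}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_results <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop("result table is empty")
  ord <- order(-table$centrality_score, table$drug_id)
  tab <- table[ord, , drop = FALSE]
  out <- data.frame(
    drug_id = tab$drug_id,
    drug_name = tab$drug_name,
    centrality_score = signif(tab$centrality_score, 6),
    p_value = if ("p_value" %in% names(tab)) signif(tab$p_value, 6) else NA,
    fdr = if ("fdr" %in% names(tab)) signif(tab$fdr, 6) else NA,
    rank = tab$rank,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a drug-drug similarity network as an edge list
#'
#' Emits one row per unordered drug pair with similarity strictly greater
#' than \code{min_weight}; the first id of each row sorts lexicographically
#' before the second. Weights are printed to 6 significant digits.
#'
#' @param net A \code{DrugSimilarityMatrix} (see
#'   \code{\link{project_similarity}}).
#' @param path Output path.
#' @param min_weight Edges with similarity \code{<= min_weight} are omitted.
#' @return The path, invisibly.
#' @export
write_edge_list <- function(net, path, min_weight = 0) {
  A <- net$A
  ids <- net$drug_ids
  idx <- which(upper.tri(A) & A > min_weight, arr.ind = TRUE)
  a <- ids[idx[, 1L]]
  b <- ids[idx[, 2L]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  w <- A[idx]
  ord <- order(a, b)
  out <- data.frame(drug_a = a[ord], drug_b = b[ord],
                    similarity = signif(w[ord], 6),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an edge list written by \code{\link{write_edge_list}}
#'
#' @param path Path to the edge-list TSV.
#' @return Data frame with columns drug_a, drug_b, similarity.
#' @export
read_edge_list <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
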