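# Interchange formats: tab-separated tables with '#' comment headers,
# numeric values written as decimal text at 17 significant digits so a
# write -> read round trip is lossless.

fmt_num <- function(x) formatC(x, digits = 17, format = "g")

read_tsv_checked <- function(path, comment = "#", sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  read.table(
    path, header = TRUE, sep = sep, comment.char = comment,
    stringsAsFactors = FALSE, check.names = FALSE, quote = ""
  )
}

#' Read an expression matrix and its design table
#'
#' The expression file is tab-separated: first column the gene id,
#' header row the sample ids. The design table is comma- or
#' tab-separated (autodetected) with columns `sample_id`, `ecotype`,
#' `treatment`, `replicate`. Duplicate gene or sample ids are an error
#' naming the offending line.
#'
#' @param expr_path Path to the expression matrix file.
#' @param design_path Path to the design table.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(expr_path, design_path) {
  if (!file.exists(expr_path)) stop("file not found: ", expr_path)
  tab <- read.table(
    expr_path, header = TRUE, sep = "\t", comment.char = "#",
    stringsAsFactors = FALSE, check.names = FALSE, quote = ""
  )
  gene_ids <- as.character(tab[[1L]])
  if (anyDuplicated(gene_ids)) {
    dup <- which(duplicated(gene_ids))[1L]
    stop(
      "duplicate gene id '", gene_ids[dup], "' at data line ", dup,
      " of ", expr_path
    )
  }
  values <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(values)) stop("non-numeric expression values in ", expr_path)
  rownames(values) <- gene_ids
  design <- read_design(design_path)
  expression_matrix(values, design)
}

#' Read a design table
#'
#' @param path Comma- or tab-separated file with columns `sample_id`,
#'   `ecotype`, `treatment` (`control`/`heat`), `replicate`.
#' @return Data frame.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  design <- read.table(
    path, header = TRUE, sep = sep, comment.char = "#",
    stringsAsFactors = FALSE, quote = ""
  )
  required <- c("sample_id", "ecotype", "treatment", "replicate")
  missing_cols <- setdiff(required, names(design))
  if (length(missing_cols)) {
    stop("design is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  bad <- which(!design$treatment %in% c("control", "heat"))
  if (length(bad)) {
    stop(
      "unknown treatment label '", design$treatment[bad[1L]],
      "' at data line ", bad[1L], " of ", path
    )
  }
  design
}

#' Write an expression matrix and design table
#'
#' @param expr An [expression_matrix()].
#' @param expr_path,design_path Output paths (expression tab-separated;
#'   design tab-separated).
#' @export
write_expression <- function(expr, expr_path, design_path = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  tab <- data.frame(
    gene_id = rownames(expr$values),
    apply(expr$values, 2L, fmt_num),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  names(tab) <- c("gene_id", colnames(expr$values))
  write.table(
    tab, expr_path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  if (!is.null(design_path)) {
    write.table(
      expr$design, design_path, sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(expr_path)
}

#' Read an annotation table
#'
#' Tab-separated with columns `gene_id`, `tags` (semicolon-joined) and
#' optionally `family`.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_annotation <- function(path) {
  annot <- read_tsv_checked(path)
  if (!all(c("gene_id", "tags") %in% names(annot))) {
    stop("annotation must have columns gene_id and tags: ", path)
  }
  dup <- which(duplicated(annot$gene_id))
  if (length(dup)) {
    stop(
      "duplicate gene id '", annot$gene_id[dup[1L]], "' at data line ",
      dup[1L], " of ", path
    )
  }
  annot
}

#' Write / read a signed edge list
#'
#' Tab-separated columns `tf_id`, `target_id`, `r`, `sign`. On reading,
#' a sign column inconsistent with the sign of `r` is an error naming
#' the line.
#'
#' @param net A `regulatory_network`.
#' @param path File path.
#' @return `read_edge_list` returns a `regulatory_network`;
#'   `write_edge_list` returns the path invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "regulatory_network"))
  e <- net$edges
  tab <- data.frame(
    tf_id = e$tf_id, target_id = e$target_id,
    r = fmt_num(e$weight), sign = e$sign,
    stringsAsFactors = FALSE
  )
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  tab <- read_tsv_checked(path)
  required <- c("tf_id", "target_id", "r", "sign")
  if (!all(required %in% names(tab))) {
    stop("edge list must have columns: ", paste(required, collapse = ", "))
  }
  bad <- which(sign(tab$r) != tab$sign)
  if (length(bad)) {
    stop(
      "edge sign inconsistent with r at data line ", bad[1L], " of ", path,
      " (r = ", tab$r[bad[1L]], ", sign = ", tab$sign[bad[1L]], ")"
    )
  }
  dup <- which(duplicated(tab[, c("tf_id", "target_id")]))
  if (length(dup)) {
    stop("duplicate edge at data line ", dup[1L], " of ", path)
  }
  structure(
    list(
      tfs = sort(unique(tab$tf_id)),
      targets = sort(unique(tab$target_id)),
      edges = data.frame(
        tf_id = tab$tf_id, target_id = tab$target_id,
        weight = tab$r, sign = as.integer(tab$sign),
        stringsAsFactors = FALSE
      )
    ),
    class = "regulatory_network"
  )
}

#' Export a network in SIF-like format
#'
#' One line per edge: `tf relation target`, relation `activates` or
#' `represses`.
#'
#' @param net A `regulatory_network`.
#' @param path File path.
#' @export
write_sif <- function(net, path) {
  stopifnot(inherits(net, "regulatory_network"))
  rel <- ifelse(net$edges$sign > 0, "activates", "represses")
  writeLines(
    paste(net$edges$tf_id, rel, net$edges$target_id, sep = "\t"), path
  )
  invisible(path)
}

#' Write a fitted NCA model
#'
#' Writes `a_hat` (gene x TF, support entries only, long format),
#' `p_hat` (TF x condition) and a key-value metadata block (tolerance,
#' iterations, ridge, convergence).
#'
#' @param model An `nca_model`.
#' @param dir Output directory (created if needed).
#' @export
write_nca_model <- function(model, dir) {
  stopifnot(inherits(model, "nca_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nz <- which(model$a_hat != 0, arr.ind = TRUE)
  a_tab <- data.frame(
    gene_id = rownames(model$a_hat)[nz[, 1L]],
    tf_id = colnames(model$a_hat)[nz[, 2L]],
    strength = fmt_num(model$a_hat[nz]),
    stringsAsFactors = FALSE
  )
  write.table(
    a_tab, file.path(dir, "a_hat.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  p_tab <- data.frame(
    tf_id = rownames(model$p_hat),
    apply(model$p_hat, 2L, fmt_num),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  names(p_tab) <- c("tf_id", colnames(model$p_hat))
  write.table(
    p_tab, file.path(dir, "p_hat.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  meta <- c(
    iterations = model$iterations,
    converged = model$converged,
    ridge = fmt_num(model$ridge),
    final_objective = fmt_num(tail_or(model$residual_trace, NA_real_))
  )
  writeLines(paste(names(meta), meta, sep = ": "), file.path(dir, "model.meta"))
  invisible(dir)
}

#' Export a clustering as a Newick tree
#'
#' @param clustering Result of [hierarchical_cluster()] (or an `hclust`).
#' @param path File path.
#' @export
write_newick <- function(clustering, path) {
  hc <- if (inherits(clustering, "hclust")) clustering else clustering$hclust
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Load a packaged table fixture
#'
#' Verbatim transcriptions of printed summary tables from a
#' multi-ecotype heat-stress array study, used by the test suite:
#' \describe{
#'   \item{table1}{Per-ecotype differential-expression counts (total /
#'     up / down and ecotype-unique splits).}
#'   \item{table2}{Per-TF predicted connection counts of the 35-TF
#'     regulatory network (see the file's header comment about its
#'     activation/repression column labels).}
#'   \item{table3}{Ecotypes in which each of the 35 TFs was called
#'     active.}
#'   \item{curated_tf_list}{The printed members of the curated
#'     heat-responsive TF list (the 35 loci of table2; the full curated
#'     list was longer but is not printed).}
#' }
#'
#' @param name One of `"table1"`, `"table2"`, `"table3"`,
#'   `"curated_tf_list"`.
#' @return Data frame.
#' @export
load_fixture <- function(name = c("table1", "table2", "table3",
                                  "curated_tf_list")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "heatnca")
  if (!nzchar(path)) stop("fixture not found: ", name)
  read_tsv_checked(path)
}
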