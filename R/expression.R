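#' Construct an expression matrix with per-sample design metadata
#'
#' Bundles a genes-by-samples matrix of log2-scale expression values with
#' the experimental design: which ecotype each array belongs to, whether
#' it is a control or heat-treated sample, and its replicate number.
#'
#' @param values Numeric matrix, genes in rows (unique rownames = locus
#'   identifiers), samples in columns (unique colnames = sample ids),
#'   log2 scale.
#' @param design Data frame with columns `sample_id`, `ecotype`,
#'   `treatment` (`"control"` or `"heat"`) and `replicate` (positive
#'   integer). Rows must correspond one-to-one with the columns of
#'   `values` (matched by `sample_id`).
#'
#' @return An object of class `expression_matrix` with elements `values`
#'   and `design`.
#' @export
expression_matrix <- function(values, design) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || anyDuplicated(gene_ids)) {
    stop("`values` must have unique rownames (gene ids)")
  }
  if (is.null(sample_ids) || anyDuplicated(sample_ids)) {
    stop("`values` must have unique colnames (sample ids)")
  }
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  required <- c("sample_id", "ecotype", "treatment", "replicate")
  missing_cols <- setdiff(required, names(design))
  if (length(missing_cols)) {
    stop("design is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(design$sample_id)) {
    stop("design sample_id values must be unique")
  }
  if (!setequal(design$sample_id, sample_ids)) {
    stop("design sample_id set must match the columns of `values`")
  }
  bad_trt <- setdiff(unique(design$treatment), c("control", "heat"))
  if (length(bad_trt)) {
    stop("unknown treatment label(s): ", paste(bad_trt, collapse = ", "))
  }
  if (any(!is.finite(design$replicate)) || any(design$replicate < 1)) {
    stop("replicate must be a positive integer")
  }
  design <- design[match(sample_ids, design$sample_id), , drop = FALSE]
  rownames(design) <- NULL
  structure(
    list(values = values, design = design),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(
    "expression_matrix:", nrow(x$values), "genes x", ncol(x$values),
    "samples\n"
  )
  tab <- table(x$design$ecotype, x$design$treatment)
  cat("ecotypes:", paste(rownames(tab), collapse = ", "), "\n")
  print(tab)
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

# Columns (sample indices) for one (ecotype, treatment) cell.
cell_columns <- function(expr, ecotype, treatment) {
  which(expr$design$ecotype == ecotype & expr$design$treatment == treatment)
}

# Ensure an ecotype is present with both arms and minimum replication.
check_two_arms <- function(expr, ecotype, min_reps = 2L) {
  if (!ecotype %in% expr$design$ecotype) {
    stop("unknown ecotype: ", ecotype)
  }
  for (trt in c("control", "heat")) {
    n <- length(cell_columns(expr, ecotype, trt))
    if (n == 0L) {
      stop("ecotype ", ecotype, " has no ", trt, " samples")
    }
    if (n < min_reps) {
      stop(
        "ecotype ", ecotype, " has only ", n, " ", trt,
        " replicate(s); need at least ", min_reps
      )
    }
  }
  invisible(TRUE)
}
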