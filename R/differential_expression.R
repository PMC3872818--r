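#' Per-gene log2 fold change for one ecotype
#'
#' Mean log2 expression of the heat replicates minus the mean of the
#' control replicates, per gene.
#'
#' @param expr An [expression_matrix()].
#' @param ecotype Ecotype label present in the design with both arms.
#'
#' @return Named numeric vector (one value per gene).
#' @export
log2_fold_change <- function(expr, ecotype) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (!ecotype %in% expr$design$ecotype) {
    stop("unknown ecotype: ", ecotype)
  }
  heat <- cell_columns(expr, ecotype, "heat")
  ctrl <- cell_columns(expr, ecotype, "control")
  if (length(heat) == 0L) stop("ecotype ", ecotype, " has no heat samples")
  if (length(ctrl) == 0L) stop("ecotype ", ecotype, " has no control samples")
  rowMeans(expr$values[, heat, drop = FALSE]) -
    rowMeans(expr$values[, ctrl, drop = FALSE])
}

#' Log2 fold-change matrix across ecotypes
#'
#' Convenience wrapper: one [log2_fold_change()] column per ecotype.
#'
#' @param expr An [expression_matrix()].
#' @param ecotypes Ecotype labels; defaults to all in the design.
#' @return Numeric matrix, genes x ecotypes.
#' @export
fold_change_matrix <- function(expr, ecotypes = unique(expr$design$ecotype)) {
  fc <- vapply(
    ecotypes, function(e) log2_fold_change(expr, e),
    numeric(nrow(expr$values))
  )
  dimnames(fc) <- list(rownames(expr$values), ecotypes)
  fc
}

#' Per-ecotype two-sample t-tests (heat vs control)
#'
#' Two-sided per-gene t-test of heat against control replicates within
#' one ecotype. The default is the Welch (unequal-variance) test;
#' `var_equal = TRUE` gives the pooled-variance Student test. Degenerate
#' genes with zero variance in both arms and equal means are assigned
#' p = 1 by convention (conservative; keeps constant probes in the
#' pipeline); zero variance with unequal means gives p = 0.
#'
#' @param expr An [expression_matrix()].
#' @param ecotype Ecotype label; both arms need >= 2 replicates.
#' @param alpha Significance cut-off for the `significant` flag
#'   (default 0.01).
#' @param var_equal Use pooled variance instead of Welch.
#' @param adjust P-value adjustment applied before the cut-off:
#'   `"none"` (default, raw p-values) or `"BH"`.
#'
#' @return Data frame of per-gene records: `gene_id`, `ecotype`,
#'   `log2fc`, `t_pvalue`, `direction` (`"up"`/`"down"`, `NA` when the
#'   fold change is exactly zero) and `significant`.
#' @export
per_ecotype_t_test <- function(expr, ecotype, alpha = 0.01,
                               var_equal = FALSE, adjust = c("none", "BH")) {
  stopifnot(inherits(expr, "expression_matrix"))
  stopifnot(alpha > 0, alpha < 1)
  adjust <- match.arg(adjust)
  check_two_arms(expr, ecotype, min_reps = 2L)
  h <- expr$values[, cell_columns(expr, ecotype, "heat"), drop = FALSE]
  c_ <- expr$values[, cell_columns(expr, ecotype, "control"), drop = FALSE]
  nh <- ncol(h)
  nc <- ncol(c_)
  mh <- rowMeans(h)
  mc <- rowMeans(c_)
  vh <- row_vars(h)
  vc <- row_vars(c_)
  if (var_equal) {
    sp2 <- ((nh - 1) * vh + (nc - 1) * vc) / (nh + nc - 2)
    se2 <- sp2 * (1 / nh + 1 / nc)
    df <- rep(nh + nc - 2, length(mh))
  } else {
    se2 <- vh / nh + vc / nc
    df <- se2^2 / ((vh / nh)^2 / (nh - 1) + (vc / nc)^2 / (nc - 1))
  }
  tt <- (mh - mc) / sqrt(se2)
  p <- 2 * pt(-abs(tt), df)
  degen <- se2 == 0
  p[degen] <- ifelse(mh[degen] == mc[degen], 1, 0)
  if (adjust == "BH") {
    p_use <- stats::p.adjust(p, method = "BH")
  } else {
    p_use <- p
  }
  log2fc <- mh - mc
  data.frame(
    gene_id = rownames(expr$values),
    ecotype = ecotype,
    log2fc = log2fc,
    t_pvalue = p,
    direction = ifelse(log2fc > 0, "up", ifelse(log2fc < 0, "down", NA)),
    significant = p_use <= alpha,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Genotype-by-treatment interaction p-values (two-way ANOVA)
#'
#' Per gene, fits the two-factor fixed-effects model
#' `expression ~ ecotype * treatment` and returns the p-value of the
#' interaction term. On balanced designs a vectorised cell-means
#' decomposition is used (identical to the `lm`/`aov` interaction F;
#' sum-of-squares type is immaterial under balance). Unbalanced but
#' complete designs fall back to per-gene linear models with the
#' interaction fitted last. Any empty (ecotype, treatment) cell, or a
#' cell with fewer than 2 replicates, is an error naming the cell.
#'
#' @param expr An [expression_matrix()] with >= 2 ecotypes.
#' @param alpha Cut-off used for the `significant` flag (default 0.01).
#'
#' @return Data frame: `gene_id`, `interaction_pvalue`, `significant`.
#' @export
interaction_anova <- function(expr, alpha = 0.01) {
  stopifnot(inherits(expr, "expression_matrix"))
  stopifnot(alpha > 0, alpha < 1)
  eco <- factor(expr$design$ecotype)
  trt <- factor(expr$design$treatment, levels = c("control", "heat"))
  a <- nlevels(eco)
  b <- nlevels(trt)
  if (a < 2) stop("interaction ANOVA needs at least 2 ecotypes")
  if (b < 2) stop("both control and heat samples are required")
  counts <- table(eco, trt)
  if (any(counts == 0)) {
    idx <- which(counts == 0, arr.ind = TRUE)[1L, ]
    stop(
      "empty design cell: ecotype ", rownames(counts)[idx[1L]],
      ", treatment ", colnames(counts)[idx[2L]]
    )
  }
  if (any(counts < 2)) {
    idx <- which(counts < 2, arr.ind = TRUE)[1L, ]
    stop(
      "design cell with a single replicate: ecotype ",
      rownames(counts)[idx[1L]], ", treatment ", colnames(counts)[idx[2L]]
    )
  }
  y <- expr$values
  n <- ncol(y)
  sep <- "\001" # safe separator: cannot occur in ecotype labels read from text
  cell <- factor(paste(as.character(eco), as.character(trt), sep = sep))
  if (length(unique(as.vector(counts))) == 1L) {
    # Balanced design: closed-form decomposition, vectorised over genes.
    r <- counts[1L, 1L]
    cell_sum <- t(rowsum(t(y), cell))          # genes x (a*b)
    cell_mean <- cell_sum / r
    cell_levels <- levels(cell)
    parts <- strsplit(cell_levels, sep, fixed = TRUE)
    cell_eco <- vapply(parts, `[`, character(1L), 1L)
    cell_trt <- vapply(parts, `[`, character(1L), 2L)
    grand <- rowMeans(y)
    eco_mean <- t(rowsum(t(cell_mean), cell_eco)) / b  # genes x a
    trt_mean <- t(rowsum(t(cell_mean), cell_trt)) / a  # genes x b
    dev <- cell_mean -
      eco_mean[, match(cell_eco, colnames(eco_mean)), drop = FALSE] -
      trt_mean[, match(cell_trt, colnames(trt_mean)), drop = FALSE] + grand
    ss_int <- r * rowSums(dev^2)
    fitted_cell <- cell_mean[, match(as.character(cell), cell_levels),
                             drop = FALSE]
    ss_err <- rowSums((y - fitted_cell)^2)
    df_int <- (a - 1) * (b - 1)
    df_err <- n - a * b
    fstat <- (ss_int / df_int) / (ss_err / df_err)
    p <- pf(fstat, df_int, df_err, lower.tail = FALSE)
    # Constant genes: 0/0 -> NaN; no evidence of interaction.
    p[!is.finite(fstat)] <- 1
  } else {
    p <- apply(y, 1L, function(row) {
      fit <- stats::lm(row ~ eco * trt)
      an <- stats::anova(fit)
      an[["Pr(>F)"]][rownames(an) == "eco:trt"]
    })
  }
  data.frame(
    gene_id = rownames(y),
    interaction_pvalue = unname(p),
    significant = p <= alpha,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Assemble the unified differential-expression list across ecotypes
#'
#' Takes per-ecotype test records (rows from [per_ecotype_t_test()],
#' possibly concatenated) and builds the unified list (set union of
#' significant genes over ecotypes), the per-gene ecotype-membership
#' map, and the set of "unique" genes -- those significant in exactly
#' one ecotype.
#'
#' @param records Data frame with at least `gene_id`, `ecotype`,
#'   `significant` (and `direction` for up/down splits).
#'
#' @return List with `membership` (named list: ecotype -> significant
#'   gene ids), `unified` (character vector), `unique_genes` (character
#'   vector), and `summary` (a [summarize_counts()] result).
#' @export
assemble_union <- function(records) {
  stopifnot(is.data.frame(records))
  needed <- c("gene_id", "ecotype", "significant")
  if (!all(needed %in% names(records))) {
    stop("records must have columns: ", paste(needed, collapse = ", "))
  }
  if (nrow(records) == 0L || length(unique(records$ecotype)) < 1L) {
    stop("records must cover at least one ecotype")
  }
  sig <- records[records$significant, , drop = FALSE]
  ecotypes <- unique(records$ecotype)
  membership <- lapply(
    setNames(ecotypes, ecotypes),
    function(e) unique(sig$gene_id[sig$ecotype == e])
  )
  unified <- sort(unique(unlist(membership, use.names = FALSE)))
  n_eco_per_gene <- table(unlist(lapply(membership, unique)))
  unique_genes <- sort(names(n_eco_per_gene)[n_eco_per_gene == 1L])
  list(
    membership = membership,
    unified = unified,
    unique_genes = unique_genes,
    summary = summarize_counts(records, membership)
  )
}

#' Tabulate per-ecotype differential-expression counts
#'
#' Produces the per-ecotype total / up / down counts and their
#' ecotype-unique splits, plus the unified-list size and the number of
#' genes significant in exactly one ecotype. Genes whose fold change is
#' exactly zero carry no direction: they count in totals but in neither
#' the up nor the down split.
#'
#' @param records Per-ecotype test records (see [assemble_union()]);
#'   must carry a `direction` column for the up/down splits.
#' @param membership Named list ecotype -> significant gene ids; if
#'   omitted it is derived from `records`.
#'
#' @return Object of class `de_summary`: a data frame with one row per
#'   ecotype (`ecotype`, `total`, `total_up`, `total_down`,
#'   `unique_total`, `unique_up`, `unique_down`) and attributes
#'   `unified_count` and `unique_overall_count`.
#' @export
summarize_counts <- function(records, membership = NULL) {
  stopifnot(is.data.frame(records))
  if (is.null(membership)) {
    sig <- records[records$significant, , drop = FALSE]
    ecotypes <- unique(records$ecotype)
    membership <- lapply(
      setNames(ecotypes, ecotypes),
      function(e) unique(sig$gene_id[sig$ecotype == e])
    )
  }
  counts_per_gene <- table(unlist(lapply(membership, unique)))
  unique_genes <- names(counts_per_gene)[counts_per_gene == 1L]
  has_dir <- "direction" %in% names(records)
  rows <- lapply(names(membership), function(e) {
    genes <- membership[[e]]
    rec <- records[records$ecotype == e & records$significant &
                     records$gene_id %in% genes, , drop = FALSE]
    uniq <- rec[rec$gene_id %in% unique_genes, , drop = FALSE]
    data.frame(
      ecotype = e,
      total = length(genes),
      total_up = if (has_dir) sum(rec$direction == "up", na.rm = TRUE) else NA_integer_,
      total_down = if (has_dir) sum(rec$direction == "down", na.rm = TRUE) else NA_integer_,
      unique_total = nrow(uniq),
      unique_up = if (has_dir) sum(uniq$direction == "up", na.rm = TRUE) else NA_integer_,
      unique_down = if (has_dir) sum(uniq$direction == "down", na.rm = TRUE) else NA_integer_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "unified_count") <-
    length(unique(unlist(membership, use.names = FALSE)))
  attr(out, "unique_overall_count") <- length(unique_genes)
  class(out) <- c("de_summary", "data.frame")
  out
}

#' @export
print.de_summary <- function(x, ...) {
  cat(
    "de_summary: unified =", attr(x, "unified_count"),
    "genes, unique to one ecotype =", attr(x, "unique_overall_count"), "\n"
  )
  print.data.frame(x, ...)
  invisible(x)
}

#' Tag genes with annotation categories and count per tag
#'
#' Looks each gene up in an annotation table mapping loci to category
#' tags (e.g. TF, TE, HSP) and tallies per-tag counts over the input
#' list. Genes absent from the table, or present with no tags, are
#' reported separately as unannotated.
#'
#' @param gene_ids Character vector of loci.
#' @param annot Annotation table: data frame with `gene_id`, `tags`
#'   (semicolon-joined string or list column) and optionally `family`.
#'
#' @return List with `records` (data frame `gene_id`, `tags`, `family`),
#'   `counts` (named integer vector per tag) and `unannotated`
#'   (character vector).
#' @export
annotate_genes <- function(gene_ids, annot) {
  stopifnot(is.character(gene_ids) || length(gene_ids) == 0L)
  annot <- as.data.frame(annot, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "tags") %in% names(annot))) {
    stop("annot must have columns gene_id and tags")
  }
  if (anyDuplicated(annot$gene_id)) {
    stop("annotation gene_id values must be unique")
  }
  idx <- match(gene_ids, annot$gene_id)
  tag_of <- function(i) {
    if (is.na(i)) return(character())
    tg <- annot$tags[[i]]
    if (is.character(tg) && length(tg) == 1L) {
      tg <- strsplit(tg, ";", fixed = TRUE)[[1]]
    }
    tg[nzchar(tg)]
  }
  tag_list <- lapply(idx, tag_of)
  fam <- if ("family" %in% names(annot)) annot$family[idx] else NA_character_
  counts <- table(unlist(tag_list))
  counts <- setNames(as.integer(counts), names(counts))
  records <- data.frame(
    gene_id = as.character(gene_ids),
    tags = vapply(tag_list, paste, character(1L), collapse = ";"),
    family = fam,
    stringsAsFactors = FALSE
  )
  list(
    records = records,
    counts = counts,
    unannotated = as.character(gene_ids[lengths(tag_list) == 0L])
  )
}
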