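#' Classify regulators as ecotype-specific or multi-responsive
#'
#' For each regulator, standardises its activity profile across
#' conditions with a robust z-score (centre = median, scale = MAD) and
#' calls a condition "responsive" when `|z| >= threshold_z`. Regulators
#' responsive in exactly one condition are `unique`, in two or more
#' `multi`, in none `none`. Constant activity rows (MAD = 0) are `none`
#' by convention.
#'
#' @param activities Numeric matrix, regulators x conditions (rownames =
#'   TF ids, colnames = condition labels).
#' @param threshold_z Robust z-score cut-off (default 2.0).
#'
#' @return Object of class `tf_activity_profile`: list with `tf_ids`,
#'   `conditions`, `activities`, `responsive_in` (named list per TF) and
#'   `category` (named character per TF).
#' @export
classify_responsive <- function(activities, threshold_z = 2.0) {
  activities <- as.matrix(activities)
  if (ncol(activities) < 2L) stop("at least 2 conditions are required")
  stopifnot(threshold_z > 0)
  tf_ids <- rownames(activities) %||% sprintf("tf%02d", seq_len(nrow(activities)))
  conditions <- colnames(activities) %||% sprintf("c%02d", seq_len(ncol(activities)))
  responsive_in <- lapply(seq_len(nrow(activities)), function(i) {
    x <- activities[i, ]
    s <- mad(x)
    # MAD can be 0 for non-constant rows (a majority of ties); fall back
    # to the s.d. so a clear outlier is still callable. Truly constant
    # rows have no responsive condition.
    if (s == 0) s <- sd(x)
    if (s == 0) return(character())
    z <- (x - median(x)) / s
    conditions[abs(z) >= threshold_z]
  })
  names(responsive_in) <- tf_ids
  category <- vapply(responsive_in, function(r) {
    if (length(r) == 0L) "none" else if (length(r) == 1L) "unique" else "multi"
  }, character(1L))
  structure(
    list(
      tf_ids = tf_ids, conditions = conditions, activities = activities,
      responsive_in = responsive_in, category = category
    ),
    class = "tf_activity_profile"
  )
}

#' @export
print.tf_activity_profile <- function(x, ...) {
  tab <- table(factor(x$category, levels = c("unique", "multi", "none")))
  cat(
    "tf_activity_profile:", length(x$tf_ids), "TFs x",
    length(x$conditions), "conditions |",
    tab[["unique"]], "unique,", tab[["multi"]], "multi,",
    tab[["none"]], "none\n"
  )
  invisible(x)
}

#' Hierarchical clustering with Pearson correlation distance
#'
#' Agglomerative clustering of the rows (or columns) of a matrix with
#' distance `d = 1 - Pearson r` and average linkage (UPGMA). Constant
#' profiles have undefined correlation and are dropped with a warning.
#'
#' @param mat Numeric matrix.
#' @param axis Cluster `"rows"` (default) or `"columns"`.
#'
#' @return List with `hclust` (the [stats::hclust()] tree), `labels`,
#'   `order` (leaf labels in dendrogram order) and `dropped` (labels of
#'   constant profiles).
#' @export
hierarchical_cluster <- function(mat, axis = c("rows", "columns")) {
  axis <- match.arg(axis)
  m <- as.matrix(mat)
  if (axis == "columns") m <- t(m)
  if (is.null(rownames(m))) rownames(m) <- sprintf("item%03d", seq_len(nrow(m)))
  const <- apply(m, 1L, function(x) max(x) == min(x))
  dropped <- rownames(m)[const]
  if (any(const)) {
    warning(
      sum(const), " constant profile(s) dropped before clustering: ",
      paste(head(dropped, 5L), collapse = ", ")
    )
    m <- m[!const, , drop = FALSE]
  }
  if (nrow(m) < 2L) stop("at least 2 non-constant profiles are required")
  d <- as.dist(1 - cor(t(m)))
  hc <- hclust(d, method = "average")
  list(
    hclust = hc,
    labels = rownames(m),
    order = rownames(m)[hc$order],
    dropped = dropped
  )
}

# Leaf label sets of every internal node of an hclust tree, in merge
# order. Node i of the merge matrix corresponds to element i.
node_leaf_sets <- function(hc) {
  n <- length(hc$labels)
  sets <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    members <- unlist(lapply(hc$merge[i, ], function(m) {
      if (m < 0) hc$labels[-m] else sets[[m]]
    }))
    sets[[i]] <- sort(members)
  }
  sets
}

#' Bootstrap support for hierarchical-clustering nodes
#'
#' Resamples the columns (conditions) of the matrix with replacement,
#' re-clusters each replicate with the same correlation-distance /
#' average-linkage procedure, and reports for every internal node of the
#' reference tree the fraction of replicates whose tree contains the
#' same leaf set. Replicates in which a resample renders a profile
#' constant are skipped (the support denominator is the number of usable
#' replicates). Fully seeded and reproducible.
#'
#' @param mat Numeric matrix (>= 3 rows to cluster).
#' @param n_boot Positive number of bootstrap replicates.
#' @param seed Integer seed.
#' @param axis Cluster `"rows"` (default) or `"columns"`.
#'
#' @return List with `reference` (the [hierarchical_cluster()] result on
#'   the full data), `support` (numeric in \[0, 1\] per internal node,
#'   in merge order), `node_members` (leaf sets per node) and `n_used`
#'   (usable replicates).
#' @export
bootstrap_support <- function(mat, n_boot, seed, axis = c("rows", "columns")) {
  axis <- match.arg(axis)
  if (n_boot < 1) stop("n_boot must be a positive integer")
  m <- as.matrix(mat)
  if (axis == "columns") m <- t(m)
  if (is.null(rownames(m))) rownames(m) <- sprintf("item%03d", seq_len(nrow(m)))
  if (nrow(m) < 3L) stop("at least 3 profiles are required")
  reference <- hierarchical_cluster(m, axis = "rows")
  ref_sets <- node_leaf_sets(reference$hclust)
  ref_keys <- vapply(ref_sets, paste, character(1L), collapse = "\001")
  hits <- numeric(length(ref_keys))
  n_used <- 0L
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(ncol(m), ncol(m), replace = TRUE)
      mb <- m[, idx, drop = FALSE]
      if (any(apply(mb, 1L, function(x) max(x) == min(x)))) next
      hb <- hclust(as.dist(1 - cor(t(mb))), method = "average")
      keys_b <- vapply(
        node_leaf_sets(hb), paste, character(1L), collapse = "\001"
      )
      hits <- hits + as.numeric(ref_keys %in% keys_b)
      n_used <- n_used + 1L
    }
  })
  if (n_used == 0L) stop("no usable bootstrap replicate (constant resamples)")
  list(
    reference = reference,
    support = hits / n_used,
    node_members = ref_sets,
    n_used = n_used
  )
}

#' Hypergeometric gene-set over-representation test
#'
#' One-sided hypergeometric upper-tail test, per gene set, of whether
#' the overlap between a gene list and the set (both intersected with
#' the universe) is larger than expected by chance:
#' `P[X >= overlap]` for X hypergeometric. P-values are Bonferroni
#' corrected over the number of sets tested.
#'
#' @param gene_list Character vector; must be a subset of `universe`.
#' @param universe Character vector of all assayed genes.
#' @param gene_sets Named list of character vectors (or a two-column
#'   data frame `set_id`, `gene_id`).
#'
#' @return Data frame: `set_id`, `overlap`, `set_size`, `list_size`,
#'   `universe_size`, `p_raw`, `p_adjusted`, ordered by `p_raw`.
#' @export
enrichment_test <- function(gene_list, universe, gene_sets) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("the gene universe is empty")
  gene_list <- unique(as.character(gene_list))
  outside <- setdiff(gene_list, universe)
  if (length(outside)) {
    stop(
      "gene_list must be a subset of the universe; offending: ",
      paste(head(outside, 5L), collapse = ", ")
    )
  }
  if (is.data.frame(gene_sets)) {
    stopifnot(all(c("set_id", "gene_id") %in% names(gene_sets)))
    gene_sets <- split(gene_sets$gene_id, gene_sets$set_id)
  }
  if (is.null(names(gene_sets)) || any(!nzchar(names(gene_sets)))) {
    stop("gene_sets must be named")
  }
  n_sets <- length(gene_sets)
  k <- length(gene_list)
  n_univ <- length(universe)
  rows <- lapply(names(gene_sets), function(id) {
    set <- intersect(unique(as.character(gene_sets[[id]])), universe)
    m <- length(set)
    ov <- length(intersect(set, gene_list))
    p <- phyper(ov - 1L, m, n_univ - m, k, lower.tail = FALSE)
    data.frame(
      set_id = id, overlap = ov, set_size = m, list_size = k,
      universe_size = n_univ, p_raw = p,
      p_adjusted = min(1, p * n_sets),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_raw, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
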