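#' Pearson correlation between regulator and target profiles
#'
#' Computes the full regulators-by-targets Pearson correlation matrix
#' between two sets of expression profiles measured over the same
#' conditions. Constant rows have undefined correlation and are dropped
#' with a warning before computing.
#'
#' @param tf_profiles Numeric matrix, TFs x conditions (rownames = ids).
#' @param tg_profiles Numeric matrix, targets x conditions.
#' @param method Correlation flavour: `"pearson"` (default) or
#'   `"spearman"`.
#'
#' @return Numeric matrix, TFs x targets.
#' @export
correlation_profiles <- function(tf_profiles, tg_profiles,
                                 method = c("pearson", "spearman")) {
  method <- match.arg(method)
  tf_profiles <- as.matrix(tf_profiles)
  tg_profiles <- as.matrix(tg_profiles)
  if (ncol(tf_profiles) != ncol(tg_profiles)) {
    stop("profile matrices must share the same conditions (columns)")
  }
  if (ncol(tf_profiles) < 3L) {
    stop("at least 3 conditions are required for correlation")
  }
  drop_constant <- function(m, what) {
    const <- apply(m, 1L, function(x) max(x) == min(x))
    if (any(const)) {
      warning(
        sum(const), " constant ", what,
        " profile(s) dropped (undefined correlation): ",
        paste(head(rownames(m)[const], 5L), collapse = ", ")
      )
      m <- m[!const, , drop = FALSE]
    }
    m
  }
  tf_profiles <- drop_constant(tf_profiles, "TF")
  tg_profiles <- drop_constant(tg_profiles, "target")
  cor(t(tf_profiles), t(tg_profiles), method = method)
}

#' Build a signed bipartite TF-target network by correlation threshold
#'
#' Keeps an edge for every (TF, target) pair whose absolute correlation
#' meets the threshold; the edge sign is the sign of the correlation
#' (positive = activation, negative = repression). Targets that also
#' appear in the TF list are removed from the target side first (the
#' decomposition's data model keeps regulator and target layers
#' disjoint), and TFs left without any surviving edge are dropped with
#' a message.
#'
#' @param corr Correlation matrix, TFs x targets (e.g. from
#'   [correlation_profiles()]).
#' @param threshold Absolute-correlation cut-off in (0, 1]; default 0.8.
#' @param tf_ids,target_ids Identifiers; default to `dimnames(corr)`.
#'
#' @return Object of class `regulatory_network`: list with `tfs`,
#'   `targets`, and `edges` (data frame `tf_id`, `target_id`, `weight`,
#'   `sign`).
#' @export
build_signed_network <- function(corr, threshold = 0.8,
                                 tf_ids = rownames(corr),
                                 target_ids = colnames(corr)) {
  if (!is.matrix(corr)) stop("`corr` must be a matrix")
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  if (is.null(tf_ids) || is.null(target_ids)) {
    stop("tf_ids and target_ids are required (or set dimnames on corr)")
  }
  keep_tg <- !(target_ids %in% tf_ids)
  if (any(!keep_tg)) {
    message(
      sum(!keep_tg), " target(s) also in the TF list removed from the ",
      "target side"
    )
    corr <- corr[, keep_tg, drop = FALSE]
    target_ids <- target_ids[keep_tg]
  }
  hits <- which(abs(corr) >= threshold, arr.ind = TRUE)
  edges <- data.frame(
    tf_id = tf_ids[hits[, 1L]],
    target_id = target_ids[hits[, 2L]],
    weight = corr[hits],
    sign = as.integer(sign(corr[hits])),
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$tf_id, edges$target_id), , drop = FALSE]
  rownames(edges) <- NULL
  kept_tfs <- sort(unique(edges$tf_id))
  dropped <- setdiff(tf_ids, kept_tfs)
  if (length(dropped)) {
    message(
      length(dropped), " TF(s) with no edge at |r| >= ", threshold,
      " dropped: ", paste(head(dropped, 5L), collapse = ", ")
    )
  }
  structure(
    list(
      tfs = kept_tfs,
      targets = sort(unique(edges$target_id)),
      edges = edges
    ),
    class = "regulatory_network"
  )
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(
    "regulatory_network:", length(x$tfs), "TFs,", length(x$targets),
    "targets,", nrow(x$edges), "edges (",
    sum(x$edges$sign > 0), "activating /", sum(x$edges$sign < 0),
    "repressing )\n"
  )
  invisible(x)
}

#' Convert a regulatory network to a signed connectivity pattern
#'
#' The pattern view used as the support constraint of the decomposition:
#' targets in rows, TFs in columns, entries the edge signs.
#'
#' @param net A `regulatory_network`.
#' @return A [connectivity_pattern()].
#' @export
as_pattern <- function(net) {
  stopifnot(inherits(net, "regulatory_network"))
  mat <- matrix(
    0, length(net$targets), length(net$tfs),
    dimnames = list(net$targets, net$tfs)
  )
  mat[cbind(
    match(net$edges$target_id, net$targets),
    match(net$edges$tf_id, net$tfs)
  )] <- net$edges$sign
  connectivity_pattern(mat)
}

#' Per-TF connection counts
#'
#' Tabulates, for each TF, its total number of connections and the
#' activation/repression split, sorted by total connections descending
#' (ties broken by TF id).
#'
#' @param net A `regulatory_network`.
#' @return Data frame: `tf_id`, `connections`, `activations`,
#'   `repressions`.
#' @export
degree_table <- function(net) {
  stopifnot(inherits(net, "regulatory_network"))
  if (nrow(net$edges) == 0L) {
    return(data.frame(
      tf_id = character(), connections = integer(),
      activations = integer(), repressions = integer(),
      stringsAsFactors = FALSE
    ))
  }
  e <- net$edges
  tf <- sort(unique(e$tf_id))
  act <- vapply(tf, function(t) sum(e$tf_id == t & e$sign > 0), integer(1L))
  rep_ <- vapply(tf, function(t) sum(e$tf_id == t & e$sign < 0), integer(1L))
  out <- data.frame(
    tf_id = tf,
    connections = act + rep_,
    activations = act,
    repressions = rep_,
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$connections, out$tf_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Degree distribution and top hubs of a network
#'
#' @param net A `regulatory_network`.
#' @param k Number of top hubs to report (default 5).
#' @return List with `degrees` (the [degree_table()]),
#'   `degree_distribution` (data frame `degree`, `n_tfs`), and
#'   `top_hubs` (first `k` rows of the degree table). No distribution
#'   fit is performed or claimed.
#' @export
hub_summary <- function(net, k = 5L) {
  deg <- degree_table(net)
  dist <- as.data.frame(table(deg$connections), stringsAsFactors = FALSE)
  names(dist) <- c("degree", "n_tfs")
  dist$degree <- as.integer(dist$degree)
  list(
    degrees = deg,
    degree_distribution = dist,
    top_hubs = head(deg, k)
  )
}

#' Intersect differentially expressed TFs with a curated list
#'
#' @param de_tfs Character vector of differentially expressed TF loci.
#' @param curated Character vector of curated (e.g. known
#'   heat-responsive) TF loci.
#' @return Sorted character vector of the intersection.
#' @export
intersect_curated <- function(de_tfs, curated) {
  sort(unique(intersect(as.character(de_tfs), as.character(curated))))
}
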