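# Independent oracles used across the suite. Each is a deliberately
# naive implementation (enumeration, double loops, textbook formulas)
# kept separate from the package's code paths.

# Structural (term) rank of a 0/1 pattern: size of a maximum bipartite
# matching between rows and columns -- equals the generic numeric rank.
structural_rank <- function(mat) {
  if (nrow(mat) == 0L || ncol(mat) == 0L) return(0L)
  nz <- which(mat != 0, arr.ind = TRUE)
  if (nrow(nz) == 0L) return(0L)
  g <- igraph::graph_from_edgelist(
    cbind(paste0("r", nz[, 1L]), paste0("c", nz[, 2L])),
    directed = FALSE
  )
  igraph::V(g)$type <- grepl("^c", igraph::V(g)$name)
  igraph::max_bipartite_match(g)$matching_size
}

# Identifiability criteria 1 and 2 evaluated through the matching
# oracle rather than numeric rank.
oracle_criterion1 <- function(mat) {
  ncol(mat) <= nrow(mat) &&
    all(colSums(mat != 0) > 0) &&
    structural_rank(mat) == ncol(mat)
}

oracle_criterion2 <- function(mat) {
  n_tfs <- ncol(mat)
  vapply(seq_len(n_tfs), function(l) {
    if (n_tfs == 1L) return(TRUE)
    sub <- mat[mat[, l] == 0, -l, drop = FALSE]
    structural_rank(sub) == n_tfs - 1L
  }, logical(1L))
}

# Naive UPGMA on a distance matrix: returns merge heights (sorted) and
# the leaf sets of every internal node.
upgma_oracle <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  sizes <- rep(1L, n)
  active <- rep(TRUE, n)
  heights <- numeric(0)
  node_sets <- list()
  dd <- d
  diag(dd) <- Inf
  while (sum(active) > 1L) {
    idx <- which(active)
    best <- c(NA, NA)
    best_d <- Inf
    for (i in idx) {
      for (j in idx) {
        if (i < j && dd[i, j] < best_d) {
          best_d <- dd[i, j]
          best <- c(i, j)
        }
      }
    }
    i <- best[1L]; j <- best[2L]
    merged <- sort(c(clusters[[i]], clusters[[j]]))
    heights <- c(heights, best_d)
    node_sets[[length(node_sets) + 1L]] <- merged
    # Average linkage: size-weighted mean of distances to the members.
    for (k in idx) {
      if (k == i || k == j) next
      dd[i, k] <- dd[k, i] <-
        (sizes[i] * dd[i, k] + sizes[j] * dd[j, k]) / (sizes[i] + sizes[j])
    }
    clusters[[i]] <- merged
    sizes[i] <- sizes[i] + sizes[j]
    active[j] <- FALSE
  }
  list(heights = sort(heights), node_sets = node_sets)
}

# Exhaustive hypergeometric upper-tail oracle: enumerate every possible
# gene list of the same size drawn from the universe and count how
# often the overlap with the set is at least as large as observed.
hyper_oracle <- function(universe_n, set_n, list_n, overlap) {
  combs <- utils::combn(universe_n, list_n)
  ovs <- apply(combs, 2L, function(cols) sum(cols <= set_n))
  mean(ovs >= overlap)
}

# Small helper to build an expression_matrix directly from group means.
make_expr <- function(values, ecotypes, treatments, replicates) {
  design <- data.frame(
    sample_id = colnames(values),
    ecotype = ecotypes,
    treatment = treatments,
    replicate = replicates,
    stringsAsFactors = FALSE
  )
  expression_matrix(values, design)
}

# Two-cell (one ecotype) expression matrix from explicit replicate
# values per gene: `heat` and `control` are genes x reps matrices.
two_arm_expr <- function(control, heat, ecotype = "Col-0") {
  control <- as.matrix(control)
  heat <- as.matrix(heat)
  values <- cbind(control, heat)
  rownames(values) <- rownames(control) %||%
    sprintf("AT1G%05d", seq_len(nrow(control)) * 10L)
  colnames(values) <- c(
    sprintf("%s_control_r%d", ecotype, seq_len(ncol(control))),
    sprintf("%s_heat_r%d", ecotype, seq_len(ncol(heat)))
  )
  make_expr(
    values,
    ecotypes = rep(ecotype, ncol(values)),
    treatments = rep(c("control", "heat"), c(ncol(control), ncol(heat))),
    replicates = c(seq_len(ncol(control)), seq_len(ncol(heat)))
  )
}

# Members of the cluster created at merge step `step` of an hclust tree.
cutree_members <- function(hc, step) {
  sets <- list()
  for (i in seq_len(step)) {
    sets[[i]] <- unlist(lapply(hc$merge[i, ], function(mm) {
      if (mm < 0) hc$labels[-mm] else sets[[mm]]
    }))
  }
  sets[[step]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
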