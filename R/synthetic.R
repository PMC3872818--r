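#' Construct a connectivity pattern
#'
#' A connectivity pattern is the binary (optionally signed) genes-by-TFs
#' matrix of allowed regulatory links. It constrains the support of the
#' control-strength matrix A in the decomposition E = A P.
#'
#' @param mat Numeric matrix (genes x TFs) with entries in \{-1, 0, 1\};
#'   nonzero entries mark allowed links, signs (if any) mark the expected
#'   direction of regulation.
#' @param gene_ids,tf_ids Optional identifier vectors; default to the
#'   dimnames of `mat` or generated labels.
#'
#' @return An object of class `connectivity_pattern`: a list with
#'   elements `mat`, `gene_ids`, `tf_ids`.
#' @export
connectivity_pattern <- function(mat, gene_ids = NULL, tf_ids = NULL) {
  if (!is.matrix(mat) || !is.numeric(mat)) {
    stop("`mat` must be a numeric matrix")
  }
  if (!all(mat %in% c(-1, 0, 1))) {
    stop("pattern entries must be -1, 0 or 1")
  }
  gene_ids <- gene_ids %||% rownames(mat) %||% sprintf("g%03d", seq_len(nrow(mat)))
  tf_ids <- tf_ids %||% colnames(mat) %||% sprintf("tf%02d", seq_len(ncol(mat)))
  if (anyDuplicated(gene_ids) || anyDuplicated(tf_ids)) {
    stop("gene_ids and tf_ids must be unique")
  }
  if (length(gene_ids) != nrow(mat) || length(tf_ids) != ncol(mat)) {
    stop("id lengths must match pattern dimensions")
  }
  dimnames(mat) <- list(gene_ids, tf_ids)
  structure(
    list(mat = mat, gene_ids = gene_ids, tf_ids = tf_ids),
    class = "connectivity_pattern"
  )
}

#' @export
print.connectivity_pattern <- function(x, ...) {
  cat(
    "connectivity_pattern:", nrow(x$mat), "genes x", ncol(x$mat),
    "TFs,", sum(x$mat != 0), "links\n"
  )
  invisible(x)
}

#' Generate a random identifiable connectivity pattern
#'
#' Draws a random sparse genes-by-TFs link pattern at the requested
#' density, guarantees every TF at least one target and every gene at
#' least one regulator, and rejection-samples until the pattern passes
#' the structural identifiability criteria (full column rank and per-TF
#' reduced-pattern full rank; see [check_identifiability()]).
#'
#' @param n_genes,n_tfs Positive integers, `n_tfs <= n_genes`.
#' @param density Fraction of possible links present, in (0, 1];
#'   `density * n_genes >= 1` so each TF can get a target.
#' @param seed Integer seed; identical inputs give identical patterns.
#' @param max_retries Rejection-sampling budget before giving up.
#'
#' @return A [connectivity_pattern()] (unsigned: entries 0/1).
#' @export
generate_connectivity <- function(n_genes, n_tfs, density, seed,
                                  max_retries = 100L) {
  stopifnot(n_genes >= 1, n_tfs >= 1, density > 0, density <= 1)
  if (n_tfs > n_genes) {
    stop("n_tfs must not exceed n_genes")
  }
  if (density * n_genes < 1) {
    stop("density * n_genes must be >= 1 so every TF can receive a target")
  }
  with_seed(seed, {
    for (try in seq_len(max_retries)) {
      mat <- matrix(
        as.numeric(runif(n_genes * n_tfs) < density),
        nrow = n_genes, ncol = n_tfs
      )
      # Repair empty rows/columns so the structural minimums hold.
      for (j in which(colSums(mat) == 0)) {
        mat[sample.int(n_genes, 1L), j] <- 1
      }
      for (i in which(rowSums(mat) == 0)) {
        mat[i, sample.int(n_tfs, 1L)] <- 1
      }
      pat <- connectivity_pattern(mat)
      rep <- check_identifiability(pat, n_conditions = n_tfs)
      if (rep$criterion1 && all(rep$criterion2)) {
        return(pat)
      }
    }
  })
  stop(
    "no identifiable pattern found in ", max_retries,
    " tries; the density/dimension combination appears infeasible"
  )
}

#' Simulate a ground-truth NCA instance
#'
#' Instantiates a connectivity pattern with known control strengths and
#' activities and returns noisy expression generated from them:
#' `expression = a_true %*% p_true + N(0, noise_sd)`. Nonzero control
#' strengths are drawn uniformly on +/-\[0.5, 1.5\] (bounded away from
#' zero so the support is unambiguous); true activities are i.i.d.
#' standard normal.
#'
#' @param pattern A [connectivity_pattern()].
#' @param n_conditions Positive integer number of conditions (columns of
#'   the activity matrix).
#' @param noise_sd Nonnegative additive Gaussian noise s.d. (log2 scale).
#' @param seed Integer seed.
#'
#' @return Object of class `nca_truth`: list with `seed`, `pattern`,
#'   `a_true`, `p_true`, `noise_sd`, `expression`.
#' @export
simulate_nca_instance <- function(pattern, n_conditions, noise_sd, seed) {
  stopifnot(inherits(pattern, "connectivity_pattern"))
  stopifnot(n_conditions >= 1, noise_sd >= 0)
  mat <- pattern$mat
  n_genes <- nrow(mat)
  n_tfs <- ncol(mat)
  with_seed(seed, {
    nnz <- sum(mat != 0)
    mags <- runif(nnz, 0.5, 1.5)
    # Signed patterns keep their signs; unsigned patterns get random signs.
    signs <- if (any(mat < 0)) {
      mat[mat != 0]
    } else {
      sample(c(-1, 1), nnz, replace = TRUE)
    }
    a_true <- matrix(0, n_genes, n_tfs, dimnames = dimnames(mat))
    a_true[mat != 0] <- signs * mags
    p_true <- matrix(
      rnorm(n_tfs * n_conditions), n_tfs, n_conditions,
      dimnames = list(pattern$tf_ids, sprintf("c%02d", seq_len(n_conditions)))
    )
    expression <- a_true %*% p_true
    if (noise_sd > 0) {
      expression <- expression + matrix(
        rnorm(n_genes * n_conditions, sd = noise_sd), n_genes, n_conditions
      )
    }
    structure(
      list(
        seed = seed, pattern = pattern, a_true = a_true, p_true = p_true,
        noise_sd = noise_sd, expression = expression
      ),
      class = "nca_truth"
    )
  })
}

#' Simulate a replicated multi-ecotype control/heat experiment
#'
#' Generates a log2-scale expression matrix emulating a multi-accession
#' heat-stress array study: shared per-gene baselines, triplicated (or
#' `n_reps`-replicated) control and heat arrays per ecotype, a minority
#' of genes with planted, ecotype-specific log2 shifts under heat, and
#' Gaussian replicate noise. A planted responder responds in 1, 2 or 3
#' ecotypes with probabilities 0.85/0.10/0.05, mirroring the strongly
#' ecotype-specific response structure typical of such studies.
#'
#' @param n_genes Positive integer.
#' @param ecotypes Character vector of ecotype labels.
#' @param n_reps Replicates per (ecotype, treatment) cell; at least 2.
#' @param prevalence Fraction of genes with any planted heat response,
#'   in \[0, 1\].
#' @param effect_sd S.d. of the planted log2 fold-change effect sizes
#'   (drawn from N(0, effect_sd)).
#' @param replicate_sd Replicate noise s.d. (log2 scale).
#' @param seed Integer seed.
#'
#' @return List with `expression` (an [expression_matrix()]) and `truth`
#'   (class `ecotype_sim_truth`: `seed`, `de_labels` genes-x-ecotypes
#'   logical, `effect_sizes` same shape, `replicate_sd`, `prevalence`).
#' @export
simulate_ecotype_experiment <- function(n_genes, ecotypes, n_reps,
                                        prevalence, effect_sd, replicate_sd,
                                        seed) {
  stopifnot(n_genes >= 1, length(ecotypes) >= 1, !anyDuplicated(ecotypes))
  if (n_reps < 2) {
    stop("n_reps must be at least 2 (tests need within-group variance)")
  }
  stopifnot(prevalence >= 0, prevalence <= 1, effect_sd > 0, replicate_sd > 0)
  n_eco <- length(ecotypes)
  gene_ids <- sprintf("AT%dG%05d", (seq_len(n_genes) - 1L) %% 5L + 1L,
                      seq_len(n_genes) * 10L)
  with_seed(seed, {
    baseline <- rnorm(n_genes, mean = 7, sd = 1.5)
    de_labels <- matrix(FALSE, n_genes, n_eco,
                        dimnames = list(gene_ids, ecotypes))
    effect_sizes <- matrix(0, n_genes, n_eco,
                           dimnames = list(gene_ids, ecotypes))
    n_resp <- round(prevalence * n_genes)
    if (n_resp > 0) {
      responders <- sample.int(n_genes, n_resp)
      for (g in responders) {
        k <- min(sample(1:3, 1L, prob = c(0.85, 0.10, 0.05)), n_eco)
        ecos <- sample.int(n_eco, k)
        de_labels[g, ecos] <- TRUE
        eff <- rnorm(k, 0, effect_sd)
        eff[eff == 0] <- effect_sd # measure-zero guard: labels imply effect
        effect_sizes[g, ecos] <- eff
      }
    }
    design <- expand.grid(
      replicate = seq_len(n_reps),
      treatment = c("control", "heat"),
      ecotype = ecotypes,
      stringsAsFactors = FALSE
    )[, c("ecotype", "treatment", "replicate")]
    design$sample_id <- sprintf(
      "%s_%s_r%d", design$ecotype, design$treatment, design$replicate
    )
    n_samp <- nrow(design)
    values <- matrix(baseline, n_genes, n_samp)
    heat_cols <- which(design$treatment == "heat")
    for (s in heat_cols) {
      values[, s] <- values[, s] + effect_sizes[, design$ecotype[s]]
    }
    values <- values + matrix(
      rnorm(n_genes * n_samp, sd = replicate_sd), n_genes, n_samp
    )
    dimnames(values) <- list(gene_ids, design$sample_id)
    truth <- structure(
      list(
        seed = seed, de_labels = de_labels, effect_sizes = effect_sizes,
        replicate_sd = replicate_sd, prevalence = prevalence
      ),
      class = "ecotype_sim_truth"
    )
    list(expression = expression_matrix(values, design), truth = truth)
  })
}
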