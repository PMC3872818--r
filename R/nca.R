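# Network Component Analysis: decompose expression E (genes x
# conditions) as E = A P where the support of A is fixed by a known
# connectivity pattern and the rows of P are the hidden regulator
# activities. The decomposition is essentially unique (up to per-TF
# scaling/sign) when three structural criteria hold.

# Instantiate a pattern with random nonzeros, bounded away from zero.
random_instance <- function(mat) {
  inst <- matrix(0, nrow(mat), ncol(mat))
  nnz <- sum(mat != 0)
  inst[mat != 0] <- runif(nnz, 0.5, 1.5) * sample(c(-1, 1), nnz, replace = TRUE)
  inst
}

# Generic (numerical) rank of a pattern: instantiate twice with random
# nonzeros and take the max observed rank -- a random instance achieves
# the structural rank with probability one.
generic_rank <- function(mat, n_draws = 2L) {
  if (length(mat) == 0L || nrow(mat) == 0L || ncol(mat) == 0L) return(0L)
  max(vapply(
    seq_len(n_draws),
    function(i) rank_numeric(random_instance(mat)),
    integer(1L)
  ))
}

#' Check the NCA identifiability criteria of a connectivity pattern
#'
#' Evaluates the three structural conditions under which the
#' decomposition E = A P with support(A) fixed by `pattern` is
#' essentially unique:
#' \enumerate{
#'   \item the pattern admits full column rank (needs `n_tfs <= n_genes`
#'     and no empty TF column);
#'   \item for every TF, removing its column and the rows of its support
#'     leaves a pattern that still admits full column rank on the
#'     remaining TFs;
#'   \item the number of conditions is at least the number of TFs.
#' }
#' Rank conditions are tested numerically on random instantiations of
#' the pattern (two draws at a fixed internal seed; rank tolerance
#' `1e-8` times the largest singular value), the standard generic-rank
#' surrogate for structural rank.
#'
#' @param pattern A [connectivity_pattern()].
#' @param n_conditions Number of expression conditions available.
#' @param seed Seed for the random instantiations (default 20131226).
#'
#' @return Object of class `identifiability_report`: list with
#'   `criterion1` (logical), `criterion2` (named logical per TF),
#'   `criterion3` (logical), `identifiable` (all three).
#' @export
check_identifiability <- function(pattern, n_conditions, seed = 20131226L) {
  stopifnot(inherits(pattern, "connectivity_pattern"))
  mat <- pattern$mat
  n_genes <- nrow(mat)
  n_tfs <- ncol(mat)
  with_seed(seed, {
    crit1 <- n_tfs <= n_genes &&
      all(colSums(mat != 0) > 0) &&
      generic_rank(mat) == n_tfs
    crit2 <- vapply(seq_len(n_tfs), function(l) {
      keep_rows <- mat[, l] == 0
      sub <- mat[keep_rows, -l, drop = FALSE]
      if (n_tfs == 1L) return(TRUE) # no other TFs to confound
      generic_rank(sub) == n_tfs - 1L
    }, logical(1L))
    names(crit2) <- pattern$tf_ids
    crit3 <- n_conditions >= n_tfs
    structure(
      list(
        criterion1 = crit1,
        criterion2 = crit2,
        criterion3 = crit3,
        identifiable = crit1 && all(crit2) && crit3
      ),
      class = "identifiability_report"
    )
  })
}

#' @export
print.identifiability_report <- function(x, ...) {
  cat(
    "identifiability_report: criterion1 =", x$criterion1,
    "| criterion2 =", sum(x$criterion2), "/", length(x$criterion2), "TFs",
    "| criterion3 =", x$criterion3,
    "| identifiable =", x$identifiable, "\n"
  )
  invisible(x)
}

#' Reduce a connectivity pattern to an identifiable sub-pattern
#'
#' Greedily removes TFs that fail the per-TF reduced-rank criterion
#' (lowest degree first among the failures; ties broken by TF id) until
#' criteria 1 and 2 of [check_identifiability()] pass. Gene rows left
#' without any regulator are dropped along the way. Never raises: if
#' nothing identifiable remains, an empty pattern plus the full removal
#' list is returned.
#'
#' @param pattern A [connectivity_pattern()].
#' @return List with `pattern` (the reduced [connectivity_pattern()])
#'   and `removed` (character vector of removed TF ids, in removal
#'   order).
#' @export
reduce_to_identifiable <- function(pattern) {
  stopifnot(inherits(pattern, "connectivity_pattern"))
  removed <- character()
  mat <- pattern$mat
  repeat {
    if (ncol(mat) == 0L || nrow(mat) == 0L) {
      removed <- c(removed, colnames(mat)) # TFs stranded without genes
      empty <- connectivity_pattern(
        matrix(numeric(), 0L, 0L),
        gene_ids = character(), tf_ids = character()
      )
      return(list(pattern = empty, removed = removed))
    }
    pat <- connectivity_pattern(mat)
    rep_ <- check_identifiability(pat, n_conditions = ncol(mat))
    if (rep_$criterion1 && all(rep_$criterion2)) {
      return(list(pattern = pat, removed = removed))
    }
    failing <- names(rep_$criterion2)[!rep_$criterion2]
    if (length(failing) == 0L) {
      # criterion1 alone fails (rank-deficient overall): drop the
      # lowest-degree TF.
      failing <- colnames(mat)
    }
    deg <- colSums(mat[, failing, drop = FALSE] != 0)
    victim <- failing[order(deg, failing)][1L]
    removed <- c(removed, victim)
    mat <- mat[, colnames(mat) != victim, drop = FALSE]
    mat <- mat[rowSums(mat != 0) > 0, , drop = FALSE]
  }
}

#' Fit the constrained decomposition E = A P by alternating least squares
#'
#' Minimises `||E - A P||_F^2 (+ ridge * ||P||_F^2)` subject to
#' `support(A)` contained in the pattern's nonzero set, by exact
#' alternating least-squares half-steps: the P-step solves for all
#' activities given A (ridge-regularised when `ridge > 0`); the A-step
#' solves each gene's control strengths over its allowed regulators
#' only. Iteration stops when the relative change of the objective drops
#' below `tol` or `max_iter` is reached. The returned model is
#' normalised to unit-norm A columns with signs anchored to the
#' pattern's signs when present (see [normalize_model()]).
#'
#' When the instance is under-determined in the condition direction
#' (fewer conditions than TFs, identifiability criterion 3 violated) and
#' `ridge = 0`, a default Tikhonov ridge of `1e-3` times the mean
#' diagonal of `t(A) %*% A` at initialisation is applied to the P-step
#' and a warning is emitted: the activities are then a regularised
#' representative of a non-unique solution family, not a unique
#' estimate.
#'
#' @param expression Numeric matrix, genes x conditions; rows must match
#'   the pattern's genes (matched by rowname when both are named).
#' @param pattern A [connectivity_pattern()]; signed entries are used to
#'   initialise and sign-anchor A.
#' @param tol Relative objective-change stopping tolerance
#'   (default 1e-6).
#' @param max_iter Maximum number of ALS sweeps per start (default 500).
#' @param ridge Nonnegative P-step regularisation (default 0 = choose
#'   automatically only if criterion 3 fails).
#' @param seed Seed for the random initialisations of A.
#' @param n_starts Number of random restarts (default 3). The objective
#'   `||E - A P||_F` is nonconvex in (A, P) jointly and ALS can stall in
#'   a poor local optimum from an unlucky start; the best final
#'   objective over the starts is kept. When a start reaches an
#'   essentially exact reconstruction the remaining starts are skipped.
#'   For signed patterns the first start is the sign-anchored
#'   initialisation, the rest are random.
#'
#' @return Object of class `nca_model`: list with `a_hat`, `p_hat`,
#'   `residual_trace` (the objective value
#'   `sqrt(||E - A P||_F^2 + ridge ||P||_F^2)` per sweep of the winning
#'   start, non-increasing), `iterations`, `converged`, `ridge` (the
#'   value actually applied).
#' @export
fit_nca <- function(expression, pattern, tol = 1e-6, max_iter = 500L,
                    ridge = 0, seed = 1L, n_starts = 3L) {
  stopifnot(inherits(pattern, "connectivity_pattern"))
  stopifnot(tol > 0, max_iter >= 1, ridge >= 0, n_starts >= 1)
  expression <- as.matrix(expression)
  if (anyNA(expression)) stop("expression contains NA/NaN")
  mat <- pattern$mat
  if (!is.null(rownames(expression)) &&
      all(pattern$gene_ids %in% rownames(expression))) {
    expression <- expression[pattern$gene_ids, , drop = FALSE]
  }
  if (nrow(expression) != nrow(mat)) {
    stop(
      "expression has ", nrow(expression), " rows but the pattern has ",
      nrow(mat), " genes"
    )
  }
  n_genes <- nrow(mat)
  n_tfs <- ncol(mat)
  n_cond <- ncol(expression)

  if (all(expression == 0)) {
    a_hat <- matrix(0, n_genes, n_tfs, dimnames = dimnames(mat))
    p_hat <- matrix(0, n_tfs, n_cond,
                    dimnames = list(pattern$tf_ids, colnames(expression)))
    return(structure(
      list(
        a_hat = a_hat, p_hat = p_hat, residual_trace = 0,
        iterations = 0L, converged = TRUE, ridge = ridge
      ),
      class = "nca_model"
    ))
  }

  random_init <- function(s) {
    a0 <- matrix(0, n_genes, n_tfs, dimnames = dimnames(mat))
    a0[mat != 0] <- with_seed(s, {
      nnz <- sum(mat != 0)
      runif(nnz, 0.5, 1.5) * sample(c(-1, 1), nnz, replace = TRUE)
    })
    a0
  }
  inits <- lapply(seq_len(n_starts) - 1L, function(k) random_init(seed + k))
  if (any(mat < 0)) {
    # signed prior: anchor the first start to the pattern's signs
    a0 <- matrix(0, n_genes, n_tfs, dimnames = dimnames(mat))
    a0[mat != 0] <- mat[mat != 0]
    inits[[1L]] <- a0
  }

  if (n_cond < n_tfs && ridge == 0) {
    ridge <- 1e-3 * mean(diag(crossprod(inits[[1L]])))
    warning(
      "under-determined instance (", n_cond, " conditions < ", n_tfs,
      " TFs): identifiability criterion 3 fails; applying default ridge ",
      signif(ridge, 3),
      " to the P-step. Activities are regularised, not unique.",
      call. = FALSE
    )
  }

  # Group genes by support signature so each A-step solves one
  # least-squares system per distinct regulator set.
  support <- lapply(seq_len(n_genes), function(i) which(mat[i, ] != 0))
  sig <- vapply(support, paste, character(1L), collapse = ",")
  groups <- split(seq_len(n_genes), sig)
  e_norm <- fro_norm(expression)

  run_als <- function(a_hat) {
    objective <- function(p_hat) {
      sqrt(fro_norm(expression - a_hat %*% p_hat)^2 +
             ridge * fro_norm(p_hat)^2)
    }
    trace <- numeric()
    p_hat <- NULL
    converged <- FALSE
    iter <- 0L
    for (iter in seq_len(max_iter)) {
      # P-step: (A'A + ridge I) P = A'E (min-norm fallback when singular).
      ata <- crossprod(a_hat)
      rhs <- crossprod(a_hat, expression)
      p_hat <- tryCatch(
        solve(ata + diag(ridge, n_tfs), rhs),
        error = function(e) lstsq(a_hat, expression)
      )
      # A-step: per support-signature exact least squares.
      for (g in groups) {
        idx <- support[[g[1L]]]
        x <- t(p_hat[idx, , drop = FALSE]) # conditions x k
        beta <- lstsq(x, t(expression[g, , drop = FALSE])) # k x |g|
        a_hat[g, ] <- 0
        a_hat[g, idx] <- t(beta)
      }
      # A-step leaves the P-penalty unchanged, so the objective after
      # the sweep is evaluated with the fresh A and the current P.
      trace <- c(trace, objective(p_hat))
      # Converged when the relative objective change falls below tol,
      # or the objective itself is negligible against the data scale
      # (exact reconstruction up to machine noise).
      if (trace[iter] < tol * e_norm) {
        converged <- TRUE
        break
      }
      if (iter >= 2L) {
        prev <- trace[iter - 1L]
        if (prev == 0 ||
            abs(prev - trace[iter]) / max(prev, .Machine$double.eps) < tol) {
          converged <- TRUE
          break
        }
      }
    }
    list(a_hat = a_hat, p_hat = p_hat, trace = trace, iterations = iter,
         converged = converged)
  }

  best <- NULL
  for (a0 in inits) {
    fit <- run_als(a0)
    if (is.null(best) ||
        tail_or(fit$trace, Inf) < tail_or(best$trace, Inf)) {
      best <- fit
    }
    if (tail_or(best$trace, Inf) < tol * e_norm) break
  }

  dimnames(best$p_hat) <- list(pattern$tf_ids, colnames(expression))
  model <- structure(
    list(
      a_hat = best$a_hat, p_hat = best$p_hat, residual_trace = best$trace,
      iterations = best$iterations, converged = best$converged,
      ridge = ridge
    ),
    class = "nca_model"
  )
  prior <- if (any(mat < 0)) mat else NULL
  normalize_model(model, prior_signs = prior)
}

#' @export
print.nca_model <- function(x, ...) {
  cat(
    "nca_model:", nrow(x$a_hat), "genes x", ncol(x$a_hat), "TFs x",
    ncol(x$p_hat), "conditions |", x$iterations, "iterations,",
    if (x$converged) "converged" else "NOT converged",
    "| final objective", signif(tail_or(x$residual_trace, NA_real_), 4),
    "| ridge", signif(x$ridge, 3), "\n"
  )
  invisible(x)
}

tail_or <- function(x, default) if (length(x)) x[length(x)] else default

#' Normalise an NCA model's scale and sign conventions
#'
#' The decomposition is invariant under `A -> A D`, `P -> D^-1 P` for
#' any diagonal `D`. This fixes the convention: each column of A is
#' scaled to unit Euclidean norm (the inverse scale absorbed into the
#' matching row of P), and each TF's sign is flipped so that the signs
#' of its control strengths agree maximally with `prior_signs` when
#' given (fallback: the first nonzero of each column is positive). The
#' reconstruction `A P` is unchanged to machine precision. All-zero A
#' columns are left as is and the matching activity rows flagged
#' indeterminate.
#'
#' @param model An `nca_model`.
#' @param prior_signs Optional genes-x-TFs signed matrix (e.g. the
#'   signed pattern) used to anchor per-TF signs.
#'
#' @return The normalised `nca_model` (with attribute
#'   `indeterminate_tfs` naming TFs whose A column is all zero, if any).
#' @export
normalize_model <- function(model, prior_signs = NULL) {
  stopifnot(inherits(model, "nca_model"))
  a <- model$a_hat
  p <- model$p_hat
  norms <- sqrt(colSums(a^2))
  indeterminate <- which(norms == 0)
  scale <- ifelse(norms == 0, 1, norms)
  a <- sweep(a, 2L, scale, "/")
  p <- sweep(p, 1L, scale, "*")
  for (j in seq_len(ncol(a))) {
    if (norms[j] == 0) next
    flip <- if (!is.null(prior_signs)) {
      agree <- sum(sign(a[, j]) * sign(prior_signs[, j]))
      agree < 0
    } else {
      first_nz <- which(a[, j] != 0)[1L]
      a[first_nz, j] < 0
    }
    if (isTRUE(flip)) {
      a[, j] <- -a[, j]
      p[j, ] <- -p[j, ]
    }
  }
  model$a_hat <- a
  model$p_hat <- p
  if (length(indeterminate)) {
    attr(model, "indeterminate_tfs") <- colnames(a)[indeterminate]
  }
  model
}

#' Compare a fitted NCA model against simulated ground truth
#'
#' Reports, per TF, the absolute Pearson correlation between the fitted
#' and true activity rows; the relative reconstruction residual
#' `||E - A P||_F / ||E||_F`; and the fraction of support entries whose
#' fitted control-strength sign matches the truth. Because the
#' decomposition has an inherent per-TF sign indeterminacy, each TF is
#' sign-aligned to the truth (the A column and the matching P row
#' flipped together when the activity correlation is negative) before
#' the sign agreement is measured.
#'
#' @param model An `nca_model`.
#' @param truth An `nca_truth` from [simulate_nca_instance()].
#'
#' @return List with `tfa_abs_cor` (named numeric per TF),
#'   `residual_ratio`, `sign_agreement` (fraction in \[0, 1\]).
#' @export
recovery_metrics <- function(model, truth) {
  stopifnot(inherits(model, "nca_model"), inherits(truth, "nca_truth"))
  if (!all(dim(model$p_hat) == dim(truth$p_true))) {
    stop("model and truth have mismatched activity dimensions")
  }
  n_tfs <- nrow(model$p_hat)
  a <- model$a_hat
  p <- model$p_hat
  raw_cor <- vapply(seq_len(n_tfs), function(j) {
    if (sd(p[j, ]) == 0 || sd(truth$p_true[j, ]) == 0) return(0)
    cor(p[j, ], truth$p_true[j, ])
  }, numeric(1L))
  for (j in which(raw_cor < 0)) {
    a[, j] <- -a[, j]
    p[j, ] <- -p[j, ]
  }
  support <- truth$a_true != 0
  agree <- sign(a[support]) == sign(truth$a_true[support])
  list(
    tfa_abs_cor = setNames(abs(raw_cor), rownames(p)),
    residual_ratio =
      fro_norm(truth$expression - model$a_hat %*% model$p_hat) /
        fro_norm(truth$expression),
    sign_agreement = mean(agree)
  )
}
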