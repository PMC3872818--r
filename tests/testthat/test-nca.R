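test_that("identity patterns pass all identifiability criteria", {
  pat <- connectivity_pattern(diag(3))
  rep_ <- check_identifiability(pat, n_conditions = 3)
  expect_true(rep_$criterion1)
  expect_true(all(rep_$criterion2))
  expect_true(rep_$criterion3)
  expect_true(rep_$identifiable)
})

test_that("duplicated support columns break the per-TF reduced-rank criterion", {
  mat <- cbind(c(1, 1, 0, 0, 1), c(1, 1, 0, 0, 1), c(0, 0, 1, 1, 0))
  pat <- connectivity_pattern(mat)
  rep_ <- check_identifiability(pat, n_conditions = 3)
  # removing either duplicate's rows empties the other's column
  expect_false(rep_$criterion2[[1]])
  expect_false(rep_$criterion2[[2]])
  expect_true(rep_$criterion2[[3]])
  expect_false(rep_$identifiable)
})

test_that("too few conditions fail criterion 3 only", {
  pat <- generate_connectivity(30, 5, 0.3, seed = 6)
  rep_ <- check_identifiability(pat, n_conditions = 4)
  expect_true(rep_$criterion1)
  expect_true(all(rep_$criterion2))
  expect_false(rep_$criterion3)
  expect_false(rep_$identifiable)
})

test_that("the rank checker agrees with the structural matching oracle on random patterns", {
  set.seed(55)
  n_agree <- 0L
  n_total <- 0L
  for (i in 1:100) {
    n_genes <- sample(4:20, 1)
    n_tfs <- sample(2:min(6, n_genes), 1)
    mat <- matrix(as.numeric(runif(n_genes * n_tfs) < runif(1, 0.15, 0.6)),
                  n_genes, n_tfs)
    # keep patterns valid enough to be interesting (no all-zero columns)
    for (j in which(colSums(mat) == 0)) mat[sample(n_genes, 1), j] <- 1
    pat <- connectivity_pattern(mat)
    rep_ <- check_identifiability(pat, n_conditions = n_tfs)
    ok1 <- rep_$criterion1 == oracle_criterion1(mat)
    ok2 <- all(unname(rep_$criterion2) == oracle_criterion2(mat))
    n_total <- n_total + 1L
    n_agree <- n_agree + as.integer(ok1 && ok2)
  }
  expect_equal(n_agree, n_total)
})

test_that("reduction leaves identifiable patterns untouched", {
  pat <- generate_connectivity(40, 5, 0.25, seed = 14)
  red <- reduce_to_identifiable(pat)
  expect_identical(red$pattern, pat)
  expect_equal(red$removed, character())
})

test_that("reduction removes a duplicate-support TF and yields an identifiable pattern", {
  mat <- cbind(
    tfa = c(1, 1, 0, 0, 1, 0),
    tfb = c(1, 1, 0, 0, 1, 0),
    tfc = c(0, 0, 1, 0, 0, 1),
    tfd = c(0, 0, 0, 1, 0, 1)
  )
  rownames(mat) <- sprintf("g%d", 1:6)
  red <- reduce_to_identifiable(connectivity_pattern(mat))
  # equal degree -> lexicographic tie-break picks tfa
  expect_equal(red$removed, "tfa")
  rep_ <- check_identifiability(red$pattern, ncol(red$pattern$mat))
  expect_true(rep_$criterion1 && all(rep_$criterion2))
})

test_that("reduction of a hopeless pattern returns an empty pattern, never raises", {
  mat <- cbind(a = c(1, 1), b = c(1, 1))
  red <- reduce_to_identifiable(connectivity_pattern(mat))
  # a 2-gene/2-TF fully tied pattern: removing either leaves one TF on
  # its own rows; final state depends on rank checks but never errors
  expect_true(is.character(red$removed))
  expect_s3_class(red$pattern, "connectivity_pattern")
})

test_that("noise-free identifiable instances are recovered exactly", {
  pat <- generate_connectivity(60, 5, 0.2, seed = 7)
  tr <- simulate_nca_instance(pat, 20, noise_sd = 0, seed = 11)
  model <- fit_nca(tr$expression, pat, seed = 3)
  expect_true(model$converged)
  met <- recovery_metrics(model, tr)
  expect_lt(met$residual_ratio, 1e-6)
  expect_true(all(met$tfa_abs_cor >= 0.999))
  expect_equal(met$sign_agreement, 1)
})

test_that("fitted control strengths never leave the allowed support", {
  pat <- generate_connectivity(30, 4, 0.3, seed = 9)
  tr <- simulate_nca_instance(pat, 15, noise_sd = 0.3, seed = 2)
  model <- fit_nca(tr$expression, pat, seed = 5)
  expect_true(all(model$a_hat[pat$mat == 0] == 0))
})

test_that("the objective trace descends monotonically", {
  pat <- generate_connectivity(50, 5, 0.25, seed = 13)
  tr <- simulate_nca_instance(pat, 12, noise_sd = 0.5, seed = 4)
  model <- fit_nca(tr$expression, pat, seed = 6)
  expect_true(all(diff(model$residual_trace) <= 1e-9))
  # ridged path descends too
  model_r <- fit_nca(tr$expression, pat, ridge = 0.5, seed = 6)
  expect_true(all(diff(model_r$residual_trace) <= 1e-9))
  expect_equal(model_r$ridge, 0.5)
})

test_that("fits are deterministic and degenerate inputs follow conventions", {
  pat <- generate_connectivity(20, 3, 0.4, seed = 8)
  tr <- simulate_nca_instance(pat, 10, noise_sd = 0.2, seed = 3)
  m1 <- fit_nca(tr$expression, pat, seed = 99)
  m2 <- fit_nca(tr$expression, pat, seed = 99)
  expect_identical(m1, m2)
  # all-zero expression: zero model, converged
  zero <- matrix(0, 20, 10)
  mz <- fit_nca(zero, pat)
  expect_true(mz$converged)
  expect_true(all(mz$a_hat == 0) && all(mz$p_hat == 0))
  # NaN input is an error
  bad <- tr$expression
  bad[1, 1] <- NaN
  expect_error(fit_nca(bad, pat), "NA/NaN")
})

test_that("under-determined instances trigger the automatic ridge with a warning", {
  pat <- generate_connectivity(40, 6, 0.3, seed = 17)
  tr <- simulate_nca_instance(pat, 4, noise_sd = 0.1, seed = 5)
  expect_warning(
    model <- fit_nca(tr$expression, pat, max_iter = 50, seed = 2),
    "criterion 3"
  )
  expect_gt(model$ridge, 0)
  expect_equal(dim(model$p_hat), c(6L, 4L))
})

test_that("normalisation fixes scale without changing the reconstruction", {
  pat <- generate_connectivity(30, 4, 0.3, seed = 10)
  tr <- simulate_nca_instance(pat, 12, noise_sd = 0, seed = 6)
  # build a deliberately mis-scaled model around the truth
  scales <- c(2, -3, 0.5, 10)
  model <- structure(
    list(
      a_hat = sweep(tr$a_true, 2, scales, "*"),
      p_hat = sweep(tr$p_true, 1, scales, "/"),
      residual_trace = numeric(), iterations = 0L, converged = TRUE,
      ridge = 0
    ),
    class = "nca_model"
  )
  before <- model$a_hat %*% model$p_hat
  norm_model <- normalize_model(model)
  after <- norm_model$a_hat %*% norm_model$p_hat
  expect_lt(max(abs(before - after)), 1e-10)
  expect_equal(unname(sqrt(colSums(norm_model$a_hat^2))), rep(1, 4))
  # sign convention: first nonzero of each column positive
  firsts <- apply(norm_model$a_hat, 2, function(col) col[col != 0][1])
  expect_true(all(firsts > 0))
  # an already-normalised model is a fixed point
  again <- normalize_model(norm_model)
  expect_equal(again$a_hat, norm_model$a_hat)
  expect_equal(again$p_hat, norm_model$p_hat)
})

test_that("recovery metrics detect perfect recovery and row misalignment", {
  pat <- generate_connectivity(40, 4, 0.3, seed = 19)
  tr <- simulate_nca_instance(pat, 15, noise_sd = 0.2, seed = 7)
  ident <- structure(
    list(
      a_hat = tr$a_true, p_hat = tr$p_true, residual_trace = numeric(),
      iterations = 0L, converged = TRUE, ridge = 0
    ),
    class = "nca_model"
  )
  met <- recovery_metrics(ident, tr)
  expect_equal(unname(met$tfa_abs_cor), rep(1, 4))
  expect_equal(met$sign_agreement, 1)
  # residual ratio equals the actual noise share of the data
  noise_share <- sqrt(sum((tr$expression - tr$a_true %*% tr$p_true)^2)) /
    sqrt(sum(tr$expression^2))
  expect_equal(met$residual_ratio, noise_share)
  # permuting activity rows destroys the correlations
  perm <- ident
  perm$p_hat <- perm$p_hat[c(2, 3, 4, 1), ]
  rownames(perm$p_hat) <- rownames(ident$p_hat)
  met_p <- recovery_metrics(perm, tr)
  expect_lt(median(met_p$tfa_abs_cor), 0.9)
  # per-TF metrics match an independent correlation loop
  model <- fit_nca(tr$expression, pat, seed = 1)
  met_f <- recovery_metrics(model, tr)
  for (j in 1:4) {
    expect_equal(
      unname(met_f$tfa_abs_cor[j]),
      abs(cor(model$p_hat[j, ], tr$p_true[j, ]))
    )
  }
})
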