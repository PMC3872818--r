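test_that("log2 fold change is the difference of arm means", {
  expr <- two_arm_expr(
    control = rbind(c(2, 2, 2), c(1, 1, 1)),
    heat = rbind(c(4, 4, 4), c(1, 1, 1))
  )
  fc <- log2_fold_change(expr, "Col-0")
  expect_equal(unname(fc), c(2, 0))
  expect_error(log2_fold_change(expr, "nope"), "unknown ecotype")
})

test_that("fold-change estimates concentrate around the planted effect", {
  # effect 1.5, replicate sd 0.3, 3v3: s.e. of the difference of means
  # is 0.3 * sqrt(2/3)
  n <- 200
  set.seed(44)
  ctrl <- matrix(rnorm(n * 3, 5, 0.3), n)
  heat <- matrix(rnorm(n * 3, 6.5, 0.3), n)
  fc <- log2_fold_change(two_arm_expr(ctrl, heat), "Col-0")
  se <- 0.3 * sqrt(2 / 3)
  expect_true(all(abs(fc - 1.5) < 4 * se))
  expect_lt(abs(mean(fc) - 1.5), 3 * se / sqrt(n))
})

test_that("Welch t-test matches the textbook formula and stats::t.test", {
  ctrl <- c(1, 2, 3)
  heat <- c(4, 5, 6)
  expr <- two_arm_expr(rbind(ctrl), rbind(heat))
  rec <- per_ecotype_t_test(expr, "Col-0")
  # Textbook Welch oracle
  se2 <- var(heat) / 3 + var(ctrl) / 3
  t_or <- (mean(heat) - mean(ctrl)) / sqrt(se2)
  df_or <- se2^2 / ((var(heat) / 3)^2 / 2 + (var(ctrl) / 3)^2 / 2)
  p_or <- 2 * pt(-abs(t_or), df_or)
  expect_equal(t_or, 3.6742346, tolerance = 1e-6)
  expect_equal(df_or, 4)
  expect_equal(p_or, 0.021312, tolerance = 1e-4)
  expect_equal(rec$t_pvalue, p_or)
  expect_equal(rec$log2fc, 3)
  expect_equal(rec$direction, "up")
  ref <- t.test(heat, ctrl)
  expect_equal(rec$t_pvalue, ref$p.value)
})

test_that("vectorised t-tests agree with per-gene stats::t.test loops", {
  set.seed(7)
  ctrl <- matrix(rnorm(30 * 4, 5, 1), 30)
  heat <- matrix(rnorm(30 * 3, 5.5, 2), 30)
  expr <- two_arm_expr(ctrl, heat)
  for (pooled in c(FALSE, TRUE)) {
    rec <- per_ecotype_t_test(expr, "Col-0", var_equal = pooled)
    ref <- vapply(seq_len(30), function(g) {
      t.test(heat[g, ], ctrl[g, ], var.equal = pooled)$p.value
    }, numeric(1))
    expect_equal(rec$t_pvalue, ref)
  }
})

test_that("degenerate constant probes follow the p = 1 convention", {
  expr <- two_arm_expr(
    control = rbind(c(3, 3, 3), c(2, 2, 2)),
    heat = rbind(c(3, 3, 3), c(5, 5, 5))
  )
  rec <- per_ecotype_t_test(expr, "Col-0")
  expect_equal(rec$t_pvalue, c(1, 0))
  expect_false(rec$significant[1])
  expect_true(rec$significant[2])
  expect_true(is.na(rec$direction[1]))
})

test_that("lowering alpha never adds significant genes", {
  sim <- simulate_ecotype_experiment(300, "A", 3, 0.2, 1.5, 0.3, seed = 12)
  sets <- lapply(c(0.1, 0.05, 0.01, 0.001), function(a) {
    rec <- per_ecotype_t_test(sim$expression, "A", alpha = a)
    rec$gene_id[rec$significant]
  })
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
  }
})

test_that("interaction ANOVA matches per-gene linear models on balanced data", {
  sim <- simulate_ecotype_experiment(40, c("A", "B", "C"), 3, 0.3, 1.5, 0.4,
                                     seed = 21)
  res <- interaction_anova(sim$expression)
  eco <- factor(sim$expression$design$ecotype)
  trt <- factor(sim$expression$design$treatment)
  ref <- apply(sim$expression$values, 1, function(y) {
    an <- anova(lm(y ~ eco * trt))
    an[["Pr(>F)"]][3]
  })
  expect_equal(res$interaction_pvalue, unname(ref))
})

test_that("a planted genotype-specific effect yields a tiny interaction p", {
  # effect +2 under heat in ecotype A only, replicate sd 0.1
  set.seed(5)
  base <- matrix(rnorm(10 * 12, 6, 0.1), 10)
  colnames(base) <- sprintf("s%02d", 1:12)
  rownames(base) <- sprintf("AT1G%05d", 1:10 * 10)
  design <- data.frame(
    sample_id = colnames(base),
    ecotype = rep(c("A", "B"), each = 6),
    treatment = rep(rep(c("control", "heat"), each = 3), 2),
    replicate = rep(1:3, 4)
  )
  base[, design$ecotype == "A" & design$treatment == "heat"] <-
    base[, design$ecotype == "A" & design$treatment == "heat"] + 2
  res <- interaction_anova(expression_matrix(base, design))
  # F ~ 300 on (1, 8) df for this effect/noise ratio
  expect_true(all(res$interaction_pvalue < 1e-4))
})

test_that("interaction ANOVA enforces its design preconditions", {
  sim <- simulate_ecotype_experiment(10, "A", 3, 0, 1, 0.3, seed = 1)
  expect_error(interaction_anova(sim$expression), "2 ecotypes")
  sim2 <- simulate_ecotype_experiment(10, c("A", "B"), 2, 0, 1, 0.3, seed = 1)
  drop_cols <- sim2$expression$design$ecotype == "B" &
    sim2$expression$design$treatment == "heat"
  vals <- sim2$expression$values[, !drop_cols]
  des <- sim2$expression$design[!drop_cols, ]
  expect_error(
    interaction_anova(expression_matrix(vals, des)),
    "empty design cell: ecotype B, treatment heat"
  )
})

test_that("union assembly implements the membership definitions", {
  records <- data.frame(
    gene_id = c("g1", "g2", "g1", "g3", "g4"),
    ecotype = c("A", "A", "B", "B", "B"),
    log2fc = c(1, -1, 2, 0.5, -2),
    direction = c("up", "down", "up", "up", "down"),
    significant = c(TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  u <- assemble_union(records)
  expect_setequal(u$unified, c("g1", "g2", "g3"))
  # g1 significant in two ecotypes: unified once, unique in neither
  expect_setequal(u$unique_genes, c("g2", "g3"))
  expect_equal(attr(u$summary, "unified_count"), 3)
  expect_equal(attr(u$summary, "unique_overall_count"), 2)
  # single ecotype: everything unique
  one <- assemble_union(records[records$ecotype == "A", ])
  expect_setequal(one$unified, one$unique_genes)
})

test_that("summary counts equal a brute-force recount on random records", {
  set.seed(88)
  genes <- sprintf("g%02d", 1:40)
  records <- do.call(rbind, lapply(c("A", "B", "C"), function(e) {
    fc <- round(rnorm(40), 2)
    fc[sample(40, 3)] <- 0
    data.frame(
      gene_id = genes, ecotype = e, log2fc = fc,
      direction = ifelse(fc > 0, "up", ifelse(fc < 0, "down", NA)),
      significant = runif(40) < 0.3
    )
  }))
  s <- summarize_counts(records)
  # brute-force loop oracle
  sig_by_eco <- lapply(c("A", "B", "C"), function(e) {
    records$gene_id[records$ecotype == e & records$significant]
  })
  names(sig_by_eco) <- c("A", "B", "C")
  n_eco_of <- function(g) sum(vapply(sig_by_eco, function(s) g %in% s, TRUE))
  for (e in c("A", "B", "C")) {
    rec <- records[records$ecotype == e & records$significant, ]
    expect_equal(s$total[s$ecotype == e], nrow(rec))
    expect_equal(
      s$total_up[s$ecotype == e],
      sum(rec$direction == "up", na.rm = TRUE)
    )
    expect_equal(
      s$total_down[s$ecotype == e],
      sum(rec$direction == "down", na.rm = TRUE)
    )
    uniq <- rec[vapply(rec$gene_id, n_eco_of, 0) == 1, ]
    expect_equal(s$unique_total[s$ecotype == e], nrow(uniq))
    expect_equal(
      s$unique_up[s$ecotype == e],
      sum(uniq$direction == "up", na.rm = TRUE)
    )
  }
  # invariants: totals split into up + down + zero-fc genes
  zero_sig <- vapply(c("A", "B", "C"), function(e) {
    sum(records$ecotype == e & records$significant & records$log2fc == 0)
  }, 0)
  expect_equal(s$total, s$total_up + s$total_down + unname(zero_sig))
  expect_true(all(s$unique_total <= s$total))
  expect_lte(attr(s, "unique_overall_count"), attr(s, "unified_count"))
})

test_that("empty significant sets tabulate to zeros", {
  records <- data.frame(
    gene_id = "g1", ecotype = "A", log2fc = 1,
    direction = "up", significant = FALSE
  )
  s <- summarize_counts(records)
  expect_equal(s$total, 0)
  expect_equal(attr(s, "unified_count"), 0)
})

test_that("annotation tagging counts per tag and reports unannotated genes", {
  annot <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    tags = c("TF", "TF;HSP", "TE", ""),
    family = c("HSF", "MYB", NA, NA)
  )
  res <- annotate_genes(c("g1", "g2", "g4", "g9", "g3"), annot)
  expect_equal(res$counts[["TF"]], 2L)
  expect_equal(res$counts[["HSP"]], 1L)
  expect_equal(res$counts[["TE"]], 1L)
  expect_setequal(res$unannotated, c("g4", "g9"))
  expect_length(annotate_genes(character(), annot)$counts, 0)

  # random annotation vs brute-force loop
  set.seed(3)
  genes <- sprintf("g%03d", 1:50)
  tags_pool <- c("TF", "TE", "HSP")
  annot2 <- data.frame(
    gene_id = genes,
    tags = vapply(seq_along(genes), function(i) {
      paste(sample(tags_pool, sample(0:3, 1)), collapse = ";")
    }, "")
  )
  query <- sample(c(genes, sprintf("x%02d", 1:5)), 30)
  res2 <- annotate_genes(query, annot2)
  for (tg in tags_pool) {
    brute <- sum(vapply(query, function(g) {
      i <- match(g, annot2$gene_id)
      !is.na(i) && tg %in% strsplit(annot2$tags[i], ";")[[1]]
    }, TRUE))
    got <- if (tg %in% names(res2$counts)) res2$counts[[tg]] else 0L
    expect_equal(got, brute)
  }
})
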