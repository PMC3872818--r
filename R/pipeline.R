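#' Pipeline configuration
#'
#' Collects the tunable parameters of the full analysis with the
#' defaults used throughout: raw p-value cut-off 0.01 for
#' differential-expression calls, absolute-correlation threshold 0.8
#' for network edges, correlation across per-ecotype log2 fold-change
#' profiles, and the decomposition's stopping/regularisation controls.
#'
#' @param alpha DE significance cut-off in (0, 1) (default 0.01).
#' @param corr_threshold Network |r| threshold in (0, 1] (default 0.8).
#' @param corr_axis Correlate `"foldchange"` profiles (one point per
#'   ecotype; default) or raw `"samples"`.
#' @param tol,max_iter,ridge [fit_nca()] controls.
#' @param threshold_z Robust z cut-off for [classify_responsive()].
#' @param n_boot Bootstrap replicates for clustering support.
#' @param seed Integer seed used by every stochastic stage.
#'
#' @return Object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(alpha = 0.01, corr_threshold = 0.8,
                            corr_axis = c("foldchange", "samples"),
                            tol = 1e-6, max_iter = 500L, ridge = 0,
                            threshold_z = 2.0, n_boot = 200L, seed = 1L) {
  corr_axis <- match.arg(corr_axis)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)")
  }
  if (!is.numeric(corr_threshold) || corr_threshold <= 0 ||
      corr_threshold > 1) {
    stop("corr_threshold must be in (0, 1]")
  }
  stopifnot(tol > 0, max_iter >= 1, ridge >= 0, threshold_z > 0, n_boot >= 1)
  structure(
    list(
      alpha = alpha, corr_threshold = corr_threshold, corr_axis = corr_axis,
      tol = tol, max_iter = max_iter, ridge = ridge,
      threshold_z = threshold_z, n_boot = n_boot, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

stage <- function(name, code) {
  tryCatch(code, error = function(e) {
    stop("[", name, "] ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Chains the stages in order: per-ecotype differential expression
#' (t-test at `alpha`, plus the genotype-by-treatment interaction ANOVA
#' and the unified-list summary), signed network construction between
#' the differentially expressed TFs and targets, identifiability
#' reduction plus the constrained decomposition, and reporting
#' (activity classification and clustering). All artifacts are written
#' to `out_dir` as tab-separated text together with a `run.log` echoing
#' every parameter and the seed; deterministic stages are bit-identical
#' under rerun with the same config.
#'
#' @param expr An [expression_matrix()].
#' @param annotation Annotation table (data frame with `gene_id`,
#'   `tags`); genes tagged `TF` form the regulator layer.
#' @param out_dir Output directory (created).
#' @param config A [pipeline_config()].
#' @param curated_tfs Optional character vector; when given, the
#'   regulator layer is restricted to DE TFs also on this curated list.
#'
#' @return Invisible list with the stage results: `de` (records,
#'   union, summary), `network`, `nca` (model, removed TFs,
#'   identifiability report), `report` (activity profile, clustering).
#' @export
run_pipeline <- function(expr, annotation, out_dir,
                         config = pipeline_config(), curated_tfs = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- c(
    "# heatnca pipeline run",
    paste0(names(unclass(config)), " = ", unlist(config))
  )

  ecotypes <- unique(expr$design$ecotype)

  de <- stage("de", {
    records <- do.call(rbind, lapply(
      ecotypes, function(e) per_ecotype_t_test(expr, e, alpha = config$alpha)
    ))
    anova_tab <- if (length(ecotypes) >= 2L) {
      interaction_anova(expr, alpha = config$alpha)
    } else {
      NULL
    }
    if (!is.null(anova_tab)) {
      records$interaction_pvalue <-
        anova_tab$interaction_pvalue[match(records$gene_id, anova_tab$gene_id)]
    }
    union <- assemble_union(records)
    write.table(
      records, file.path(out_dir, "de_table.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE
    )
    write.table(
      union$summary, file.path(out_dir, "de_summary.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE
    )
    list(records = records, union = union, anova = anova_tab)
  })

  net <- stage("network", {
    ann <- annotate_genes(de$union$unified, annotation)
    tf_tagged <- ann$records$gene_id[
      vapply(
        strsplit(ann$records$tags, ";", fixed = TRUE),
        function(t) "TF" %in% t, logical(1L)
      )
    ]
    de_tfs <- if (is.null(curated_tfs)) {
      sort(tf_tagged)
    } else {
      intersect_curated(tf_tagged, curated_tfs)
    }
    if (length(de_tfs) == 0L) stop("no differentially expressed TFs found")
    targets <- setdiff(de$union$unified, de_tfs)
    if (length(targets) == 0L) stop("no target genes left after TF removal")
    profiles <- if (config$corr_axis == "foldchange") {
      fold_change_matrix(expr, ecotypes)
    } else {
      expr$values
    }
    corr <- correlation_profiles(
      profiles[de_tfs, , drop = FALSE],
      profiles[targets, , drop = FALSE]
    )
    network <- build_signed_network(corr, threshold = config$corr_threshold)
    if (nrow(network$edges) == 0L) {
      stop("no edges at |r| >= ", config$corr_threshold)
    }
    write_edge_list(network, file.path(out_dir, "edges.tsv"))
    write_sif(network, file.path(out_dir, "network.sif"))
    write.table(
      degree_table(network), file.path(out_dir, "degree_table.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    list(network = network, de_tfs = de_tfs, profiles = profiles)
  })

  nca <- stage("nca", {
    pattern <- as_pattern(net$network)
    red <- reduce_to_identifiable(pattern)
    e_mat <- net$profiles[red$pattern$gene_ids, , drop = FALSE]
    report_ident <- check_identifiability(red$pattern, ncol(e_mat))
    model <- withCallingHandlers(
      fit_nca(
        e_mat, red$pattern, tol = config$tol, max_iter = config$max_iter,
        ridge = config$ridge, seed = config$seed
      ),
      warning = function(w) {
        log_lines <<- c(log_lines, paste0("[nca] warning: ",
                                          conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    )
    write_nca_model(model, file.path(out_dir, "nca"))
    list(model = model, removed = red$removed, identifiability = report_ident)
  })

  report <- stage("report", {
    prof <- classify_responsive(nca$model$p_hat,
                                threshold_z = config$threshold_z)
    tab3 <- data.frame(
      tf_id = prof$tf_ids,
      responsive_ecotypes = vapply(
        prof$responsive_in, paste, character(1L), collapse = ","
      ),
      category = prof$category,
      stringsAsFactors = FALSE
    )
    write.table(
      tab3, file.path(out_dir, "tf_activity_classes.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE
    )
    clust <- NULL
    if (nrow(nca$model$p_hat) >= 3L) {
      clust <- tryCatch(
        {
          cl <- hierarchical_cluster(nca$model$p_hat)
          write_newick(cl, file.path(out_dir, "tfa_clustering.nwk"))
          cl
        },
        error = function(e) NULL
      )
    }
    list(profile = prof, clustering = clust)
  })

  log_lines <- c(
    log_lines,
    paste0("de: ", attr(de$union$summary, "unified_count"), " unified genes"),
    paste0(
      "network: ", length(net$network$tfs), " TFs, ",
      nrow(net$network$edges), " edges"
    ),
    paste0(
      "nca: ", length(nca$removed), " TFs removed for identifiability; ",
      "ridge = ", fmt_num(nca$model$ridge), "; iterations = ",
      nca$model$iterations
    )
  )
  writeLines(log_lines, log_path)
  invisible(list(de = de, network = net, nca = nca, report = report,
                 out_dir = out_dir))
}
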