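#' Run the full dysregulated-pathway pipeline
#'
#' Standardize expression, restrict gene sets to measured genes, compute
#' pathway activities, build the condition-specific pathway interaction
#' network, and greedily select a connected pathway marker set. Inputs may be
#' file paths (the loaders' formats) or in-memory objects already in the
#' package's tabular forms. When `outdir` is given, all artifacts are written
#' there: activity matrix and loadings, PIN (SIF + evidence TSV), selection
#' trace and marker list, and a JSON run manifest recording the parameters
#' and stage-by-stage counts.
#'
#' @param expression Expression file path or wide tibble.
#' @param labels Labels file path or tibble.
#' @param gene_sets GMT file path or long gene-set tibble.
#' @param ppi PPI file path or pair tibble.
#' @param outdir Optional output directory.
#' @param alpha DE threshold for PIN edges (default 0.05).
#' @param rho_min Co-expression threshold for PIN edges (default 0.8).
#' @param min_genes Minimum measured genes per pathway (default 1).
#' @param probe_map Optional probe annotation path, forwarded to
#'   [read_expression()].
#' @param cfg An [eval_config()].
#' @param quiet Suppress stage progress messages.
#' @return Invisibly, a list: `expression` (standardized), `gene_sets`
#'   (restricted), `activity`, `pin`, `selection`, `counts`.
#' @export
run_pipeline <- function(expression, labels, gene_sets, ppi, outdir = NULL,
                         alpha = 0.05, rho_min = 0.8, min_genes = 1L,
                         probe_map = NULL, cfg = eval_config(),
                         quiet = FALSE) {
  say <- function(...) if (!quiet) inform(paste0("[pathmark] ", ...))

  if (is.character(expression)) {
    expression <- read_expression(expression, probe_map = probe_map)
  }
  if (is.character(labels)) labels <- read_labels(labels)
  if (is.character(gene_sets)) gene_sets <- read_gmt(gene_sets)
  if (is.character(ppi)) ppi <- read_ppi(ppi)

  expr_std <- standardize_expression(expression)
  say("standardized ", nrow(expr_std), " genes x ",
      ncol(expr_std) - 1L, " samples")

  sets <- map_genes_to_pathways(gene_sets, expr_std, min_genes = min_genes)
  say("kept ", dplyr::n_distinct(sets$pathway), "/",
      dplyr::n_distinct(gene_sets$pathway), " pathways covering ",
      length(attr(sets, "gene_universe")), " measured genes")

  activity <- compute_activity(expr_std, sets)
  say("computed ", nrow(activity$scores), " pathway activity scores")

  pin <- build_pin(sets, ppi, expr_std, labels,
                   alpha = alpha, rho_min = rho_min)
  say("PIN: ", length(pin$nodes), " pathways, ", nrow(pin$edges),
      " condition-supported edges")

  selection <- greedy_select(activity, pin, labels, cfg = cfg)
  say("selected ", length(selection$final_set), " marker pathway(s), ",
      "final CV-AUC ", sprintf("%.3f", selection$final_auc))

  counts <- list(
    n_genes = nrow(expr_std),
    n_samples = ncol(expr_std) - 1L,
    n_pathways_input = dplyr::n_distinct(gene_sets$pathway),
    n_pathways_kept = dplyr::n_distinct(sets$pathway),
    n_pathway_genes = length(attr(sets, "gene_universe")),
    n_pin_edges = nrow(pin$edges),
    n_markers = length(selection$final_set)
  )

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(activity$scores, file.path(outdir, "activity.tsv"),
                     progress = FALSE)
    readr::write_tsv(activity$loadings, file.path(outdir, "loadings.tsv"),
                     progress = FALSE)
    write_pin(pin, file.path(outdir, "pin.sif"),
              file.path(outdir, "pin_evidence.tsv"))
    write_selection(selection, file.path(outdir, "selection_trace.tsv"),
                    file.path(outdir, "markers.tsv"))
    manifest <- list(
      package = "pathmark",
      version = as.character(utils::packageVersion("pathmark")),
      r_version = R.version.string,
      parameters = list(alpha = alpha, rho_min = rho_min,
                        min_genes = min_genes,
                        cfg = unclass(cfg)),
      counts = counts,
      final_set = selection$final_set,
      final_auc = selection$final_auc
    )
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    say("artifacts written to ", outdir)
  }

  invisible(list(
    expression = expr_std, gene_sets = sets, activity = activity,
    pin = pin, selection = selection, counts = counts
  ))
}

#' Apply trained pathway markers to an independent dataset
#'
#' Hold-out evaluation: the marker pathways selected on a training dataset
#' are scored on a second dataset without re-selection. By default each
#' marker's activity is recomputed on the test data with the training run's
#' pathway membership but the test data's own first principal component
#' (loadings do not transfer across platforms); `transfer_loadings` instead
#' projects the test data onto the training loadings restricted to shared
#' genes (renormalized to unit norm).
#'
#' @param markers Character vector of marker pathway ids.
#' @param train_sets Gene-set tibble used in training (restricted form).
#' @param test_expression Hold-out expression tibble or file path (raw).
#' @param test_labels Hold-out labels tibble or file path.
#' @param cfg An [eval_config()].
#' @param transfer_loadings Use training loadings on shared genes instead of
#'   refitting PCA on the test data.
#' @param train_loadings Loadings tibble from the training
#'   `pathway_activity` (required when `transfer_loadings = TRUE`).
#' @return Tibble with `mean_auc`, `auc_sd`, `n_repeats`.
#' @export
evaluate_holdout <- function(markers, train_sets, test_expression, test_labels,
                             cfg = eval_config(), transfer_loadings = FALSE,
                             train_loadings = NULL) {
  if (is.character(test_expression)) {
    test_expression <- read_expression(test_expression)
  }
  if (is.character(test_labels)) test_labels <- read_labels(test_labels)
  expr_std <- standardize_expression(test_expression)

  sets <- train_sets |>
    dplyr::filter(.data$pathway %in% markers,
                  .data$gene %in% expr_std$gene)
  if (dplyr::n_distinct(sets$pathway) < length(markers)) {
    warn("some marker pathways have no measured genes in the hold-out data")
  }
  if (nrow(sets) == 0L) {
    abort("no marker pathway gene is measured in the hold-out data")
  }

  if (transfer_loadings) {
    if (is.null(train_loadings)) {
      abort("train_loadings is required when transfer_loadings = TRUE")
    }
    m <- as_feature_matrix(expr_std)
    scores <- purrr::map_dfr(unique(sets$pathway), function(p) {
      w <- train_loadings |>
        dplyr::filter(.data$pathway == p, .data$gene %in% rownames(m))
      if (nrow(w) == 0L) return(NULL)
      v <- w$loading / sqrt(sum(w$loading^2))
      tibble::tibble(pathway = p,
                     !!!as.list(drop(crossprod(v, m[w$gene, , drop = FALSE]))))
    })
    activity <- structure(list(scores = scores, loadings = train_loadings),
                          class = "pathway_activity")
  } else {
    activity <- compute_activity(expr_std, sets)
  }
  evaluate_feature_set(activity, test_labels,
                       intersect(markers, activity$scores$pathway), cfg)
}
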