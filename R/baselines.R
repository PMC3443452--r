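#' Rank genes by two-sample t-test
#'
#' The gene-biomarker baseline: genes ordered by ascending t-test p-value
#' (ties by descending |t|, then gene id), truncated to the top k. The
#' returned genes' standardized expression rows can be fed directly to
#' [evaluate_feature_set()] so the pathway and gene baselines differ only in
#' their features.
#'
#' @param expr Wide expression tibble.
#' @param labels Labels tibble (`sample`, `label`).
#' @param k Number of top genes to keep (defaults to all genes).
#' @param var_equal Pooled-variance t-test if `TRUE` (default).
#' @return Tibble (`gene`, `statistic`, `p_value`), best-ranked first.
#' @export
rank_genes_ttest <- function(expr, labels, k = nrow(expr), var_equal = TRUE) {
  if (k <= 0L) {
    abort("k must be a positive integer")
  }
  if (k > nrow(expr)) {
    abort("k exceeds the number of genes")
  }
  differential_genes(expr, labels, var_equal = var_equal) |>
    dplyr::select("gene", "statistic", "p_value") |>
    dplyr::arrange(.data$p_value, dplyr::desc(abs(.data$statistic)),
                   .data$gene) |>
    dplyr::slice_head(n = k)
}

#' Overlap between pathway-marker genes and top-ranked genes
#'
#' Compares the union of the selected pathways' measured genes with an
#' equally sized head of the t-test gene ranking, reporting the intersection
#' size and its percentage of the pathway gene count.
#'
#' @param selected_pathways Character vector of marker pathway ids.
#' @param sets Gene-set tibble restricted to measured genes.
#' @param ranked A [rank_genes_ttest()] result (will be truncated to the
#'   pathway gene count).
#' @return One-row tibble (`n_pathway_genes`, `n_overlap`, `percentage`).
#' @export
marker_gene_overlap <- function(selected_pathways, sets, ranked) {
  pwy_genes <- sets |>
    dplyr::filter(.data$pathway %in% selected_pathways) |>
    dplyr::pull("gene") |>
    unique()
  if (length(pwy_genes) == 0L) {
    abort("selected pathways contain no measured genes")
  }
  if (nrow(ranked) < length(pwy_genes)) {
    warn("gene ranking shorter than the pathway gene set; using all of it")
  }
  top <- head(ranked$gene, length(pwy_genes))
  n_overlap <- length(intersect(pwy_genes, top))
  tibble::tibble(
    n_pathway_genes = length(pwy_genes),
    n_overlap = n_overlap,
    percentage = 100 * n_overlap / length(pwy_genes)
  )
}
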