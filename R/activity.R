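#' Restrict gene sets to measured genes
#'
#' Intersects each pathway's membership with the genes present in the
#' expression matrix; pathways retaining fewer than `min_genes` measured genes
#' are dropped with a message. Single-gene pathways are permitted by default
#' (their activity is the gene's standardized profile).
#'
#' @param sets Long gene-set tibble (`pathway`, `description`, `gene`).
#' @param expr Standardized wide expression tibble.
#' @param min_genes Minimum measured genes a pathway must retain (default 1).
#' @return The restricted gene-set tibble; attribute `gene_universe` holds the
#'   union of retained pathway genes.
#' @export
map_genes_to_pathways <- function(sets, expr, min_genes = 1L) {
  stopifnot(min_genes >= 1L)
  measured <- expr$gene
  kept <- sets |>
    dplyr::filter(.data$gene %in% measured) |>
    dplyr::filter(dplyr::n() >= min_genes, .by = "pathway")
  n_dropped <- dplyr::n_distinct(sets$pathway) - dplyr::n_distinct(kept$pathway)
  if (n_dropped > 0L) {
    inform(paste0("dropped ", n_dropped, " pathway(s) with fewer than ",
                  min_genes, " measured gene(s)"))
  }
  if (nrow(kept) == 0L) {
    abort("no pathway retains any measured gene")
  }
  attr(kept, "gene_universe") <- sort(unique(kept$gene))
  kept
}

# Leading principal component of a member-gene submatrix (genes x samples).
# Returns unit-norm loadings with the deterministic sign convention:
# sum(loadings) > 0; an exact-zero sum is broken by requiring a positive
# loading on the lexicographically smallest gene id.
leading_component <- function(z) {
  if (nrow(z) == 1L) {
    w <- 1
  } else {
    zc <- z - rowMeans(z)
    w <- svd(zc, nu = 1L, nv = 0L)$u[, 1L]
  }
  s <- sum(w)
  if (abs(s) > 1e-12) {
    if (s < 0) w <- -w
  } else {
    first <- order(rownames(z))[1L]
    if (w[first] < 0) w <- -w
  }
  names(w) <- rownames(z)
  w
}

#' Compute pathway activity scores
#'
#' Summarizes each pathway's member genes as a per-sample meta-gene: the
#' projection of the standardized member-gene submatrix onto its first
#' principal component (the unit-norm leading eigenvector of the gene-gene
#' covariance across samples). The component sign is fixed so the loadings
#' sum positive, making recomputation deterministic.
#'
#' @param expr Standardized wide expression tibble.
#' @param sets Gene-set tibble restricted to measured genes
#'   (see [map_genes_to_pathways()]).
#' @return A `pathway_activity` object: `$scores` is a wide tibble
#'   (`pathway` plus one column per sample), `$loadings` a tibble
#'   (`pathway`, `gene`, `loading`).
#' @export
compute_activity <- function(expr, sets) {
  assert_standardized(expr)
  m <- as_feature_matrix(expr)
  missing <- setdiff(unique(sets$gene), rownames(m))
  if (length(missing) > 0L) {
    abort(paste0("gene(s) not in expression matrix: ",
                 paste(head(missing, 5L), collapse = ", "),
                 "; run map_genes_to_pathways() first"))
  }
  members <- split(sets$gene, sets$pathway)
  if (any(lengths(members) == 0L)) {
    abort("empty pathway in gene-set collection")
  }
  pathways <- names(members)

  res <- purrr::map(pathways, function(p) {
    genes <- sort(unique(members[[p]]))
    z <- m[genes, , drop = FALSE]
    w <- leading_component(z)
    list(
      score = drop(crossprod(w, z)),
      loadings = tibble::tibble(pathway = p, gene = genes,
                                loading = unname(w))
    )
  })

  scores <- do.call(rbind, purrr::map(res, "score"))
  rownames(scores) <- pathways
  structure(
    list(
      scores = matrix_to_tibble(scores, "pathway"),
      loadings = purrr::list_rbind(purrr::map(res, "loadings"))
    ),
    class = "pathway_activity"
  )
}

#' @export
print.pathway_activity <- function(x, ...) {
  cat("<pathway_activity> ", nrow(x$scores), " pathways x ",
      ncol(x$scores) - 1L, " samples\n", sep = "")
  print(x$scores, n = 5L)
  invisible(x)
}

#' Extract the activity score matrix
#'
#' @param activity A `pathway_activity` object.
#' @return Numeric matrix, pathways in rows, samples in columns.
#' @export
activity_matrix <- function(activity) {
  stopifnot(inherits(activity, "pathway_activity"))
  as_feature_matrix(activity$scores)
}

#' @describeIn compute_activity Long tibble of per-sample activity scores
#'   (`pathway`, `sample`, `activity`).
#' @param x A `pathway_activity` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.pathway_activity <- function(x, ...) {
  tidyr::pivot_longer(x$scores, -"pathway",
                      names_to = "sample", values_to = "activity")
}

#' @describeIn compute_activity One-row summary (pathway and sample counts).
#' @exportS3Method generics::glance
glance.pathway_activity <- function(x, ...) {
  tibble::tibble(
    n_pathways = nrow(x$scores),
    n_samples = ncol(x$scores) - 1L,
    n_genes = dplyr::n_distinct(x$loadings$gene)
  )
}

#' Plot pathway activity distributions by class
#'
#' Boxplots of per-sample activity scores split by disease status, one facet
#' per pathway. With many pathways, pass a subset via `pathways`.
#'
#' @param object A `pathway_activity` object.
#' @param labels Labels tibble (`sample`, `label`).
#' @param pathways Optional character vector of pathways to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pathway_activity <- function(object, labels, pathways = NULL, ...) {
  df <- tidy(object) |>
    dplyr::inner_join(labels, by = "sample")
  if (!is.null(pathways)) {
    df <- dplyr::filter(df, .data$pathway %in% pathways)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = .data$activity,
                                   fill = .data$label)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$pathway), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "pathway activity (PC1 score)") +
    ggplot2::theme_bw()
}
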