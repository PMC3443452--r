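#' Per-gene two-sample differential expression
#'
#' Student's two-sample t-test (pooled variance by default; Welch optionally)
#' of each gene's expression between disease and control samples. The
#' differentially expressed (DE) set is the genes with p < `alpha`; p-values
#' are not corrected for multiplicity by default, matching the raw threshold
#' convention, with Benjamini-Hochberg available via `adjust`.
#'
#' @param expr Wide expression tibble.
#' @param labels Labels tibble (`sample`, `label`).
#' @param alpha DE significance threshold (strict inequality; default 0.05).
#' @param var_equal Pooled-variance t-test if `TRUE` (default), Welch otherwise.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Tibble (`gene`, `statistic`, `p_value`, `de`), in input gene order.
#' @export
differential_genes <- function(expr, labels, alpha = 0.05,
                               var_equal = TRUE, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  m <- as_feature_matrix(expr)
  lab <- align_labels(labels, colnames(m))
  if (sum(lab == "disease") < 2L || sum(lab == "control") < 2L) {
    abort("each class needs at least 2 samples for a t-test")
  }
  dis <- m[, lab == "disease", drop = FALSE]
  ctl <- m[, lab == "control", drop = FALSE]
  res <- purrr::map(seq_len(nrow(m)), function(i) {
    # a gene constant in both classes carries no evidence: t = 0, p = 1
    tryCatch({
      ht <- t.test(dis[i, ], ctl[i, ], var.equal = var_equal)
      c(ht$statistic, ht$p.value)
    }, error = function(e) c(0, 1))
  })
  stat <- vapply(res, `[[`, numeric(1L), 1L)
  p <- vapply(res, `[[`, numeric(1L), 2L)
  if (adjust == "BH") {
    p <- stats::p.adjust(p, method = "BH")
  }
  tibble::tibble(
    gene = rownames(m),
    statistic = stat,
    p_value = p,
    de = p < alpha
  )
}

#' Co-expressed gene pairs
#'
#' Retains the gene pairs whose Pearson correlation across all samples
#' (both classes pooled) exceeds `rho_min` in absolute value (strictly).
#'
#' @param pairs Tibble (`gene1`, `gene2`).
#' @param expr Wide expression tibble containing every paired gene.
#' @param rho_min Absolute-correlation threshold (default 0.8).
#' @return The input pairs with a `cor` column, filtered to `|cor| > rho_min`.
#' @export
coexpressed_pairs <- function(pairs, expr, rho_min = 0.8) {
  if (nrow(pairs) == 0L) {
    return(dplyr::mutate(pairs, cor = numeric(0L)))
  }
  m <- as_feature_matrix(expr)
  missing <- setdiff(c(pairs$gene1, pairs$gene2), rownames(m))
  if (length(missing) > 0L) {
    abort(paste0("gene(s) not in expression matrix: ",
                 paste(head(missing, 5L), collapse = ", ")))
  }
  r <- vapply(seq_len(nrow(pairs)), function(i) {
    cor(m[pairs$gene1[i], ], m[pairs$gene2[i], ])
  }, numeric(1L))
  pairs |>
    dplyr::mutate(cor = r) |>
    dplyr::filter(abs(.data$cor) > rho_min)
}

#' Build the condition-specific pathway interaction network
#'
#' Candidate edges connect two pathways that share at least one gene or whose
#' genes interact in the PPI graph. A candidate edge is retained only with
#' condition-specific support: at least one shared gene differentially
#' expressed (Student's t-test, p < `alpha`) or at least one cross-pathway
#' interacting gene pair strongly co-expressed (|Pearson r| > `rho_min`).
#' A PPI pair supports the edge when its two genes are distinct and belong to
#' the respective pathways — membership, not exclusivity, is required, so
#' genes in the pathway overlap can anchor either endpoint.
#'
#' @param sets Gene-set tibble restricted to measured genes.
#' @param ppi PPI tibble (`gene1`, `gene2`).
#' @param expr Wide expression tibble.
#' @param labels Labels tibble.
#' @param alpha DE threshold for shared genes (default 0.05).
#' @param rho_min Co-expression threshold for PPI pairs (default 0.8).
#' @param var_equal Passed to [differential_genes()].
#' @return A `pathway_pin` object: `$nodes` (all pathways), `$edges` (tibble
#'   with evidence counts and list-columns of supporting genes/pairs),
#'   `$params`.
#' @export
build_pin <- function(sets, ppi, expr, labels, alpha = 0.05, rho_min = 0.8,
                      var_equal = TRUE) {
  members <- split(sets$gene, sets$pathway)
  members <- purrr::map(members, unique)
  pathways <- sort(names(members))
  m <- as_feature_matrix(expr)
  missing <- setdiff(unlist(members), rownames(m))
  if (length(missing) > 0L) {
    abort("gene sets must be restricted to measured genes (map_genes_to_pathways)")
  }

  de <- differential_genes(expr, labels, alpha = alpha, var_equal = var_equal)
  de_genes <- de$gene[de$de]

  # Candidate pairs from shared genes: any gene in >= 2 pathways.
  gene2pwy <- split(sets$pathway, sets$gene)
  shared_cand <- purrr::list_rbind(purrr::map(gene2pwy, function(ps) {
    ps <- sort(unique(ps))
    if (length(ps) < 2L) return(NULL)
    idx <- combn(ps, 2L)
    tibble::tibble(p1 = idx[1L, ], p2 = idx[2L, ])
  }))

  # Candidate pairs from PPIs crossing two pathways.
  ppi_cand <- NULL
  if (nrow(ppi) > 0L) {
    ppi_in <- ppi |>
      dplyr::filter(.data$gene1 %in% names(gene2pwy),
                    .data$gene2 %in% names(gene2pwy))
    ppi_cand <- purrr::list_rbind(purrr::map(seq_len(nrow(ppi_in)), function(i) {
      a <- ppi_in$gene1[i]
      b <- ppi_in$gene2[i]
      pa <- unique(gene2pwy[[a]])
      pb <- unique(gene2pwy[[b]])
      grid <- tidyr::expand_grid(pa = pa, pb = pb) |>
        dplyr::filter(.data$pa != .data$pb)
      if (nrow(grid) == 0L) return(NULL)
      tibble::tibble(
        p1 = pmin(grid$pa, grid$pb),
        p2 = pmax(grid$pa, grid$pb),
        gene1 = a, gene2 = b
      )
    }))
  }

  cand <- dplyr::distinct(dplyr::bind_rows(
    shared_cand,
    if (!is.null(ppi_cand) && nrow(ppi_cand) > 0L)
      dplyr::select(ppi_cand, "p1", "p2")
  ))

  edges <- purrr::list_rbind(purrr::map(seq_len(nrow(cand)), function(i) {
    p1 <- cand$p1[i]
    p2 <- cand$p2[i]
    shared <- intersect(members[[p1]], members[[p2]])
    shared_de <- intersect(shared, de_genes)
    pp <- if (!is.null(ppi_cand) && nrow(ppi_cand) > 0L) {
      dplyr::filter(ppi_cand, .data$p1 == !!p1, .data$p2 == !!p2) |>
        dplyr::distinct(.data$gene1, .data$gene2)
    } else {
      tibble::tibble(gene1 = character(), gene2 = character())
    }
    coexp <- coexpressed_pairs(pp, expr, rho_min = rho_min)
    tibble::tibble(
      pathway1 = p1, pathway2 = p2,
      n_shared = length(shared),
      n_shared_de = length(shared_de),
      n_ppi = nrow(pp),
      n_coexp_ppi = nrow(coexp),
      shared_genes = list(sort(shared)),
      shared_de_genes = list(sort(shared_de)),
      ppi_pairs = list(pp),
      coexp_ppi_pairs = list(dplyr::select(coexp, "gene1", "gene2"))
    )
  }))

  if (!is.null(edges) && nrow(edges) > 0L) {
    edges <- edges |>
      dplyr::filter(.data$n_shared_de > 0L | .data$n_coexp_ppi > 0L) |>
      dplyr::arrange(.data$pathway1, .data$pathway2)
  } else {
    edges <- empty_edge_tbl()
  }
  if (nrow(edges) == 0L) {
    warn("pathway interaction network has no edges under the given thresholds")
    edges <- empty_edge_tbl()
  }

  structure(
    list(
      nodes = pathways,
      edges = edges,
      params = list(alpha = alpha, rho_min = rho_min)
    ),
    class = "pathway_pin"
  )
}

empty_edge_tbl <- function() {
  tibble::tibble(
    pathway1 = character(), pathway2 = character(),
    n_shared = integer(), n_shared_de = integer(),
    n_ppi = integer(), n_coexp_ppi = integer(),
    shared_genes = list(), shared_de_genes = list(),
    ppi_pairs = list(), coexp_ppi_pairs = list()
  )
}

#' @export
print.pathway_pin <- function(x, ...) {
  cat("<pathway_pin> ", length(x$nodes), " pathways, ", nrow(x$edges),
      " edges (alpha = ", x$params$alpha, ", rho_min = ", x$params$rho_min,
      ")\n", sep = "")
  invisible(x)
}

# igraph view used for neighbor queries during selection.
pin_igraph <- function(pin) {
  igraph::graph_from_data_frame(
    pin$edges[, c("pathway1", "pathway2")],
    directed = FALSE,
    vertices = pin$nodes
  )
}

#' Neighbors of a set of pathways in the PIN
#'
#' @param pin A `pathway_pin` object.
#' @param pathways Character vector of pathway ids.
#' @return Character vector of adjacent pathways, excluding the input set.
#' @export
pin_neighbors <- function(pin, pathways) {
  e <- pin$edges
  nb <- c(
    e$pathway2[e$pathway1 %in% pathways],
    e$pathway1[e$pathway2 %in% pathways]
  )
  sort(setdiff(unique(nb), pathways))
}

#' @describeIn build_pin Edge table with evidence counts (one row per edge).
#' @param x A `pathway_pin` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.pathway_pin <- function(x, ...) {
  dplyr::select(x$edges, "pathway1", "pathway2", "n_shared", "n_shared_de",
                "n_ppi", "n_coexp_ppi")
}

#' @describeIn build_pin One-row network summary.
#' @exportS3Method generics::glance
glance.pathway_pin <- function(x, ...) {
  tibble::tibble(
    n_pathways = length(x$nodes),
    n_edges = nrow(x$edges),
    alpha = x$params$alpha,
    rho_min = x$params$rho_min
  )
}

#' Plot the pathway interaction network
#'
#' Draws the PIN with a force-directed layout; edge width scales with the
#' total number of supporting evidence items.
#'
#' @param object A `pathway_pin` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pathway_pin <- function(object, ...) {
  g <- pin_igraph(object)
  set.seed(42L)
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble::tibble(pathway = igraph::V(g)$name,
                          x = xy[, 1L], y = xy[, 2L])
  edges <- tidy(object) |>
    dplyr::left_join(nodes, by = c(pathway1 = "pathway")) |>
    dplyr::left_join(nodes, by = c(pathway2 = "pathway"),
                     suffix = c("", "end"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend,
                   linewidth = .data$n_shared_de + .data$n_coexp_ppi),
      colour = "grey60"
    ) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y), size = 3) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$pathway),
                       vjust = -1, size = 3) +
    ggplot2::scale_linewidth(range = c(0.3, 1.5), guide = "none") +
    ggplot2::theme_void()
}

#' Export a PIN as SIF plus an evidence table
#'
#' @param pin A `pathway_pin` object.
#' @param sif_path Output path for the SIF file (`pathway1 pp pathway2`).
#' @param evidence_path Optional output path for the evidence TSV.
#' @return The PIN, invisibly.
#' @export
write_pin <- function(pin, sif_path, evidence_path = NULL) {
  sif <- sprintf("%s\tpp\t%s", pin$edges$pathway1, pin$edges$pathway2)
  readr::write_lines(sif, sif_path)
  if (!is.null(evidence_path)) {
    readr::write_tsv(tidy(pin), evidence_path, progress = FALSE)
  }
  invisible(pin)
}
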