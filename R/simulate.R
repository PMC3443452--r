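#' Describe a synthetic case/control expression study
#'
#' Parameters of the latent-factor simulator. Each pathway carries one latent
#' factor per sample; member genes load on it with weight `sqrt(rho)` plus
#' independent noise, giving within-pathway pairwise correlation `rho` and
#' unit marginal variance. Planted pathways have their factor mean shifted by
#' `delta` (in factor standard deviations) in disease samples only.
#' Consecutive pathways share `overlap_fraction` of their genes, so planted
#' defaults (the first two pathways) are adjacent through shared genes; genes
#' in several pathways average their factors, rescaled back to unit variance.
#' A PPI graph is drawn with independent Bernoulli edges, denser within
#' pathways than between.
#'
#' @param n_genes Total genes, including background genes in no pathway.
#' @param n_per_class Samples per class (disease and control).
#' @param n_pathways Number of gene sets.
#' @param genes_per_pathway Length-2 integer range of pathway sizes.
#' @param overlap_fraction Fraction of each pathway's genes shared with the
#'   previous pathway, in \[0, 1).
#' @param rho Within-pathway gene correlation, in \[0, 1).
#' @param planted Pathway ids whose factor is shifted in disease.
#' @param delta Standardized mean shift of planted factors in disease.
#' @param ppi_within,ppi_between Bernoulli densities for PPI edges between
#'   genes sharing / not sharing a pathway.
#' @param seed Integer seed; the dataset is bit-reproducible from it.
#' @return A `sim_design` list.
#' @export
sim_design <- function(n_genes = 400L, n_per_class = 100L, n_pathways = 30L,
                       genes_per_pathway = c(8L, 15L), overlap_fraction = 0.2,
                       rho = 0.6, planted = c("PW01", "PW02"), delta = 1.5,
                       ppi_within = 0.25, ppi_between = 0.01, seed = 1L) {
  stopifnot(
    n_genes >= 1L, n_per_class >= 2L, n_pathways >= 1L,
    length(genes_per_pathway) == 2L,
    genes_per_pathway[1L] >= 1L,
    genes_per_pathway[2L] >= genes_per_pathway[1L],
    overlap_fraction >= 0, overlap_fraction < 1,
    rho >= 0, rho < 1,
    ppi_within >= 0, ppi_within <= 1,
    ppi_between >= 0, ppi_between <= 1
  )
  ids <- pathway_ids(n_pathways)
  if (!all(planted %in% ids)) {
    abort("planted pathways must be among the generated pathway ids")
  }
  structure(
    list(n_genes = as.integer(n_genes), n_per_class = as.integer(n_per_class),
         n_pathways = as.integer(n_pathways),
         genes_per_pathway = as.integer(genes_per_pathway),
         overlap_fraction = overlap_fraction, rho = rho, planted = planted,
         delta = delta, ppi_within = ppi_within, ppi_between = ppi_between,
         seed = as.integer(seed)),
    class = "sim_design"
  )
}

pathway_ids <- function(n) {
  sprintf("PW%02d", seq_len(n))
}

#' Simulate a pathway-structured case/control dataset
#'
#' Draws an expression matrix, labels, overlapping gene sets, a PPI graph and
#' the identity of the planted dysregulated pathways from a latent-factor
#' model (see [sim_design()]). Output objects are in exactly the forms the
#' loaders produce, so the full pipeline runs unchanged on simulated data.
#'
#' @param design A [sim_design()].
#' @return List with `expression` (wide tibble, raw scale), `labels`,
#'   `gene_sets`, `ppi`, `truth` (planted pathway ids), `design`.
#' @export
simulate_dataset <- function(design = sim_design()) {
  stopifnot(inherits(design, "sim_design"))
  withr::with_seed(design$seed, simulate_dataset_impl(design))
}

simulate_dataset_impl <- function(design) {
  d <- design
  gene_ids <- sprintf("g%04d", seq_len(d$n_genes))
  pwys <- pathway_ids(d$n_pathways)

  # Assign genes to pathways sequentially; each pathway reuses a fraction of
  # the previous pathway's genes so consecutive pathways overlap.
  sizes <- sample(seq(d$genes_per_pathway[1L], d$genes_per_pathway[2L]),
                  d$n_pathways, replace = TRUE)
  membership <- vector("list", d$n_pathways)
  names(membership) <- pwys
  next_free <- 1L
  for (p in seq_len(d$n_pathways)) {
    n_overlap <- if (p == 1L) 0L else {
      min(round(d$overlap_fraction * sizes[p]), length(membership[[p - 1L]]))
    }
    n_fresh <- sizes[p] - n_overlap
    if (next_free + n_fresh - 1L > d$n_genes) {
      abort("design infeasible: not enough genes for the requested pathways")
    }
    reused <- if (n_overlap > 0L) {
      sample(membership[[p - 1L]], n_overlap)
    } else {
      character(0L)
    }
    fresh <- gene_ids[next_free:(next_free + n_fresh - 1L)]
    next_free <- next_free + n_fresh
    membership[[p]] <- c(reused, fresh)
  }

  n <- 2L * d$n_per_class
  sample_ids <- sprintf("s%03d", seq_len(n))
  is_disease <- rep(c(TRUE, FALSE), each = d$n_per_class)
  labels <- tibble::tibble(
    sample = sample_ids,
    label = ifelse(is_disease, "disease", "control")
  )

  # One latent factor per pathway per sample; planted factors are mean-shifted
  # by delta in disease samples.
  shift <- outer(pwys %in% d$planted, is_disease) * d$delta
  factors <- matrix(rnorm(d$n_pathways * n), d$n_pathways, n) + shift
  rownames(factors) <- pwys

  gene2pwy <- split(
    rep(pwys, lengths(membership)),
    unlist(membership)
  )
  # Background genes are pure unit noise; pathway genes mix their factor and
  # noise so every gene has unit marginal variance.
  expr <- matrix(rnorm(d$n_genes * n), d$n_genes, n,
                 dimnames = list(gene_ids, sample_ids))
  for (g in names(gene2pwy)) {
    ps <- gene2pwy[[g]]
    f <- if (length(ps) == 1L) {
      factors[ps, ]
    } else {
      # Overlap genes average their pathways' factors, rescaled to unit
      # variance (mean of k independent factors has variance 1/k).
      colMeans(factors[ps, , drop = FALSE]) * sqrt(length(ps))
    }
    expr[g, ] <- sqrt(d$rho) * f + sqrt(1 - d$rho) * expr[g, ]
  }

  gene_sets <- tibble::tibble(
    pathway = rep(pwys, lengths(membership)),
    description = paste0("simulated pathway ", rep(pwys, lengths(membership))),
    gene = unlist(membership, use.names = FALSE)
  ) |>
    dplyr::arrange(.data$pathway, .data$gene)

  ppi <- simulate_ppi(gene_ids, gene2pwy, d$ppi_within, d$ppi_between)

  expression <- matrix_to_tibble(expr, "gene")
  attr(expression, "standardized") <- FALSE

  list(
    expression = expression,
    labels = labels,
    gene_sets = gene_sets,
    ppi = ppi,
    truth = d$planted,
    design = d
  )
}

# Bernoulli PPI edges over all gene pairs: density ppi_within where the two
# genes share a pathway, ppi_between otherwise.
simulate_ppi <- function(gene_ids, gene2pwy, ppi_within, ppi_between) {
  n <- length(gene_ids)
  if (n < 2L || (ppi_within == 0 && ppi_between == 0)) {
    return(tibble::tibble(gene1 = character(), gene2 = character()))
  }
  pwys <- unique(unlist(gene2pwy))
  inc <- matrix(FALSE, n, length(pwys), dimnames = list(gene_ids, pwys))
  for (g in names(gene2pwy)) {
    inc[g, gene2pwy[[g]]] <- TRUE
  }
  share_mat <- tcrossprod(inc * 1) > 0
  idx <- which(upper.tri(share_mat), arr.ind = TRUE)
  a <- gene_ids[idx[, 1L]]
  b <- gene_ids[idx[, 2L]]
  share <- share_mat[idx]
  p <- ifelse(share, ppi_within, ppi_between)
  keep <- runif(length(p)) < p
  canonical_pairs(a[keep], b[keep])
}

#' Write a simulated dataset to disk
#'
#' Serializes the five artifacts of [simulate_dataset()] in the formats the
#' loaders read: expression TSV, labels TSV, GMT, PPI TSV, and a truth file
#' listing the planted pathways.
#'
#' @param sim A [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return The file paths, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    expression = file.path(dir, "expression.tsv"),
    labels = file.path(dir, "labels.tsv"),
    gene_sets = file.path(dir, "gene_sets.gmt"),
    ppi = file.path(dir, "ppi.tsv"),
    truth = file.path(dir, "truth.txt")
  )
  write_expression(sim$expression, paths$expression)
  write_labels(sim$labels, paths$labels)
  write_gmt(sim$gene_sets, paths$gene_sets)
  write_ppi(sim$ppi, paths$ppi)
  readr::write_lines(sim$truth, paths$truth)
  invisible(paths)
}
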