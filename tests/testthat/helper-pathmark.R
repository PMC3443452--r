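# Shared fixtures built in code.

# Wide expression tibble from a genes x samples matrix.
expr_tbl <- function(m, standardized = FALSE) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  out <- dplyr::bind_cols(
    tibble::tibble(gene = rownames(m)),
    tibble::as_tibble(m, .name_repair = "minimal")
  )
  attr(out, "standardized") <- standardized
  out
}

random_expr <- function(n_genes, n_samples, seed = 1L, standardize = TRUE) {
  m <- withr::with_seed(seed, {
    matrix(rnorm(n_genes * n_samples), n_genes, n_samples)
  })
  x <- expr_tbl(m)
  if (standardize) suppressMessages(standardize_expression(x)) else x
}

balanced_labels <- function(sample_ids) {
  n <- length(sample_ids)
  tibble::tibble(
    sample = sample_ids,
    label = rep(c("disease", "control"), length.out = n)
  )
}

# Small, fast simulation design for search-level tests.
small_design <- function(seed, n_pathways = 10L, n_per_class = 30L,
                         n_genes = 130L, delta = 1.5) {
  sim_design(
    n_genes = n_genes, n_per_class = n_per_class, n_pathways = n_pathways,
    genes_per_pathway = c(6L, 10L), overlap_fraction = 0.2, rho = 0.6,
    planted = c("PW01", "PW02"), delta = delta,
    ppi_within = 0.25, ppi_between = 0.01, seed = seed
  )
}

# Brute-force AUC over all disease/control score pairs (ties count 1/2);
# the independent oracle for the rank-based implementation.
auc_brute <- function(scores, is_disease) {
  pos <- scores[is_disease]
  neg <- scores[!is_disease]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}
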