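# Internal helpers shared across modules.

# Coerce a wide expression/feature tibble (first column = identifier, remaining
# columns = one numeric column per sample) to a numeric matrix with rownames.
as_feature_matrix <- function(x, id_col = 1L) {
  stopifnot(is.data.frame(x), ncol(x) >= 2L)
  ids <- as.character(x[[id_col]])
  m <- as.matrix(x[, -id_col, drop = FALSE])
  if (!is.numeric(m)) {
    abort("all sample columns must be numeric")
  }
  rownames(m) <- ids
  m
}

matrix_to_tibble <- function(m, id_name) {
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble::tibble(!!id_name := rownames(m)), out)
}

sample_ids_of <- function(expr) {
  colnames(expr)[-1L]
}

is_standardized <- function(expr) {
  isTRUE(attr(expr, "standardized"))
}

# Check standardization either by flag or numerically (attributes can be lost
# through data-frame manipulation; the numeric check keeps the contract honest).
assert_standardized <- function(expr, what = "expr") {
  if (is_standardized(expr)) {
    return(invisible(TRUE))
  }
  m <- as_feature_matrix(expr)
  mu <- rowMeans(m)
  s <- apply(m, 1L, sd)
  if (all(abs(mu) < 1e-6) && all(abs(s - 1) < 1e-6)) {
    return(invisible(TRUE))
  }
  abort(paste0(
    "`", what, "` must be standardized per gene ",
    "(run standardize_expression() first)"
  ))
}

# Align a labels tibble (sample, label) to a vector of sample ids; errors on
# missing or duplicate assignments. Returns a character vector of labels.
align_labels <- function(labels, sample_ids) {
  stopifnot(is.data.frame(labels), all(c("sample", "label") %in% names(labels)))
  if (anyDuplicated(labels$sample) > 0L) {
    abort("duplicate sample ids in labels")
  }
  bad <- setdiff(labels$label, c("disease", "control"))
  if (length(bad) > 0L) {
    abort(paste0(
      "labels must be 'disease' or 'control'; found: ",
      paste(unique(bad), collapse = ", ")
    ))
  }
  idx <- match(sample_ids, labels$sample)
  if (anyNA(idx)) {
    abort(paste0(
      "no label for sample(s): ",
      paste(head(sample_ids[is.na(idx)], 5L), collapse = ", ")
    ))
  }
  lab <- labels$label[idx]
  if (length(unique(lab)) < 2L) {
    abort("both classes (disease and control) must be present")
  }
  lab
}

canonical_pairs <- function(a, b) {
  swap <- a > b
  tibble::tibble(
    gene1 = ifelse(swap, b, a),
    gene2 = ifelse(swap, a, b)
  )
}
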