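#' Read a gene or probe expression matrix
#'
#' Reads a tab-delimited expression table whose first column holds gene (or
#' probe) identifiers and whose header row names the samples. If a probe
#' annotation is supplied, probe rows are collapsed to genes: probes without a
#' gene are dropped and genes measured by several probes get the arithmetic
#' mean of the raw probe values, per sample.
#'
#' @param path Path to the tab-delimited expression file.
#' @param probe_map Optional path to a two-column tab-delimited file
#'   (probe id, gene symbol); an empty gene field marks an unmapped probe.
#' @param impute_missing If `TRUE`, missing values are imputed with the
#'   per-gene mean; the default rejects files with missing values.
#' @param uppercase_genes If `TRUE`, gene symbols are upper-cased after
#'   collapsing, for cross-source identifier matching.
#'
#' @return A wide tibble: column `gene` plus one numeric column per sample,
#'   with attribute `standardized = FALSE`.
#' @export
read_expression <- function(path, probe_map = NULL, impute_missing = FALSE,
                            uppercase_genes = FALSE) {
  raw <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                         name_repair = "minimal")
  if (ncol(raw) < 2L) {
    abort("malformed expression header: need an id column plus sample columns")
  }
  if (nrow(raw) == 0L) {
    abort("empty expression matrix")
  }
  sample_ids <- names(raw)[-1L]
  if (anyDuplicated(sample_ids) > 0L) {
    abort("duplicate sample ids in expression header")
  }
  names(raw)[1L] <- "gene"
  raw$gene <- as.character(raw$gene)
  # columns that are entirely NA are guessed as logical; they are numeric here
  raw <- dplyr::mutate(raw, dplyr::across(
    dplyr::where(is.logical), as.numeric
  ))
  if (!all(vapply(raw[-1L], is.numeric, logical(1L)))) {
    abort("non-numeric expression values; check the file format")
  }

  if (!is.null(probe_map)) {
    pm <- readr::read_tsv(
      probe_map,
      col_names = c("probe", "gene"),
      col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE
    )
    raw <- collapse_probes(raw, pm)
  } else if (anyDuplicated(raw$gene) > 0L) {
    abort("duplicate gene ids in expression matrix")
  }

  if (uppercase_genes) {
    raw$gene <- toupper(raw$gene)
    if (anyDuplicated(raw$gene) > 0L) {
      abort("upper-casing gene symbols created duplicate gene ids")
    }
  }

  m <- as_feature_matrix(raw)
  if (anyNA(m)) {
    if (!impute_missing) {
      abort(paste0(
        "expression matrix contains missing values; ",
        "set impute_missing = TRUE to impute per-gene means"
      ))
    }
    for (i in which(rowSums(is.na(m)) > 0L)) {
      m[i, is.na(m[i, ])] <- mean(m[i, ], na.rm = TRUE)
    }
    raw <- matrix_to_tibble(m, "gene")
  }
  if (nrow(raw) == 0L) {
    abort("empty expression matrix after probe collapsing")
  }
  attr(raw, "standardized") <- FALSE
  raw
}

#' Collapse probe-level rows to gene-level rows
#'
#' Probes absent from the annotation or annotated to an empty gene symbol are
#' discarded; genes with several probes take the per-sample arithmetic mean of
#' the raw probe values.
#'
#' @param expr Wide probe-level tibble (first column = probe id).
#' @param probe_map Tibble with columns `probe` and `gene`.
#' @return Wide gene-level tibble, `standardized = FALSE`.
#' @export
collapse_probes <- function(expr, probe_map) {
  stopifnot(all(c("probe", "gene") %in% names(probe_map)))
  if (anyDuplicated(probe_map$probe) > 0L) {
    abort("duplicate probe ids in probe map")
  }
  names(expr)[1L] <- "probe"
  mapped <- probe_map |>
    dplyr::filter(!is.na(.data$gene), .data$gene != "")
  out <- expr |>
    dplyr::inner_join(mapped, by = "probe") |>
    dplyr::select(-"probe") |>
    dplyr::summarise(
      dplyr::across(dplyr::everything(), mean),
      .by = "gene"
    )
  if (nrow(out) == 0L) {
    abort("no probes mapped to genes")
  }
  attr(out, "standardized") <- FALSE
  out
}

#' Standardize each gene's expression across samples
#'
#' Transforms each gene row to zero mean and unit standard deviation across
#' samples (sample standard deviation, divisor n - 1). Genes with zero
#' variance cannot be standardized and are removed with a message.
#'
#' @param expr Wide expression tibble from [read_expression()].
#' @return The standardized tibble, attribute `standardized = TRUE`.
#' @export
standardize_expression <- function(expr) {
  if (is_standardized(expr)) {
    abort("expression matrix is already standardized")
  }
  m <- as_feature_matrix(expr)
  s <- apply(m, 1L, sd)
  zero_var <- s == 0 | is.na(s)
  dropped <- rownames(m)[zero_var]
  if (any(zero_var)) {
    inform(paste0(
      "removed ", sum(zero_var), " zero-variance gene(s): ",
      paste(head(rownames(m)[zero_var], 5L), collapse = ", "),
      if (sum(zero_var) > 5L) ", ..." else ""
    ))
    m <- m[!zero_var, , drop = FALSE]
    s <- s[!zero_var]
  }
  if (nrow(m) == 0L) {
    abort("no genes left after removing zero-variance rows")
  }
  z <- (m - rowMeans(m)) / s
  out <- matrix_to_tibble(z, "gene")
  attr(out, "standardized") <- TRUE
  attr(out, "dropped_zero_variance") <- dropped
  out
}

#' Read a gene-set collection in GMT format
#'
#' One gene set per line: name, description, then member genes, tab-separated
#' (MSigDB dialect). Duplicate genes within a line are deduplicated.
#'
#' @param path Path to the GMT file.
#' @return A long tibble with columns `pathway`, `description`, `gene`.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warn("empty GMT file: returning an empty gene-set collection")
    return(tibble::tibble(pathway = character(), description = character(),
                          gene = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    abort(paste0("GMT format error: line ", which(nf < 3L)[1L],
                 " has fewer than 3 fields"))
  }
  names_ <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(names_) > 0L) {
    abort(paste0("duplicate gene-set name: ",
                 names_[duplicated(names_)][1L]))
  }
  purrr::map_dfr(fields, function(f) {
    tibble::tibble(
      pathway = f[[1L]],
      description = f[[2L]],
      gene = unique(f[-(1:2)])
    )
  })
}

#' Read a protein-protein interaction edge list
#'
#' Two tab-delimited gene-symbol columns; extra columns are ignored.
#' Self-interactions are dropped and duplicate pairs (in either order) are
#' collapsed to one canonical undirected edge.
#'
#' @param path Path to the edge-list file.
#' @return A tibble with columns `gene1`, `gene2` (`gene1 < gene2`).
#' @export
read_ppi <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble::tibble(gene1 = character(), gene2 = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    abort(paste0("PPI format error: line ", which(nf < 2L)[1L],
                 " has fewer than 2 fields"))
  }
  a <- vapply(fields, `[[`, character(1L), 1L)
  b <- vapply(fields, `[[`, character(1L), 2L)
  keep <- a != b
  canonical_pairs(a[keep], b[keep]) |> dplyr::distinct()
}

#' Read sample class labels
#'
#' Two tab-delimited columns: sample id and label, where the label is
#' `disease` or `control`. A header line is detected and skipped if its second
#' field is not a valid label.
#'
#' @param path Path to the labels file.
#' @return A tibble with columns `sample`, `label`.
#' @export
read_labels <- function(path) {
  x <- readr::read_tsv(
    path,
    col_names = c("sample", "label"),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  looks_like_header <- nrow(x) > 0L &&
    (tolower(x$sample[1L]) %in% c("sample", "sample_id", "id") ||
       tolower(x$label[1L]) %in% c("label", "class", "status", "group"))
  if (looks_like_header) {
    x <- x[-1L, , drop = FALSE]
  }
  if (nrow(x) == 0L) {
    abort("empty labels file")
  }
  bad <- setdiff(unique(x$label), c("disease", "control"))
  if (length(bad) > 0L) {
    abort(paste0("invalid label(s): ", paste(bad, collapse = ", "),
                 " (expected 'disease' or 'control')"))
  }
  if (anyDuplicated(x$sample) > 0L) {
    abort("duplicate sample ids in labels file")
  }
  x
}

#' Write the file formats the loaders read
#'
#' Serializers matching [read_expression()], [read_gmt()], [read_ppi()] and
#' [read_labels()], so simulated datasets round-trip through the same I/O
#' path as real data.
#'
#' @param expr,sets,ppi,labels Objects in the package's tabular forms.
#' @param path Output file path.
#' @return The input, invisibly.
#' @name writers
NULL

#' @rdname writers
#' @export
write_expression <- function(expr, path) {
  readr::write_tsv(expr, path, progress = FALSE)
  invisible(expr)
}

#' @rdname writers
#' @export
write_gmt <- function(sets, path) {
  lines <- sets |>
    dplyr::summarise(
      line = paste(c(.data$pathway[1L], .data$description[1L],
                     unique(.data$gene)), collapse = "\t"),
      .by = "pathway"
    )
  readr::write_lines(lines$line, path)
  invisible(sets)
}

#' @rdname writers
#' @export
write_ppi <- function(ppi, path) {
  readr::write_tsv(ppi, path, col_names = FALSE, progress = FALSE)
  invisible(ppi)
}

#' @rdname writers
#' @export
write_labels <- function(labels, path) {
  readr::write_tsv(labels, path, col_names = FALSE, progress = FALSE)
  invisible(labels)
}
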