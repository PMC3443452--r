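#' Deterministic toy dataset with a hand-enumerable pathway network
#'
#' A fixed 20-gene, 20-sample (10 disease / 10 control), 6-pathway, 12-PPI
#' instance built from closed-form expression patterns (class shifts plus
#' sinusoids — no random numbers), so every stage of the pipeline can be
#' traced by hand. Genes `g01`-`g03` carry a +3 disease shift; all other
#' genes are pure sinusoids. `g12` duplicates `g10`'s pattern (plus a tiny
#' perturbation), giving the one strongly co-expressed cross-pathway PPI
#' pair.
#'
#' Pathways: P1 = \{g01-g04\}, P2 = \{g03-g06\}, P3 = \{g06-g08\},
#' P4 = \{g09-g11\}, P5 = \{g11-g13\}, P6 = \{g14-g16\}; `g17`-`g20` belong
#' to no pathway.
#'
#' Applying the network rules at alpha = 0.05, rho_min = 0.8 yields exactly
#' two edges: P1-P2 (shared gene `g03` is differentially expressed) and
#' P4-P5 (PPI pair `g10`-`g12` has |r| > 0.99). Greedy selection picks P1
#' first (its activity separates the classes perfectly, CV-AUC 1) and stops:
#' the marker set is \{P1\}. The full construction is documented in
#' `inst/extdata/toy-fixture-README.md`.
#'
#' @return Same bundle as [simulate_dataset()]: `expression`, `labels`,
#'   `gene_sets`, `ppi`, `truth` (P1, the shifted pathway).
#' @export
make_toy_fixture <- function() {
  j <- 1:20
  cls <- rep(c(1, 0), each = 10L) # first 10 samples are disease
  sample_ids <- c(sprintf("d%02d", 1:10), sprintf("c%02d", 1:10))

  rows <- list(
    g01 = 3 * cls + 0.5 * sin(j),
    g02 = 3 * cls + 0.5 * cos(j),
    g03 = 3 * cls + 0.5 * sin(2 * j),
    g04 = 0.5 * cos(2 * j),
    g05 = 0.5 * sin(3 * j),
    g06 = 0.5 * cos(3 * j),
    g07 = 0.5 * sin(4 * j),
    g08 = 0.5 * cos(4 * j),
    g09 = 0.5 * sin(5 * j),
    g10 = 0.5 * cos(5 * j),
    g11 = 0.5 * sin(12 * j),
    g12 = 0.5 * cos(5 * j) + 0.01 * sin(7 * j),
    g13 = 0.5 * sin(8 * j),
    g14 = 0.5 * cos(8 * j),
    g15 = 0.5 * sin(9 * j),
    g16 = 0.5 * cos(9 * j),
    g17 = 0.5 * sin(10 * j),
    g18 = 0.5 * cos(10 * j),
    g19 = 0.5 * sin(11 * j),
    g20 = 0.5 * cos(11 * j)
  )
  m <- do.call(rbind, rows)
  colnames(m) <- sample_ids
  expression <- matrix_to_tibble(m, "gene")
  attr(expression, "standardized") <- FALSE

  labels <- tibble::tibble(
    sample = sample_ids,
    label = rep(c("disease", "control"), each = 10L)
  )

  members <- list(
    P1 = c("g01", "g02", "g03", "g04"),
    P2 = c("g03", "g04", "g05", "g06"),
    P3 = c("g06", "g07", "g08"),
    P4 = c("g09", "g10", "g11"),
    P5 = c("g11", "g12", "g13"),
    P6 = c("g14", "g15", "g16")
  )
  gene_sets <- tibble::tibble(
    pathway = rep(names(members), lengths(members)),
    description = paste0("toy pathway ", rep(names(members), lengths(members))),
    gene = unlist(members, use.names = FALSE)
  )

  ppi <- tibble::tribble(
    ~gene1, ~gene2,
    "g01", "g02", # within P1
    "g03", "g05", # within P2 (also crosses P1-P2 via g03's membership)
    "g07", "g08", # within P3
    "g09", "g10", # within P4
    "g12", "g13", # within P5
    "g15", "g16", # within P6
    "g02", "g07", # P1-P3 cross, weakly correlated -> filtered out
    "g10", "g12", # P4-P5 cross, |r| > 0.99 -> retained
    "g08", "g14", # P3-P6 cross, weakly correlated -> filtered out
    "g05", "g09", # P2-P4 cross, weakly correlated -> filtered out
    "g01", "g17", # pathway gene to background gene
    "g18", "g19"  # background-background
  )

  list(
    expression = expression,
    labels = labels,
    gene_sets = gene_sets,
    ppi = ppi,
    truth = "P1",
    design = NULL
  )
}
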