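test_that("t-test matches the textbook pooled-variance formula", {
  m <- rbind(
    flat = rep(1, 6),
    shifted = c(1, 1.1, 0.9, 5, 5.1, 4.9)
  )
  colnames(m) <- sprintf("s%d", 1:6)
  expr <- expr_tbl(m)
  labels <- tibble::tibble(sample = colnames(m),
                           label = rep(c("disease", "control"), each = 3))
  de <- differential_genes(expr, labels)

  # gene identical in both classes: t = 0 (or NaN), never DE
  expect_false(de$de[de$gene == "flat"])

  # pooled-variance oracle computed from first principles
  x <- c(1, 1.1, 0.9); y <- c(5, 5.1, 4.9)
  sp <- sqrt(((2 * var(x)) + (2 * var(y))) / 4)
  t_oracle <- (mean(x) - mean(y)) / (sp * sqrt(1 / 3 + 1 / 3))
  p_oracle <- 2 * pt(-abs(t_oracle), df = 4)
  row <- de[de$gene == "shifted", ]
  expect_equal(row$statistic, t_oracle, tolerance = 1e-12)
  expect_equal(row$p_value, p_oracle, tolerance = 1e-12)
  expect_lt(row$p_value, 0.001)
  expect_true(row$de)

  expect_error(
    differential_genes(expr, tibble::tibble(
      sample = colnames(m),
      label = c("disease", rep("control", 5))
    )),
    "at least 2 samples"
  )
})

test_that("null data yields a DE fraction near the nominal level", {
  expr <- random_expr(1000, 40, seed = 31L, standardize = FALSE)
  labels <- balanced_labels(names(expr)[-1])
  de <- differential_genes(expr, labels, alpha = 0.05)
  expect_lt(abs(mean(de$de) - 0.05), 0.02)
})

test_that("co-expression filter keeps |r| > rho_min pairs in either sign", {
  base <- rnorm(15)
  m <- rbind(a = base, b = base, c = -base, d = rnorm(15))
  colnames(m) <- sprintf("s%d", 1:15)
  expr <- expr_tbl(m)
  pairs <- tibble::tibble(gene1 = c("a", "a", "a"),
                          gene2 = c("b", "c", "d"))
  kept <- coexpressed_pairs(pairs, expr, rho_min = 0.8)
  expect_setequal(kept$gene2, c("b", "c")) # r = +1 and r = -1 both retained

  # random pairs match a direct Pearson recomputation
  m2 <- withr::with_seed(8L, matrix(rnorm(40 * 15), 40, 15))
  expr2 <- expr_tbl(m2)
  pairs2 <- withr::with_seed(9L, {
    tibble::tibble(gene1 = sample(expr2$gene, 20),
                   gene2 = sample(expr2$gene, 20))
  }) |> dplyr::filter(gene1 != gene2)
  kept2 <- coexpressed_pairs(pairs2, expr2, rho_min = 0.3)
  oracle <- vapply(seq_len(nrow(pairs2)), function(i) {
    abs(cor(m2[match(pairs2$gene1[i], expr2$gene), ],
            m2[match(pairs2$gene2[i], expr2$gene), ])) > 0.3
  }, logical(1))
  expect_equal(nrow(kept2), sum(oracle))
  expect_setequal(paste(kept2$gene1, kept2$gene2),
                  paste(pairs2$gene1, pairs2$gene2)[oracle])
})

test_that("minimal shared-gene and PPI edges are retained with evidence", {
  # pathways {A,B}, {B,C}: shared gene B is DE -> edge via shared_de_genes
  m <- rbind(
    A = rnorm(10),
    B = c(rnorm(5) + 4, rnorm(5)),
    C = rnorm(10)
  )
  colnames(m) <- sprintf("s%d", 1:10)
  expr <- expr_tbl(m)
  labels <- tibble::tibble(sample = colnames(m),
                           label = rep(c("disease", "control"), each = 5))
  sets <- tibble::tibble(pathway = c("P1", "P1", "P2", "P2"),
                         description = "d", gene = c("A", "B", "B", "C"))
  pin <- suppressWarnings(build_pin(sets, tibble::tibble(gene1 = character(),
                                                         gene2 = character()),
                                    expr, labels))
  expect_equal(nrow(pin$edges), 1L)
  expect_equal(pin$edges$shared_de_genes[[1]], "B")

  # disjoint pathways {A}, {C} joined by a strongly co-expressed PPI pair
  m2 <- rbind(A = m["A", ], C = m["A", ] * 0.9 + 0.01 * rnorm(10))
  expr2 <- expr_tbl(m2)
  sets2 <- tibble::tibble(pathway = c("P1", "P2"), description = "d",
                          gene = c("A", "C"))
  pin2 <- build_pin(sets2, tibble::tibble(gene1 = "A", gene2 = "C"),
                    expr2, labels)
  expect_equal(nrow(pin2$edges), 1L)
  expect_equal(pin2$edges$n_coexp_ppi, 1L)
  expect_equal(pin2$edges$n_shared, 0L)
})

test_that("the toy fixture yields exactly the hand-enumerated edge set", {
  toy <- make_toy_fixture()
  z <- suppressMessages(standardize_expression(toy$expression))
  sets <- map_genes_to_pathways(toy$gene_sets, z)
  pin <- build_pin(sets, toy$ppi, z, toy$labels)

  edges <- tidy(pin)
  expect_equal(nrow(edges), 2L)
  expect_equal(edges$pathway1, c("P1", "P4"))
  expect_equal(edges$pathway2, c("P2", "P5"))
  # P1-P2 is retained through the differentially expressed shared gene g03
  expect_equal(pin$edges$shared_de_genes[[1]], "g03")
  expect_equal(pin$edges$shared_genes[[1]], c("g03", "g04"))
  expect_equal(pin$edges$n_coexp_ppi[1], 0L)
  # P4-P5 is retained only through the co-expressed PPI pair g10-g12
  expect_equal(pin$edges$n_shared_de[2], 0L)
  expect_equal(pin$edges$shared_genes[[2]], "g11")
  expect_equal(pin$edges$coexp_ppi_pairs[[2]],
               tibble::tibble(gene1 = "g10", gene2 = "g12"))
})

test_that("edge sets are nested in alpha and rho_min", {
  for (seed in c(101L, 102L, 103L)) {
    sim <- simulate_dataset(small_design(seed))
    z <- suppressMessages(standardize_expression(sim$expression))
    sets <- map_genes_to_pathways(sim$gene_sets, z)
    key <- function(pin) paste(pin$edges$pathway1, pin$edges$pathway2)
    build <- function(alpha, rho_min) {
      suppressWarnings(build_pin(sets, sim$ppi, z, sim$labels,
                                 alpha = alpha, rho_min = rho_min))
    }
    expect_true(all(key(build(0.01, 0.8)) %in% key(build(0.05, 0.8))))
    expect_true(all(key(build(0.05, 0.9)) %in% key(build(0.05, 0.8))))
    # degenerate thresholds: nothing passes / every shared-gene edge passes
    expect_equal(nrow(build(0, 1.1)$edges), 0L)
    # alpha = 1 restores every shared-gene candidate edge
    permissive <- build(1, 0.8)
    shared_cand <- unique(unlist(lapply(
      split(sets$pathway, sets$gene),
      function(ps) {
        ps <- sort(unique(ps))
        if (length(ps) < 2L) return(NULL)
        idx <- combn(ps, 2L)
        paste(idx[1L, ], idx[2L, ])
      }
    )))
    expect_true(all(shared_cand %in% key(permissive)))
    expect_true(all(key(build(0.05, 0.8)) %in% key(permissive)))
  }
})

test_that("build_pin is invariant to pathway enumeration order", {
  sim <- simulate_dataset(small_design(7L, n_pathways = 6L, n_genes = 80L))
  z <- suppressMessages(standardize_expression(sim$expression))
  sets <- map_genes_to_pathways(sim$gene_sets, z)
  sets_rev <- sets[rev(seq_len(nrow(sets))), ]
  p1 <- suppressWarnings(build_pin(sets, sim$ppi, z, sim$labels))
  p2 <- suppressWarnings(build_pin(sets_rev, sim$ppi, z, sim$labels))
  expect_equal(tidy(p1), tidy(p2))
  expect_equal(p1$nodes, p2$nodes)
})
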