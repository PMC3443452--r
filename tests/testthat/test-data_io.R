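test_that("probe collapsing averages multi-probe genes and drops unmapped probes", {
  probes <- expr_tbl(matrix(c(1, 3, 3, 5, 9, 9), nrow = 3, byrow = TRUE,
                            dimnames = list(c("p1", "p2", "p3"), c("s1", "s2"))))
  names(probes)[1] <- "probe"
  pm <- tibble::tibble(probe = c("p1", "p2", "p3"), gene = c("gA", "gA", ""))
  out <- collapse_probes(probes, pm)
  expect_equal(out$gene, "gA")
  expect_equal(unlist(out[1, c("s1", "s2")], use.names = FALSE), c(2, 4))

  # single probe, single gene: identity
  one <- expr_tbl(matrix(7, 1, 1, dimnames = list("p1", "s1")))
  names(one)[1] <- "probe"
  out1 <- collapse_probes(one, tibble::tibble(probe = "p1", gene = "gX"))
  expect_equal(out1$s1, 7)
  expect_equal(out1$gene, "gX")
})

test_that("probe collapsing matches independent group-by means and conserves group means", {
  m <- withr::with_seed(42L, matrix(rnorm(15), 3, 5))
  rownames(m) <- c("p1", "p2", "p3")
  colnames(m) <- sprintf("s%d", 1:5)
  probes <- expr_tbl(m)
  names(probes)[1] <- "probe"
  pm <- tibble::tibble(probe = c("p1", "p2", "p3"),
                       gene = c("gA", "gA", "gB"))
  out <- collapse_probes(probes, pm)
  mat <- as.matrix(out[, -1])
  rownames(mat) <- out$gene
  # independent oracle: group-by mean per sample
  expect_equal(mat["gA", ], colMeans(m[c("p1", "p2"), ]), tolerance = 1e-12)
  expect_equal(mat["gB", ], m["p3", ], tolerance = 1e-12)
  # collapsing conserves the per-sample mean within each probe group
  expect_equal(colMeans(mat[c("gA", "gA", "gB"), ]),
               colMeans(m), tolerance = 1e-12)
})

test_that("read_expression validates format and handles missing values by policy", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(expr_tbl(matrix(1:6, 2, 3)), path)
  x <- read_expression(path)
  expect_false(attr(x, "standardized"))
  expect_equal(dim(x), c(2L, 4L))

  dup <- withr::local_tempfile(fileext = ".tsv")
  readr::write_lines(c("gene\ts1\ts2", "gA\t1\t2", "gA\t3\t4"), dup)
  expect_error(read_expression(dup), "duplicate gene")

  nas <- withr::local_tempfile(fileext = ".tsv")
  readr::write_lines(c("gene\ts1\ts2\ts3", "gA\t1\tNA\t3"), nas)
  expect_error(read_expression(nas), "missing values")
  imputed <- read_expression(nas, impute_missing = TRUE)
  expect_equal(unlist(imputed[1, -1], use.names = FALSE), c(1, 2, 3))
})

test_that("standardization centers and scales each gene with the n-1 divisor", {
  x <- expr_tbl(matrix(c(1, 2, 3), 1, 3, dimnames = list("gA", NULL)))
  z <- standardize_expression(x)
  expect_equal(unlist(z[1, -1], use.names = FALSE), c(-1, 0, 1))
  expect_true(attr(z, "standardized"))

  # zero-variance gene is removed with a message
  x2 <- expr_tbl(rbind(gA = c(1, 2, 3), gB = c(5, 5, 5)))
  expect_message(z2 <- standardize_expression(x2), "zero-variance")
  expect_equal(z2$gene, "gA")

  # random matrix: all row means ~0, row sds ~1
  z3 <- random_expr(10, 20, seed = 3L)
  m <- as.matrix(z3[, -1])
  expect_lt(max(abs(rowMeans(m))), 1e-9)
  expect_lt(max(abs(apply(m, 1, sd) - 1)), 1e-9)

  expect_error(standardize_expression(z3), "already standardized")
})

test_that("standardization is idempotent in effect", {
  z <- random_expr(8, 15, seed = 9L)
  z_again <- z
  attr(z_again, "standardized") <- FALSE # bypass the guard
  z2 <- standardize_expression(z_again)
  expect_equal(as.matrix(z2[, -1]), as.matrix(z[, -1]), tolerance = 1e-9)
})

test_that("GMT parsing dedups genes and enforces format", {
  path <- withr::local_tempfile(fileext = ".gmt")
  readr::write_lines(c(
    "PWY1\tdesc one\tA\tB\tB",
    "PWY2\tdesc two\tC\tD\tE",
    "PWY3\tdesc three\tA\tE"
  ), path)
  sets <- read_gmt(path)
  expect_equal(sets$gene[sets$pathway == "PWY1"], c("A", "B"))
  expect_equal(dplyr::n_distinct(sets$pathway), 3L)
  expect_equal(sets$gene[sets$pathway == "PWY3"], c("A", "E"))
  expect_equal(unique(sets$description[sets$pathway == "PWY2"]), "desc two")

  bad <- withr::local_tempfile(fileext = ".gmt")
  readr::write_lines("PWY1\tonly-two-fields", bad)
  expect_error(read_gmt(bad), "fewer than 3 fields")

  dup <- withr::local_tempfile(fileext = ".gmt")
  readr::write_lines(c("PWY1\td\tA", "PWY1\td\tB"), dup)
  expect_error(read_gmt(dup), "duplicate gene-set name")

  empty <- withr::local_tempfile(fileext = ".gmt")
  readr::write_lines(character(0), empty)
  expect_warning(e <- read_gmt(empty), "empty")
  expect_equal(nrow(e), 0L)
})

test_that("PPI loading canonicalizes pairs, drops self-loops, and round-trips", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_lines(c("A\tB", "B\tA", "C\tC"), path)
  ppi <- read_ppi(path)
  expect_equal(ppi, tibble::tibble(gene1 = "A", gene2 = "B"))

  # 10-line fixture with 2 duplicate pairs and 1 self-loop -> 7 edges
  lines <- c("A\tB", "C\tD", "E\tF", "G\tH", "I\tJ", "K\tL", "M\tN",
             "B\tA", "D\tC", "E\tE")
  path2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_lines(lines, path2)
  ppi2 <- read_ppi(path2)
  expect_equal(nrow(ppi2), 7L)

  # re-serialized output is a fixed point
  path3 <- withr::local_tempfile(fileext = ".tsv")
  write_ppi(ppi2, path3)
  expect_equal(read_ppi(path3), ppi2)

  bad <- withr::local_tempfile(fileext = ".tsv")
  readr::write_lines("lonely", bad)
  expect_error(read_ppi(bad), "fewer than 2 fields")
})

test_that("label reading enforces the two-class contract", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_lines(c("s1\tdisease", "s2\tcontrol"), path)
  expect_equal(read_labels(path)$label, c("disease", "control"))

  bad <- withr::local_tempfile(fileext = ".tsv")
  readr::write_lines(c("s1\tcase", "s2\tcontrol"), bad)
  expect_error(read_labels(bad), "invalid label")

  # alignment errors: missing sample and single class
  labs <- tibble::tibble(sample = c("s1", "s2"),
                         label = c("disease", "control"))
  expect_error(pathmark:::align_labels(labs, c("s1", "s3")), "no label")
  one_class <- tibble::tibble(sample = c("s1", "s2"),
                              label = c("disease", "disease"))
  expect_error(pathmark:::align_labels(one_class, c("s1", "s2")),
               "both classes")
})
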