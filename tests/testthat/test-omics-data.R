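test_that("omics matrices round-trip through TSV for every layer kind", {
  for (kind in c("expression", "mutation", "cna")) {
    m <- tiny_matrix(kind, n = 4, m = 3, seed = 2)
    path <- withr::local_tempfile(fileext = ".tsv")
    write_omics_matrix(m, path)
    m2 <- read_omics_matrix(path, kind)
    expect_identical(m2$sample_ids, m$sample_ids)
    expect_identical(m2$feature_ids, m$feature_ids)
    if (kind == "mutation") {
      expect_identical(m2$values, m$values)
    } else {
      expect_equal(m2$values, m$values, tolerance = 1e-12)
    }
  }
})

test_that("labels and ln(IC50) tables round-trip and accept label synonyms", {
  lv <- label_vector(c(1, 0, 1, 0), c("a", "b", "c", "d"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_labels(lv, path)
  expect_identical(read_labels(path)$labels, lv$labels)

  tab <- ic50_table(c("a", "b"), c(-1.25, 3.5))
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_ic50(tab, path2)
  expect_equal(read_ic50(path2)$ln_ic50, tab$ln_ic50)

  expect_identical(label_vector(c("R", "S", "r", "s"), letters[1:4])$labels,
                   c(0, 1, 0, 1))
  expect_identical(
    label_vector(c("resistant", "Sensitive"), c("a", "b"))$labels, c(0, 1))
})

test_that("malformed tables are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tg1\tg2", "s1\t1\t2", "s1\t3\t4"), path)
  expect_error(read_omics_matrix(path, "expression"), "duplicate sample")

  writeLines(c("sample_id\tg1\tg2", "s1\t1\toops", "s2\t3\t4"), path)
  expect_error(read_omics_matrix(path, "expression"), "non-numeric")

  writeLines(c("sample_id\tg1", "s1\t2", "s2\t0"), path)
  expect_error(read_omics_matrix(path, "mutation"), "\\{0, 1\\}")

  writeLines(c("sample_id\tg1", "s1\tNA", "s2\t0"), path)
  expect_error(read_omics_matrix(path, "expression"), "missing values")
  expect_identical(
    read_omics_matrix(path, "mutation", impute_zero = TRUE)$values[1, 1], 0)
})

test_that("mutation layers must be binary and invariants are enforced", {
  vals <- matrix(c(0, 1, 0.5, 1), 2, 2,
                 dimnames = list(c("a", "b"), c("g1", "g2")))
  expect_error(omics_matrix(vals, "mutation"), "\\{0, 1\\}")
  expect_error(omics_matrix(matrix(1, 2, 2,
    dimnames = list(c("a", "a"), c("g1", "g2"))), "expression"),
    "duplicate sample")
  expect_error(label_vector(c(0, 2), c("a", "b")), "binary")
})

test_that("align_samples intersects, sorts canonically and reports drops", {
  mk <- function(ids, kind) {
    omics_matrix(matrix(seq_along(ids), length(ids), 1,
                        dimnames = list(ids, "g1")),
                 kind)
  }
  expr <- mk(c("a", "b", "c"), "expression")
  mut <- omics_matrix(matrix(c(0, 1, 0), 3, 1,
    dimnames = list(c("b", "c", "d"), "g1")), "mutation")
  cna <- mk(c("c", "b"), "cna")
  labels <- label_vector(c(1, 0, 1, 0), c("a", "b", "c", "d"))
  suppressMessages(d <- align_samples(expr, mut, cna, labels))
  expect_identical(d$labels$sample_ids, c("b", "c"))
  expect_identical(attr(d, "dropped")$expression, "a")
  # row-order independence: shuffled inputs give the identical dataset
  expr2 <- tripletdr:::omics_subset(expr, c(3, 1, 2))
  suppressMessages(d2 <- align_samples(expr2, mut, cna, labels))
  expect_identical(d2$expression$values, d$expression$values)
  expect_identical(d2$labels$labels, d$labels$labels)
})

test_that("identical sample sets align without drops; disjoint sets error", {
  d <- small_sim(seed = 4)
  out <- align_samples(d$expression, d$mutation, d$cna, d$labels)
  expect_identical(out$labels$sample_ids, sort(d$labels$sample_ids,
                                               method = "radix"))
  expect_true(all(lengths(attr(out, "dropped")) == 0))

  expr <- tiny_matrix("expression")
  other <- omics_matrix(matrix(0, 2, 1,
    dimnames = list(c("x1", "x2"), "g1")), "mutation")
  cna <- tiny_matrix("cna")
  expect_error(
    align_samples(expr, other, cna,
                  label_vector(c(1, 0, 1), c("s1", "s2", "s3"))),
    "no samples shared")
})

test_that("multiomics_dataset rejects misaligned components", {
  d <- small_sim(seed = 4)
  shuffled <- tripletdr:::omics_subset(d$expression, rev(seq_len(nrow(d$expression$values))))
  expect_error(
    multiomics_dataset(shuffled, d$mutation, d$cna, d$labels),
    "identical ordered sample_id")
})
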