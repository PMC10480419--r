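test_that("expression matrices round-trip through TSV", {
  m <- expr_matrix(
    matrix(c(3, 0, 0, 3), 2, dimnames = list(c("g1", "g2"), c("s1", "s2"))),
    unit = "counts", gene_lengths = c(g1 = 1000, g2 = 1000)
  )
  expect_equal(dim(m), c(2L, 2L))
  path <- withr::local_tempfile(fileext = ".tsv")
  lpath <- withr::local_tempfile(fileext = ".tsv")
  write_expression(m, path)
  write_gene_lengths(m$gene_lengths, lpath)
  back <- read_expression(path, unit = "counts", lengths_path = lpath)
  expect_equal(back$values, m$values)
  expect_equal(back$gene_lengths, m$gene_lengths)
})

test_that("non-numeric cells are parse errors with coordinates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "g1\t1\tNA", "g2\t3\t4"), path)
  expect_error(read_expression(path, unit = "tpm"), "row 1.*g1.*column 2.*s2")
})

test_that("duplicate gene ids after version-strip are rejected", {
  v <- matrix(1, 2, 1, dimnames = list(c("ENSG1.5", "ENSG1.7"), "s1"))
  expect_error(expr_matrix(v, unit = "tpm"), "Duplicate gene ids")
})

test_that("counts_to_tpm normalises length-scaled rates to one million", {
  mk <- function(counts, lengths) {
    v <- matrix(counts, ncol = 1,
                dimnames = list(paste0("g", seq_along(counts)), "s1"))
    expr_matrix(v, unit = "counts",
                gene_lengths = setNames(lengths, rownames(v)))
  }
  expect_equal(
    counts_to_tpm(mk(c(10, 10), c(1000, 1000)))$values[, 1],
    c(g1 = 5e5, g2 = 5e5)
  )
  # doubled counts at doubled length: identical rates
  expect_equal(
    counts_to_tpm(mk(c(10, 20), c(1000, 2000)))$values[, 1],
    c(g1 = 5e5, g2 = 5e5)
  )
  # hand-computed rate normalisation
  expect_equal(
    counts_to_tpm(mk(c(1, 2, 3), c(1000, 1000, 1000)))$values[, 1],
    c(g1 = 1e6 / 6, g2 = 2e6 / 6, g3 = 3e6 / 6)
  )
  expect_error(counts_to_tpm(toy_matrix()), "expects unit 'counts'")
})

test_that("TPM columns sum to 1e6 for random counts and are library-size invariant", {
  set.seed(42)
  for (i in 1:20) {
    g <- sample(5:40, 1); s <- sample(2:6, 1)
    v <- matrix(rpois(g * s, lambda = 30), g, s,
                dimnames = list(sprintf("g%02d", 1:g), sprintf("s%d", 1:s)))
    v[1, ] <- v[1, ] + 1  # keep columns non-degenerate
    lens <- setNames(sample(200:5000, g), rownames(v))
    m <- expr_matrix(v, unit = "counts", gene_lengths = lens)
    tpm <- counts_to_tpm(m)
    expect_equal(unname(colSums(tpm$values)), rep(1e6, s), tolerance = 1e-9)
    scaled <- expr_matrix(sweep(v, 2, sample(1:5, s, TRUE), "*"),
                          unit = "counts", gene_lengths = lens)
    expect_equal(counts_to_tpm(scaled)$values, tpm$values, tolerance = 1e-12)
  }
})

test_that("an all-zero sample yields zeros plus a warning", {
  v <- matrix(c(1, 2, 0, 0), 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  m <- expr_matrix(v, unit = "counts", gene_lengths = c(g1 = 500, g2 = 500))
  expect_warning(tpm <- counts_to_tpm(m), "All-zero sample")
  expect_equal(unname(tpm$values[, "s2"]), c(0, 0))
})

test_that("log transform is log2(x + 1), zero-preserving and monotone", {
  v <- matrix(c(0, 1, 1e6 - 1, 0), 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  v[, 2] <- c(1e6, 0)
  m <- structure(list(values = v, unit = "tpm", gene_lengths = NULL),
                 class = "expr_matrix")
  lt <- log_transform(m)
  expect_equal(lt$unit, "log2tpm")
  expect_equal(lt$values["g1", "s1"], 0)
  expect_equal(lt$values["g2", "s1"], 1)
  expect_equal(lt$values["g1", "s2"], log2(1e6 + 1), tolerance = 1e-12)
  expect_error(log_transform(lt), "expects unit 'tpm'")
})

test_that("harmonize restricts to the shared gene space and is idempotent", {
  # build as counts to dodge the TPM sum invariant on tiny fixtures
  mk <- function(genes, sample = "s1") {
    v <- matrix(seq_along(genes) * 10, ncol = 1,
                dimnames = list(genes, sample))
    expr_matrix(v, unit = "counts",
                gene_lengths = setNames(rep(1000, length(genes)), genes))
  }
  a <- mk(c("a", "b", "x"))
  b <- mk(c("b", "a", "y"), "s2")
  out <- suppressMessages(harmonize(list(a, b)))
  expect_equal(gene_ids(out[[1]]), c("a", "b"))
  expect_equal(gene_ids(out[[2]]), c("a", "b"))
  expect_equal(attr(out, "dropped"), c(1L, 1L))
  twice <- suppressMessages(harmonize(out))
  expect_equal(twice[[1]]$values, out[[1]]$values)
  expect_equal(twice[[2]]$values, out[[2]]$values)
  # versioned ids match after stripping
  versioned <- suppressMessages(
    harmonize(list(mk(c("ENSG1.5", "ENSG2.1")), mk(c("ENSG1", "ENSG3"), "s2")))
  )
  expect_equal(gene_ids(versioned[[1]]), "ENSG1")
  expect_error(
    suppressMessages(harmonize(list(mk(c("a")), mk(c("z"), "s2")))),
    "No genes shared"
  )
})

test_that("GMT files round-trip and malformed lines are rejected", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\tg1\tg2", "S2\tother\tg3"), path)
  sets <- read_gmt(path)
  expect_equal(sets$set, c("S1", "S2"))
  expect_equal(sets$genes[[1]], c("g1", "g2"))
  out <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, out)
  expect_equal(read_gmt(out), sets)
  writeLines("S1\tdesc", path)
  expect_error(read_gmt(path), "line 1")
  expect_error(
    write_gmt(tibble::tibble(set = "e", description = "d",
                             genes = list(character())), out),
    "at least one member"
  )
})

test_that("metadata validation enforces the sample contract", {
  meta <- toy_meta(paste0("s", 1:4), "brain", "tumor",
                   c("cell_line", "pdx", "tissue", "tissue"))
  expect_s3_class(validate_metadata(meta), "tbl_df")
  expect_error(validate_metadata(meta[, -2]), "missing required column")
  bad <- meta; bad$disease_state <- "metastasis"
  expect_error(validate_metadata(bad), "disease_state")
  bad <- meta; bad$purity <- 1.2
  expect_error(validate_metadata(bad), "purity")
  bad <- meta; bad$disease_state <- "non_diseased"; bad$purity <- 0.5
  expect_error(validate_metadata(bad), "tumor samples")
  expect_error(align_metadata(toy_matrix(), meta[1:2, ]), "Metadata missing")
})
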