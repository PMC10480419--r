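test_that("spearman matches hand-computed examples and the error contract", {
  expect_equal(spearman(1:3, c(10, 20, 30))$rho, 1)
  expect_equal(spearman(1:3, c(3, 2, 1))$rho, -1)
  # average-rank oracle: ranks of x are (1, 2.5, 2.5, 4)
  expect_equal(spearman(c(1, 2, 2, 3), 1:4)$rho,
               oracle_spearman(c(1, 2, 2, 3), 1:4), tolerance = 1e-12)
  expect_equal(round(spearman(c(1, 2, 2, 3), 1:4)$rho, 4), 0.9487)
  expect_error(spearman(1:3, 1:4), "equal length")
  expect_error(spearman(1:2, 1:2), "at least 3")
  const <- spearman(c(5, 5, 5), 1:3)
  expect_true(const$constant)
  expect_true(is.na(const$rho))
})

test_that("spearman equals the brute-force rank oracle on random tied data", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(4:25, 1)
    x <- sample(round(rnorm(n), sample(0:1, 1)), n, replace = TRUE)
    y <- round(rnorm(n), 1)
    if (var(x) == 0 || var(y) == 0) next
    expect_equal(spearman(x, y)$rho, oracle_spearman(x, y),
                 tolerance = 1e-12)
    # agreement with the reference implementation, too
    expect_equal(spearman(x, y)$rho, cor(x, y, method = "spearman"),
                 tolerance = 1e-12)
  }
})

test_that("spearman is invariant under strictly increasing transforms", {
  set.seed(55)
  maps <- list(function(z) exp(z), function(z) z^3, function(z) log2(z + 10),
               function(z) 5 * z - 2)
  for (i in 1:40) {
    n <- sample(5:20, 1)
    x <- rnorm(n); y <- rnorm(n)
    f <- maps[[sample(length(maps), 1)]]
    expect_equal(spearman(f(x), y)$rho, spearman(x, y)$rho,
                 tolerance = 1e-12)
  }
  # in particular: correlation on TPM equals correlation on log2(TPM + 1)
  tpm <- small_cohort()$tpm
  a <- tpm$values[, 1]; b <- tpm$values[, 2]
  expect_equal(spearman(log2(a + 1), log2(b + 1))$rho, spearman(a, b)$rho,
               tolerance = 1e-12)
})

test_that("model_to_tissue aggregates pairwise correlations by the median", {
  set.seed(9)
  v <- matrix(rexp(10 * 5), 10, 5,
              dimnames = list(sprintf("g%02d", 1:10), paste0("s", 1:5)))
  v[, 5] <- v[, 1]  # model sample identical to tissue sample s1
  m <- structure(list(values = v, unit = "tpm", gene_lengths = NULL),
                 class = "expr_matrix")
  meta <- toy_meta(paste0("s", 1:5),
                   c("brain", "brain", "brain", "lung", "brain"),
                   c("tumor", "tumor", "tumor", "tumor", "tumor"),
                   c("tissue", "tissue", "tissue", "tissue", "cell_line"))
  recs <- model_to_tissue(m, meta)
  brain <- dplyr::filter(recs, tissue_group == "brain")
  # median of the three pairwise rhos, via the reference implementation
  rhos <- sort(sapply(1:3, function(i) {
    cor(v[, 5], v[, i], method = "spearman")
  }))
  expect_equal(brain$rho_median, rhos[2], tolerance = 1e-12)
  expect_equal(brain$n_tissue_samples, 3L)
  expect_equal(brain$n_genes_used, 10L)
  # a singleton group containing the model's twin gives exactly 1
  lung1 <- dplyr::filter(recs, tissue_group == "lung")
  meta2 <- meta; meta2$tissue_group[1] <- "solo"
  solo <- dplyr::filter(model_to_tissue(m, meta2), tissue_group == "solo")
  expect_equal(solo$rho_median, 1)
  expect_equal(lung1$n_tissue_samples, 1L)
})

test_that("model_to_tissue is invariant to tissue sample order", {
  co <- small_cohort()
  recs <- model_to_tissue(co$tpm, co$sim$metadata)
  perm <- sample(ncol(co$tpm$values))
  m2 <- structure(
    list(values = co$tpm$values[, perm], unit = "tpm", gene_lengths = NULL),
    class = "expr_matrix"
  )
  recs2 <- model_to_tissue(m2, co$sim$metadata)
  expect_equal(recs, recs2)
})

test_that("restricting the matrix beforehand equals passing the subset", {
  co <- small_cohort()
  genes <- sort(sample(gene_ids(co$tpm), 50))
  by_subset <- model_to_tissue(co$tpm, co$sim$metadata, genes, "sub")
  restricted <- structure(
    list(values = co$tpm$values[genes, ], unit = "tpm", gene_lengths = NULL),
    class = "expr_matrix"
  )
  by_matrix <- model_to_tissue(restricted, co$sim$metadata, NULL, "sub")
  expect_equal(by_subset, by_matrix)
})

test_that("specificity ranks matched groups with a strict tie policy", {
  base <- tibble::tibble(
    model_sample_id = "m1", model_type = "cell_line",
    model_tissue_group = "brain",
    tissue_group = c("brain", "lung", "skin"),
    disease_state = "tumor", gene_subset = "all",
    rho_median = c(0.9, 0.8, 0.7), n_tissue_samples = 3L, n_genes_used = 10L
  )
  s <- specificity(base)
  expect_equal(s$per_model$matched_rank, 1L)
  expect_equal(
    s$percent_best_match$percent_best_match[
      s$percent_best_match$model_type == "all"], 100
  )
  # tie at the top: matched group wins only by id-ascending tie-break
  tie <- base; tie$rho_median <- c(0.9, 0.9, 0.7)
  st <- specificity(tie)   # "brain|tumor" < "lung|tumor": matched still best
  expect_true(st$per_model$matched_best)
  expect_true(st$per_model$top_tie)
  tie2 <- base
  tie2$tissue_group <- c("skin", "lung", "alung")
  tie2$model_tissue_group <- "skin"
  tie2$rho_median <- c(0.9, 0.8, 0.9)
  st2 <- specificity(tie2) # tied "alung|tumor" precedes "skin|tumor"
  expect_false(st2$per_model$matched_best)
  # incomplete record grids are contract errors
  two <- dplyr::bind_rows(base, dplyr::mutate(base, model_sample_id = "m2"))
  expect_error(specificity(two[-2, ]), "incomplete|every candidate")
  miss <- base; miss$model_tissue_group <- "kidney"
  expect_error(specificity(miss), "No matched tumor group")
})

test_that("pca_qc returns ordered variance fractions with fixed signs", {
  set.seed(3)
  v <- matrix(rnorm(40), 8, 5,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:5)))
  m <- structure(list(values = v, unit = "log2tpm", gene_lengths = NULL),
                 class = "expr_matrix")
  qc <- pca_qc(m, n_components = 3)
  expect_true(all(diff(qc$variance$variance_fraction) <= 0))
  expect_lte(sum(qc$variance$variance_fraction), 1 + 1e-12)
  # one varying gene: PC1 captures everything
  v1 <- matrix(5, 4, 4, dimnames = list(paste0("g", 1:4), paste0("s", 1:4)))
  v1[2, ] <- c(1, 2, 3, 4)
  m1 <- structure(list(values = v1, unit = "log2tpm", gene_lengths = NULL),
                  class = "expr_matrix")
  qc1 <- pca_qc(m1, n_components = 1)
  expect_equal(qc1$variance$variance_fraction[1], 1)
  # degenerate and contract errors
  ident <- structure(
    list(values = matrix(1, 3, 3, dimnames = list(paste0("g", 1:3),
                                                  paste0("s", 1:3))),
         unit = "log2tpm", gene_lengths = NULL),
    class = "expr_matrix"
  )
  expect_error(pca_qc(ident), "Zero total variance")
  expect_error(pca_qc(m, n_components = 5), "n_components")
})
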