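test_that("top_variable_genes ranks by variance with deterministic ties", {
  m <- toy_matrix()
  # raw-value construction: g2 constant, g1/g3/g4 vary
  v <- rbind(A = c(0, 10, 0, 10), B = c(5, 5, 5, 5))
  colnames(v) <- paste0("s", 1:4)
  ab <- structure(list(values = v, unit = "log2tpm", gene_lengths = NULL),
                  class = "expr_matrix")
  expect_equal(as.character(top_variable_genes(ab, 1)), "A")
  expect_equal(length(top_variable_genes(ab, 2)), 2L)

  # tie broken by gene id ascending, checked against an exhaustive oracle
  v5 <- rbind(g7 = c(0, 4), g2 = c(0, sqrt(6)), g9 = c(0, sqrt(6)),
              g1 = c(0, sqrt(2)), g5 = c(3, 3))
  v5 <- cbind(v5, v5[, 1])
  colnames(v5) <- paste0("s", 1:3)
  m5 <- structure(list(values = v5, unit = "log2tpm", gene_lengths = NULL),
                  class = "expr_matrix")
  oracle <- {
    vs <- apply(v5, 1, var)
    names(sort(vs, decreasing = TRUE))  # base sort is unstable on ties
    ord <- order(-vs, names(vs))
    names(vs)[ord]
  }
  expect_equal(as.character(top_variable_genes(m5, 2)), c("g7", "g2"))
  expect_equal(as.character(top_variable_genes(m5, 5)), oracle)
  expect_error(top_variable_genes(m5, 0), "positive")
  expect_error(top_variable_genes(m5, 6), "exceeds")
  expect_error(top_variable_genes(m5, 2, samples = c("s1", "s2")),
               "at least 3 samples")
})

test_that("top-k subsets are nested in k", {
  set.seed(11)
  for (i in 1:25) {
    g <- sample(5:30, 1); s <- sample(3:8, 1)
    v <- matrix(round(rnorm(g * s), 2), g, s,
                dimnames = list(sprintf("g%02d", sample(g)), paste0("s", 1:s)))
    m <- structure(list(values = v, unit = "log2tpm", gene_lengths = NULL),
                   class = "expr_matrix")
    ks <- sort(sample(seq_len(g), min(3, g)))
    subs <- lapply(ks, function(k) top_variable_genes(m, k))
    for (j in seq_along(ks)[-1]) {
      expect_true(all(subs[[j - 1]] %in% subs[[j]]))
    }
  }
})

test_that("exclude_genes is an order-preserving set difference", {
  expect_equal(as.character(exclude_genes(c("a", "b", "c"), "b")), c("a", "c"))
  expect_equal(as.character(exclude_genes(c("a", "b"), character())),
               c("a", "b"))
  empty <- exclude_genes(c("a", "b"), c("a", "b"))
  expect_length(empty, 0)
  # downstream correlation ops must reject the empty subset
  co <- small_cohort()
  expect_error(model_to_tissue(co$tpm, co$sim$metadata, empty, "none"),
               "empty")
  # removing then re-adding restores membership
  s <- c("x", "y", "z"); excl <- c("y")
  expect_setequal(union(exclude_genes(s, excl), excl), s)
})

test_that("purity detector flags the perfect monotone gene and skips degenerate ones", {
  n <- 12
  purity <- seq(0.3, 0.96, length.out = n)
  v <- rbind(gmono = purity * 100, gconst = rep(5, n), gnoise = c(
    0.52, 0.18, 0.74, 0.41, 0.93, 0.07, 0.66, 0.29, 0.85, 0.12, 0.58, 0.37
  ) * 100)
  colnames(v) <- sprintf("t%02d", 1:n)
  m <- structure(list(values = v, unit = "tpm", gene_lengths = NULL),
                 class = "expr_matrix")
  meta <- toy_meta(colnames(v), "brain", "tumor", "tissue", purity)
  res <- purity_correlated_genes(m, meta, min_samples = 10)
  mono <- dplyr::filter(res, gene_id == "gmono")
  expect_equal(mono$rho, 1)
  expect_true(mono$flagged)
  const <- dplyr::filter(res, gene_id == "gconst")
  expect_true(is.na(const$rho))
  expect_false(const$flagged)
  expect_equal(purity_gene_union(res), "gmono", ignore_attr = TRUE)

  const_purity <- toy_meta(colnames(v), "brain", "tumor", "tissue", 0.5)
  expect_error(purity_correlated_genes(m, const_purity, min_samples = 10),
               "constant in cohort 'brain'")
  no_purity <- toy_meta(colnames(v), "brain", "tumor", "tissue")
  expect_error(purity_correlated_genes(m, no_purity), "purity estimate")
  expect_error(purity_correlated_genes(m, meta, min_samples = 20), ">= 20")
})

test_that("tissue z-scores call extreme markers and ignore flat genes", {
  tissues <- paste0("T", 1:5)
  samples <- paste0("s", 1:5)
  v <- rbind(marker = c(10, 0.01, 0.012, 0.011, 0.009),
             flat = rep(3, 5),
             low = c(0.001, 6, 6.01, 5.99, 6.02))
  colnames(v) <- samples
  m <- structure(list(values = v, unit = "log2tpm", gene_lengths = NULL),
                 class = "expr_matrix")
  meta <- toy_meta(samples, tissues, "non_diseased", "tissue")
  sets <- suppressWarnings(tissue_specific_sets(m, meta, z_threshold = 3))
  expect_true("marker" %in% sets$genes[[which(sets$set == "T1_high")]])
  expect_true("low" %in% sets$genes[[which(sets$set == "T1_low")]])
  expect_false("flat" %in% unlist(sets$genes))
  one_tissue <- toy_meta(samples, "T1", "non_diseased", "tissue")
  expect_error(tissue_specific_sets(m, one_tissue), "two tissue groups")
})

test_that("tissue-specific sets recover ground-truth markers on a multi-tissue cohort", {
  # six tissues: the reference s.d. in the z-score is over five values, where
  # the 3-sigma marker construction separates cleanly at a moderate threshold
  cfg <- sim_config(
    n_tissues = 6, n_genes = 900, n_tissue_specific = 30,
    n_purity_responsive = 60, n_tumor = 10, n_non_diseased = 8,
    n_cell_line = 3, n_pdx = 3, seed = 21
  )
  s <- simulate_cohort(cfg)
  ltpm <- log_transform(counts_to_tpm(s$counts))
  sets <- tissue_specific_sets(ltpm, s$metadata, z_threshold = 1.5)
  truth <- s$truth$genes
  base_rate <- (cfg$n_tissue_specific / 2) / cfg$n_genes
  for (t in paste0("tissue", LETTERS[1:6])) {
    found <- sets$genes[[which(sets$set == paste0(t, "_high"))]]
    want <- truth$gene_id[truth$role == "tissue_high" & truth$tissue == t]
    recall <- length(intersect(found, want)) / length(want)
    precision <- length(intersect(found, want)) / length(found)
    expect_gte(recall, 0.8)
    # the z-score reference s.d. is estimated from T - 1 tissue means, so the
    # null is t-like and heavy-tailed: precision is bounded well below 1 at
    # desk scale, but called sets must still be strongly enriched in truth
    expect_gte(precision / base_rate, 5)
  }
})
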