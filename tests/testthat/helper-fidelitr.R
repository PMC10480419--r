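# shared fixtures and independent oracles ------------------------------

# deterministic toy matrix: 4 genes x 4 samples with distinct variances
toy_matrix <- function(unit = "tpm") {
  v <- rbind(
    g1 = c(1, 2, 3, 4),
    g2 = c(10, 10, 10, 10),
    g3 = c(5, 1, 9, 5),
    g4 = c(0, 0, 1, 0)
  )
  v <- sweep(v, 2, colSums(v), "/") * 1e6
  colnames(v) <- paste0("s", 1:4)
  expr_matrix(v, unit = unit)
}

# small metadata frame matching hand-built matrices
toy_meta <- function(sample_id, tissue_group, disease_state, model_type,
                     purity = NA_real_) {
  tibble::tibble(
    sample_id = sample_id, source = "test", tissue_group = tissue_group,
    disease_state = disease_state, model_type = model_type, purity = purity
  )
}

# one small simulated cohort reused across test files
small_sim_config <- function(seed = 7, ...) {
  sim_config(
    n_tissues = 3, n_genes = 600, n_tissue_specific = 40,
    n_purity_responsive = 80, n_tumor = 15, n_non_diseased = 8,
    n_cell_line = 8, n_pdx = 8, seed = seed, ...
  )
}

.cohort_cache <- new.env(parent = emptyenv())

# the full default study cohort (shared by the end-to-end checks)
default_cohort <- function() {
  if (is.null(.cohort_cache$def_sim)) {
    .cohort_cache$def_sim <- simulate_cohort(sim_config())
    .cohort_cache$def_tpm <- counts_to_tpm(.cohort_cache$def_sim$counts)
    .cohort_cache$def_records <- model_to_tissue(
      .cohort_cache$def_tpm, .cohort_cache$def_sim$metadata
    )
  }
  list(sim = .cohort_cache$def_sim, tpm = .cohort_cache$def_tpm,
       records = .cohort_cache$def_records)
}

small_cohort <- function() {
  if (is.null(.cohort_cache$sim)) {
    .cohort_cache$sim <- simulate_cohort(small_sim_config())
    .cohort_cache$tpm <- counts_to_tpm(.cohort_cache$sim$counts)
  }
  list(sim = .cohort_cache$sim, tpm = .cohort_cache$tpm)
}

# --- independent oracles ----------------------------------------------

# average ranks built from first principles (counts of smaller + tie share)
oracle_ranks <- function(x) {
  vapply(seq_along(x), function(i) {
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }, 0)
}

# Spearman rho via the explicit covariance formula on oracle ranks
oracle_spearman <- function(x, y) {
  rx <- oracle_ranks(x); ry <- oracle_ranks(y)
  n <- length(x)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# exact Mann-Whitney p by exhaustive enumeration of rank assignments
oracle_wilcox_exact <- function(a, b) {
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  all_u <- apply(utils::combn(N, n1), 2, function(ix) {
    sum(ix) - n1 * (n1 + 1) / 2
  })
  min(1, 2 * min(mean(all_u <= u_obs), mean(all_u >= u_obs)))
}

# hypergeometric upper tail by exhaustive enumeration of query draws
oracle_hypergeom <- function(N, s, q, k) {
  universe <- seq_len(N)
  in_set <- universe <= s
  draws <- utils::combn(N, q)
  mean(apply(draws, 2, function(ix) sum(in_set[ix])) >= k)
}

# quantile pairing built by hand for the per-gene correlation oracle
oracle_quantile_pairs <- function(a, b) {
  n <- min(length(a), length(b))
  probs <- seq(0, 1, length.out = n)
  list(a = quantile(a, probs, type = 7, names = FALSE),
       b = quantile(b, probs, type = 7, names = FALSE))
}
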