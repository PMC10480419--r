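#' Per-gene correlation between a model group and a tissue group
#'
#' For each gene, the expression values of the two (unpaired) sample
#' groups are sorted and mapped to `n = min(n_model, n_tissue)` matched
#' quantile points (type-7 interpolation), and the quantile-paired vectors
#' are Spearman-correlated. This pairing is deterministic, invariant to
#' sample order within either group, and reduces to rho = 1 when the two
#' distributions coincide. Because both paired vectors are non-decreasing
#' by construction, the pairing itself cannot produce negative rho — the
#' sign of a per-gene association between unpaired groups is not
#' identifiable from the two marginal distributions. The anticorrelated
#' classes are retained in the classification rule for paired designs and
#' future pairing strategies.
#'
#' Classification (unadjusted p, threshold `alpha`): `correlated_sig`
#' (rho > 0, p < alpha), `correlated_ns`, `anticorrelated_sig` (rho < 0,
#' p < alpha), `anticorrelated_ns`, `undefined` (rho undefined because a
#' group is constant).
#'
#' @param m An `expr_matrix` (`tpm` or `log2tpm`).
#' @param model_samples,tissue_samples Disjoint character vectors of sample
#'   ids, each of length >= 3 (build them with [pick_samples()]).
#' @param alpha Significance threshold for the class labels. Default 0.05.
#' @param pairing Pairing strategy; only `"quantile"` is implemented.
#' @param model_group,tissue_group Labels recorded in the output.
#' @return A tibble, one row per gene: `gene_id`, `rho`, `p`, `class`,
#'   `n_pairs`, `model_group`, `tissue_group`.
#' @export
per_gene_correlation <- function(m, model_samples, tissue_samples,
                                 alpha = 0.05, pairing = "quantile",
                                 model_group = "model",
                                 tissue_group = "tissue") {
  stopifnot(inherits(m, "expr_matrix"))
  pairing <- match.arg(pairing, "quantile")
  overlap <- intersect(model_samples, tissue_samples)
  if (length(overlap)) {
    abort(paste0("Sample(s) present in both groups: ",
                 paste(head(overlap, 5), collapse = ", ")))
  }
  for (s in list(model_samples, tissue_samples)) {
    missing <- setdiff(s, colnames(m$values))
    if (length(missing)) {
      abort(paste0("Unknown sample id(s): ",
                   paste(head(missing, 5), collapse = ", ")))
    }
    if (length(s) < 3) abort("Each group needs at least 3 samples.")
  }
  n <- min(length(model_samples), length(tissue_samples))
  probs <- seq(0, 1, length.out = n)
  A <- m$values[, model_samples, drop = FALSE]
  B <- m$values[, tissue_samples, drop = FALSE]
  qa <- t(apply(A, 1, quantile, probs = probs, type = 7, names = FALSE))
  qb <- t(apply(B, 1, quantile, probs = probs, type = 7, names = FALSE))
  const <- apply(qa, 1, var) == 0 | apply(qb, 1, var) == 0
  rho <- rep(NA_real_, nrow(qa))
  if (any(!const)) {
    ra <- rank_columns(t(qa[!const, , drop = FALSE]))
    rb <- rank_columns(t(qb[!const, , drop = FALSE]))
    rho[!const] <- colSums(scale(ra) * scale(rb)) / (n - 1)
  }
  p <- spearman_pvalue(rho, n)
  cls <- dplyr::case_when(
    is.na(rho) ~ "undefined",
    rho > 0 & p < alpha ~ "correlated_sig",
    rho < 0 & p < alpha ~ "anticorrelated_sig",
    rho >= 0 ~ "correlated_ns",
    TRUE ~ "anticorrelated_ns"
  )
  tibble::tibble(
    gene_id = rownames(m$values), rho = rho, p = p, class = cls,
    n_pairs = n, model_group = model_group, tissue_group = tissue_group
  )
}

#' Overlap of gene classes between two comparisons
#'
#' Partitions the genes carrying a given class label in two per-gene
#' correlation tables (e.g. cell-line-vs-tumor and PDX-vs-tumor) into
#' exclusive and shared sets — the Venn-diagram decomposition.
#'
#' @param records_a,records_b Tibbles from [per_gene_correlation()] over
#'   the same gene universe.
#' @param class Class label to partition, e.g. `"correlated_sig"`.
#' @return List with character vectors `only_a`, `only_b`, `both`.
#' @export
class_overlap <- function(records_a, records_b, class) {
  if (!setequal(records_a$gene_id, records_b$gene_id)) {
    abort("The two record sets cover different gene universes.")
  }
  a <- records_a$gene_id[records_a$class == class]
  b <- records_b$gene_id[records_b$class == class]
  list(only_a = setdiff(a, b), only_b = setdiff(b, a),
       both = intersect(a, b))
}

#' Hypergeometric over-representation of gene sets
#'
#' One-sided upper-tail hypergeometric test of the overlap between a query
#' gene list (e.g. the significantly correlated genes of a comparison) and
#' each set of a GMT collection, within a stated universe. Each set is
#' intersected with the universe before testing; the query must be a
#' subset of the universe. Reported `recall` is overlap divided by the
#' (universe-restricted) set size.
#'
#' @param query Character vector of genes (subset of `universe`).
#' @param sets Gene-set tibble (`set`, `description`, `genes`), e.g. from
#'   [read_gmt()] or [tissue_specific_sets()].
#' @param universe Character vector: the testable gene universe (standard
#'   ORA practice: all genes with a defined statistic in the comparison).
#' @param adjust `"bh"` (default) or `"bonferroni"`, applied across all
#'   tested sets.
#' @return A tibble sorted by `p_adj` then set name: `set`, `overlap`,
#'   `query_size`, `set_size`, `universe_size`, `recall`, `p`, `p_adj`.
#' @export
overrepresentation <- function(query, sets, universe,
                               adjust = c("bh", "bonferroni")) {
  adjust <- match.arg(adjust)
  if (length(query) == 0) abort("Empty query gene list.")
  if (length(universe) == 0) abort("Empty universe.")
  query <- unique(strip_gene_version(query))
  universe <- unique(strip_gene_version(universe))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    abort(paste0("Query gene(s) outside the universe: ",
                 paste(head(outside, 5), collapse = ", ")))
  }
  N <- length(universe); q <- length(query)
  out <- purrr::pmap_dfr(sets[c("set", "genes")], function(set, genes) {
    s_genes <- intersect(unique(strip_gene_version(genes)), universe)
    s <- length(s_genes)
    k <- length(intersect(query, s_genes))
    p <- if (s == 0) 1 else phyper(k - 1, s, N - s, q, lower.tail = FALSE)
    tibble::tibble(
      set = set, overlap = k, query_size = q, set_size = s,
      universe_size = N, recall = if (s == 0) NA_real_ else k / s, p = p
    )
  })
  method <- c(bh = "BH", bonferroni = "bonferroni")[[adjust]]
  out %>%
    dplyr::mutate(p_adj = p.adjust(.data$p, method)) %>%
    dplyr::arrange(.data$p_adj, .data$set)
}
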