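#' Top-k most-variable genes of a reference cohort
#'
#' Per-gene sample variance is computed across the selected reference
#' samples only, on the matrix as given (conventionally log2 TPM — raw-TPM
#' variance is dominated by a handful of extreme genes). Genes are sorted
#' by variance descending with ties broken by gene id ascending, so
#' subsets are reproducible across platforms and nested in k.
#'
#' @param m An `expr_matrix` (conventionally `log2tpm`).
#' @param k Number of genes to return (`1 <= k <= n_genes`).
#' @param samples Optional character vector of reference sample ids (e.g.
#'   from [pick_samples()]); `NULL` uses every column. At least 3 samples.
#' @return Character vector of k gene ids, in variance order, with
#'   attributes `provenance = "variance_topk"`, `k` and `variances`.
#' @export
top_variable_genes <- function(m, k, samples = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  if (k <= 0) abort("`k` must be positive.")
  if (k > nrow(m$values)) abort("`k` exceeds the number of genes.")
  vals <- m$values
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(vals))
    if (length(missing)) {
      abort(paste0("Unknown sample id(s): ",
                   paste(head(missing, 5), collapse = ", ")))
    }
    vals <- vals[, samples, drop = FALSE]
  }
  if (ncol(vals) < 3) abort("Variance ranking needs at least 3 samples.")
  v <- apply(vals, 1, var)
  ord <- order(-v, names(v))
  out <- names(v)[ord][seq_len(k)]
  structure(out, provenance = "variance_topk", k = as.integer(k),
            variances = unname(v[ord][seq_len(k)]))
}

#' Remove genes from a subset
#'
#' Set difference preserving the order of `genes`; used e.g. to drop
#' purity-correlated genes from a variance subset. The result keeps both
#' parents in its `provenance` attribute. An empty result is returned as
#' an empty vector — downstream correlation functions reject it.
#'
#' @param genes Character vector (the subset to filter).
#' @param exclude Character vector of genes to drop.
#' @return Character vector.
#' @export
exclude_genes <- function(genes, exclude) {
  out <- setdiff(genes, exclude)
  structure(out, provenance = c(attr(genes, "provenance") %||% "custom",
                                "minus", attr(exclude, "provenance") %||%
                                  "custom"))
}

#' Detect tumor-purity-correlated genes
#'
#' Within each cohort (by default each `tissue_group` of the tumor tissue
#' samples), every gene's expression is Spearman-correlated with the
#' per-sample purity estimate; p-values come from the t-approximation and
#' are adjusted within the cohort. A gene is flagged when its adjusted p
#' falls below `alpha` *and* |rho| reaches `min_abs_rho`. Genes constant
#' within a cohort get `rho = NA` and are never flagged.
#'
#' @param m An `expr_matrix` with `unit = "tpm"` (or `log2tpm`; Spearman is
#'   rank-based).
#' @param meta Metadata with `purity` for tumor tissue samples.
#' @param alpha Significance level on the adjusted p. Default 0.05.
#' @param adjust `"bh"` (Benjamini-Hochberg, default) or `"bonferroni"`.
#' @param min_abs_rho Minimum |rho| for flagging. Default 0.3.
#' @param min_samples Minimum tumor samples with purity per cohort
#'   (default 10); a smaller cohort is a contract error.
#' @return A tibble with one row per (cohort, gene): `cohort`, `gene_id`,
#'   `rho`, `p`, `p_adj`, `flagged`. The union of flagged genes across
#'   cohorts — the exported purity subset — is available via
#'   [purity_gene_union()].
#' @export
purity_correlated_genes <- function(m, meta, alpha = 0.05,
                                    adjust = c("bh", "bonferroni"),
                                    min_abs_rho = 0.3, min_samples = 10) {
  stopifnot(inherits(m, "expr_matrix"))
  adjust <- match.arg(adjust)
  meta <- align_metadata(m, meta)
  tum <- dplyr::filter(meta, .data$disease_state == "tumor",
                       .data$model_type == "tissue", !.data$excluded)
  if (all(is.na(tum$purity))) {
    abort("No tumor tissue sample has a purity estimate.")
  }
  tum <- dplyr::filter(tum, !is.na(.data$purity))
  method <- c(bh = "BH", bonferroni = "bonferroni")[[adjust]]
  out <- purrr::map_dfr(split(tum, tum$tissue_group), function(coh) {
    cohort <- coh$tissue_group[1]
    if (nrow(coh) < min_samples) {
      abort(sprintf(
        "Cohort '%s' has %d tumor samples with purity; >= %d required.",
        cohort, nrow(coh), min_samples
      ))
    }
    if (var(coh$purity) == 0) {
      abort(sprintf("Purity is constant in cohort '%s'.", cohort))
    }
    vals <- m$values[, coh$sample_id, drop = FALSE]
    n <- nrow(coh)
    const <- apply(vals, 1, var) == 0
    rho <- rep(NA_real_, nrow(vals))
    # Pearson of ranks: rank each gene across samples, then against purity ranks
    rr <- rank_columns(t(vals[!const, , drop = FALSE]))
    rho[!const] <- cor(rr, rank(coh$purity))[, 1]
    p <- spearman_pvalue(rho, n)
    p_adj <- rep(NA_real_, length(p))
    p_adj[!const] <- p.adjust(p[!const], method)
    tibble::tibble(
      cohort = cohort, gene_id = rownames(vals), rho = rho, p = p,
      p_adj = p_adj,
      flagged = !is.na(rho) & p_adj < alpha & abs(rho) >= min_abs_rho
    )
  })
  attr(out, "alpha") <- alpha
  attr(out, "adjust") <- adjust
  attr(out, "min_abs_rho") <- min_abs_rho
  out
}

#' @rdname purity_correlated_genes
#' @param result The tibble returned by [purity_correlated_genes()].
#' @return `purity_gene_union()`: character vector, the union of flagged
#'   genes across cohorts in gene order.
#' @export
purity_gene_union <- function(result) {
  out <- unique(result$gene_id[result$flagged])
  structure(out[order(match(out, unique(result$gene_id)))],
            provenance = "purity_correlated")
}

#' Tissue-specific high/low gene sets
#'
#' For every tissue `t` among the non-diseased tissue samples, each gene
#' gets the score `z_t = (mean in t - mean of the other tissues' means) /
#' s.d. of the other tissues' means`; genes with `z_t >= z_threshold` form
#' the `<t>_high` set and `z_t <= -z_threshold` the `<t>_low` set. Means
#' are taken per tissue first, so unequal cohort sizes do not weight the
#' reference. Empty sets are dropped with a warning. Note that with few
#' tissues the denominator is an s.d. over few values and the score is
#' heavy-tailed; thresholds calibrated for large multi-tissue references
#' are conservative there.
#'
#' @param m An `expr_matrix` with `unit = "log2tpm"`.
#' @param meta Metadata; only non-diseased `model_type == "tissue"` samples
#'   are used. At least two tissue groups required.
#' @param z_threshold Threshold on the tissue z-score. Default 3.
#' @return A gene-set tibble (`set`, `description`, `genes`) as produced by
#'   [read_gmt()].
#' @export
tissue_specific_sets <- function(m, meta, z_threshold = 3) {
  stopifnot(inherits(m, "expr_matrix"))
  meta <- align_metadata(m, meta)
  nd <- dplyr::filter(meta, .data$disease_state == "non_diseased",
                      .data$model_type == "tissue", !.data$excluded)
  tissues <- sort(unique(nd$tissue_group))
  if (length(tissues) < 2) {
    abort("tissue_specific_sets() needs at least two tissue groups.")
  }
  tissue_means <- vapply(tissues, function(t) {
    rowMeans(m$values[, nd$sample_id[nd$tissue_group == t], drop = FALSE])
  }, numeric(nrow(m$values)))
  sets <- purrr::map_dfr(seq_along(tissues), function(i) {
    others <- tissue_means[, -i, drop = FALSE]
    mo <- rowMeans(others)
    so <- apply(others, 1, sd)
    z <- (tissue_means[, i] - mo) / so
    hi <- rownames(m$values)[!is.na(z) & z >= z_threshold]
    lo <- rownames(m$values)[!is.na(z) & z <= -z_threshold]
    tibble::tibble(
      set = paste0(tissues[i], c("_high", "_low")),
      description = paste0("genes with z ", c(">= ", "<= -"), z_threshold,
                           " in ", tissues[i], " vs other tissues"),
      genes = list(hi, lo)
    )
  })
  empty <- vapply(sets$genes, length, 0L) == 0
  if (any(empty)) {
    warn(paste0("Dropping empty tissue-specific set(s): ",
                paste(sets$set[empty], collapse = ", ")))
    sets <- sets[!empty, ]
  }
  sets
}
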