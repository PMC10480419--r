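#' Median Spearman correlation of each model sample to each tissue group
#'
#' For every model sample (cell line or PDX) and every tissue group (a
#' `tissue_group` x `disease_state` cell of the tissue cohort), computes the
#' pairwise Spearman correlation against each tissue sample in the group
#' over the chosen gene subset and takes the median — the per-model-sample
#' median-correlation record. Samples are rank-transformed once per subset,
#' then ranks are correlated with a single Pearson matrix product.
#'
#' @param m An `expr_matrix` with `unit = "tpm"` (Spearman correlation is
#'   invariant to monotone transforms, so TPM and log2 TPM give identical
#'   results).
#' @param meta Metadata tibble covering the matrix samples.
#' @param genes Optional character vector restricting the correlation to a
#'   gene subset; `NULL` uses every gene. At least 3 subset genes must be
#'   present in the matrix.
#' @param subset_name Label recorded in the output.
#' @param model_types Which model classes to correlate.
#' @param profile `"pairwise"` (median over per-sample correlations,
#'   default) or `"median"` (correlate against the group's median
#'   profile).
#' @param min_mean_tpm Optional expression floor: drop subset genes whose
#'   mean TPM across the used samples is below this value. Default 0 (no
#'   floor).
#' @return A tibble with one row per (model sample, tissue group):
#'   `model_sample_id`, `model_type`, `model_tissue_group`, `tissue_group`,
#'   `disease_state`, `gene_subset`, `rho_median`, `n_tissue_samples`,
#'   `n_genes_used`, ordered by model id then group.
#' @export
model_to_tissue <- function(m, meta, genes = NULL, subset_name = "all",
                            model_types = c("cell_line", "pdx"),
                            profile = c("pairwise", "median"),
                            min_mean_tpm = 0) {
  stopifnot(inherits(m, "expr_matrix"))
  profile <- match.arg(profile)
  if (m$unit == "counts") {
    abort("model_to_tissue() expects TPM (or log2 TPM) values, not raw counts.")
  }
  meta <- align_metadata(m, meta)
  meta <- dplyr::filter(meta, !.data$excluded)

  ids <- strip_gene_version(gene_ids(m))
  if (is.null(genes)) {
    keep <- seq_along(ids)
  } else {
    if (length(genes) == 0) {
      abort(sprintf("Gene subset '%s' is empty.", subset_name))
    }
    keep <- which(ids %in% strip_gene_version(genes))
    if (length(keep) < 3) {
      abort(sprintf(
        "Gene subset '%s' shares fewer than 3 genes with the matrix.",
        subset_name
      ))
    }
  }
  model_meta <- dplyr::filter(meta, .data$model_type %in% model_types)
  tissue_meta <- dplyr::filter(meta, .data$model_type == "tissue")
  if (nrow(model_meta) == 0) abort("No model samples selected.")
  if (nrow(tissue_meta) == 0) abort("No tissue samples available.")

  vals <- m$values[keep, c(model_meta$sample_id, tissue_meta$sample_id),
                   drop = FALSE]
  if (min_mean_tpm > 0) {
    vals <- vals[rowMeans(vals) >= min_mean_tpm, , drop = FALSE]
    if (nrow(vals) < 3) {
      abort("Fewer than 3 genes left after the min_mean_tpm filter.")
    }
  }
  n_genes_used <- nrow(vals)

  groups <- tissue_meta %>%
    dplyr::mutate(group = paste(.data$tissue_group, .data$disease_state,
                                sep = "|"))
  if (profile == "pairwise") {
    ranks <- rank_columns(vals)
    rho <- cor(ranks[, model_meta$sample_id, drop = FALSE],
               ranks[, groups$sample_id, drop = FALSE])
    records <- purrr::map_dfr(
      split(seq_len(nrow(groups)), groups$group),
      function(ix) {
        tibble::tibble(
          model_sample_id = model_meta$sample_id,
          rho_median = unname(apply(rho[, ix, drop = FALSE], 1, median)),
          n_tissue_samples = length(ix),
          tissue_group = groups$tissue_group[ix[1]],
          disease_state = groups$disease_state[ix[1]]
        )
      }
    )
  } else {
    med <- vapply(
      split(seq_len(nrow(groups)), groups$group),
      function(ix) apply(vals[, groups$sample_id[ix], drop = FALSE], 1, median),
      numeric(n_genes_used)
    )
    ranks_m <- rank_columns(vals[, model_meta$sample_id, drop = FALSE])
    ranks_t <- rank_columns(med)
    rho <- cor(ranks_m, ranks_t)
    key <- vapply(split(seq_len(nrow(groups)), groups$group),
                  function(ix) ix[1], 0L)
    records <- purrr::imap_dfr(
      as.data.frame(rho, optional = TRUE),
      function(col, grp) {
        ix <- key[[grp]]
        tibble::tibble(
          model_sample_id = model_meta$sample_id,
          rho_median = unname(col),
          n_tissue_samples = sum(groups$group == grp),
          tissue_group = groups$tissue_group[ix],
          disease_state = groups$disease_state[ix]
        )
      }
    )
  }
  records %>%
    dplyr::left_join(
      dplyr::select(model_meta, "sample_id", "model_type",
                    model_tissue_group = "tissue_group"),
      by = c(model_sample_id = "sample_id")
    ) %>%
    dplyr::mutate(gene_subset = subset_name, n_genes_used = n_genes_used) %>%
    dplyr::select("model_sample_id", "model_type", "model_tissue_group",
                  "tissue_group", "disease_state", "gene_subset",
                  "rho_median", "n_tissue_samples", "n_genes_used") %>%
    dplyr::arrange(.data$model_sample_id, .data$tissue_group,
                   .data$disease_state)
}

#' Matched-origin rank specificity of model samples
#'
#' Ranks, for every model sample, all candidate tissue groups by their
#' median correlation and asks whether the top-ranked group is the model's
#' matched-origin *tumor* group. The tie policy is strict: on a tied
#' maximum the matched group counts as best only if it comes first under
#' group-id-ascending tie-break, and ties at the top are flagged in the
#' output — silent optimistic tie-breaking would inflate specificity.
#'
#' @param records Correlation records from [model_to_tissue()] (one gene
#'   subset at a time).
#' @return A `specificity_summary`: list with `percent_best_match` (percent
#'   of model samples whose top group is their matched tumor group, overall
#'   and per model type), `per_model` (best group, matched-group dense rank
#'   and tie flag per model sample) and `group_medians` (median of the
#'   per-model medians for every origin x target cell, the heatmap analog).
#' @export
specificity <- function(records) {
  needed <- c("model_sample_id", "model_type", "model_tissue_group",
              "tissue_group", "disease_state", "rho_median")
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    abort(paste0("records are missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (length(unique(records$gene_subset %||% "all")) > 1) {
    abort("specificity() expects records from a single gene subset.")
  }
  records <- dplyr::mutate(
    records, group = paste(.data$tissue_group, .data$disease_state, sep = "|")
  )
  n_groups <- length(unique(records$group))
  complete <- records %>%
    dplyr::count(.data$model_sample_id) %>%
    dplyr::filter(.data$n != n_groups)
  if (nrow(complete)) {
    abort(paste0(
      "Every model sample needs a record for every candidate group; incomplete: ",
      paste(head(complete$model_sample_id, 10), collapse = ", ")
    ))
  }
  per_model <- records %>%
    dplyr::group_by(.data$model_sample_id) %>%
    dplyr::arrange(dplyr::desc(.data$rho_median), .data$group,
                   .by_group = TRUE) %>%
    dplyr::mutate(rank = dplyr::dense_rank(dplyr::desc(.data$rho_median))) %>%
    dplyr::summarise(
      model_type = .data$model_type[1],
      model_tissue_group = .data$model_tissue_group[1],
      best_group = .data$group[1],
      top_tie = sum(.data$rank == 1) > 1,
      matched_group = paste(.data$model_tissue_group[1], "tumor", sep = "|"),
      matched_rank = .data$rank[match(.data$matched_group[1], .data$group)],
      matched_rho = .data$rho_median[match(.data$matched_group[1], .data$group)],
      matched_best = !is.na(.data$matched_rank) &
        .data$best_group == .data$matched_group,
      .groups = "drop"
    )
  if (anyNA(per_model$matched_rank)) {
    bad <- per_model$model_sample_id[is.na(per_model$matched_rank)]
    abort(paste0("No matched tumor group among candidates for: ",
                 paste(head(bad, 10), collapse = ", ")))
  }
  pct <- per_model %>%
    dplyr::group_by(.data$model_type) %>%
    dplyr::summarise(
      percent_best_match = 100 * mean(.data$matched_best),
      n_models = dplyr::n(), .groups = "drop"
    ) %>%
    dplyr::bind_rows(tibble::tibble(
      model_type = "all",
      percent_best_match = 100 * mean(per_model$matched_best),
      n_models = nrow(per_model)
    ))
  group_medians <- records %>%
    dplyr::group_by(.data$model_type, .data$model_tissue_group,
                    .data$tissue_group, .data$disease_state) %>%
    dplyr::summarise(median_rho = median(.data$rho_median),
                     n_models = dplyr::n(), .groups = "drop")
  structure(
    list(
      percent_best_match = pct,
      per_model = per_model,
      group_medians = group_medians,
      gene_subset = records$gene_subset[1] %||% "all"
    ),
    class = "specificity_summary"
  )
}

#' @export
print.specificity_summary <- function(x, ...) {
  cat(sprintf("<specificity_summary> gene subset '%s'\n", x$gene_subset))
  print(x$percent_best_match)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.specificity_summary <- function(x, ...) x$per_model

#' @exportS3Method generics::glance
glance.specificity_summary <- function(x, ...) {
  tidyr::pivot_wider(
    dplyr::select(x$percent_best_match, -"n_models"),
    names_from = "model_type", values_from = "percent_best_match",
    names_prefix = "percent_best_match_"
  ) %>%
    dplyr::mutate(n_models = nrow(x$per_model), gene_subset = x$gene_subset)
}

#' Principal-component QC of an expression matrix
#'
#' Centered (not scaled) PCA over genes, the standard sanity check that
#' cohort classes separate along the leading components. The sign of each
#' component is fixed so that its largest-magnitude gene loading is
#' positive, making scores reproducible across platforms.
#'
#' @param m An `expr_matrix`, normally `log2tpm`.
#' @param meta Optional metadata joined onto the scores.
#' @param n_components Number of components to return.
#' @return A list of class `pca_qc`: `scores` (tibble, one row per sample),
#'   `variance` (tibble of per-component explained-variance fractions,
#'   non-increasing).
#' @export
pca_qc <- function(m, meta = NULL, n_components = 2) {
  stopifnot(inherits(m, "expr_matrix"))
  n_max <- min(nrow(m$values), ncol(m$values) - 1)
  if (ncol(m$values) < 3) abort("PCA needs at least 3 samples.")
  if (n_components > n_max) {
    abort(sprintf("n_components must be <= %d for this matrix.", n_max))
  }
  total_var <- sum(apply(m$values, 1, var))
  if (total_var == 0) abort("Zero total variance: all samples are identical.")
  fit <- prcomp(t(m$values), center = TRUE, scale. = FALSE)
  k <- seq_len(n_components)
  flip <- vapply(k, function(i) {
    l <- fit$rotation[, i]
    sign(l[which.max(abs(l))])
  }, 0)
  scores <- sweep(fit$x[, k, drop = FALSE], 2, flip, "*")
  out <- tibble::tibble(sample_id = colnames(m$values)) %>%
    dplyr::bind_cols(tibble::as_tibble(scores))
  if (!is.null(meta)) {
    out <- dplyr::left_join(out, validate_metadata(meta), by = "sample_id")
  }
  variance <- tibble::tibble(
    component = paste0("PC", k),
    variance_fraction = (fit$sdev^2 / sum(fit$sdev^2))[k]
  )
  structure(list(scores = out, variance = variance), class = "pca_qc")
}

#' @export
print.pca_qc <- function(x, ...) {
  cat("<pca_qc>\n")
  print(x$variance)
  invisible(x)
}
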