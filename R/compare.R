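#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Reports the statistic in the Mann-Whitney U convention: the rank sum of
#' `a` in the pooled sample minus `|a|(|a| + 1)/2`; this equals the `W`
#' printed by R's conventions, and the rank-sum form is `U + |a|(|a|+1)/2`.
#' The exact two-sided p (enumeration over rank assignments, via the exact
#' null distribution) is used when `|a| + |b| <= 20` and there are no
#' ties; otherwise a normal approximation with tie and continuity
#' correction.
#'
#' @param a,b Non-empty numeric vectors.
#' @param mode `"auto"` (default rule above), `"exact"` or
#'   `"normal_approx"`.
#' @return A one-row tibble: `U`, `p`, `method`, `n_a`, `n_b`.
#' @export
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4))  # U = 0, p = 1/3
wilcoxon_rank_sum <- function(a, b, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  if (length(a) == 0 || length(b) == 0) {
    abort("Both samples must be non-empty.")
  }
  if (anyNA(a) || anyNA(b)) abort("Missing values are not allowed.")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  pooled <- c(a, b)
  r <- rank(pooled)
  ties <- anyDuplicated(pooled) > 0
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  use_exact <- switch(mode,
    exact = TRUE,
    normal_approx = FALSE,
    auto = N <= 20 && !ties
  )
  if (use_exact && ties) {
    abort("Exact p-values are not defined with ties; use normal_approx.")
  }
  if (use_exact) {
    p <- 2 * min(pwilcox(U, n1, n2),
                 pwilcox(U - 1, n1, n2, lower.tail = FALSE))
    p <- min(1, p)
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(pooled)
    sigma2 <- n1 * n2 / 12 *
      ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- U - mu
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal_approx"
  }
  tibble::tibble(U = U, p = p, method = method, n_a = n1, n_b = n2)
}

#' Compare model types per tissue group
#'
#' For every tissue group x disease state with enough records of both
#' model classes, tests the per-model-sample median correlations of cell
#' lines against PDXs with the rank-sum test, Bonferroni-corrects within
#' the family of comparisons actually performed, and declares the model
#' type with the higher median the winner when the adjusted p clears
#' `alpha`. Groups with fewer than `min_n` records of either type are
#' skipped with a warning — real metadata is ragged and a hard error would
#' make mixed cohorts unusable.
#'
#' @param records Correlation records from [model_to_tissue()] containing
#'   both model types (single gene subset).
#' @param alpha Significance level on the adjusted p. Default 0.05.
#' @param min_n Minimum records per model type per group. Default 3.
#' @return A tibble, one row per comparison: `tissue_group`,
#'   `disease_state`, `n_cell_line`, `n_pdx`, `median_rho_cell_line`,
#'   `median_rho_pdx`, `U` (Mann-Whitney convention; rank sum of the
#'   cell-line sample = `U + n_cell_line (n_cell_line + 1) / 2`), `p_raw`,
#'   `p_adj`, `winner`.
#' @export
compare_model_types <- function(records, alpha = 0.05, min_n = 3) {
  types <- unique(records$model_type)
  unknown <- setdiff(types, c("cell_line", "pdx"))
  if (length(unknown)) {
    abort(paste0("Unknown model type(s) in records: ",
                 paste(unknown, collapse = ", ")))
  }
  if (length(unique(records$gene_subset %||% "all")) > 1) {
    abort("compare_model_types() expects records from a single gene subset.")
  }
  groups <- split(
    records,
    paste(records$tissue_group, records$disease_state, sep = "|")
  )
  rows <- purrr::map(groups, function(g) {
    a <- g$rho_median[g$model_type == "cell_line"]
    b <- g$rho_median[g$model_type == "pdx"]
    if (length(a) < min_n || length(b) < min_n) {
      warn(sprintf(
        "Skipping %s (%s): %d cell-line vs %d PDX records (need >= %d each).",
        g$tissue_group[1], g$disease_state[1], length(a), length(b), min_n
      ))
      return(NULL)
    }
    w <- wilcoxon_rank_sum(a, b, mode = "auto")
    tibble::tibble(
      tissue_group = g$tissue_group[1],
      disease_state = g$disease_state[1],
      n_cell_line = length(a), n_pdx = length(b),
      median_rho_cell_line = median(a), median_rho_pdx = median(b),
      U = w$U, p_raw = w$p
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) abort("No comparison had enough records of both types.")
  m <- nrow(out)
  out %>%
    dplyr::mutate(
      p_adj = pmin(1, .data$p_raw * m),
      winner = dplyr::case_when(
        .data$p_adj >= alpha ~ "none",
        .data$median_rho_cell_line > .data$median_rho_pdx ~ "cell_line",
        .data$median_rho_pdx > .data$median_rho_cell_line ~ "pdx",
        TRUE ~ "none"
      )
    ) %>%
    dplyr::arrange(.data$tissue_group, .data$disease_state)
}
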