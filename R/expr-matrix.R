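#' Expression matrix container
#'
#' A light wrapper around a genes x samples numeric matrix that carries the
#' expression unit (`"counts"`, `"tpm"` or `"log2tpm"`) and, for count
#' matrices, per-gene transcript lengths in base pairs. Rows are genes
#' (Ensembl-style identifiers, optionally versioned), columns are samples.
#'
#' Invariants enforced at construction:
#' * gene identifiers unique after version-stripping, sample identifiers
#'   unique;
#' * values finite, and non-negative for `counts`/`tpm`;
#' * for `unit = "tpm"`, every non-degenerate column sums to one million
#'   within a relative tolerance of 1e-6;
#' * for `unit = "counts"`, a positive length is required for every gene.
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   rownames (gene ids) and colnames (sample ids).
#' @param unit One of `"counts"`, `"tpm"`, `"log2tpm"`.
#' @param gene_lengths Numeric vector of per-gene lengths in base pairs,
#'   named by gene id or in row order. Required when `unit = "counts"`.
#' @return An `expr_matrix` object.
#' @export
#' @examples
#' m <- expr_matrix(
#'   matrix(c(3, 0, 0, 3), 2, dimnames = list(c("g1", "g2"), c("s1", "s2"))),
#'   unit = "counts", gene_lengths = c(g1 = 1000, g2 = 1000)
#' )
#' counts_to_tpm(m)
expr_matrix <- function(values, unit = c("counts", "tpm", "log2tpm"),
                        gene_lengths = NULL) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (genes x samples).")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must have gene ids as rownames and sample ids as colnames.")
  }
  if (anyDuplicated(colnames(values))) {
    abort("Duplicate sample ids in expression matrix.")
  }
  stripped <- strip_gene_version(rownames(values))
  if (anyDuplicated(stripped)) {
    dups <- unique(stripped[duplicated(stripped)])
    abort(paste0(
      "Duplicate gene ids after version-stripping: ",
      paste(head(dups, 10), collapse = ", ")
    ))
  }
  if (any(!is.finite(values))) {
    abort("Expression values must be finite.")
  }
  if (unit != "log2tpm" && any(values < 0)) {
    abort(sprintf("Negative values are not allowed for unit '%s'.", unit))
  }
  if (unit == "counts") {
    gene_lengths <- check_gene_lengths(gene_lengths, rownames(values))
  } else if (!is.null(gene_lengths)) {
    gene_lengths <- check_gene_lengths(gene_lengths, rownames(values))
  }
  if (unit == "tpm") {
    sums <- colSums(values)
    bad <- sums > 0 & abs(sums - 1e6) > 1e-6 * 1e6
    if (any(bad)) {
      abort(paste0(
        "TPM columns must sum to 1e6 (rel. tol 1e-6); offending samples: ",
        paste(head(colnames(values)[bad], 10), collapse = ", ")
      ))
    }
  }
  structure(
    list(values = values, unit = unit, gene_lengths = gene_lengths),
    class = "expr_matrix"
  )
}

check_gene_lengths <- function(gene_lengths, gene_ids) {
  if (is.null(gene_lengths)) {
    abort("`gene_lengths` is required for unit = 'counts'.")
  }
  if (!is.null(names(gene_lengths))) {
    missing <- setdiff(gene_ids, names(gene_lengths))
    if (length(missing)) {
      abort(paste0(
        "Missing gene length for ", length(missing), " gene(s): ",
        paste(head(missing, 10), collapse = ", ")
      ))
    }
    gene_lengths <- gene_lengths[gene_ids]
  } else if (length(gene_lengths) != length(gene_ids)) {
    abort("`gene_lengths` must be named by gene id or match the gene count.")
  } else {
    names(gene_lengths) <- gene_ids
  }
  if (any(!is.finite(gene_lengths)) || any(gene_lengths <= 0)) {
    abort("Gene lengths must be positive and finite.")
  }
  gene_lengths
}

#' Strip Ensembl-style version suffixes from gene identifiers
#'
#' Removes a trailing `.N` from each identifier so that cohorts annotated at
#' different GENCODE patch levels can be joined.
#'
#' @param ids Character vector of gene identifiers.
#' @return Character vector with trailing `.N` removed.
#' @export
#' @examples
#' strip_gene_version(c("ENSG00000141510.16", "ENSG00000141510"))
strip_gene_version <- function(ids) {
  sub("\\.\\d+$", "", ids)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf(
    "<expr_matrix> %d genes x %d samples, unit = %s\n",
    nrow(x$values), ncol(x$values), x$unit
  ))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Gene and sample identifiers of an expression matrix
#'
#' @param x An `expr_matrix`.
#' @return Character vector of identifiers.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Convert raw counts to transcripts per million
#'
#' Per sample, counts are divided by gene length in kilobases to obtain
#' length-normalised rates, and the rates are scaled to sum to one million.
#' A sample whose counts are all zero yields an all-zero output column and a
#' warning rather than an error, so that degraded libraries can be excluded
#' downstream instead of crashing ingestion.
#'
#' @param m An `expr_matrix` with `unit = "counts"`.
#' @return An `expr_matrix` with `unit = "tpm"`.
#' @export
counts_to_tpm <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$unit != "counts") {
    abort(sprintf("counts_to_tpm() expects unit 'counts', got '%s'.", m$unit))
  }
  rates <- m$values / (m$gene_lengths / 1000)
  totals <- colSums(rates)
  zero <- totals == 0
  if (any(zero)) {
    warn(paste0(
      "All-zero sample column(s) in TPM conversion: ",
      paste(head(colnames(m$values)[zero], 10), collapse = ", ")
    ))
    totals[zero] <- 1
  }
  tpm <- sweep(rates, 2, totals, "/") * 1e6
  expr_matrix(tpm, unit = "tpm", gene_lengths = m$gene_lengths)
}

#' Log-transform a TPM matrix
#'
#' Applies `log2(x + 1)` elementwise; monotone and zero-preserving. Used for
#' variance ranking and PCA, where raw TPM is dominated by a handful of
#' extreme genes.
#'
#' @param m An `expr_matrix` with `unit = "tpm"`.
#' @return An `expr_matrix` with `unit = "log2tpm"`.
#' @export
log_transform <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$unit != "tpm") {
    abort(sprintf("log_transform() expects unit 'tpm', got '%s'.", m$unit))
  }
  expr_matrix(log2(m$values + 1), unit = "log2tpm",
              gene_lengths = m$gene_lengths)
}

#' Restrict matrices to their common gene space
#'
#' Gene identifiers are matched after version-stripping; every output matrix
#' is restricted to the intersection, in the gene order of the first input.
#' The number of genes dropped from each input is reported as a message and
#' attached as the `"dropped"` attribute.
#'
#' @param matrices List of at least two `expr_matrix` objects.
#' @return List of `expr_matrix` objects over the shared gene space.
#' @export
harmonize <- function(matrices) {
  if (!is.list(matrices) || length(matrices) < 2) {
    abort("harmonize() needs a list of at least two expression matrices.")
  }
  stripped <- lapply(matrices, function(m) strip_gene_version(gene_ids(m)))
  common <- Reduce(intersect, stripped)
  if (length(common) == 0) {
    abort("No genes shared between the input matrices.")
  }
  common <- stripped[[1]][stripped[[1]] %in% common]
  dropped <- vapply(stripped, function(s) length(s) - length(common), 0L)
  message(
    "harmonize: ", length(common), " shared genes; dropped per input: ",
    paste(dropped, collapse = ", ")
  )
  out <- purrr::map2(matrices, stripped, function(m, s) {
    idx <- match(common, s)
    v <- m$values[idx, , drop = FALSE]
    rownames(v) <- common
    gl <- m$gene_lengths
    if (!is.null(gl)) {
      gl <- gl[idx]
      names(gl) <- common
    }
    if (m$unit == "counts") {
      expr_matrix(v, unit = "counts", gene_lengths = gl)
    } else {
      # subsetting a TPM matrix breaks the column-sum invariant on purpose:
      # carry the subset forward as plain values with the parent's unit
      structure(list(values = v, unit = m$unit, gene_lengths = gl),
                class = "expr_matrix")
    }
  })
  attr(out, "dropped") <- dropped
  out
}
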