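#' Read an expression matrix from tab-separated text
#'
#' Expects one header row of sample ids, a first column of gene ids, and a
#' numeric body. Any cell that does not parse as a number (including the
#' string `"NA"`) is a hard error reported with its row and column, because
#' silently imputed expression values corrupt every downstream correlation.
#'
#' @param path Path to the TSV file.
#' @param unit Expression unit of the file (`"counts"`, `"tpm"`,
#'   `"log2tpm"`).
#' @param lengths_path Optional path to a two-column TSV (gene_id,
#'   length_bp); required when `unit = "counts"`.
#' @return An `expr_matrix`.
#' @export
read_expression <- function(path, unit = c("counts", "tpm", "log2tpm"),
                            lengths_path = NULL) {
  unit <- match.arg(unit)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  if (ncol(raw) < 2) abort("Expression file needs a gene id column and at least one sample.")
  genes <- raw[[1]]
  body <- as.matrix(raw[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(body), nrow(body), ncol(body)))
  bad <- which(is.na(num) & !is.na(body), arr.ind = TRUE)
  bad <- rbind(bad, which(is.na(body), arr.ind = TRUE))
  if (nrow(bad)) {
    i <- bad[1, 1]; j <- bad[1, 2]
    abort(sprintf(
      "Non-numeric expression value '%s' at row %d (gene %s), column %d (sample %s).",
      body[i, j], i, genes[i], j, colnames(body)[j]
    ))
  }
  dimnames(num) <- list(genes, colnames(body))
  lengths <- NULL
  if (!is.null(lengths_path)) lengths <- read_gene_lengths(lengths_path)
  expr_matrix(num, unit = unit, gene_lengths = lengths)
}

#' Write an expression matrix as tab-separated text
#'
#' @param m An `expr_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  stopifnot(inherits(m, "expr_matrix"))
  df <- data.frame(gene_id = gene_ids(m), m$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-gene transcript lengths
#'
#' @param path Two-column TSV with header: gene_id, length_bp.
#' @return Named numeric vector of lengths in base pairs.
#' @export
read_gene_lengths <- function(path) {
  tbl <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = c("character", "numeric"))
  setNames(tbl[[2]], tbl[[1]])
}

#' @rdname read_gene_lengths
#' @param lengths Named numeric vector of lengths.
#' @export
write_gene_lengths <- function(lengths, path) {
  utils::write.table(
    data.frame(gene_id = names(lengths), length_bp = unname(lengths)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

metadata_columns <- c("sample_id", "source", "tissue_group", "disease_state",
                      "model_type")

#' Read and validate a sample-metadata table
#'
#' Required columns: `sample_id`, `source`, `tissue_group`, `disease_state`
#' (`tumor`/`non_diseased`), `model_type` (`cell_line`/`pdx`/`tissue`).
#' Optional: `purity` in \[0, 1\] (tumor samples only), `excluded` (logical)
#' and `exclusion_reason`.
#'
#' @param path Path to a TSV file.
#' @return A tibble, one row per sample.
#' @export
read_metadata <- function(path) {
  meta <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_metadata(meta)
}

#' @rdname read_metadata
#' @param meta A data frame of per-sample annotations.
#' @export
validate_metadata <- function(meta) {
  meta <- tibble::as_tibble(meta)
  missing <- setdiff(metadata_columns, names(meta))
  if (length(missing)) {
    abort(paste0("Metadata is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(meta$sample_id)) {
    abort("Metadata sample_id values must be unique.")
  }
  bad_state <- setdiff(unique(meta$disease_state), c("tumor", "non_diseased"))
  if (length(bad_state)) {
    abort(paste0("Unknown disease_state value(s): ",
                 paste(bad_state, collapse = ", ")))
  }
  bad_type <- setdiff(unique(meta$model_type), c("cell_line", "pdx", "tissue"))
  if (length(bad_type)) {
    abort(paste0("Unknown model_type value(s): ",
                 paste(bad_type, collapse = ", ")))
  }
  if (!"purity" %in% names(meta)) meta$purity <- NA_real_
  if (!"excluded" %in% names(meta)) meta$excluded <- FALSE
  meta$excluded[is.na(meta$excluded)] <- FALSE
  if (!"exclusion_reason" %in% names(meta)) meta$exclusion_reason <- NA_character_
  ok <- is.na(meta$purity) | (meta$purity >= 0 & meta$purity <= 1)
  if (!all(ok)) abort("purity must lie in [0, 1] where present.")
  if (any(!is.na(meta$purity) & meta$disease_state != "tumor")) {
    abort("purity may only be present for tumor samples.")
  }
  meta
}

#' @rdname read_metadata
#' @export
write_metadata <- function(meta, path) {
  readr::write_tsv(meta, path, progress = FALSE)
  invisible(path)
}

#' Check that metadata covers an expression matrix
#'
#' Every sample column of `m` must have exactly one metadata row.
#'
#' @param m An `expr_matrix`.
#' @param meta Metadata tibble.
#' @return The metadata restricted to the matrix samples, in matrix order.
#' @export
align_metadata <- function(m, meta) {
  meta <- validate_metadata(meta)
  missing <- setdiff(sample_ids(m), meta$sample_id)
  if (length(missing)) {
    abort(paste0("Metadata missing for sample(s): ",
                 paste(head(missing, 10), collapse = ", ")))
  }
  meta[match(sample_ids(m), meta$sample_id), ]
}

#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: one set per line, `name TAB description TAB member
#' TAB member ...`. Members are version-stripped. A line with fewer than
#' three fields (i.e. an empty member list) is a parse error.
#'
#' @param path Path to a GMT file.
#' @return A tibble with columns `set`, `description` and a list-column
#'   `genes`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parsed <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(parsed, length, 0L) < 3)
  if (length(short)) {
    abort(sprintf("GMT line %d has fewer than 3 fields.", short[1]))
  }
  out <- tibble::tibble(
    set = vapply(parsed, `[[`, "", 1),
    description = vapply(parsed, `[[`, "", 2),
    genes = lapply(parsed, function(f) strip_gene_version(f[-(1:2)]))
  )
  if (anyDuplicated(out$set)) abort("GMT set names must be unique.")
  out
}

#' @rdname read_gmt
#' @param sets A gene-set tibble as returned by [read_gmt()].
#' @export
write_gmt <- function(sets, path) {
  stopifnot(all(c("set", "description", "genes") %in% names(sets)))
  if (any(vapply(sets$genes, length, 0L) == 0)) {
    abort("GMT sets must have at least one member gene.")
  }
  lines <- purrr::pmap_chr(sets[c("set", "description", "genes")],
    function(set, description, genes) {
      paste(c(set, description, genes), collapse = "\t")
    })
  writeLines(lines, path)
  invisible(path)
}

#' Select sample identifiers from metadata with tidy predicates
#'
#' A small convenience wrapper so correlation functions can be driven by
#' dplyr-style filters, e.g.
#' `pick_samples(meta, model_type == "cell_line", tissue_group == "brain")`.
#'
#' @param meta Metadata tibble.
#' @param ... Filter expressions evaluated in the metadata.
#' @param include_excluded Keep samples flagged `excluded`? Default `FALSE`.
#' @return Character vector of sample ids.
#' @export
pick_samples <- function(meta, ..., include_excluded = FALSE) {
  meta <- validate_metadata(meta)
  if (!include_excluded) meta <- dplyr::filter(meta, !.data$excluded)
  dplyr::filter(meta, ...)$sample_id
}
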