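#' Default pipeline configuration
#'
#' A flat, typed key-value configuration for [run_pipeline()]. Unknown keys
#' are errors, not warnings — silent typos in analysis configs are the
#' classic reproducibility failure.
#'
#' @param seed Master seed for every source of randomness.
#' @param simulate Named list of [sim_config()] overrides.
#' @param subset_sizes Most-variable-gene subset sizes; positive, unique,
#'   ascending. Sizes exceeding the simulated gene count are dropped with
#'   a warning.
#' @param variance_reference Which cohorts define the variance ranking:
#'   any of `"tumor"`, `"non_diseased"`.
#' @param purity_mode `"include"`, `"exclude"` or `"both"`: correlate with
#'   purity-correlated genes left in, removed, or both ways.
#' @param alpha,adjust,min_abs_rho Purity-detector parameters (see
#'   [purity_correlated_genes()]).
#' @param z_threshold Tissue-specific z-score threshold.
#' @param stages Character vector of stages to run, in dependency order.
#' @return A validated `run_config` list.
#' @export
run_config <- function(seed = 1,
                       simulate = list(),
                       subset_sizes = c(100, 1000, 5000, 10000),
                       variance_reference = c("tumor", "non_diseased"),
                       purity_mode = "both",
                       alpha = 0.05,
                       adjust = "bh",
                       min_abs_rho = 0.3,
                       z_threshold = 3,
                       stages = c("simulate", "tpm", "pca", "subsets",
                                  "correlate", "specificity", "compare",
                                  "gene_corr", "enrich")) {
  cfg <- list(
    seed = as.integer(seed), simulate = simulate,
    subset_sizes = as.integer(subset_sizes),
    variance_reference = variance_reference,
    purity_mode = purity_mode, alpha = alpha, adjust = adjust,
    min_abs_rho = min_abs_rho, z_threshold = z_threshold, stages = stages
  )
  validate_run_config(cfg)
}

all_stages <- c("simulate", "tpm", "pca", "subsets", "correlate",
                "specificity", "compare", "gene_corr", "enrich")

validate_run_config <- function(cfg) {
  known <- names(formals(run_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  defaults <- lapply(formals(run_config)[setdiff(known, names(cfg))], eval)
  cfg <- c(cfg, defaults)
  ks <- cfg$subset_sizes
  if (any(ks <= 0) || anyDuplicated(ks) || is.unsorted(ks)) {
    abort("subset_sizes must be positive, unique and ascending.")
  }
  bad <- setdiff(cfg$variance_reference, c("tumor", "non_diseased"))
  if (length(bad)) abort("variance_reference must be 'tumor'/'non_diseased'.")
  if (!cfg$purity_mode %in% c("include", "exclude", "both")) {
    abort("purity_mode must be include, exclude or both.")
  }
  bad <- setdiff(cfg$stages, all_stages)
  if (length(bad)) {
    abort(paste0("Unknown stage(s): ", paste(bad, collapse = ", ")))
  }
  structure(cfg[known], class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path Path to a YAML file whose keys mirror [run_config()].
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

#' Run the end-to-end synthetic benchmark pipeline
#'
#' Executes the enabled stages in dependency order — simulate, TPM
#' normalisation, PCA QC, gene-subset construction, model-tissue
#' correlation over every subset and purity mode, matched-origin
#' specificity, cell-line vs PDX comparison, per-gene correlation
#' classification and over-representation against the ground-truth marker
#' sets — writing every stage's outputs to `out_dir` before the next stage
#' starts, and a machine-readable manifest last. All randomness flows from
#' the config seed, so a rerun with the same config reproduces identical
#' files.
#'
#' @param config A `run_config`, a named list of its keys, or a YAML path.
#' @param out_dir Output directory (created if needed).
#' @return The run manifest (list), invisibly. Written as `manifest.json`:
#'   package version, config checksum, per-file md5 checksums, per-stage
#'   wall times and collected warnings.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) config <- validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  timings <- list()
  warnings <- character()
  log_file <- function(path, stage) {
    files[[length(files) + 1]] <<- path
    names(files)[length(files)] <<- stage
  }
  note <- function(msg) {
    warnings <<- c(warnings, msg)
    message("[pipeline] ", msg)
  }
  run_stage <- function(stage, fun) {
    if (!stage %in% config$stages) return(invisible(NULL))
    t0 <- Sys.time()
    message("[pipeline] stage: ", stage)
    withCallingHandlers(
      fun(),
      warning = function(w) {
        note(paste0(stage, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    )
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  }
  path <- function(name) file.path(out_dir, name)

  cfg_path <- path("config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)

  sim <- NULL; tpm <- NULL; ltpm <- NULL; subsets <- NULL
  purity_union <- character(); correlations <- NULL

  run_stage("simulate", function() {
    scfg <- do.call(sim_config, c(config$simulate,
                                  if (!"seed" %in% names(config$simulate))
                                    list(seed = config$seed)))
    sim <<- simulate_cohort(scfg)
    write_expression(sim$counts, path("expression_counts.tsv"))
    write_gene_lengths(sim$counts$gene_lengths, path("gene_lengths.tsv"))
    write_metadata(sim$metadata, path("metadata.tsv"))
    readr::write_tsv(sim$truth$genes, path("truth_genes.tsv"), progress = FALSE)
    write_gmt(sim$truth$marker_sets, path("truth_marker_sets.gmt"))
    for (f in c("expression_counts.tsv", "gene_lengths.tsv", "metadata.tsv",
                "truth_genes.tsv", "truth_marker_sets.gmt"))
      log_file(path(f), "simulate")
  })
  if (is.null(sim)) abort("The simulate stage is required by every other stage.")

  run_stage("tpm", function() {
    tpm <<- counts_to_tpm(sim$counts)
    ltpm <<- log_transform(tpm)
    write_expression(tpm, path("expression_tpm.tsv"))
    log_file(path("expression_tpm.tsv"), "tpm")
  })
  if (is.null(tpm)) abort("Stage 'tpm' is required downstream; enable it.")

  run_stage("pca", function() {
    qc <- pca_qc(ltpm, sim$metadata, n_components = 2)
    readr::write_tsv(qc$scores, path("pca_scores.tsv"), progress = FALSE)
    readr::write_tsv(qc$variance, path("pca_variance.tsv"), progress = FALSE)
    log_file(path("pca_scores.tsv"), "pca")
    log_file(path("pca_variance.tsv"), "pca")
  })

  run_stage("subsets", function() {
    n_genes <- nrow(tpm$values)
    ks <- config$subset_sizes
    if (any(ks > n_genes)) {
      note(sprintf("Dropping subset sizes > %d genes: %s", n_genes,
                   paste(ks[ks > n_genes], collapse = ", ")))
      ks <- ks[ks <= n_genes]
    }
    subs <- list()
    for (ref in config$variance_reference) {
      ref_samples <- pick_samples(sim$metadata, .data$model_type == "tissue",
                                  .data$disease_state == ref)
      for (k in ks) {
        nm <- sprintf("var%d_%s", k, ref)
        subs[[nm]] <- top_variable_genes(ltpm, k, ref_samples)
        writeLines(subs[[nm]], path(paste0("subset_", nm, ".txt")))
        log_file(path(paste0("subset_", nm, ".txt")), "subsets")
      }
    }
    purity_tbl <- purity_correlated_genes(
      tpm, sim$metadata, alpha = config$alpha, adjust = config$adjust,
      min_abs_rho = config$min_abs_rho
    )
    readr::write_tsv(purity_tbl, path("purity_genes.tsv"), progress = FALSE)
    purity_union <<- purity_gene_union(purity_tbl)
    writeLines(purity_union, path("purity_union.txt"))
    ts_sets <- tissue_specific_sets(ltpm, sim$metadata,
                                    z_threshold = config$z_threshold)
    if (nrow(ts_sets)) write_gmt(ts_sets, path("tissue_specific_sets.gmt"))
    for (f in c("purity_genes.tsv", "purity_union.txt",
                if (nrow(ts_sets)) "tissue_specific_sets.gmt"))
      log_file(path(f), "subsets")
    subsets <<- subs
  })

  run_stage("correlate", function() {
    jobs <- c(list(all = NULL), subsets %||% list())
    recs <- purrr::imap(jobs, function(genes, nm) {
      out <- list()
      if (config$purity_mode %in% c("include", "both")) {
        out$incl <- model_to_tissue(tpm, sim$metadata, genes, nm)
      }
      if (config$purity_mode %in% c("exclude", "both")) {
        base <- genes %||% gene_ids(tpm)
        kept <- exclude_genes(base, purity_union)
        out$excl <- model_to_tissue(tpm, sim$metadata, kept,
                                    paste0(nm, "_noPurity"))
      }
      dplyr::bind_rows(out)
    })
    correlations <<- dplyr::bind_rows(recs)
    readr::write_tsv(correlations, path("correlations.tsv"), progress = FALSE)
    log_file(path("correlations.tsv"), "correlate")
  })

  run_stage("specificity", function() {
    if (is.null(correlations)) abort("Stage 'specificity' needs 'correlate'.")
    per_subset <- correlations %>%
      dplyr::group_split(.data$gene_subset) %>%
      purrr::map(specificity)
    summary_tbl <- purrr::map_dfr(per_subset, glance)
    readr::write_tsv(summary_tbl, path("specificity.tsv"), progress = FALSE)
    full <- per_subset[[which(vapply(per_subset, function(s)
      s$gene_subset, "") == "all")]]
    readr::write_tsv(full$group_medians, path("group_medians_all.tsv"),
                     progress = FALSE)
    log_file(path("specificity.tsv"), "specificity")
    log_file(path("group_medians_all.tsv"), "specificity")
  })

  run_stage("compare", function() {
    if (is.null(correlations)) abort("Stage 'compare' needs 'correlate'.")
    cmp <- compare_model_types(
      dplyr::filter(correlations, .data$gene_subset == "all"),
      alpha = config$alpha
    )
    readr::write_tsv(cmp, path("comparisons.tsv"), progress = FALSE)
    log_file(path("comparisons.tsv"), "compare")
  })

  gene_corr_results <- list()
  run_stage("gene_corr", function() {
    tg <- sort(unique(sim$metadata$tissue_group))[1]
    tissue_s <- pick_samples(sim$metadata, .data$model_type == "tissue",
                             .data$disease_state == "tumor",
                             .data$tissue_group == tg)
    for (mt in c("cell_line", "pdx")) {
      model_s <- pick_samples(sim$metadata, .data$model_type == mt,
                              .data$tissue_group == tg)
      res <- per_gene_correlation(tpm, model_s, tissue_s,
                                  alpha = config$alpha,
                                  model_group = paste0(tg, "_", mt),
                                  tissue_group = paste0(tg, "_tumor"))
      gene_corr_results[[mt]] <<- res
      f <- sprintf("gene_correlation_%s.tsv", mt)
      readr::write_tsv(res, path(f), progress = FALSE)
      log_file(path(f), "gene_corr")
    }
  })

  run_stage("enrich", function() {
    if (!length(gene_corr_results)) abort("Stage 'enrich' needs 'gene_corr'.")
    for (mt in names(gene_corr_results)) {
      res <- gene_corr_results[[mt]]
      universe <- res$gene_id[res$class != "undefined"]
      query <- res$gene_id[res$class == "correlated_sig"]
      if (!length(query)) {
        note(sprintf("No significantly correlated genes for %s; skipping.", mt))
        next
      }
      enr <- overrepresentation(query, sim$truth$marker_sets, universe,
                                adjust = config$adjust)
      f <- sprintf("enrichment_%s.tsv", mt)
      readr::write_tsv(enr, path(f), progress = FALSE)
      log_file(path(f), "enrich")
    }
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("fidelitr")),
    seed = config$seed,
    config_file = basename(cfg_path),
    config_md5 = unname(tools::md5sum(cfg_path)),
    stages_run = intersect(all_stages, config$stages),
    files = tibble::tibble(
      stage = names(files),
      file = basename(unlist(files)),
      md5 = unname(tools::md5sum(unlist(files)))
    ),
    timings_sec = timings,
    warnings = warnings
  )
  jsonlite::write_json(
    manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(manifest)
}
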