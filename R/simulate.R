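#' Configuration for the synthetic-cohort generator
#'
#' Builds and validates the parameter list consumed by [simulate_cohort()].
#' Defaults describe a desk-scale multi-tissue study: three tissues, 2,000
#' genes, per tissue 30 tumor and 15 non-diseased tissue samples plus 30
#' cell lines and 30 PDXs, tumor purity drawn from Beta(3, 1.5) (wide, mean
#' 0.67, mirroring the spread of copy-number-based purity estimates), and
#' model classes whose fidelity to the origin tissue is controlled by a
#' log-scale drift standard deviation (cell lines 1.0, PDXs 0.3, so PDXs
#' are the higher-fidelity class).
#'
#' Gene architecture: each tissue owns `n_tissue_specific` marker genes
#' (half expressed distinctly high, half distinctly low, at +/- 3 x
#' `tissue_signal_sd` on the log2 scale); `n_purity_responsive` genes split
#' into tumor-cell-intrinsic "+" genes (contrast 3 x `tissue_signal_sd`
#' between tumor cells and stroma) and stromal "-" markers (milder contrast
#' of `tissue_signal_sd`, with a baseline offset chosen so that the total
#' linear-scale library mass is invariant to purity — this keeps TPM
#' compositional effects from inducing spurious purity correlations in
#' background genes). Purity-responsive baselines are drawn from the upper
#' expression range (floor `purity_baseline_floor`), reflecting that
#' stromal and proliferation markers are not low-abundance transcripts.
#'
#' @param n_tissues Number of tissues (>= 2).
#' @param n_genes Total number of genes.
#' @param n_tissue_specific Tissue-specific genes per tissue (even; split
#'   into high and low halves).
#' @param n_purity_responsive Purity-responsive genes (even; split into
#'   "+" and "-" directions).
#' @param n_tumor,n_non_diseased,n_cell_line,n_pdx Samples per tissue for
#'   each cohort class.
#' @param purity_beta Length-2 vector, (alpha, beta) of the purity Beta
#'   distribution on \[0, 1\].
#' @param drift_cell_line,drift_pdx Standard deviation (log2 scale) of the
#'   gene-wise model-specific perturbation; larger = lower fidelity.
#' @param tissue_signal_sd S.d. of the small per-gene tissue shifts;
#'   tissue-specific markers sit at 3 x this value.
#' @param noise_sd Per-sample per-gene biological noise s.d. (log2 scale).
#' @param baseline_log_mean_range (lo, hi) of the per-gene baseline log2
#'   mean expression.
#' @param dispersion Negative-binomial size parameter of the count noise.
#' @param library_size_sd S.d. of the log-normal library-size factor.
#' @param gene_length Transcript length in bp written for every gene.
#' @param purity_baseline_floor Lower bound of the baseline log2 mean for
#'   purity-responsive genes.
#' @param seed Master seed; all stage substreams derive from it by fixed
#'   offsets, so adding a stage never reshuffles earlier draws.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_tissues = 3,
                       n_genes = 2000,
                       n_tissue_specific = 100,
                       n_purity_responsive = 200,
                       n_tumor = 30,
                       n_non_diseased = 15,
                       n_cell_line = 30,
                       n_pdx = 30,
                       purity_beta = c(3, 1.5),
                       drift_cell_line = 1.0,
                       drift_pdx = 0.3,
                       tissue_signal_sd = 1.0,
                       noise_sd = 0.25,
                       baseline_log_mean_range = c(1, 8),
                       dispersion = 15,
                       library_size_sd = 0.2,
                       gene_length = 1000,
                       purity_baseline_floor = 3.5,
                       seed = 1) {
  cfg <- list(
    n_tissues = as.integer(n_tissues), n_genes = as.integer(n_genes),
    n_tissue_specific = as.integer(n_tissue_specific),
    n_purity_responsive = as.integer(n_purity_responsive),
    n_tumor = as.integer(n_tumor),
    n_non_diseased = as.integer(n_non_diseased),
    n_cell_line = as.integer(n_cell_line), n_pdx = as.integer(n_pdx),
    purity_beta = as.numeric(purity_beta),
    drift_cell_line = drift_cell_line, drift_pdx = drift_pdx,
    tissue_signal_sd = tissue_signal_sd, noise_sd = noise_sd,
    baseline_log_mean_range = as.numeric(baseline_log_mean_range),
    dispersion = dispersion, library_size_sd = library_size_sd,
    gene_length = gene_length,
    purity_baseline_floor = purity_baseline_floor,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_tissues < 2) abort("n_tissues must be >= 2.")
  if (cfg$n_tissue_specific %% 2 != 0 || cfg$n_purity_responsive %% 2 != 0) {
    abort("n_tissue_specific and n_purity_responsive must be even.")
  }
  reserved <- cfg$n_tissue_specific * cfg$n_tissues + cfg$n_purity_responsive
  if (reserved > cfg$n_genes) {
    abort(sprintf(
      "Gene budget exceeded: %d tissue-specific + purity-responsive genes > %d total.",
      reserved, cfg$n_genes
    ))
  }
  if (cfg$drift_cell_line < 0 || cfg$drift_pdx < 0) {
    abort("Drift values must be non-negative.")
  }
  if (length(cfg$purity_beta) != 2 || any(cfg$purity_beta <= 0)) {
    abort("purity_beta must be two positive shape parameters.")
  }
  if (cfg$noise_sd < 0 || cfg$tissue_signal_sd < 0) {
    abort("noise_sd and tissue_signal_sd must be non-negative.")
  }
  if (diff(cfg$baseline_log_mean_range) <= 0) {
    abort("baseline_log_mean_range must be an increasing (lo, hi) pair.")
  }
  if (cfg$dispersion <= 0) abort("dispersion must be positive.")
  if (min(cfg$n_tumor, cfg$n_non_diseased, cfg$n_cell_line, cfg$n_pdx) < 1) {
    abort("All per-tissue sample counts must be >= 1.")
  }
  invisible(cfg)
}

# fixed-offset substreams off the master seed; adding a stage appends a new
# offset and never reshuffles earlier draws
substream <- function(seed, k) {
  set.seed((as.integer(seed) %% 1000003L) + 1009L * k)
}

#' Simulate a multi-tissue cohort with preclinical models
#'
#' Generates raw negative-binomial counts for tumor and non-diseased tissue
#' samples, cell lines and PDXs across several tissues, with full
#' ground-truth labels. The generative model, deterministic given the
#' config seed:
#'
#' 1. baseline log2 mean per gene ~ Uniform(lo, hi);
#' 2. tissue effect: a tissue's specific-high genes sit at +3 x
#'    `tissue_signal_sd`, its specific-low genes at -3 x, and every other
#'    gene receives a small Normal(0, `tissue_signal_sd`) shift;
#' 3. a non-diseased tissue sample's log mean is baseline + tissue effect;
#' 4. a tumor sample draws a latent purity p ~ Beta(alpha, beta) and mixes,
#'    on the linear scale, p parts tumor-cell profile with (1 - p) parts
#'    stromal profile. Both components carry the host tissue's identity
#'    signal (stroma is host tissue); they differ on the purity-responsive
#'    genes, so across tumors those genes track purity with the labelled
#'    sign;
#' 5. a model sample (cell line or PDX) is the origin tissue's tumor-cell
#'    profile (purity 1, no stroma) plus gene-wise Normal(0, drift) on the
#'    log scale;
#' 6. counts ~ NB(mean = 2^logmean x library factor, size = dispersion)
#'    with library factor ~ LogNormal(0, `library_size_sd`).
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `counts` (an `expr_matrix` of raw counts),
#'   `metadata` (sample tibble incl. latent purity for tumor samples) and
#'   `truth` (gene-role tibble, per-tissue marker sets, the config).
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  if (!inherits(cfg, "sim_config")) cfg <- do.call(sim_config, cfg)
  validate_sim_config(cfg)
  G <- cfg$n_genes; T_ <- cfg$n_tissues
  delta <- 3 * cfg$tissue_signal_sd          # tissue / tumor-cell contrast
  d_strom <- cfg$tissue_signal_sd            # stromal-marker contrast
  tissues <- paste0("tissue", LETTERS[seq_len(T_)])
  genes <- sprintf("g%05d", seq_len(G))

  ## stage 1: gene architecture ------------------------------------------
  substream(cfg$seed, 1)
  lo <- cfg$baseline_log_mean_range[1]; hi <- cfg$baseline_log_mean_range[2]
  mu <- runif(G, lo, hi)
  half_ts <- cfg$n_tissue_specific / 2
  idx <- 1L
  ts_high <- ts_low <- vector("list", T_)
  for (t in seq_len(T_)) {
    ts_high[[t]] <- seq.int(idx, length.out = half_ts); idx <- idx + half_ts
    ts_low[[t]] <- seq.int(idx, length.out = half_ts); idx <- idx + half_ts
  }
  half_pur <- cfg$n_purity_responsive / 2
  pur_pos <- seq.int(idx, length.out = half_pur); idx <- idx + half_pur
  pur_neg <- seq.int(idx, length.out = half_pur)
  if (half_pur > 0) {
    mu[pur_pos] <- runif(half_pur, max(cfg$purity_baseline_floor, lo), hi)
    # offset the stromal markers so p * 2^(+delta) + (1-p) * 2^(-delta) mass
    # lost on "+" genes is exactly recouped on "-" genes: library mass is
    # then purity-invariant and TPM carries no compositional purity signal
    offset <- log2((2^delta - 2^-delta) / (2^d_strom - 2^-d_strom))
    mu[pur_neg] <- mu[pur_pos] + offset
  }
  contrast <- numeric(G)
  contrast[pur_pos] <- delta
  contrast[pur_neg] <- d_strom
  direction <- numeric(G)
  direction[pur_pos] <- 1
  direction[pur_neg] <- -1

  ## stage 2: tissue effects ---------------------------------------------
  substream(cfg$seed, 2)
  TE <- matrix(rnorm(T_ * G, 0, cfg$tissue_signal_sd), T_, G)
  for (t in seq_len(T_)) {
    TE[t, ts_high[[t]]] <- delta
    TE[t, ts_low[[t]]] <- -delta
    # paired +/- purity genes share the small tissue shift so the mass
    # balance above holds within every tissue
    if (half_pur > 0) TE[t, pur_neg] <- TE[t, pur_pos]
  }

  ## stage 3: per-tissue samples -----------------------------------------
  blocks <- vector("list", T_)
  metas <- vector("list", T_)
  for (t in seq_len(T_)) {
    substream(cfg$seed, 10 + t)
    mt <- mu + TE[t, ]
    mu_tc <- mt + direction * contrast
    mu_st <- mt - direction * contrast
    n_nd <- cfg$n_non_diseased; n_tu <- cfg$n_tumor
    n_cl <- cfg$n_cell_line; n_px <- cfg$n_pdx
    lm_nd <- matrix(mt, G, n_nd) +
      matrix(rnorm(G * n_nd, 0, cfg$noise_sd), G, n_nd)
    p <- rbeta(n_tu, cfg$purity_beta[1], cfg$purity_beta[2])
    lm_tu <- log2(outer(2^mu_tc, p) + outer(2^mu_st, 1 - p)) +
      matrix(rnorm(G * n_tu, 0, cfg$noise_sd), G, n_tu)
    lm_cl <- matrix(mu_tc, G, n_cl) +
      matrix(rnorm(G * n_cl, 0, cfg$drift_cell_line), G, n_cl) +
      matrix(rnorm(G * n_cl, 0, cfg$noise_sd), G, n_cl)
    lm_px <- matrix(mu_tc, G, n_px) +
      matrix(rnorm(G * n_px, 0, cfg$drift_pdx), G, n_px) +
      matrix(rnorm(G * n_px, 0, cfg$noise_sd), G, n_px)
    lm <- cbind(lm_nd, lm_tu, lm_cl, lm_px)
    substream(cfg$seed, 100 + t)
    n_all <- ncol(lm)
    libf <- exp(rnorm(n_all, 0, cfg$library_size_sd))
    mean_mat <- sweep(2^lm, 2, libf, "*")
    blocks[[t]] <- matrix(
      rnbinom(length(mean_mat), mu = mean_mat, size = cfg$dispersion),
      G, n_all
    )
    metas[[t]] <- tibble::tibble(
      sample_id = c(
        sprintf("%s_nd_%02d", tissues[t], seq_len(n_nd)),
        sprintf("%s_tum_%02d", tissues[t], seq_len(n_tu)),
        sprintf("%s_cl_%02d", tissues[t], seq_len(n_cl)),
        sprintf("%s_pdx_%02d", tissues[t], seq_len(n_px))
      ),
      source = "synthetic",
      tissue_group = tissues[t],
      disease_state = rep(c("non_diseased", "tumor", "tumor", "tumor"),
                          c(n_nd, n_tu, n_cl, n_px)),
      model_type = rep(c("tissue", "tissue", "cell_line", "pdx"),
                       c(n_nd, n_tu, n_cl, n_px)),
      purity = c(rep(NA_real_, n_nd), p, rep(NA_real_, n_cl + n_px)),
      excluded = FALSE,
      exclusion_reason = NA_character_
    )
  }
  counts <- do.call(cbind, blocks)
  metadata <- dplyr::bind_rows(metas)
  dimnames(counts) <- list(genes, metadata$sample_id)

  role <- rep("background", G)
  role_tissue <- rep(NA_character_, G)
  for (t in seq_len(T_)) {
    role[ts_high[[t]]] <- "tissue_high"
    role[ts_low[[t]]] <- "tissue_low"
    role_tissue[c(ts_high[[t]], ts_low[[t]])] <- tissues[t]
  }
  role[pur_pos] <- role[pur_neg] <- "purity_responsive"
  gene_truth <- tibble::tibble(
    gene_id = genes, role = role, tissue = role_tissue,
    direction = ifelse(direction == 0, NA_real_, direction)
  )
  marker_sets <- purrr::map_dfr(seq_len(T_), function(t) {
    tibble::tibble(
      set = paste0(tissues[t], c("_high", "_low")),
      description = paste0("specific-", c("high", "low"), " genes of ",
                           tissues[t]),
      genes = list(genes[ts_high[[t]]], genes[ts_low[[t]]])
    )
  })
  list(
    counts = expr_matrix(counts, unit = "counts",
                         gene_lengths = setNames(rep(cfg$gene_length, G), genes)),
    metadata = metadata,
    truth = list(genes = gene_truth, marker_sets = marker_sets, config = cfg)
  )
}
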