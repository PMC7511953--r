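#' Generate a synthetic transcriptome with a TOP-like gene class
#'
#' Draws per-gene kinetic parameters for a transcriptome containing a
#' high-initiation-rate, charge-rich ("TOP") class and a background class.
#' The defaults encode the biology the model is built around: TOP transcripts
#' initiate roughly ten-fold faster (short unstructured 5' ends with a
#' terminal pyrimidine tract), encode shorter proteins, and are rich in
#' lysine/arginine, which slows their translocation through the exit-tunnel
#' charge penalty. Each gene's effective elongation rate `ke` is computed
#' from the two-phase dwell at full elongation-factor availability
#' ([effective_elongation_rate()] at `E = 1`), so the transcriptome is
#' immediately usable by the closed-form model and consistent with the
#' depletion scenario.
#'
#' @param n_genes number of genes (>= 2).
#' @param top_fraction fraction of genes in the TOP class, in \[0, 1\].
#' @param seed integer seed (mandatory; generation is fully reproducible).
#' @param ki_meanlog,ki_sdlog named length-2 vectors (`TOP`, `other`) of
#'   log-normal parameters for the initiation constant.
#' @param charge_mean,charge_sd normal parameters (same naming) for the
#'   fraction of positively charged residues; draws are clipped to
#'   `[0.02, 0.45]`.
#' @param n_codon_range named list of length-2 ranges for coding length.
#' @param m_meanlog,m_sdlog log-normal parameters for mRNA abundance.
#' @param L ribosome footprint, codons.
#' @param elongation list with `k_bind`, `k_trans0`, `beta`, `W`: the dwell
#'   model shared by `ke` computation and the depletion scenario.
#' @param with_profiles also draw explicit per-residue 0/1 charge profiles
#'   (Bernoulli at each gene's `charge_frac`) and attach them.
#' @return a [as_transcriptome()] table with extra columns `class` and
#'   `charge_frac`, and attribute `elongation` (the dwell parameters).
#' @export
generate_transcriptome <- function(n_genes = 200, top_fraction = 0.1, seed,
                                   ki_meanlog = c(TOP = log(1), other = log(0.1)),
                                   ki_sdlog = c(TOP = 0.2, other = 0.4),
                                   charge_mean = c(TOP = 0.25, other = 0.10),
                                   charge_sd = c(TOP = 0.05, other = 0.05),
                                   n_codon_range = list(TOP = c(80, 250),
                                                        other = c(150, 600)),
                                   m_meanlog = log(0.012), m_sdlog = 0.6,
                                   L = 10,
                                   elongation = list(k_bind = 20, k_trans0 = 10,
                                                     beta = 0.5, W = 10),
                                   with_profiles = FALSE) {
  if (missing(seed)) stop("seed must be given explicitly")
  stopifnot(n_genes >= 2, top_fraction >= 0, top_fraction <= 1)
  set.seed(seed)
  n_top <- round(n_genes * top_fraction)
  cls <- c(rep("TOP", n_top), rep("other", n_genes - n_top))
  is_top <- cls == "TOP"
  pick <- function(par) ifelse(is_top, par[["TOP"]], par[["other"]])

  ki <- exp(stats::rnorm(n_genes, pick(ki_meanlog), pick(ki_sdlog)))
  charge <- pmin(0.45, pmax(0.02, stats::rnorm(n_genes, pick(charge_mean),
                                               pick(charge_sd))))
  nc <- integer(n_genes)
  nc[is_top] <- as.integer(round(stats::runif(sum(is_top), n_codon_range$TOP[1],
                                              n_codon_range$TOP[2])))
  nc[!is_top] <- as.integer(round(stats::runif(sum(!is_top),
                                               n_codon_range$other[1],
                                               n_codon_range$other[2])))
  m <- stats::rlnorm(n_genes, m_meanlog, m_sdlog)
  ke <- effective_elongation_rate(1, elongation$k_bind, elongation$k_trans0,
                                  elongation$beta,
                                  qbar = elongation$W * charge)
  df <- data.frame(gene_id = sprintf("g%04d", seq_len(n_genes)),
                   ki = ki, ke = ke, m = m, L = as.integer(L),
                   n_codons = nc, class = cls, charge_frac = charge,
                   stringsAsFactors = FALSE)
  profiles <- NULL
  if (with_profiles) {
    profiles <- lapply(seq_len(n_genes), function(g) {
      stats::rbinom(nc[g], 1L, charge[g])
    })
    names(profiles) <- df$gene_id
  }
  tx <- as_transcriptome(df, charge_profiles = profiles)
  attr(tx, "elongation") <- elongation
  tx
}

#' Calibrate a total-ribosome level for a transcriptome
#'
#' Chooses `R_total` so that, at baseline, the median TOP gene sits at the
#' congestion level `u = ke/(ki*R_free) = congestion_u` -- the regime in which
#' high-initiation transcripts are partly elongation-limited, as described
#' for ribosomal-protein mRNAs. The implied free level is capped at
#' `jam_margin` times the jam boundary of the most jam-prone gene, and
#' `R_total` is the free level plus the bound pool it supports.
#'
#' @param transcriptome a [generate_transcriptome()] table (needs `class`).
#' @param congestion_u target `ke/(ki*R)` for the median TOP gene.
#' @param jam_margin safety factor below the jam boundary.
#' @return scalar `R_total`.
#' @export
calibrate_r_total <- function(transcriptome, congestion_u = 1.8,
                              jam_margin = 0.85) {
  tx <- transcriptome
  stopifnot("class" %in% names(tx), congestion_u > 1)
  top <- tx$class == "TOP"
  ref <- if (any(top)) top else rep(TRUE, nrow(tx))
  R0 <- stats::median(tx$ke[ref]) / (stats::median(tx$ki[ref]) * congestion_u)
  R0 <- min(R0, jam_margin * min(tx$ke / tx$ki))
  R0 + total_bound(tx, R0)
}

#' Generate paired mRNA-seq / Ribo-seq count matrices
#'
#' Simulates a paired bulk experiment: `n_reps` control and `n_reps`
#' knockdown samples, each profiled by mRNA-seq and ribosome footprinting.
#' Expected mRNA counts are proportional to mRNA abundance `m_g`; expected
#' footprint counts are proportional to `m_g * load_per_mrna(g)` at the
#' condition's solved ribosome pool -- footprints sample ribosome occupancy,
#' so stalled ribosomes raise footprint signal. Each sample is scaled to a
#' nominal depth with a library-size factor drawn uniformly within
#' `1 +/- lib_size_range` (so the normalisation stage has real work to do),
#' and counts are drawn negative-binomially with per-gene dispersions from a
#' log-normal.
#'
#' The truth table records, per gene, the mechanistic expectations from
#' [simulate_knockdown()]: the relative log2 yield change, the raw and
#' median-centred expected log2 TE change, plus class, `ki` and charge.
#'
#' @param transcriptome a [generate_transcriptome()] table.
#' @param R_total total ribosome level; NULL = [calibrate_r_total()] default.
#' @param depletion_factor residual elongation-factor fraction (default 0.05,
#'   i.e. a 95 percent knockdown).
#' @param scenario_mode `"eEF2"` (charge-aware, default) or `"ke_uniform"`.
#' @param n_reps replicates per condition (>= 2).
#' @param nominal_counts nominal mean counts per gene per sample.
#' @param lib_size_range half-width of the uniform library-size factor.
#' @param dispersion_meanlog,dispersion_sdlog log-normal parameters of the
#'   per-gene NB dispersion.
#' @param seed integer seed (mandatory).
#' @return object of class `omics_experiment`: list with integer matrices
#'   `mrna`, `fp` (genes x samples), `sample_meta`, `truth`, `transcriptome`,
#'   `knockdown` (the `knockdown_result`), `params`.
#' @export
generate_counts <- function(transcriptome, R_total = NULL,
                            depletion_factor = 0.05,
                            scenario_mode = c("eEF2", "ke_uniform"),
                            n_reps = 3, nominal_counts = 2000,
                            lib_size_range = 0.2,
                            dispersion_meanlog = log(0.01),
                            dispersion_sdlog = 0.4, seed) {
  if (missing(seed)) stop("seed must be given explicitly")
  stopifnot(n_reps >= 2)
  scenario_mode <- match.arg(scenario_mode)
  tx <- transcriptome
  elong <- attr(tx, "elongation")
  if (is.null(elong)) elong <- list(k_bind = 20, k_trans0 = 10, beta = 0.5, W = 10)
  if (is.null(R_total)) R_total <- calibrate_r_total(tx)
  scen <- knockdown_scenario(depletion_factor, mode = scenario_mode,
                             k_bind = elong$k_bind, k_trans0 = elong$k_trans0,
                             beta = elong$beta, W = elong$W)
  kd <- simulate_knockdown(tx, R_total, scen)

  n_genes <- nrow(tx)
  lam0 <- kd$baseline$yield$load_per_mrna
  lam1 <- kd$knockdown$yield$load_per_mrna

  set.seed(seed)
  disp <- stats::rlnorm(n_genes, dispersion_meanlog, dispersion_sdlog)
  n_samp <- 2 * n_reps
  cond <- rep(c("control", "knockdown"), each = n_reps)
  sample_id <- sprintf("%s_%d", ifelse(cond == "control", "ctl", "kd"),
                       rep(seq_len(n_reps), 2))
  lib_mrna <- stats::runif(n_samp, 1 - lib_size_range, 1 + lib_size_range)
  lib_fp <- stats::runif(n_samp, 1 - lib_size_range, 1 + lib_size_range)

  rel_mrna <- tx$m / mean(tx$m)                      # same in both conditions
  occ0 <- tx$m * lam0; occ1 <- tx$m * lam1
  rel_fp0 <- occ0 / mean(occ0); rel_fp1 <- occ1 / mean(occ1)

  draw <- function(rel, lib) {
    mu <- rel * nominal_counts * lib
    matrix(stats::rnbinom(n_genes, mu = mu, size = 1 / disp), ncol = 1)
  }
  mrna <- matrix(0L, n_genes, n_samp)
  fp <- matrix(0L, n_genes, n_samp)
  for (s in seq_len(n_samp)) {
    rel_fp <- if (cond[s] == "control") rel_fp0 else rel_fp1
    mrna[, s] <- draw(rel_mrna, lib_mrna[s])
    fp[, s] <- draw(rel_fp, lib_fp[s])
  }
  dimnames(mrna) <- dimnames(fp) <- list(tx$gene_id, sample_id)

  # expected-count TE change: library factors cancel, depth normalisation
  # contributes the constant log2(mean(occ1)/mean(occ0))
  dte_counts <- log2((rel_fp1 / rel_mrna) / (rel_fp0 / rel_mrna))
  truth <- data.frame(
    gene_id = tx$gene_id,
    class = if ("class" %in% names(tx)) tx$class else NA_character_,
    ki = tx$ki,
    charge_frac = if ("charge_frac" %in% names(tx)) tx$charge_frac else NA_real_,
    rel_log2_change = kd$per_gene$rel_log2_change,
    dte_log2 = kd$per_gene$dte_log2,
    dte_log2_counts = dte_counts,
    dte_log2_rel = kd$per_gene$dte_log2_rel,
    stringsAsFactors = FALSE
  )
  sample_meta <- data.frame(sample_id = sample_id, condition = cond,
                            replicate = rep(seq_len(n_reps), 2),
                            lib_mrna = lib_mrna, lib_fp = lib_fp,
                            stringsAsFactors = FALSE)
  structure(list(mrna = mrna, fp = fp, sample_meta = sample_meta,
                 truth = truth, transcriptome = tx, knockdown = kd,
                 params = list(R_total = R_total,
                               depletion_factor = depletion_factor,
                               scenario_mode = scenario_mode,
                               n_reps = n_reps,
                               nominal_counts = nominal_counts,
                               lib_size_range = lib_size_range,
                               dispersion_meanlog = dispersion_meanlog,
                               dispersion_sdlog = dispersion_sdlog,
                               seed = seed)),
            class = "omics_experiment")
}

#' @export
print.omics_experiment <- function(x, ...) {
  cat(sprintf("omics_experiment: %d genes x %d samples (%s), depletion %g, seed %d\n",
              nrow(x$mrna), ncol(x$mrna),
              paste(table(x$sample_meta$condition), collapse = " vs "),
              x$params$depletion_factor, x$params$seed))
  invisible(x)
}
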