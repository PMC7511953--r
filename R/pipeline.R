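pipeline_keys <- c(
  "seed", "out_dir", "n_genes", "top_fraction", "depletion_factor",
  "scenario_mode", "n_reps", "nominal_counts", "lib_size_range",
  "dispersion_meanlog", "dispersion_sdlog", "R_total", "n_perm",
  "enrichment_n_perm", "pseudocount", "min_count", "tasep_check",
  "seed_transcriptome", "seed_counts", "seed_te", "seed_enrichment"
)

#' Validate a pipeline configuration
#'
#' Accepts a named list or a JSON file path. Unknown keys are rejected; a
#' master `seed` is mandatory and stage seeds are derived from it by fixed
#' offsets unless given explicitly, so that one stage's draw count cannot
#' perturb another stage.
#'
#' @param config named list or path to a JSON object.
#' @return validated config list of class `pipeline_config`, with all stage
#'   seeds filled in.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), pipeline_keys)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(config$seed)) stop("configuration is missing required field: seed")
  defaults <- list(
    out_dir = "ribocomp_out", n_genes = 200, top_fraction = 0.1,
    depletion_factor = 0.05, scenario_mode = "eEF2", n_reps = 3,
    nominal_counts = 2000, lib_size_range = 0.2,
    dispersion_meanlog = log(0.01), dispersion_sdlog = 0.4,
    R_total = NULL, n_perm = 1000, enrichment_n_perm = 10000,
    pseudocount = 0.5, min_count = 10, tasep_check = FALSE
  )
  for (k in names(defaults)) {
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  }
  seed <- as.integer(config$seed)
  offs <- c(seed_transcriptome = 101L, seed_counts = 202L,
            seed_te = 303L, seed_enrichment = 404L)
  for (k in names(offs)) {
    if (is.null(config[[k]])) config[[k]] <- (seed + offs[[k]]) %% .Machine$integer.max
  }
  structure(config, class = c("pipeline_config", "list"))
}

#' Run the end-to-end synthetic pipeline
#'
#' Stages: (1) generate the transcriptome; (2) solve the baseline and
#' knockdown ribosome pools and predict polysome profiles; (3) generate
#' paired mRNA-seq/Ribo-seq counts; (4) optionally spot-check the closed-form
#' yields against the stochastic lattice simulator; (5) estimate differential
#' translation efficiency and TOP-class enrichment. All artifacts are written
#' under the output directory together with a `manifest.json` listing every
#' file with its MD5 checksum; the same configuration reproduces every byte.
#'
#' @param config a [pipeline_config()] (or list/path coercible to one).
#' @param out_dir overrides the configured output directory.
#' @return the manifest, invisibly (list with `files`, `config`).
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  cfg <- pipeline_config(config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(name) file.path(cfg$out_dir, name)
  stage <- function(msg) message(sprintf("[ribocomp] %s", msg))

  stage("generate transcriptome")
  tx <- generate_transcriptome(n_genes = cfg$n_genes,
                               top_fraction = cfg$top_fraction,
                               seed = cfg$seed_transcriptome)
  write_transcriptome_tsv(tx, outfile("transcriptome.tsv"))

  stage("solve ribosome pools")
  exp <- generate_counts(tx, R_total = cfg$R_total,
                         depletion_factor = cfg$depletion_factor,
                         scenario_mode = cfg$scenario_mode,
                         n_reps = cfg$n_reps,
                         nominal_counts = cfg$nominal_counts,
                         lib_size_range = cfg$lib_size_range,
                         dispersion_meanlog = cfg$dispersion_meanlog,
                         dispersion_sdlog = cfg$dispersion_sdlog,
                         seed = cfg$seed_counts)
  kd <- exp$knockdown
  pools <- list(
    baseline = kd$baseline$pool[c("R_total", "R_free", "R_bound", "E")],
    knockdown = kd$knockdown$pool[c("R_total", "R_free", "R_bound", "E")]
  )
  jsonlite::write_json(pools, outfile("pool_state.json"),
                       auto_unbox = TRUE, digits = NA)
  prof <- rbind(
    data.frame(condition = "baseline", as.data.frame(unclass(kd$baseline$profile))),
    data.frame(condition = "knockdown", as.data.frame(unclass(kd$knockdown$profile)))
  )
  utils::write.table(prof, outfile("polysome_profile.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(kd$per_gene, outfile("per_gene_change.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  stage("write count matrices")
  write_counts_tsv(exp$mrna, outfile("mrna_counts.tsv"))
  write_counts_tsv(exp$fp, outfile("fp_counts.tsv"))
  utils::write.table(exp$sample_meta, outfile("samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(exp$truth, outfile("truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  if (isTRUE(cfg$tasep_check)) {
    stage("stochastic spot-check of closed-form yields")
    chk <- tasep_spot_check(tx, kd, seed = cfg$seed_counts + 1L)
    jsonlite::write_json(chk, outfile("tasep_check.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  stage("differential translation efficiency")
  res <- differential_te(exp, n_perm = cfg$n_perm, seed = cfg$seed_te,
                         pseudocount = cfg$pseudocount,
                         min_count = cfg$min_count)
  utils::write.table(as.data.frame(res), outfile("te_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  enr <- class_enrichment(res, n_perm = cfg$enrichment_n_perm,
                          seed = cfg$seed_enrichment)
  jsonlite::write_json(unclass(enr), outfile("enrichment.json"),
                       auto_unbox = TRUE, digits = NA)

  stage("manifest")
  files <- setdiff(list.files(cfg$out_dir), "manifest.json")
  manifest <- list(
    files = lapply(stats::setNames(files, files), function(f) {
      list(md5 = unname(tools::md5sum(outfile(f))))
    }),
    config = unclass(cfg)
  )
  jsonlite::write_json(manifest, outfile("manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

# compare closed-form per-copy yield with the lattice simulator for a few
# weakly-loaded genes (where the closed form is expected to be accurate)
tasep_spot_check <- function(tx, kd, seed, n_genes = 2,
                             t_burnin = 200, t_measure = 1500) {
  elong <- attr(tx, "elongation")
  pool <- kd$baseline$pool
  y <- kd$baseline$yield
  x <- tx$ki * pool$R_free / kd$per_gene$ke_baseline
  cand <- order(x)[seq_len(min(n_genes, nrow(tx)))]
  out <- lapply(cand, function(g) {
    cfg <- lattice_config(n_codons = tx$n_codons[g], L = tx$L[g],
                          alpha = tx$ki[g] * pool$R_free,
                          k_bind = elong$k_bind, E = 1,
                          k_trans0 = elong$k_trans0, beta = elong$beta,
                          W = elong$W)
    set.seed(seed + g)
    prof <- stats::rbinom(tx$n_codons[g], 1L, tx$charge_frac[g])
    s <- simulate_transcript(NULL, cfg, t_burnin = t_burnin,
                             t_measure = t_measure, seed = seed + 1000L + g,
                             charge_profile = prof)
    list(gene_id = tx$gene_id[g], closed_form = y$Q[g] / tx$m[g],
         simulated = s$production_rate, se = s$production_se)
  })
  names(out) <- tx$gene_id[cand]
  out
}
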