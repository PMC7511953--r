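#' Configuration for the stochastic elongation simulator
#'
#' Parameters of the exclusion-process lattice model. Initiation attempts
#' occur at rate `alpha = ki * R_free` and succeed when codons `1..L` are
#' vacant. Each codon advance is two sequential exponential stages:
#' elongation-factor recruitment at rate `k_bind * E`, then translocation at
#' rate `k_trans0 * exp(-beta * q)` with `q` the number of positively charged
#' residues among the `W` residues of nascent chain preceding the codon.
#' The defaults `beta = 0.15`, `W = 10` are deliberately conservative; the
#' synthetic-data generator uses its own, stronger charge model (see the
#' vignette).
#'
#' @param n_codons lattice length, codons.
#' @param L footprint, codons.
#' @param alpha initiation attempt rate.
#' @param k_bind elongation-factor recruitment rate constant.
#' @param E elongation-factor availability fraction in (0, 1].
#' @param k_trans0 baseline translocation rate.
#' @param beta charge penalty per positive residue.
#' @param W exit-tunnel window, residues.
#' @return object of class `lattice_config`.
#' @export
lattice_config <- function(n_codons, L = 10, alpha = 0.1, k_bind = 20,
                           E = 1, k_trans0 = 10, beta = 0.15, W = 10) {
  stopifnot(n_codons >= L, L >= 1, alpha >= 0, k_bind > 0,
            E > 0, E <= 1, k_trans0 > 0, beta >= 0, W >= 1, W <= n_codons)
  structure(list(n_codons = as.integer(n_codons), L = as.integer(L),
                 alpha = alpha, k_bind = k_bind, E = E,
                 k_trans0 = k_trans0, beta = beta, W = as.integer(W)),
            class = "lattice_config")
}

#' Two-stage hop rates at a codon position
#'
#' Returns the pair of rates governing the dwell at `position` (1-based):
#' `k_wait = k_bind * E` (sequence independent) and
#' `k_trans = k_trans0 * exp(-beta * q)` where `q` counts positive residues
#' among the `W` residues preceding the position (fewer when the position is
#' within the first `W` codons).
#'
#' @param position 1-based codon index.
#' @param charge_profile 0/1 vector of length `n_codons` (NULL = uncharged).
#' @param config a [lattice_config()].
#' @return list with `k_wait`, `k_trans`, `q`.
#' @export
codon_hop_rate <- function(position, charge_profile, config) {
  stopifnot(position >= 1, position <= config$n_codons)
  if (is.null(charge_profile)) {
    q <- 0L
  } else {
    q <- window_charge_counts(charge_profile, config$W)[position]
  }
  list(k_wait = config$k_bind * config$E,
       k_trans = config$k_trans0 * exp(-config$beta * q),
       q = q)
}

# per-position translocation rates for a whole lattice
translocation_rates <- function(charge_profile, config) {
  if (is.null(charge_profile)) {
    rep(config$k_trans0, config$n_codons)
  } else {
    stopifnot(length(charge_profile) == config$n_codons)
    q <- window_charge_counts(charge_profile, config$W)
    config$k_trans0 * exp(-config$beta * q)
  }
}

#' Simulate elongation on one transcript
#'
#' Continuous-time Markov (Gillespie direct method) simulation of ribosome
#' traffic with steric exclusion. Statistics are collected after `t_burnin`
#' over a window of `t_measure` time units; ribosome counts on the lattice are
#' sampled every `sample_dt`. Fully reproducible given `seed`. The standard
#' error of the production rate comes from splitting the measurement window
#' into `n_blocks` blocks, which absorbs the temporal correlation of the
#' completion stream.
#'
#' @param t single-row transcriptome table (used for `n_codons`, `L`, and its
#'   charge profile if attached), or NULL to take everything from `config`.
#' @param config a [lattice_config()].
#' @param t_burnin,t_measure burn-in and measurement durations (> 0).
#' @param seed integer seed.
#' @param charge_profile optional 0/1 vector overriding the transcriptome's.
#' @param sample_dt interval between lattice-load samples.
#' @param n_blocks blocks for the production-rate standard error.
#' @param check_exclusion assert the non-overlap invariant after every event.
#' @return object of class `tasep_summary`: list with `production_rate`,
#'   `production_se`, `n_completed`, `n_initiated`, `density` (per codon, the
#'   fraction of snapshots with a ribosome positioned there; `sum(density)`
#'   equals `mean_load` exactly), `load_samples`, `mean_load`,
#'   `flux_imbalance`, `seed`, `t_burnin`, `t_measure`, `config`.
#' @export
simulate_transcript <- function(t = NULL, config, t_burnin = 200,
                                t_measure = 1000, seed,
                                charge_profile = NULL, sample_dt = 1,
                                n_blocks = 20, check_exclusion = FALSE) {
  stopifnot(t_measure > 0, t_burnin >= 0)
  if (missing(seed)) stop("seed must be given explicitly")
  if (!is.null(t)) {
    stopifnot(nrow(t) == 1)
    config$n_codons <- as.integer(t$n_codons)
    config$L <- as.integer(t$L)
    if (is.null(charge_profile)) {
      profs <- attr(t, "charge_profiles")
      if (!is.null(profs) && t$gene_id %in% names(profs)) {
        charge_profile <- profs[[t$gene_id]]
      }
    }
  }
  k_trans <- translocation_rates(charge_profile, config)
  k_wait <- config$k_bind * config$E
  if (config$alpha == 0 && k_wait == 0) stop("no dynamics: all rates zero")
  set.seed(seed)
  res <- tasep_run(config$n_codons, config$L, config$alpha, k_wait, k_trans,
                   t_burnin, t_measure, sample_dt, check_exclusion)
  rate <- res$n_completed / t_measure
  # block standard error
  if (res$n_completed > 0 && n_blocks > 1) {
    blocks <- findInterval(res$completion_times,
                           seq(0, t_measure, length.out = n_blocks + 1),
                           rightmost.closed = TRUE)
    counts <- tabulate(blocks, nbins = n_blocks)
    block_rates <- counts / (t_measure / n_blocks)
    se <- stats::sd(block_rates) / sqrt(n_blocks)
  } else {
    se <- NA_real_
  }
  structure(list(
    production_rate = rate,
    production_se = se,
    n_completed = res$n_completed,
    n_initiated = res$n_initiated,
    density = res$density,
    load_samples = res$load_samples,
    mean_load = if (length(res$load_samples)) mean(res$load_samples) else NA_real_,
    flux_imbalance = res$n_initiated - res$n_completed -
      (res$lattice_at_end - res$lattice_at_burnin),
    seed = seed, t_burnin = t_burnin, t_measure = t_measure,
    config = config
  ), class = "tasep_summary")
}

#' @export
print.tasep_summary <- function(x, ...) {
  cat(sprintf("tasep_summary: rate %.4g +/- %.2g (n_completed %d, mean load %.3g, seed %d)\n",
              x$production_rate, x$production_se, x$n_completed, x$mean_load, x$seed))
  invisible(x)
}

#' Charge-penalty curve across elongation-factor availability
#'
#' Ratio of production rates, uncharged over charged transcript, at each
#' availability level: `P(E) = rate_uncharged(E) / rate_charged(E)`. The two
#' transcripts must be identical except for the charge profile. As `E`
#' decreases, the factor-recruitment wait dominates both dwells equally and
#' `P(E)` relaxes towards 1: depletion relieves the charge penalty.
#'
#' @param t_uncharged,t_charged single-row transcriptome tables.
#' @param config a [lattice_config()] (its `E` is overridden).
#' @param E_levels availability levels to evaluate.
#' @param seed integer seed (one stream per run, derived deterministically).
#' @param charge_profile_charged explicit profile for the charged transcript
#'   (otherwise taken from its transcriptome attribute).
#' @param ... further arguments to [simulate_transcript()].
#' @return data.frame with columns `E`, `P`, `P_se`, `rate_uncharged`,
#'   `rate_charged`.
#' @export
charge_penalty <- function(t_uncharged, t_charged, config, E_levels, seed,
                           charge_profile_charged = NULL, ...) {
  stopifnot(t_uncharged$n_codons == t_charged$n_codons,
            t_uncharged$L == t_charged$L)
  rows <- lapply(seq_along(E_levels), function(i) {
    cfg <- config
    cfg$E <- E_levels[i]
    su <- simulate_transcript(t_uncharged, cfg, seed = seed + 2L * i,
                              charge_profile = rep(0L, t_uncharged$n_codons), ...)
    sc <- simulate_transcript(t_charged, cfg, seed = seed + 2L * i + 1L,
                              charge_profile = charge_profile_charged, ...)
    if (sc$production_rate == 0) stop("charged transcript produced nothing; ",
                                      "increase t_measure")
    P <- su$production_rate / sc$production_rate
    # delta-method Monte Carlo error on the ratio
    P_se <- P * sqrt((su$production_se / su$production_rate)^2 +
                     (sc$production_se / sc$production_rate)^2)
    data.frame(E = E_levels[i], P = P, P_se = P_se,
               rate_uncharged = su$production_rate,
               rate_charged = sc$production_rate)
  })
  do.call(rbind, rows)
}

#' Analytic charge-penalty limit from expected transit times
#'
#' In the elongation-limited regime the production-rate ratio of an uncharged
#' over a charged transcript is approximated by the inverse ratio of expected
#' transit times, \eqn{P(E) \approx T_c(E) / T_u(E)} with
#' `T = sum_i [1/(k_bind E) + 1/k_trans(i)]`. The limit `E -> 0+` is exactly 1:
#' the recruitment wait dominates both transcripts equally.
#'
#' @param charge_profile 0/1 vector for the charged transcript.
#' @param config a [lattice_config()].
#' @param E availability level(s).
#' @return numeric vector of analytic penalty values, >= 1.
#' @export
charge_penalty_analytic <- function(charge_profile, config, E) {
  ktr <- translocation_rates(charge_profile, config)
  vapply(E, function(e) {
    wait <- 1 / (config$k_bind * e)
    Tc <- sum(wait + 1 / ktr)
    Tu <- config$n_codons * (wait + 1 / config$k_trans0)
    Tc / Tu
  }, numeric(1))
}

#' Empirical ribosomes-per-mRNA distribution
#'
#' Normalised histogram of the lattice-load samples of a converged run, over
#' `j = 0 .. floor(n_codons/L)`; comparable to the truncated-Poisson law
#' assumed by [polysome_fractions()].
#'
#' @param summary a `tasep_summary`.
#' @return named numeric vector of probabilities summing to 1.
#' @export
empirical_load_distribution <- function(summary) {
  stopifnot(inherits(summary, "tasep_summary"))
  cap <- floor(summary$config$n_codons / summary$config$L)
  h <- tabulate(summary$load_samples + 1L, nbins = cap + 1L)
  h <- h / sum(h)
  names(h) <- 0:cap
  h
}
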