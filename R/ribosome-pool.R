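#' Total ribosomes bound on mRNA at a given free-ribosome level
#'
#' Sum over genes of `m_g * load_per_mrna(g, R_free)`. By construction the
#' bound level is 0 at `R_free = 0` (no initiation) and, as long as every gene
#' sits on the initiation-limited side of its load peak (`u = ke/(ki*R)` above
#' `u*(L)`, the root of `1/(u-1) + (L-1)/(u+L-1) = 1`), it increases
#' monotonically in `R_free`.
#'
#' @param transcriptome a [as_transcriptome()] table.
#' @param R_free free-ribosome level, >= 0.
#' @return scalar bound-ribosome level.
#' @export
total_bound <- function(transcriptome, R_free) {
  stopifnot(length(R_free) == 1, R_free >= 0)
  if (nrow(transcriptome) == 0 || R_free == 0) return(0)
  y <- protein_yield(transcriptome, R_free)
  sum(transcriptome$m * y$load_per_mrna)
}

#' Solve for the free-ribosome pool under total-ribosome conservation
#'
#' Finds `R_free` such that `R_free + total_bound(R_free) = R_total`.
#' Root finding uses Brent's method ([stats::uniroot()]) on the bracket
#' `[1e-12 * R_total, min(R_total, (1 - 1e-9) * min(ke/ki))]`; the upper end
#' is capped below the jamming boundary of the most jam-prone ("binding")
#' gene. If conservation cannot be satisfied inside the valid domain -- the
#' bracket's upper end still leaves ribosomes unaccounted for -- a jamming
#' error names that gene: the model's validity limit has been reached.
#'
#' @param transcriptome a [as_transcriptome()] table.
#' @param R_total total ribosome level, > 0.
#' @param rel_tol relative tolerance on the conservation residual.
#' @param E elongation-factor availability fraction recorded in the returned
#'   state (bookkeeping only; apply scenarios with [simulate_knockdown()]).
#' @return object of class `pool_state`: list with `R_total`, `R_free`,
#'   `R_bound`, `E`, `residual`.
#' @export
solve_free_ribosomes <- function(transcriptome, R_total, rel_tol = 1e-10, E = 1) {
  stopifnot(length(R_total) == 1, R_total > 0)
  tx <- transcriptome
  mk <- function(R_free) {
    structure(list(R_total = R_total, R_free = R_free,
                   R_bound = R_total - R_free, E = E,
                   residual = (R_free + total_bound(tx, R_free) - R_total) / R_total),
              class = "pool_state")
  }
  if (nrow(tx) == 0 || all(tx$m == 0)) return(mk(R_total))
  jam_R <- tx$ke / tx$ki
  upper <- min(R_total, (1 - 1e-9) * min(jam_R))
  h <- function(R) R + total_bound(tx, R) - R_total
  if (h(upper) < 0) {
    binding <- tx$gene_id[which.min(jam_R)]
    stop("solve_free_ribosomes: conservation cannot be met inside the valid ",
         "domain; gene ", binding, " jams first (ke/ki = ",
         signif(min(jam_R), 6), " < required free level)")
  }
  lower <- 1e-12 * R_total
  if (h(lower) > 0) return(mk(lower))  # degenerate: essentially no binding capacity
  root <- stats::uniroot(h, c(lower, upper), tol = rel_tol * R_total)$root
  st <- mk(root)
  if (abs(st$residual) > max(rel_tol, 1e-8)) {
    # polish by a few bisection steps if uniroot's tol was not tight enough
    lo <- lower; hi <- upper
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (h(mid) > 0) hi <- mid else lo <- mid
      if ((hi - lo) / R_total < 1e-14) break
    }
    st <- mk((lo + hi) / 2)
  }
  st
}

#' @export
print.pool_state <- function(x, ...) {
  cat(sprintf("pool_state: R_total = %g, R_free = %g (%.3g%%), E = %g, residual = %.2e\n",
              x$R_total, x$R_free, 100 * x$R_free / x$R_total, x$E, x$residual))
  invisible(x)
}

#' Predicted polysome-profile class fractions
#'
#' Distributes ribosome signal over the sucrose-gradient classes: free
#' subunits (`j = 0` on mRNA), monosomes (`j = 1`), light polysomes
#' (`j` in 2..4) and heavy polysomes (`j > 4` ribosomes per mRNA). Per gene,
#' ribosomes-per-mRNA-copy follows a Poisson law with mean `load_per_mrna`,
#' truncated at the steric capacity `floor(n_codons/L)`; an mRNA carrying `j`
#' ribosomes contributes `j` ribosome units of signal. `free_frac` is
#' `R_free/R_total`, and the three bound classes are scaled to account for
#' exactly the bound pool `1 - free_frac` (the truncated-Poisson mean differs
#' from `load_per_mrna` by the truncation mass, which the scaling absorbs).
#'
#' @param transcriptome a [as_transcriptome()] table.
#' @param pool a `pool_state` from [solve_free_ribosomes()].
#' @return object of class `polysome_profile`: list with `free_frac`,
#'   `mono_frac`, `light_frac`, `heavy_frac`, `mono_to_poly` and the flag
#'   `poly_empty` (TRUE when the polysome classes carry no signal, in which
#'   case `mono_to_poly` is `Inf`).
#' @export
polysome_fractions <- function(transcriptome, pool) {
  tx <- transcriptome
  stopifnot(inherits(pool, "pool_state"))
  mono <- light <- heavy <- 0
  if (nrow(tx) > 0 && any(tx$m > 0)) {
    y <- protein_yield(tx, pool$R_free)
    for (g in seq_len(nrow(tx))) {
      if (tx$m[g] == 0) next
      cap <- floor(tx$n_codons[g] / tx$L[g])
      j <- 0:cap
      pj <- stats::dpois(j, y$load_per_mrna[g])
      pj <- pj / sum(pj)
      sig <- j * pj * tx$m[g]
      mono <- mono + sig[2]
      light <- light + sum(sig[j >= 2 & j <= 4])
      heavy <- heavy + sum(sig[j > 4])
    }
  }
  free_frac <- pool$R_free / pool$R_total
  tot <- mono + light + heavy
  if (tot > 0) {
    sc <- (1 - free_frac) / tot
    mono <- mono * sc; light <- light * sc; heavy <- heavy * sc
  } else {
    free_frac <- 1; mono <- light <- heavy <- 0
  }
  poly <- light + heavy
  structure(list(free_frac = free_frac, mono_frac = mono,
                 light_frac = light, heavy_frac = heavy,
                 mono_to_poly = if (poly > 0) mono / poly else Inf,
                 poly_empty = poly == 0),
            class = "polysome_profile")
}

#' @export
print.polysome_profile <- function(x, ...) {
  cat(sprintf("polysome_profile: free %.3f | mono %.3f | light %.3f | heavy %.3f | mono/poly %s\n",
              x$free_frac, x$mono_frac, x$light_frac, x$heavy_frac,
              if (is.finite(x$mono_to_poly)) sprintf("%.3g", x$mono_to_poly) else "Inf"))
  invisible(x)
}

#' Two-phase elongation dwell and effective elongation rate
#'
#' Per codon, elongation is modelled as two sequential exponential stages:
#' recruitment of the elongation factor (rate `k_bind * E`, sequence
#' independent) followed by translocation (rate `k_trans0 * exp(-beta * q)`,
#' where `q` counts positively charged residues among the `W` residues of
#' nascent chain preceding the codon). The effective single-rate elongation
#' constant is the harmonic combination over the mean per-codon dwell:
#' \deqn{k_e(E) = \left[\frac{1}{k_\mathrm{bind} E} +
#'   \overline{e^{\beta q}}/k_\mathrm{trans0}\right]^{-1}}
#' As `E` falls, the recruitment wait grows identically for all transcripts
#' while the translocation term is unchanged, so the relative penalty of
#' charged sequences shrinks -- the charge-relief mechanism.
#'
#' `qbar` may be given directly (mean charges per window, e.g.
#' `W * charge_frac`) or computed from a 0/1 `charge_profile`, in which case
#' the mean of `exp(beta*q)` over codon positions is used.
#'
#' @param E elongation-factor availability fraction in (0, 1].
#' @param k_bind recruitment rate constant at full availability.
#' @param k_trans0 baseline translocation rate.
#' @param beta charge penalty per positive residue (log scale).
#' @param qbar mean positive charges per exit-tunnel window, or NULL.
#' @param charge_profile optional 0/1 vector; overrides `qbar`.
#' @param W exit-tunnel window, residues.
#' @return effective elongation rate (codons per time unit).
#' @export
effective_elongation_rate <- function(E, k_bind, k_trans0, beta,
                                      qbar = NULL, charge_profile = NULL, W = 10) {
  stopifnot(all(E > 0), all(E <= 1), k_bind > 0, k_trans0 > 0, beta >= 0)
  if (!is.null(charge_profile)) {
    q <- window_charge_counts(charge_profile, W)
    trans_term <- mean(exp(beta * q)) / k_trans0
  } else {
    if (is.null(qbar)) stop("supply qbar or charge_profile")
    trans_term <- exp(beta * qbar) / k_trans0
  }
  1 / (1 / (k_bind * E) + trans_term)
}

#' Trailing-window charge counts along a coding sequence
#'
#' For each codon position `i` (1-based), counts the positive charges among
#' the `W` residues preceding `i` (positions `max(1, i-W) .. i-1`); the first
#' codon always sees 0.
#'
#' @param charge_profile 0/1 integer vector.
#' @param W window size, residues.
#' @return integer vector of the same length.
#' @export
window_charge_counts <- function(charge_profile, W) {
  n <- length(charge_profile)
  cs0 <- c(0L, cumsum(charge_profile))   # cs0[k+1] = charges in 1..k
  i <- seq_len(n)
  lo <- pmax(i - W, 1L)
  # charges in [lo, i-1] = cs0[i] - cs0[lo]
  as.integer(cs0[i] - cs0[lo])
}

#' Describe an elongation-factor knockdown scenario
#'
#' Two modes:
#' * `"eEF2"` (default): the depletion factor is the residual availability
#'   `E = f` of the elongation factor; each gene's effective elongation rate is
#'   recomputed from the two-phase dwell ([effective_elongation_rate()]) using
#'   its charge content, at `E = 1` for baseline and `E = f` for knockdown.
#'   Charge-rich transcripts are relieved of their translocation penalty
#'   relative to others as recruitment dominates the dwell.
#' * `"ke_uniform"`: the knockdown scales every gene's `ke` by `f` directly
#'   (`ke' = f * ke`). Under whole-pool conservation this mode nearly cancels:
#'   the solved free pool drops almost exactly in proportion, so relative
#'   yields barely move (see the package vignette).
#'
#' @param depletion_factor residual fraction `f` in (0, 1].
#' @param mode `"eEF2"` or `"ke_uniform"`.
#' @param k_bind,k_trans0,beta,W two-phase dwell parameters (eEF2 mode).
#' @return object of class `knockdown_scenario`.
#' @export
knockdown_scenario <- function(depletion_factor, mode = c("eEF2", "ke_uniform"),
                               k_bind = 20, k_trans0 = 10, beta = 0.5, W = 10) {
  stopifnot(length(depletion_factor) == 1,
            depletion_factor > 0, depletion_factor <= 1)
  mode <- match.arg(mode)
  structure(list(depletion_factor = depletion_factor, mode = mode,
                 k_bind = k_bind, k_trans0 = k_trans0, beta = beta, W = W),
            class = "knockdown_scenario")
}

# per-gene effective ke under a scenario at availability E
scenario_ke <- function(transcriptome, scenario, E) {
  tx <- transcriptome
  if (scenario$mode == "ke_uniform") {
    return(tx$ke * E)
  }
  profiles <- attr(tx, "charge_profiles")
  qsrc <- if (!is.null(profiles)) "profile" else "frac"
  if (qsrc == "frac" && !("charge_frac" %in% names(tx))) {
    stop("eEF2 scenario needs charge information: a charge_frac column or ",
         "charge_profiles attribute on the transcriptome")
  }
  vapply(seq_len(nrow(tx)), function(g) {
    if (qsrc == "profile" && tx$gene_id[g] %in% names(profiles)) {
      effective_elongation_rate(E, scenario$k_bind, scenario$k_trans0,
                                scenario$beta,
                                charge_profile = profiles[[tx$gene_id[g]]],
                                W = scenario$W)
    } else {
      effective_elongation_rate(E, scenario$k_bind, scenario$k_trans0,
                                scenario$beta,
                                qbar = scenario$W * tx$charge_frac[g])
    }
  }, numeric(1))
}

#' Run a paired baseline / knockdown scenario
#'
#' Solves the free-ribosome pool for the baseline transcriptome and again
#' after elongation-factor depletion, and reports the per-gene consequences.
#' Because total synthesis drops globally under depletion, per-gene effects
#' are *relative*: `rel_log2_change = log2((Q'_g/sum Q') / (Q_g/sum Q))`.
#' The table also carries the expected translation-efficiency change
#' `dte_log2 = log2(load'_g / load_g)`, which is what a paired
#' Ribo-seq/mRNA-seq experiment measures (footprints sample ribosome
#' occupancy, including stalled ribosomes), and its median-centred version
#' `dte_log2_rel` comparable to library-normalised estimates.
#'
#' In `"eEF2"` mode the baseline elongation rates are also recomputed from the
#' dwell model at `E = 1` so that baseline and knockdown live on the same
#' mechanistic footing; the transcriptome's `ke` column is ignored.
#'
#' @param transcriptome a [as_transcriptome()] table.
#' @param R_total total ribosome level for both conditions.
#' @param scenario a [knockdown_scenario()].
#' @return object of class `knockdown_result`: list with `baseline` and
#'   `knockdown` (each `pool`, `profile`, `yield`), `per_gene` table, and the
#'   scenario.
#' @export
simulate_knockdown <- function(transcriptome, R_total, scenario) {
  tx <- transcriptome
  stopifnot(inherits(scenario, "knockdown_scenario"))
  f <- scenario$depletion_factor

  tx0 <- tx
  tx0$ke <- scenario_ke(tx, scenario, E = 1)
  tx1 <- tx
  tx1$ke <- scenario_ke(tx, scenario, E = f)

  run_one <- function(txc, E) {
    pool <- solve_free_ribosomes(txc, R_total, E = E)
    list(pool = pool,
         profile = polysome_fractions(txc, pool),
         yield = protein_yield(txc, pool$R_free))
  }
  base <- run_one(tx0, 1)
  kd <- tryCatch(run_one(tx1, f), error = function(e) {
    stop("knockdown scenario not solvable: ", conditionMessage(e), call. = FALSE)
  })

  share <- function(y, m) {
    tot <- sum(y$Q)
    if (tot == 0) rep(NA_real_, nrow(y)) else y$Q / tot
  }
  s0 <- share(base$yield); s1 <- share(kd$yield)
  dte <- log2(kd$yield$load_per_mrna / base$yield$load_per_mrna)
  per_gene <- data.frame(
    gene_id = tx$gene_id,
    ki = tx$ki,
    ke_baseline = tx0$ke,
    ke_knockdown = tx1$ke,
    Q_baseline = base$yield$Q,
    Q_knockdown = kd$yield$Q,
    rel_log2_change = log2(s1 / s0),
    dte_log2 = dte,
    dte_log2_rel = dte - stats::median(dte),
    stringsAsFactors = FALSE
  )
  if ("class" %in% names(tx)) per_gene$class <- tx$class
  structure(list(baseline = base, knockdown = kd,
                 per_gene = per_gene, scenario = scenario),
            class = "knockdown_result")
}

#' @export
print.knockdown_result <- function(x, ...) {
  cat(sprintf("knockdown_result (mode %s, f = %g)\n",
              x$scenario$mode, x$scenario$depletion_factor))
  cat("  baseline : "); print(x$baseline$pool)
  cat("  knockdown: "); print(x$knockdown$pool)
  if ("class" %in% names(x$per_gene)) {
    med <- tapply(x$per_gene$rel_log2_change, x$per_gene$class, stats::median)
    cat("  median relative log2 yield change by class:\n")
    for (cl in names(med)) cat(sprintf("    %-6s %+0.3f\n", cl, med[[cl]]))
  }
  invisible(x)
}
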