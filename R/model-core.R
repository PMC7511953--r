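#' Probability that the initiation codon is clear
#'
#' Steady-state probability that the start codon of a transcript is not
#' covered by an elongating ribosome and is available for initiation:
#' \deqn{p = 1 - \frac{L}{k_e/(k_i R) + L - 1}}
#' where `R` is the free-ribosome level, `ki` and `ke` the initiation and
#' elongation rate constants and `L` the ribosome footprint in codons.
#'
#' The expression is valid on the non-jammed domain `ke/(ki*R) >= 1`; at the
#' jamming boundary `ke/(ki*R) == 1` the probability is exactly 0. Inputs
#' inside the jammed regime (`ke/(ki*R) < 1`) raise an error rather than being
#' clamped, so that solver misuse upstream cannot pass silently.
#'
#' @param ki initiation rate constant(s), > 0.
#' @param ke elongation rate(s), codons per time unit, > 0.
#' @param R free-ribosome level, scalar > 0.
#' @param L footprint size(s) in codons, integer >= 1.
#' @param gene_id optional identifiers used in error messages.
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
start_clearance_probability <- function(ki, ke, R, L, gene_id = NULL) {
  if (length(R) != 1 || !is.finite(R) || R <= 0) {
    stop("R must be a single positive free-ribosome level")
  }
  stopifnot(all(ki > 0), all(ke > 0), all(L >= 1))
  u <- ke / (ki * R)
  bad <- u < 1
  if (any(bad)) {
    who <- if (!is.null(gene_id)) paste0(" (gene ", paste(gene_id[bad], collapse = ", "), ")") else ""
    stop("jammed regime: ke/(ki*R) < 1", who,
         "; the closed-form model is not valid there")
  }
  p <- 1 - L / (u + L - 1)
  # u == 1 gives exactly 0; guard rounding at the boundary
  pmin(pmax(p, 0), 1)
}

#' Steady-state protein yield of competing transcripts
#'
#' Closed-form protein production rate per transcript species under
#' competition for free ribosomes:
#' \deqn{Q = m R k_i \left[1 - \frac{L}{k_e/(k_i R) + L - 1}\right]}
#' together with the expected number of elongating ribosomes per mRNA copy,
#' obtained by Little's law from the per-copy initiation flux `J = Q/m` and
#' the mean transit time `n_codons/ke`:
#' `load_per_mrna = (Q/m) * n_codons / ke`.
#'
#' @param transcriptome a [as_transcriptome()] table (or any data.frame with
#'   the mandatory columns).
#' @param R free-ribosome level, scalar > 0.
#' @return data.frame with columns `gene_id`, `Q` (proteins per time unit),
#'   `p_clear`, `load_per_mrna`.
#' @examples
#' tx <- as_transcriptome(data.frame(
#'   gene_id = "g1", ki = 0.1, ke = 10, m = 1, L = 10, n_codons = 300))
#' protein_yield(tx, R = 1)  # Q = 99/1090, load ~ 2.72
#' @export
protein_yield <- function(transcriptome, R) {
  t <- transcriptome
  p <- start_clearance_probability(t$ki, t$ke, R, t$L, t$gene_id)
  Q <- t$m * R * t$ki * p
  load <- R * t$ki * p * t$n_codons / t$ke   # (Q/m) * n/ke, defined also at m = 0
  data.frame(gene_id = t$gene_id, Q = Q, p_clear = p,
             load_per_mrna = load, stringsAsFactors = FALSE)
}

#' Ratio of protein yields of two transcripts
#'
#' `Q1/Q2` at a common free-ribosome level. With equal mRNA levels the ratio
#' reduces to `(ki1 * p1) / (ki2 * p2)`; as `R -> 0` it tends to `ki1/ki2`,
#' and for `ki1 > ki2` (equal `ke`, `m`, `L`) it decreases monotonically in
#' `R`: the advantage of a high-initiation transcript is largest when free
#' ribosomes are scarce.
#'
#' @param t1,t2 single-row transcriptome tables (or single-row data.frames).
#' @param R free-ribosome level.
#' @return scalar ratio `Q1/Q2`.
#' @export
yield_ratio <- function(t1, t2, R) {
  stopifnot(nrow(t1) == 1, nrow(t2) == 1)
  y1 <- protein_yield(t1, R)
  y2 <- protein_yield(t2, R)
  if (y2$Q == 0) stop("yield_ratio: Q2 is zero (division by zero)")
  y1$Q / y2$Q
}

#' Protein yield along a grid of free-ribosome levels
#'
#' Element-wise [protein_yield()] for a single transcript over a grid of `R`
#' values. On any grid inside the valid domain the yield is unimodal in `R`:
#' it grows linearly while initiation is limiting and collapses to 0 at the
#' jamming boundary `R = ke/ki`.
#'
#' @param t single-row transcriptome table.
#' @param R_grid numeric vector of free-ribosome levels (may be empty).
#' @return data.frame with columns `R`, `Q`, `p_clear`, `load_per_mrna`.
#' @export
yield_curve <- function(t, R_grid) {
  stopifnot(nrow(t) == 1)
  if (length(R_grid) == 0) {
    return(data.frame(R = numeric(0), Q = numeric(0),
                      p_clear = numeric(0), load_per_mrna = numeric(0)))
  }
  rows <- lapply(seq_along(R_grid), function(i) {
    y <- tryCatch(protein_yield(t, R_grid[i]), error = function(e) {
      stop("yield_curve: invalid domain at grid index ", i, ": ",
           conditionMessage(e), call. = FALSE)
    })
    data.frame(R = R_grid[i], Q = y$Q, p_clear = y$p_clear,
               load_per_mrna = y$load_per_mrna)
  })
  do.call(rbind, rows)
}
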