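# small builders shared across test files

tx_single <- function(ki = 0.1, ke = 10, m = 1, L = 10, n_codons = 300,
                      gene_id = "g1", ...) {
  as_transcriptome(data.frame(gene_id = gene_id, ki = ki, ke = ke, m = m,
                              L = L, n_codons = n_codons, ...,
                              stringsAsFactors = FALSE))
}

tx_pair <- function(ki = c(1, 0.1), ke = 10, m = 1, L = 10, n_codons = 300,
                    ...) {
  as_transcriptome(data.frame(gene_id = c("hi", "lo"), ki = ki, ke = ke,
                              m = m, L = L, n_codons = n_codons, ...,
                              stringsAsFactors = FALSE))
}

# random valid-domain parameter draws for property sweeps
random_params <- function(n, seed) {
  set.seed(seed)
  ki <- runif(n, 0.01, 2)
  ke <- runif(n, 1, 50)
  L <- sample(5:15, n, replace = TRUE)
  # R uniform below each jam boundary ke/ki
  R <- runif(n, 0.001, 1) * ke / ki
  list(ki = ki, ke = ke, L = L, R = R)
}

# independent root oracle: iterative grid refinement on the conservation
# residual, no use of uniroot
grid_root_oracle <- function(tx, R_total, rounds = 8, points = 200) {
  lo <- 1e-12 * R_total
  hi <- min(R_total, (1 - 1e-9) * min(tx$ke / tx$ki))
  h <- function(R) R + total_bound(tx, R) - R_total
  for (r in seq_len(rounds)) {
    grid <- seq(lo, hi, length.out = points)
    vals <- vapply(grid, h, numeric(1))
    i <- which(vals > 0)[1]
    if (is.na(i) || i == 1) return(grid[max(i, 1, na.rm = TRUE)])
    lo <- grid[i - 1]; hi <- grid[i]
  }
  (lo + hi) / 2
}
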