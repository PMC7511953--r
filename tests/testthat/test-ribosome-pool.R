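test_that("total bound ribosomes: trivial cases and single-gene value", {
  empty <- as_transcriptome(data.frame(gene_id = character(0), ki = numeric(0),
                                       ke = numeric(0), m = numeric(0),
                                       L = integer(0), n_codons = integer(0)))
  expect_identical(total_bound(empty, 1), 0)
  expect_identical(total_bound(tx_single(), 0), 0)
  expect_equal(total_bound(tx_single(ki = 0.1, ke = 10, m = 1, n_codons = 300), 1),
               (0.1 * 99 / 109) * 30)
})

test_that("total bound increases with the free pool in the uncongested regime", {
  tx <- tx_pair(ki = c(0.5, 0.05), m = c(2, 5))
  # u stays above the load peak for R below ~ke/(ki*5)
  grid <- seq(0.01, 10 / (0.5 * 5), length.out = 60)
  b <- vapply(grid, function(R) total_bound(tx, R), numeric(1))
  expect_true(all(diff(b) > 0))
})

test_that("free-pool solver satisfies conservation and matches a grid oracle", {
  empty <- as_transcriptome(data.frame(gene_id = character(0), ki = numeric(0),
                                       ke = numeric(0), m = numeric(0),
                                       L = integer(0), n_codons = integer(0)))
  expect_identical(solve_free_ribosomes(empty, 100)$R_free, 100)
  expect_identical(solve_free_ribosomes(tx_single(m = 0), 5)$R_free, 5)

  tx <- tx_single(ki = 0.1, ke = 10, m = 1, n_codons = 300)
  st <- solve_free_ribosomes(tx, 3)
  expect_lt(abs(st$residual), 1e-8)
  expect_equal(st$R_free, grid_root_oracle(tx, 3), tolerance = 1e-6)

  # random transcriptomes
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(20:60, 1)
    txr <- as_transcriptome(data.frame(
      gene_id = paste0("g", 1:n),
      ki = rlnorm(n, log(0.1), 0.5), ke = runif(n, 5, 20),
      m = rlnorm(n, 0, 0.5), L = 10L,
      n_codons = sample(100:500, n, replace = TRUE)))
    Rt <- runif(1, 1, 50)
    st <- solve_free_ribosomes(txr, Rt)
    expect_lt(abs(st$residual), 1e-8)
    expect_equal(st$R_free, grid_root_oracle(txr, Rt), tolerance = 1e-5)
  }
})

test_that("solver reports the binding gene when depletion jams the system", {
  # huge pool forces the free level towards the jam boundary of 'hi'
  tx <- tx_pair(ki = c(1, 0.1), m = c(0.001, 0.001))
  expect_error(solve_free_ribosomes(tx, 1000), "hi")
})

test_that("polysome fractions sum to one and match a Poisson enumeration", {
  tx <- tx_single(ki = 0.1, ke = 10, m = 1, n_codons = 300)
  st <- solve_free_ribosomes(tx, 6)
  prof <- polysome_fractions(tx, st)
  expect_equal(prof$free_frac + prof$mono_frac + prof$light_frac +
                 prof$heavy_frac, 1, tolerance = 1e-9)

  # exhaustive enumeration oracle for a single gene with known mean load
  lam <- protein_yield(tx, st$R_free)$load_per_mrna
  j <- 0:30
  pj <- dpois(j, lam); pj <- pj / sum(pj)
  sig <- j * pj
  expected <- c(mono = sig[2], light = sum(sig[3:5]), heavy = sum(sig[6:31]))
  expected <- expected / sum(expected) * (1 - prof$free_frac)
  expect_equal(prof$mono_frac, unname(expected["mono"]), tolerance = 1e-9)
  expect_equal(prof$light_frac, unname(expected["light"]), tolerance = 1e-9)
  expect_equal(prof$heavy_frac, unname(expected["heavy"]), tolerance = 1e-9)
})

test_that("degenerate polysome profiles are flagged", {
  tx <- tx_single(m = 0)
  st <- solve_free_ribosomes(tx, 5)
  prof <- polysome_fractions(tx, st)
  expect_identical(prof$free_frac, 1)
  expect_true(prof$poly_empty)
  expect_identical(prof$mono_to_poly, Inf)
})

test_that("identity scenario changes nothing", {
  tx <- tx_pair(charge_frac = c(0.25, 0.10))
  for (mode in c("eEF2", "ke_uniform")) {
    kd <- simulate_knockdown(tx, 3, knockdown_scenario(1, mode = mode))
    expect_identical(kd$per_gene$rel_log2_change, c(0, 0))
  }
})

test_that("uniform ke scaling nearly cancels relative yield changes", {
  # with ke' = f*ke for every gene and a conserved pool, the solved free level
  # drops almost exactly in proportion, so relative yields barely move (and
  # the high-initiation gene actually loses slightly)
  tx <- tx_pair(ki = c(1, 0.1))
  kd <- simulate_knockdown(tx, 3, knockdown_scenario(0.05, mode = "ke_uniform"))
  expect_lt(max(abs(kd$per_gene$rel_log2_change)), 0.01)
  expect_lt(kd$per_gene$rel_log2_change[1], 0)
  # the pool still shifts the polysome signature in the observed direction
  expect_lt(kd$knockdown$pool$R_free, kd$baseline$pool$R_free)
  expect_lt(kd$knockdown$profile$mono_to_poly, kd$baseline$profile$mono_to_poly)
  expect_gt(kd$knockdown$profile$heavy_frac, kd$baseline$profile$heavy_frac)
})

test_that("charge relief restores the high-initiation advantage", {
  tx <- tx_pair(ki = c(1, 0.1), charge_frac = c(0.25, 0.10))
  kd <- simulate_knockdown(tx, 3, knockdown_scenario(0.05, mode = "eEF2"))
  expect_gt(kd$per_gene$rel_log2_change[1], 0)
  expect_lt(kd$per_gene$rel_log2_change[2], 0)
})

test_that("deeper depletion monotonically strengthens the knockdown signature", {
  tx <- generate_transcriptome(n_genes = 120, top_fraction = 0.1, seed = 5)
  Rt <- calibrate_r_total(tx)
  fs <- c(1, 0.5, 0.2, 0.05)
  runs <- lapply(fs, function(f)
    simulate_knockdown(tx, Rt, knockdown_scenario(f)))
  rfree <- vapply(runs, function(k) k$knockdown$pool$R_free, numeric(1))
  m2p <- vapply(runs, function(k) k$knockdown$profile$mono_to_poly, numeric(1))
  med_top <- vapply(runs, function(k)
    median(k$per_gene$rel_log2_change[tx$class == "TOP"]), numeric(1))
  expect_true(all(diff(rfree) < 0))
  expect_true(all(diff(m2p) <= 0))
  expect_true(all(diff(med_top) > 0))
})

test_that("two-phase dwell maps availability to effective elongation rates", {
  # uncharged: plain harmonic combination
  expect_equal(effective_elongation_rate(1, 20, 10, 0.5, qbar = 0),
               1 / (1 / 20 + 1 / 10))
  # full profile average
  prof <- c(0L, 1L, 1L, 0L, 0L)
  q <- window_charge_counts(prof, W = 3)
  expect_identical(q, c(0L, 0L, 1L, 2L, 2L))
  ke <- effective_elongation_rate(0.5, 20, 10, 0.3, charge_profile = prof, W = 3)
  expect_equal(ke, 1 / (1 / (20 * 0.5) + mean(exp(0.3 * q)) / 10))
})
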