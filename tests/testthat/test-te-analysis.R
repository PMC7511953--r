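test_that("size factors reproduce median-of-ratios hand computations", {
  counts <- matrix(c(10, 30, 20, 60), nrow = 2)
  expect_equal(unname(size_factors(counts)), c(1 / sqrt(2), sqrt(2)))
  # proportional samples give proportional factors
  m <- matrix(c(5, 8, 12, 10, 16, 24), ncol = 2)
  sf <- unname(size_factors(m))
  expect_equal(sf[2] / sf[1], 2)
  # single sample: factor 1 by convention
  expect_identical(unname(size_factors(matrix(1:3, ncol = 1))), 1)
  # gene order invariance
  set.seed(2); big <- matrix(rpois(300, 50), ncol = 3)
  expect_equal(unname(size_factors(big)), unname(size_factors(big[100:1, ])))
  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2)), "all-positive")
})

make_experiment <- function(mrna, fp, cond = NULL) {
  n <- ncol(mrna)
  if (is.null(cond)) cond <- rep(c("control", "knockdown"), each = n / 2)
  ids <- paste0(substr(cond, 1, 3), ave(seq_len(n), cond, FUN = seq_along))
  dimnames(mrna) <- dimnames(fp) <- list(paste0("g", seq_len(nrow(mrna))), ids)
  list(mrna = mrna, fp = fp,
       sample_meta = data.frame(sample_id = ids, condition = cond))
}

test_that("translation efficiency normalises and matches hand arithmetic", {
  # identical matrices: TE identically 1
  m <- matrix(rpois(40, 100), ncol = 4)
  e <- make_experiment(m, m)
  te <- translation_efficiency(e)
  expect_true(all(abs(te$te - 1) < 1e-12))

  # doubling all counts of one fp sample is undone by its size factor: at
  # pseudocount 0 the TE matrix changes only by a constant overall factor
  # (the reference geometric mean shifts), so log-TE contrasts are exact
  fp2 <- m; fp2[, 2] <- fp2[, 2] * 2
  te2 <- translation_efficiency(make_experiment(m, fp2), pseudocount = 0)
  te0 <- translation_efficiency(make_experiment(m, m), pseudocount = 0)
  shift <- log2(te2$te) - log2(te0$te)
  expect_lt(diff(range(shift)), 1e-12)

  # 3-gene worked fixture: two identical samples so size factors are 1
  mrna <- cbind(c(10, 20, 40), c(10, 20, 40))
  fp <- cbind(c(20, 20, 10), c(20, 20, 10))
  e3 <- make_experiment(mrna, fp, cond = c("control", "knockdown"))
  te3 <- translation_efficiency(e3, pseudocount = 0.5, min_count = 0)
  expect_equal(unname(te3$te[, 1]),
               c(20.5 / 10.5, 20.5 / 20.5, 10.5 / 40.5))
  # count filter flags genes low in either assay
  tef <- translation_efficiency(e3, min_count = 25)
  expect_identical(unname(tef$keep), c(FALSE, TRUE, FALSE))
})

test_that("mismatched assays are rejected", {
  m <- matrix(rpois(40, 100), ncol = 4)
  e <- make_experiment(m, m)
  e$fp <- e$fp[, c(2, 1, 3, 4)]
  expect_error(translation_efficiency(e), "share")
})

test_that("2v2 permutation p-values match brute-force enumeration", {
  set.seed(30)
  mrna <- matrix(rpois(40, 200), ncol = 4)
  fp <- matrix(rpois(40, 200), ncol = 4)
  fp[1, 3:4] <- fp[1, 3:4] * 8  # one strongly shifted gene
  e <- make_experiment(mrna, fp)
  res <- differential_te(e, seed = 1)
  expect_true(attr(res, "exhaustive"))

  # independent brute force over all C(4,2) = 6 labelings
  te <- translation_efficiency(e)
  lt <- te$log2_te
  masks <- combn(4, 2)
  for (g in c(1, 5, 10)) {
    stats <- apply(masks, 2, function(idx) {
      kd <- rep(FALSE, 4); kd[idx] <- TRUE
      mean(lt[g, kd]) - mean(lt[g, !kd])
    })
    obs <- mean(lt[g, 3:4]) - mean(lt[g, 1:2])
    p_oracle <- mean(abs(stats) >= abs(obs) - 1e-12)
    expect_equal(res$p_value[g], p_oracle)
  }
  # p never 0, on the grid {k/6}
  expect_true(all(res$p_value[res$keep] >= 1 / 6))
  expect_true(all(abs(res$p_value[res$keep] * 6 -
                        round(res$p_value[res$keep] * 6)) < 1e-9))
  # the shifted gene is at the enumeration floor with the right sign
  expect_equal(res$p_value[1], 2 / 6)
  expect_gt(res$dte[1], 2)
})

test_that("q-values are BH-monotone in p and bounded", {
  tx <- generate_transcriptome(n_genes = 80, seed = 15)
  e <- generate_counts(tx, seed = 16)
  res <- differential_te(e, seed = 17)
  keep <- res$keep
  expect_true(all(res$q_value[keep] <= 1))
  o <- order(res$p_value[keep])
  expect_true(all(diff(res$q_value[keep][o]) >= -1e-12))
  expect_equal(res$q_value[keep],
               p.adjust(res$p_value[keep], "BH"))
})

test_that("pipeline statistics are invariant to rescaling a sample", {
  tx <- generate_transcriptome(n_genes = 60, seed = 18)
  e <- generate_counts(tx, seed = 19)
  # exact invariance of the difference statistic at pseudocount 0 (the
  # global normalisation factor cancels between conditions)
  res1 <- differential_te(e, seed = 20, pseudocount = 0)
  e2 <- e
  e2$fp[, 2] <- e2$fp[, 2] * 3
  e2$mrna[, 5] <- e2$mrna[, 5] * 2
  res2 <- differential_te(e2, seed = 20, pseudocount = 0)
  expect_equal(res2$dte, res1$dte, tolerance = 1e-12)
  expect_equal(res2$p_value, res1$p_value)
  # with the default pseudocount the distortion is bounded by pseudo/count
  res1p <- differential_te(e, seed = 20)
  res2p <- differential_te(e2, seed = 20)
  expect_equal(res2p$dte, res1p$dte, tolerance = 2e-3)
})

test_that("null experiments are calibrated at an attainable level", {
  # 3v3 label permutation has 20 assignments and sign-paired statistics, so
  # the smallest two-sided p is 0.1; calibration is checked there
  tx <- generate_transcriptome(n_genes = 200, seed = 22)
  e <- generate_counts(tx, depletion_factor = 1, seed = 23)
  res <- differential_te(e, seed = 24)
  frac <- mean(res$p_value[res$keep] <= 0.1)
  n <- sum(res$keep)
  ci <- qbinom(c(0.025, 0.975), n, 0.1) / n
  expect_gte(frac, ci[1]); expect_lte(frac, ci[2])
})

test_that("estimated signs recover strong true effects", {
  tx <- generate_transcriptome(seed = 25)
  e <- generate_counts(tx, seed = 26)
  res <- differential_te(e, seed = 27)
  truth <- e$truth$dte_log2_rel
  est <- res$dte - median(res$dte)
  strong <- abs(truth) >= 0.5 & res$keep
  expect_gt(mean(sign(est[strong]) == sign(truth[strong])), 0.9)
})

test_that("class enrichment finds planted shifts and behaves symmetrically", {
  set.seed(40)
  fake <- data.frame(dte = c(rnorm(20, 2), rnorm(180, 0)),
                     class = rep(c("TOP", "other"), c(20, 180)))
  enr <- class_enrichment(fake, n_perm = 999, seed = 41)
  expect_equal(enr$p_value, 1 / 1000)  # all TOP at the top ranks: floor
  # swapping the labels flips the one-sided p to its complement
  fake_sw <- fake; fake_sw$class <- ifelse(fake$class == "TOP", "other", "TOP")
  enr_sw <- class_enrichment(fake_sw, focal = "TOP", n_perm = 999, seed = 41)
  expect_gt(enr_sw$p_value, 0.99)
  expect_error(class_enrichment(data.frame(dte = 1:3, class = "TOP"),
                                n_perm = 10, seed = 1), "non-empty")
})

test_that("enrichment p-values are uniform under a random-label null", {
  set.seed(50)
  ps <- replicate(60, {
    fake <- data.frame(dte = rnorm(80), class = sample(rep(c("TOP", "other"),
                                                           c(15, 65))))
    class_enrichment(fake, n_perm = 199, seed = sample.int(1e6, 1))$p_value
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
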