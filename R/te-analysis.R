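#' Median-of-ratios size factors
#'
#' Per-sample scaling factors computed as the median across genes of the
#' ratio of each sample's counts to a per-gene geometric-mean reference,
#' using only genes with all-positive counts, then rescaled to geometric
#' mean 1. Factors are invariant to gene order; a single-sample matrix gets
#' factor 1.
#'
#' @param counts genes x samples numeric matrix.
#' @return numeric vector of positive factors, one per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) == 1) return(stats::setNames(1, colnames(counts)))
  ok <- rowSums(counts > 0) == ncol(counts)
  if (!any(ok)) stop("size_factors: no gene has all-positive counts")
  ref <- exp(rowMeans(log(counts[ok, , drop = FALSE])))
  sf <- apply(counts[ok, , drop = FALSE], 2, function(s) stats::median(s / ref))
  # fix the arbitrary overall scale: geometric mean 1, so that rescaling any
  # one sample leaves every other sample's normalised counts untouched
  sf / exp(mean(log(sf)))
}

#' Per-gene, per-sample translation efficiency
#'
#' TE is the ratio of normalised footprint to normalised mRNA signal:
#' `TE_gs = (fp_gs/sf_fp_s + pseudocount) / (mrna_gs/sf_mrna_s + pseudocount)`.
#' Genes whose summed raw counts fall below `min_count` in either assay are
#' flagged (`keep = FALSE`) and excluded from downstream testing; their TE is
#' still reported.
#'
#' @param experiment an `omics_experiment`, or a list with matrices `mrna`
#'   and `fp` sharing dimnames and a `sample_meta` data.frame.
#' @param pseudocount added to both normalised signals (default 0.5).
#' @param min_count minimum summed raw counts per assay (default 10).
#' @return list with `te` (genes x samples matrix), `log2_te`, `keep`
#'   (logical per gene), `sf_mrna`, `sf_fp`.
#' @export
translation_efficiency <- function(experiment, pseudocount = 0.5,
                                   min_count = 10) {
  mrna <- as.matrix(experiment$mrna)
  fp <- as.matrix(experiment$fp)
  if (!identical(dim(mrna), dim(fp)) ||
      !identical(colnames(mrna), colnames(fp)) ||
      !identical(rownames(mrna), rownames(fp))) {
    stop("mrna and fp matrices must share genes and samples")
  }
  sf_m <- size_factors(mrna)
  sf_f <- size_factors(fp)
  norm_m <- sweep(mrna, 2, sf_m, "/")
  norm_f <- sweep(fp, 2, sf_f, "/")
  te <- (norm_f + pseudocount) / (norm_m + pseudocount)
  keep <- rowSums(mrna) >= min_count & rowSums(fp) >= min_count
  list(te = te, log2_te = log2(te), keep = keep,
       sf_mrna = sf_m, sf_fp = sf_f)
}

# all condition labelings (columns = assignments) for exhaustive enumeration
condition_labelings <- function(cond) {
  kd_idx <- which(cond == unique(cond)[2])
  n <- length(cond)
  k <- length(kd_idx)
  combos <- utils::combn(n, k)
  combos
}

#' Differential translation efficiency by permutation
#'
#' Per gene, the statistic is the difference of condition means of per-sample
#' log2 TE (knockdown minus control). The null distribution permutes the
#' condition labels of whole samples -- jointly across both assays, which
#' preserves the paired fp/mRNA structure. When the number of distinct label
#' assignments `choose(n, n_kd)` is at most `max_exhaustive`, all of them are
#' enumerated and `p = #(|stat_perm| >= |stat_obs|) / n_assignments`
#' (the observed labelling is one of them, so p is never 0); otherwise
#' `n_perm` random permutations are drawn and the add-one estimator
#' `p = (1 + #(|perm| >= |obs|)) / (1 + n_perm)` is used. Benjamini-Hochberg
#' q-values are appended over the genes passing the count filter.
#'
#' @param experiment an `omics_experiment` (or compatible list with
#'   `sample_meta$condition` containing two levels).
#' @param n_perm random permutations when enumeration is not exhaustive.
#' @param seed integer seed (mandatory when sampling is used).
#' @param pseudocount,min_count passed to [translation_efficiency()].
#' @param max_exhaustive threshold on `choose(n, n_kd)` for full enumeration.
#' @return data.frame (`te_result`) with columns `gene_id`, `class` (if
#'   available), `mean_log2_te_control`, `mean_log2_te_knockdown`, `dte`,
#'   `p_value`, `q_value`, `keep`; attributes `n_perm`, `exhaustive`, `seed`.
#' @export
differential_te <- function(experiment, n_perm = 1000, seed = NULL,
                            pseudocount = 0.5, min_count = 10,
                            max_exhaustive = 10000) {
  meta <- experiment$sample_meta
  cond <- meta$condition
  lev <- unique(cond)
  if (length(lev) != 2) stop("need exactly two conditions")
  if (min(table(cond)) < 2) stop("need >= 2 replicates per condition")
  te <- translation_efficiency(experiment, pseudocount, min_count)
  lt <- te$log2_te

  is_kd <- cond == lev[2]
  stat_for <- function(kd_mask) {
    rowMeans(lt[, kd_mask, drop = FALSE]) - rowMeans(lt[, !kd_mask, drop = FALSE])
  }
  obs <- stat_for(is_kd)

  n <- length(cond)
  k <- sum(is_kd)
  n_assign <- choose(n, k)
  exhaustive <- n_assign <= max_exhaustive
  if (exhaustive) {
    combos <- utils::combn(n, k)
    perm_stats <- apply(combos, 2, function(idx) {
      mask <- rep(FALSE, n); mask[idx] <- TRUE
      stat_for(mask)
    })
    hits <- rowSums(abs(perm_stats) >= abs(obs) - 1e-12)
    p <- hits / n_assign
    n_perm_used <- n_assign
  } else {
    if (is.null(seed)) stop("seed must be given for sampled permutations")
    set.seed(seed)
    hits <- numeric(nrow(lt))
    for (b in seq_len(n_perm)) {
      mask <- rep(FALSE, n); mask[sample.int(n, k)] <- TRUE
      hits <- hits + (abs(stat_for(mask)) >= abs(obs) - 1e-12)
    }
    p <- (1 + hits) / (1 + n_perm)
    n_perm_used <- n_perm
  }
  p[!te$keep] <- NA_real_
  q <- rep(NA_real_, length(p))
  q[te$keep] <- stats::p.adjust(p[te$keep], method = "BH")

  out <- data.frame(
    gene_id = rownames(lt),
    mean_log2_te_control = rowMeans(lt[, !is_kd, drop = FALSE]),
    mean_log2_te_knockdown = rowMeans(lt[, is_kd, drop = FALSE]),
    dte = obs, p_value = p, q_value = q, keep = te$keep,
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (!is.null(experiment$truth) && "class" %in% names(experiment$truth)) {
    out$class <- experiment$truth$class[match(out$gene_id,
                                              experiment$truth$gene_id)]
  }
  attr(out, "n_perm") <- n_perm_used
  attr(out, "exhaustive") <- exhaustive
  attr(out, "seed") <- seed
  class(out) <- c("te_result", class(out))
  out
}

#' Class enrichment of TE changes by rank-sum permutation
#'
#' Tests whether the focal class (default `"TOP"`) is shifted towards high
#' `dte` values. The statistic is the normalised rank sum of the focal
#' genes' `dte` (the Wilcoxon/Mann-Whitney statistic standardised under the
#' permutation null); the p-value comes from `n_perm` random label
#' permutations with the add-one convention, one-sided ("greater") by
#' default, two-sided available.
#'
#' @param te_result a [differential_te()] table (or any data.frame with
#'   `dte`; `labels` supplies classes if no `class` column).
#' @param labels optional class vector aligned with rows.
#' @param focal class treated as "up" (default `"TOP"`).
#' @param n_perm number of label permutations.
#' @param seed integer seed (mandatory).
#' @param alternative `"greater"` (focal up) or `"two.sided"`.
#' @param use_keep restrict to genes passing the count filter when present.
#' @return list (`class_enrichment`) with `statistic` (standardised rank
#'   sum), `p_value`, `n_focal`, `n_other`, `n_perm`, `seed`, `alternative`.
#' @export
class_enrichment <- function(te_result, labels = NULL, focal = "TOP",
                             n_perm = 10000, seed,
                             alternative = c("greater", "two.sided"),
                             use_keep = TRUE) {
  if (missing(seed)) stop("seed must be given explicitly")
  alternative <- match.arg(alternative)
  if (is.null(labels)) {
    if (!"class" %in% names(te_result)) stop("no class labels available")
    labels <- te_result$class
  }
  x <- te_result$dte
  if (use_keep && "keep" %in% names(te_result)) {
    sel <- te_result$keep & !is.na(x)
    x <- x[sel]; labels <- labels[sel]
  }
  is_focal <- labels == focal
  n1 <- sum(is_focal); n2 <- sum(!is_focal)
  if (n1 == 0 || n2 == 0) stop("both classes must be non-empty")
  r <- rank(x)
  stat_fun <- function(mask) {
    rs <- sum(r[mask])
    mu <- n1 * (n1 + n2 + 1) / 2
    sg <- sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
    (rs - mu) / sg
  }
  obs <- stat_fun(is_focal)
  set.seed(seed)
  n_tot <- n1 + n2
  hits <- 0L
  for (b in seq_len(n_perm)) {
    mask <- rep(FALSE, n_tot); mask[sample.int(n_tot, n1)] <- TRUE
    s <- stat_fun(mask)
    hit <- if (alternative == "greater") s >= obs - 1e-12 else
      abs(s) >= abs(obs) - 1e-12
    hits <- hits + hit
  }
  p <- (1 + hits) / (1 + n_perm)
  structure(list(statistic = obs, p_value = p, n_focal = n1, n_other = n2,
                 n_perm = n_perm, seed = seed, alternative = alternative),
            class = "class_enrichment")
}

#' @export
print.class_enrichment <- function(x, ...) {
  cat(sprintf("class_enrichment: z = %+0.3f, p = %.4g (%s; %d vs %d genes, %d permutations)\n",
              x$statistic, x$p_value, x$alternative, x$n_focal, x$n_other,
              x$n_perm))
  invisible(x)
}
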