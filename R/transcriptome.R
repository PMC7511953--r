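#' Construct and validate a transcriptome parameter table
#'
#' A transcriptome is a `data.frame` with one row per transcript species and
#' the kinetic parameters of the competition model:
#'
#' * `gene_id`   -- unique identifier.
#' * `ki`        -- initiation rate constant, per free-ribosome unit per time
#'   unit (> 0).
#' * `ke`        -- effective elongation rate, codons per time unit (> 0).
#' * `m`         -- mRNA abundance in arbitrary concentration units (>= 0).
#' * `L`         -- ribosome footprint, codons (integer >= 1).
#' * `n_codons`  -- coding length, codons (integer >= `L`).
#'
#' Optional columns: `class` (e.g. `"TOP"` / `"other"`) and `charge_frac`
#' (fraction of positively charged residues, used by the elongation-factor
#' depletion scenario). Per-residue charge profiles (0/1 vectors of length
#' `n_codons`) can be attached as a named list via the `charge_profiles`
#' attribute; [charge_profiles_from_fasta()] builds them from protein
#' sequences.
#'
#' All model quantities are in dimensionless model units: only ratios and the
#' combination `x = ki * R / ke` are meaningful.
#'
#' @param df data.frame with at least the mandatory columns above.
#' @param charge_profiles optional named list of 0/1 integer vectors, one per
#'   gene, each of length `n_codons` for that gene.
#' @return the validated data.frame, with class `c("transcriptome",
#'   "data.frame")`.
#' @export
as_transcriptome <- function(df, charge_profiles = NULL) {
  stopifnot(is.data.frame(df))
  required <- c("gene_id", "ki", "ke", "m", "L", "n_codons")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("transcriptome is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$gene_id)) stop("duplicated gene_id in transcriptome")
  if (!all(df$ki > 0)) stop("ki must be > 0 for every gene")
  if (!all(df$ke > 0)) stop("ke must be > 0 for every gene")
  if (!all(df$m >= 0)) stop("m must be >= 0 for every gene")
  if (!all(df$L >= 1 & df$L == round(df$L))) stop("L must be an integer >= 1")
  if (!all(df$n_codons >= df$L & df$n_codons == round(df$n_codons))) {
    stop("n_codons must be an integer >= L")
  }
  if (!is.null(charge_profiles)) {
    idx <- match(names(charge_profiles), df$gene_id)
    if (anyNA(idx)) stop("charge_profiles contain unknown gene_id")
    len_ok <- lengths(charge_profiles) == df$n_codons[idx]
    if (!all(len_ok)) {
      stop("charge profile length != n_codons for: ",
           paste(names(charge_profiles)[!len_ok], collapse = ", "))
    }
    vals_ok <- vapply(charge_profiles, function(p) all(p %in% c(0L, 1L)), logical(1))
    if (!all(vals_ok)) stop("charge profiles must be 0/1 vectors")
    attr(df, "charge_profiles") <- charge_profiles
  }
  class(df) <- unique(c("transcriptome", class(df)))
  df
}

#' Derive 0/1 charge profiles from protein sequences
#'
#' Lysine (K) and arginine (R) count as positively charged; matching is
#' case-insensitive. Every other residue (including histidine) maps to 0.
#'
#' @param fasta path to an amino-acid FASTA file, or a named character vector
#'   of sequences.
#' @return named list of integer 0/1 vectors.
#' @export
charge_profiles_from_fasta <- function(fasta) {
  if (is.character(fasta) && length(fasta) == 1 && file.exists(fasta)) {
    if (requireNamespace("Biostrings", quietly = TRUE)) {
      aa <- Biostrings::readAAStringSet(fasta)
      seqs <- as.character(aa)
      names(seqs) <- sub("\\s.*$", "", names(aa))
    } else {
      seqs <- read_fasta(fasta)
    }
  } else {
    seqs <- fasta
    if (is.null(names(seqs))) stop("sequences must be named by gene_id")
  }
  lapply(seqs, function(s) {
    res <- strsplit(toupper(s), "")[[1]]
    as.integer(res %in% c("K", "R"))
  })
}

#' @export
print.transcriptome <- function(x, ...) {
  cat(sprintf("transcriptome: %d genes", nrow(x)))
  if ("class" %in% names(x)) {
    tab <- table(x$class)
    cat(" (", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), ")", sep = "")
  }
  cat("\n")
  NextMethod()
  invisible(x)
}
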