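#' Write a counts matrix as TSV
#'
#' Header row; `gene_id` first column; full-precision numbers.
#'
#' @param mat genes x samples matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a counts matrix from TSV
#'
#' Expects the layout written by [write_counts_tsv()]. A missing or
#' non-numeric cell is an error naming the row and column.
#'
#' @param path TSV path.
#' @return numeric matrix with gene ids as rownames.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id") stop("first column must be gene_id: ", path)
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(apply(mat, 2, as.numeric))), arr.ind = TRUE)
    stop(sprintf("non-numeric cell at row %d (gene %s), column '%s' in %s",
                 bad[1, 1], df$gene_id[bad[1, 1]], colnames(mat)[bad[1, 2]], path))
  }
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)
    stop(sprintf("missing cell at row %d (gene %s), column '%s' in %s",
                 bad[1, 1], df$gene_id[bad[1, 1]], colnames(mat)[bad[1, 2]], path))
  }
  rownames(mat) <- df$gene_id
  mat
}

#' Write / read a transcriptome parameter table
#'
#' TSV with `gene_id` first; numeric columns at full precision. Charge
#' profiles (if attached) are not serialised here -- use FASTA.
#'
#' @param tx a transcriptome table.
#' @param path TSV path.
#' @return `path` (write) or a validated transcriptome (read).
#' @export
write_transcriptome_tsv <- function(tx, path) {
  df <- as.data.frame(tx)
  attr(df, "charge_profiles") <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_transcriptome_tsv
#' @export
read_transcriptome_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (anyNA(df)) {
    bad <- which(is.na(df), arr.ind = TRUE)
    stop(sprintf("missing cell at row %d, column '%s' in %s",
                 bad[1, 1], names(df)[bad[1, 2]], path))
  }
  as_transcriptome(df)
}

#' Minimal FASTA writer / reader
#'
#' Standard 60-character wrap. Reading is case-preserving; downstream charge
#' calls are case-insensitive. [charge_profiles_from_fasta()] prefers
#' Biostrings when installed; this pair covers writing and the fallback path.
#'
#' @param seqs named character vector of sequences.
#' @param path FASTA path.
#' @return `path` (write) or a named character vector (read).
#' @export
write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    starts <- seq(1, nchar(s), by = 60)
    writeLines(substring(s, starts, pmin(starts + 59, nchar(s))), con)
  }
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("not a FASTA file: ", path)
  id <- sub("^>\\s*", "", lines[hdr])
  id <- sub("\\s.*$", "", id)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste0, character(1),
                 collapse = "")
  stats::setNames(seqs, id)
}

#' Protein sequences for a transcriptome's charge profiles
#'
#' Renders attached 0/1 charge profiles as amino-acid sequences (K for
#' charged positions, alternating A/G elsewhere) suitable for FASTA export
#' and round-tripping through [charge_profiles_from_fasta()].
#'
#' @param tx transcriptome with a `charge_profiles` attribute.
#' @return named character vector of sequences.
#' @export
profiles_to_sequences <- function(tx) {
  profiles <- attr(tx, "charge_profiles")
  if (is.null(profiles)) stop("transcriptome has no charge_profiles attribute")
  vapply(profiles, function(p) {
    bg <- rep(c("A", "G"), length.out = length(p))
    paste0(ifelse(p == 1L, "K", bg), collapse = "")
  }, character(1))
}
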