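# Readers and writers for the plain-text formats the pipeline exchanges:
# tab-separated tables (counts, conditions, TSS, truth, Ct), FASTA and
# JASPAR motif text.  All TSV is UTF-8, tab-delimited, '.' decimal.

#' Read a gene-by-sample count matrix from TSV
#'
#' First column holds gene identifiers, the header the sample identifiers.
#'
#' @param path path to the TSV file.
#' @return integer matrix with gene rownames and sample colnames.
#' @export
read_counts_tsv <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("count table needs a gene column plus >=1 sample")
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes)) stop("duplicate gene ids in count table")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- genes
  if (any(m < 0, na.rm = TRUE)) stop("negative counts in count table")
  m
}

#' Write a count matrix to TSV
#'
#' @param counts integer matrix, genes in rows.
#' @param path output path.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-to-condition table
#'
#' Two tab-separated columns: sample id, condition label.
#'
#' @param path path to the TSV file.
#' @return named factor of conditions, names are sample ids.
#' @export
read_conditions_tsv <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("conditions table needs sample and condition columns")
  setNames(factor(df[[2L]]), as.character(df[[1L]]))
}

#' @rdname read_conditions_tsv
#' @param condition named factor (names = sample ids).
#' @export
write_conditions_tsv <- function(condition, path) {
  df <- data.frame(sample = names(condition),
                   condition = as.character(condition))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSS annotation table
#'
#' Four tab-separated columns: gene id, chromosome/sequence id, 0-based TSS
#' position, strand (+/-).
#'
#' @param path path to the TSV file.
#' @return data.frame with columns gene, chrom, tss, strand.
#' @export
read_tss_tsv <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  names(df)[1:4] <- c("gene", "chrom", "tss", "strand")
  if (any(df$tss < 0)) stop("TSS positions must be >= 0 (0-based)")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  df
}

#' @rdname read_tss_tsv
#' @param tss data.frame as returned by `read_tss_tsv()`.
#' @export
write_tss_tsv <- function(tss, path) {
  write.table(tss[, c("gene", "chrom", "tss", "strand")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read promoter/genome sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  x <- toupper(as.character(ss))
  names(x) <- sub("\\s.*$", "", names(ss))
  x
}

#' @rdname read_fasta
#' @param sequences named character vector of DNA strings.
#' @export
write_fasta <- function(sequences, path) {
  ss <- Biostrings::DNAStringSet(unlist(sequences))
  names(ss) <- names(sequences)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a long-format Ct table
#'
#' Columns: sample, group, replicate, gene, ct.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_ct_tsv <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample", "group", "gene", "ct")
  if (!all(need %in% names(df))) {
    stop("Ct table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(df$ct <= 0)) stop("Ct values must be positive")
  df
}

#' @rdname read_ct_tsv
#' @param ct data.frame in long format.
#' @export
write_ct_tsv <- function(ct, path) {
  write.table(ct, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column gene-to-term mapping
#'
#' @param path TSV path with columns gene, term.
#' @return data.frame with columns gene, term.
#' @export
read_term_map_tsv <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  names(df)[1:2] <- c("gene", "term")
  df[, c("gene", "term")]
}

#' Read a plain gene list (one id per line)
#'
#' @param path text file.
#' @return character vector.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x[nzchar(x)]
}
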