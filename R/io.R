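# Readers and writers for the plain-text interchange formats. Headers in the
# UTR FASTA follow "transcript_id|gene_id"; tables are tab-separated with a
# header row; BED is 0-based half-open.

#' Read 3' UTR sequences from FASTA
#'
#' @param path FASTA file; each header is `transcript_id|gene_id` (a header
#'   without `|` uses the same string for both).
#' @return UTR tibble: `transcript_id`, `gene_id`, `sequence`, `length`.
#' @export
read_utr_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  hdr <- sub("\\s.*$", "", names(ss))
  parts <- strsplit(hdr, "|", fixed = TRUE)
  tibble::tibble(
    transcript_id = vapply(parts, `[`, character(1), 1L),
    gene_id = vapply(parts, function(p) p[min(2L, length(p))], character(1)),
    sequence = unname(as.character(ss)),
    length = Biostrings::width(ss))
}

#' Write a UTR table to FASTA
#' @param utrs UTR tibble as from [read_utr_fasta()].
#' @param path output file.
#' @export
write_utr_fasta <- function(utrs, path) {
  ss <- Biostrings::DNAStringSet(utrs$sequence)
  names(ss) <- paste(utrs$transcript_id, utrs$gene_id, sep = "|")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a miRNA table
#'
#' @param path TSV with columns `name`, `mature_sequence`, `expression`.
#' @return tibble with those columns.
#' @export
read_mirna_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "mature_sequence") %in% names(x)))
  tibble::as_tibble(x)
}

#' Read the family status table
#'
#' @param path TSV with columns `family_id` and `regulates_target`
#'   (`Yes`/`No`).
#' @return tibble with `family_id`, `regulates_target` (logical).
#' @export
read_family_status <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("family_id", "regulates_target") %in% names(x)))
  v <- x$regulates_target
  if (!is.logical(v)) v <- toupper(as.character(v)) %in% c("YES", "TRUE", "1")
  tibble::tibble(family_id = x$family_id, regulates_target = v)
}

#' Read an expression count table
#'
#' @param path TSV; first column is the entity id (gene or miRNA), remaining
#'   columns are per-sample values.
#' @return data frame with the id column named as in the file plus numeric
#'   sample columns.
#' @export
read_expression_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(x) < 2L) stop("expression table needs id + >=1 sample column",
                         call. = FALSE)
  for (j in 2:ncol(x)) x[[j]] <- as.numeric(x[[j]])
  tibble::as_tibble(x)
}

#' Read peak intervals from BED
#'
#' Uses rtracklayer when available, else a minimal BED3+ reader. Coordinates
#' stay in BED convention (0-based half-open).
#'
#' @param path BED file.
#' @return tibble `chrom`, `start`, `end` (plus `name`, `score`, `strand`
#'   when present).
#' @export
read_peaks_bed <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "BED")
    out <- tibble::tibble(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr))
    if (!is.null(gr$score)) out$score <- gr$score
    return(out)
  }
  x <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(x)[1:3] <- c("chrom", "start", "end")
  tibble::as_tibble(x)
}

#' Read 3' UTR intervals from a GTF/GFF annotation
#'
#' Extracts `three_prime_utr` features and groups them per transcript into
#' the 0-based half-open interval map used for genome-coordinate peak
#' intersection. Sequences still come from FASTA; this supplies coordinates.
#'
#' @param path GTF/GFF3 file (requires rtracklayer).
#' @return tibble `transcript_id`, `gene_id`, `genomic_intervals` (list of
#'   data frames with `chrom`, `start`, `end`, `strand`).
#' @export
read_utr_gtf <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("read_utr_gtf() requires the rtracklayer package", call. = FALSE)
  }
  gr <- rtracklayer::import(path)
  gr <- gr[tolower(as.character(gr$type)) %in%
             c("three_prime_utr", "3utr", "three_prime_UTR")]
  if (length(gr) == 0L) stop("no three_prime_utr features in ", path,
                             call. = FALSE)
  df <- data.frame(
    transcript_id = as.character(gr$transcript_id),
    gene_id = as.character(gr$gene_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # 1-based closed -> 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  sp <- split(df, df$transcript_id)
  tibble::tibble(
    transcript_id = names(sp),
    gene_id = vapply(sp, function(d) d$gene_id[1], character(1)),
    genomic_intervals = lapply(sp, function(d)
      d[order(d$start), c("chrom", "start", "end", "strand")]))
}

#' Write an MRE table
#' @param mres MRE tibble from [scan_mres()].
#' @param path output TSV.
#' @export
write_mre_table <- function(mres, path) {
  utils::write.table(mres, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an MRE table written by [write_mre_table()]
#' @param path TSV with the MRE columns.
#' @return MRE tibble.
#' @export
read_mre_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "gene_id", "family_id", "position", "site_class")
  stopifnot(all(need %in% names(x)))
  tibble::as_tibble(x)
}
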