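#' Group miRNAs into seed families
#'
#' miRNAs sharing an identical seed (mature positions 2--8) act on the same
#' sites and are collapsed into one family, the unit of regulation used by
#' every downstream feature. Family identifiers are derived from the seed so
#' that grouping is deterministic and independent of input row order.
#'
#' @param mirnas data frame with columns `name`, `mature_sequence` (RNA, length
#'   >= 8; `T` is accepted and read as `U`) and optionally `expression`
#'   (numeric abundance, summed over members per family).
#' @return A tibble with one row per family: `family_id`, `seed` (RNA 7-mer),
#'   `members` (list column of member names, sorted), `n_members`,
#'   `expression` (sum over members; `NA` if no expression column) and
#'   `expressed` (initialised `TRUE`; the pipeline overwrites it after the
#'   miRNA expression filter).
#' @examples
#' mirnas <- data.frame(
#'   name = c("miR-a", "miR-b", "miR-c"),
#'   mature_sequence = c("UAGCAGCACGUAAAUAUUGGCG",
#'                       "UAGCAGCACGUUUAUAUGGGCU",
#'                       "UUUGCACUAGAUGCACCAUUA"),
#'   expression = c(10, 5, 2))
#' group_families(mirnas)
#' @export
group_families <- function(mirnas) {
  if (is.null(mirnas) || nrow(mirnas) == 0L) {
    stop("empty miRNA table", call. = FALSE)
  }
  stopifnot(all(c("name", "mature_sequence") %in% names(mirnas)))
  seq_rna <- normalize_rna(as.character(mirnas$mature_sequence),
                           what = "mature sequence")
  short <- nchar(seq_rna) < 8L
  if (any(short)) {
    warning(sum(short), " miRNA record(s) shorter than 8 nt dropped: ",
            paste(utils::head(mirnas$name[short], 5L), collapse = ", "),
            call. = FALSE)
    mirnas <- mirnas[!short, , drop = FALSE]
    seq_rna <- seq_rna[!short]
  }
  if (nrow(mirnas) == 0L) stop("no miRNA records left after length filter",
                               call. = FALSE)
  seed <- substr(seq_rna, 2L, 8L)
  expr <- if ("expression" %in% names(mirnas)) {
    as.numeric(mirnas$expression)
  } else {
    rep(NA_real_, nrow(mirnas))
  }
  seeds <- sort(unique(seed))
  fams <- lapply(seeds, function(s) {
    i <- which(seed == s)
    tibble::tibble(
      family_id = paste0("fam-", chartr("U", "T", s)),
      seed = s,
      members = list(sort(as.character(mirnas$name[i]))),
      n_members = length(i),
      expression = if (all(is.na(expr[i]))) NA_real_ else
        sum(expr[i], na.rm = TRUE),
      expressed = TRUE)
  })
  do.call(rbind, fams)
}

#' High-affinity site patterns for a seed family
#'
#' Returns the three canonical high-affinity seed-match site patterns
#' (TargetScan conventions) for a 7-nt seed, as DNA strings to be matched on
#' the sense strand of a transcript sequence:
#' \describe{
#'   \item{7mer-m8}{reverse complement of seed (mature positions 2--8).}
#'   \item{7mer-A1}{reverse complement of mature positions 2--7, followed by
#'     an `A` opposite mature position 1.}
#'   \item{8mer}{reverse complement of positions 2--8 followed by `A`.}
#' }
#'
#' @param seed RNA 7-mer (mature positions 2--8); `T` accepted as `U`.
#' @return A tibble with columns `site` (DNA pattern) and `site_class`.
#' @examples
#' site_patterns("AGCAGCA")
#' @export
site_patterns <- function(seed) {
  seed <- normalize_rna(seed, what = "seed")
  if (length(seed) != 1L || nchar(seed) != 7L) {
    stop("seed must be a single 7-nt RNA string", call. = FALSE)
  }
  m2_m8 <- rna_revcomp_dna(seed)
  m2_m7 <- rna_revcomp_dna(substr(seed, 1L, 6L))
  tibble::tibble(
    site = c(m2_m8, paste0(m2_m7, "A"), paste0(m2_m8, "A")),
    site_class = c("7mer-m8", "7mer-A1", "8mer"))
}

# Pattern table over all families: family_id x {site, site_class}.
build_pattern_table <- function(families) {
  stopifnot(nrow(families) > 0L)
  pats <- lapply(seq_len(nrow(families)), function(i) {
    p <- site_patterns(families$seed[i])
    p$family_id <- families$family_id[i]
    p
  })
  do.call(rbind, pats)
}

# All (possibly overlapping) match start offsets, 0-based, of each pattern of
# one width in one subject, via a preassembled PDict.
match_width <- function(pdict, subject) {
  m <- Biostrings::matchPDict(pdict, subject)
  starts <- Biostrings::startIndex(m)
  n_hit <- lengths(starts)
  list(pattern = rep(seq_along(starts), n_hit),
       position = unlist(starts, use.names = FALSE) - 1L)
}

#' Scan UTR sequences for miRNA response elements
#'
#' Matches every family's high-affinity site patterns against the sense
#' strand of each UTR sequence and reports one MRE per (family, offset).
#' Within a family an 8mer match suppresses the 7mer-m8 and 7mer-A1 matches
#' it contains, so each locus is reported once at its longest site class;
#' different families matching at overlapping loci each keep their own MRE.
#' When CLIP peak intervals are supplied, a match is kept only if its
#' footprint intersects at least one peak.
#'
#' @param utrs data frame with columns `transcript_id`, `gene_id`, `sequence`
#'   (DNA). For `peak_coords = "genome"` an additional list column
#'   `genomic_intervals` must hold, per transcript, a data frame with
#'   `chrom`, `start`, `end` (0-based half-open) and `strand`.
#' @param families family table from [group_families()].
#' @param peaks optional peak intervals. For `peak_coords = "transcript"` a
#'   data frame with `transcript_id`, `start`, `end` (0-based half-open,
#'   transcript coordinates). For `"genome"` a data frame with `chrom`,
#'   `start`, `end` (BED convention), e.g. from [read_peaks_bed()].
#' @param peak_coords coordinate system of `peaks`.
#' @return MRE tibble: `transcript_id`, `gene_id`, `family_id`, `position`
#'   (0-based offset of the site start in the UTR), `site_class`,
#'   `unit_position` (`position / UTR length`), sorted by transcript,
#'   position, family.
#' @seealso [scan_utr()] for a single record, [normalize_positions()].
#' @export
scan_mres <- function(utrs, families, peaks = NULL,
                      peak_coords = c("transcript", "genome")) {
  peak_coords <- match.arg(peak_coords)
  stopifnot(all(c("transcript_id", "gene_id", "sequence") %in% names(utrs)))
  if (is.null(families) || nrow(families) == 0L) {
    stop("families must be non-empty", call. = FALSE)
  }
  pat <- build_pattern_table(families)
  widths <- nchar(pat$site)
  pdicts <- lapply(split(seq_len(nrow(pat)), widths), function(idx) {
    list(idx = idx,
         pdict = Biostrings::PDict(Biostrings::DNAStringSet(pat$site[idx])))
  })
  out <- vector("list", nrow(utrs))
  for (i in seq_len(nrow(utrs))) {
    seqc <- toupper(utrs$sequence[i])
    if (nchar(seqc) < 8L) next
    subject <- Biostrings::DNAString(seqc)
    hits <- lapply(pdicts, function(pd) {
      h <- match_width(pd$pdict, subject)
      data.frame(row = pd$idx[h$pattern], position = h$position)
    })
    hits <- do.call(rbind, hits)
    if (is.null(hits) || nrow(hits) == 0L) next
    mre <- data.frame(
      transcript_id = utrs$transcript_id[i],
      gene_id = utrs$gene_id[i],
      family_id = pat$family_id[hits$row],
      position = hits$position,
      site_class = pat$site_class[hits$row],
      stringsAsFactors = FALSE)
    mre <- resolve_site_classes(mre)
    if (!is.null(peaks)) {
      keep <- peak_overlap_keep(mre, utrs[i, , drop = FALSE],
                                peaks, peak_coords)
      mre <- mre[keep, , drop = FALSE]
    }
    if (nrow(mre) > 0L) {
      mre$unit_position <- mre$position / nchar(seqc)
      out[[i]] <- mre
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    return(tibble::tibble(transcript_id = character(), gene_id = character(),
                          family_id = character(), position = integer(),
                          site_class = character(), unit_position = double()))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$transcript_id, res$position, res$family_id,
                   res$site_class), , drop = FALSE]
  rownames(res) <- NULL
  tibble::as_tibble(res)
}

# Within one transcript: per family, an 8mer at offset o absorbs the
# 7mer-m8 at o and the 7mer-A1 at o + 1.
resolve_site_classes <- function(mre) {
  keep <- rep(TRUE, nrow(mre))
  is8 <- mre$site_class == "8mer"
  if (!any(is8)) return(mre)
  key8 <- paste(mre$family_id[is8], mre$position[is8])
  keep[mre$site_class == "7mer-m8" &
         paste(mre$family_id, mre$position) %in% key8] <- FALSE
  keep[mre$site_class == "7mer-A1" &
         paste(mre$family_id, mre$position - 1L) %in% key8] <- FALSE
  mre[keep, , drop = FALSE]
}

site_width <- function(site_class) ifelse(site_class == "8mer", 8L, 7L)

# TRUE for MREs whose footprint intersects >= 1 peak.
peak_overlap_keep <- function(mre, utr_row, peaks, peak_coords) {
  w <- site_width(mre$site_class)
  if (peak_coords == "transcript") {
    pk <- peaks[peaks$transcript_id == utr_row$transcript_id, , drop = FALSE]
    if (nrow(pk) == 0L) return(rep(FALSE, nrow(mre)))
    q <- IRanges::IRanges(start = mre$position + 1L, width = w)
    s <- IRanges::IRanges(start = pk$start + 1L, end = pk$end)
    IRanges::overlapsAny(q, s)
  } else {
    gi <- utr_row$genomic_intervals[[1]]
    if (is.null(gi)) {
      warning("transcript ", utr_row$transcript_id,
              " has no genomic intervals; peaks skipped", call. = FALSE)
      return(rep(FALSE, nrow(mre)))
    }
    gr_pk <- GenomicRanges::GRanges(
      peaks$chrom, IRanges::IRanges(start = peaks$start + 1L, end = peaks$end))
    keep <- logical(nrow(mre))
    for (j in seq_len(nrow(mre))) {
      fp <- transcript_to_genome(mre$position[j], w[j], gi)
      keep[j] <- length(fp) > 0L &&
        any(GenomicRanges::countOverlaps(fp, gr_pk, ignore.strand = TRUE) > 0L)
    }
    keep
  }
}

# Map a transcript-coordinate window [offset, offset + width) through the
# exon interval map (0-based half-open; minus-strand UTRs read right to left).
transcript_to_genome <- function(offset, width, gi) {
  gi <- gi[order(gi$start), , drop = FALSE]
  strand <- gi$strand[1]
  if (strand == "-") gi <- gi[rev(seq_len(nrow(gi))), , drop = FALSE]
  lens <- gi$end - gi$start
  offs <- cumsum(c(0L, lens))[seq_len(nrow(gi))]
  pieces <- list()
  lo <- offset
  hi <- offset + width
  for (j in seq_len(nrow(gi))) {
    a <- max(lo, offs[j]); b <- min(hi, offs[j] + lens[j])
    if (a >= b) next
    if (strand == "+") {
      gstart <- gi$start[j] + (a - offs[j])
      gend <- gi$start[j] + (b - offs[j])
    } else {
      gend <- gi$end[j] - (a - offs[j])
      gstart <- gi$end[j] - (b - offs[j])
    }
    pieces[[length(pieces) + 1L]] <- GenomicRanges::GRanges(
      gi$chrom[j], IRanges::IRanges(start = gstart + 1L, end = gend),
      strand = strand)
  }
  if (length(pieces) == 0L) return(GenomicRanges::GRanges())
  do.call(c, pieces)
}

#' Scan a single UTR record
#'
#' Convenience wrapper around [scan_mres()] for one transcript.
#'
#' @param utr one-row data frame (or list) with `transcript_id`, `gene_id`,
#'   `sequence`.
#' @inheritParams scan_mres
#' @return MRE tibble (possibly empty).
#' @export
scan_utr <- function(utr, families, peaks = NULL,
                     peak_coords = c("transcript", "genome")) {
  if (!is.data.frame(utr)) utr <- tibble::as_tibble(utr[c(
    "transcript_id", "gene_id", "sequence")])
  scan_mres(utr, families, peaks = peaks, peak_coords = peak_coords)
}

#' Map MRE positions to the unit interval
#'
#' Rescales site start offsets by UTR length so that all spatial features are
#' computed on \[0, 1) regardless of UTR length.
#'
#' @param mres MRE table with `transcript_id` and `position`.
#' @param utr_length a single length, or a named vector of lengths keyed by
#'   `transcript_id`.
#' @return `mres` with `unit_position = position / utr_length` set.
#' @export
normalize_positions <- function(mres, utr_length) {
  if (length(utr_length) == 1L && is.null(names(utr_length))) {
    len <- rep(utr_length, nrow(mres))
  } else {
    len <- unname(utr_length[mres$transcript_id])
  }
  if (any(is.na(len)) || any(len <= 0)) {
    stop("utr_length must be positive and cover every transcript",
         call. = FALSE)
  }
  if (any(mres$position < 0 | mres$position >= len)) {
    stop("MRE position outside [0, utr_length)", call. = FALSE)
  }
  mres$unit_position <- mres$position / len
  mres
}
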