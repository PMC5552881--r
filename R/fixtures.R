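# Self-contained synthetic inputs with controllable ceRNA structure: a
# target gene carrying sites of all its regulating families, planted ceRNAs
# whose shared sites are clustered and/or evenly spaced, and background
# transcripts with uniformly placed sites of random families. Every file the
# pipeline consumes can be produced from one seed.

#' Specification for a synthetic fixture
#'
#' Defaults describe the standard validation corpus: 200 background genes, 3
#' planted ceRNAs, 50 miRNA families of which 10 regulate the target, UTRs
#' of 1.5--3 kb, 8--12 shared sites per planted ceRNA packed evenly into a
#' window of 0.2 UTR lengths, and CLIP-style peaks over every planted site
#' plus random decoy windows.
#'
#' @param n_background_genes background transcripts.
#' @param n_planted_cernas planted true ceRNAs.
#' @param n_families total miRNA families (universe size N).
#' @param n_target_families families regulating the target (K).
#' @param utr_length_range min/max UTR length (nt).
#' @param shared_site_count_range min/max shared sites per planted ceRNA.
#' @param placement `"clustered"` (evenly spaced inside a random window of
#'   `cluster_width`), `"even"` (at `i/(n+1)` across the whole UTR) or
#'   `"uniform"` (no planted spatial structure).
#' @param cluster_width window width for clustered placement, in UTR units.
#' @param background_site_rate Poisson mean of planted random-family sites
#'   per background transcript.
#' @param n_samples expression samples per entity.
#' @param target_mean_expr mean target-gene count; planted ceRNAs are drawn
#'   within 2-fold of it so the fold filter never removes ground truth.
#' @param with_peaks emit transcript-coordinate peaks covering planted sites
#'   plus decoys.
#' @param seed mandatory integer seed.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_background_genes = 200, n_planted_cernas = 3,
                         n_families = 50, n_target_families = 10,
                         utr_length_range = c(1500, 3000),
                         shared_site_count_range = c(8, 12),
                         placement = c("clustered", "even", "uniform"),
                         cluster_width = 0.2, background_site_rate = 4,
                         n_samples = 6, target_mean_expr = 1000,
                         with_peaks = TRUE, seed) {
  if (missing(seed)) stop("fixture_spec requires a seed", call. = FALSE)
  placement <- match.arg(placement)
  stopifnot(n_target_families <= n_families,
            cluster_width > 0, cluster_width <= 1,
            utr_length_range[1] <= utr_length_range[2],
            shared_site_count_range[1] <= shared_site_count_range[2])
  structure(list(
    n_background_genes = n_background_genes,
    n_planted_cernas = n_planted_cernas,
    n_families = n_families,
    n_target_families = n_target_families,
    utr_length_range = utr_length_range,
    shared_site_count_range = shared_site_count_range,
    placement = placement,
    cluster_width = cluster_width,
    background_site_rate = background_site_rate,
    n_samples = n_samples,
    target_mean_expr = target_mean_expr,
    with_peaks = with_peaks,
    seed = as.integer(seed)), class = "fixture_spec")
}

#' Write site patterns into a sequence
#'
#' Overwrites the sequence at the given 0-based offsets with the given
#' pattern strings; offsets must be in bounds and the written intervals must
#' not overlap each other.
#'
#' @param sequence DNA string.
#' @param patterns character vector of site strings.
#' @param positions integer vector of 0-based start offsets, same length.
#' @return modified sequence.
#' @export
plant_sites <- function(sequence, patterns, positions) {
  stopifnot(length(patterns) == length(positions))
  if (length(patterns) == 0L) return(sequence)
  w <- nchar(patterns)
  L <- nchar(sequence)
  if (any(positions < 0L) || any(positions + w > L)) {
    stop("planted site out of bounds", call. = FALSE)
  }
  o <- order(positions)
  if (any(positions[o][-1] < (positions[o] + w[o])[-length(o)])) {
    stop("planted sites overlap", call. = FALSE)
  }
  for (i in seq_along(patterns)) {
    substr(sequence, positions[i] + 1L, positions[i] + w[i]) <- patterns[i]
  }
  sequence
}

# m planted unit positions according to the placement model.
placement_positions <- function(m, placement, cluster_width) {
  switch(placement,
         uniform = sort(stats::runif(m)),
         even = (1:m) / (m + 1),
         clustered = {
           w0 <- stats::runif(1, 0, 1 - cluster_width)
           w0 + cluster_width * (1:m) / (m + 1)
         })
}

# Unit positions -> non-overlapping integer offsets for 8-nt sites.
# A forward pass enforces the minimum gap left to right; a backward pass
# pulls overflowing sites back from the right edge.
unit_to_offsets <- function(u, L, width = 8L) {
  m <- length(u)
  if (m * width > L) stop("more sites than the UTR length permits",
                          call. = FALSE)
  pos <- as.integer(round(u * (L - width)))
  pos <- pmin(pmax(pos, 0L), L - width)
  o <- order(pos)
  pos_s <- pos[o]
  for (i in seq_len(m)[-1]) {
    if (pos_s[i] < pos_s[i - 1] + width) pos_s[i] <- pos_s[i - 1] + width
  }
  pos_s[m] <- min(pos_s[m], L - width)
  for (i in rev(seq_len(m))[-1]) {
    if (pos_s[i] > pos_s[i + 1] - width) pos_s[i] <- pos_s[i + 1] - width
  }
  stopifnot(pos_s[1] >= 0L)
  pos_s[order(o)]  # back to input order (already sorted u in practice)
}

#' Generate a complete synthetic input bundle
#'
#' Builds, from one seed: a miRNA table whose seeds define the families; a
#' Yes/No family status table for the target; UTR sequences for the target
#' (sites of every regulating family), the planted ceRNAs (shared sites with
#' the requested spatial structure) and background genes (random-family
#' sites at uniform positions); per-sample expression counts; optional
#' transcript-coordinate peaks over all planted sites plus decoys; and the
#' ground-truth table.
#'
#' @param spec a [fixture_spec()].
#' @return list of class `cerna_fixture`: `utrs`, `mirnas`, `families`,
#'   `family_status`, `gene_expr`, `peaks` (or `NULL`), `ground_truth`,
#'   `target_gene`, `spec`.
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  site_w <- 8L
  lmin <- spec$utr_length_range[1]
  if (max(spec$shared_site_count_range) * site_w >
      spec$cluster_width * lmin) {
    stop("more sites than the UTR length permits in the cluster window",
         call. = FALSE)
  }

  # families: distinct random seeds; 1-2 members each
  seeds <- character(0)
  while (length(seeds) < spec$n_families) {
    seeds <- unique(c(seeds, vapply(
      seq_len(spec$n_families), function(i)
        paste(sample(c("A", "C", "G", "U"), 7, replace = TRUE),
              collapse = ""), character(1))))
  }
  seeds <- sort(seeds[seq_len(spec$n_families)])
  yes_idx <- sort(sample(spec$n_families, spec$n_target_families))
  mir_rows <- list()
  for (i in seq_len(spec$n_families)) {
    n_mem <- sample(1:2, 1)
    for (j in seq_len(n_mem)) {
      tail_len <- 14L
      mature <- paste0(
        sample(c("A", "C", "G", "U"), 1), seeds[i],
        paste(sample(c("A", "C", "G", "U"), tail_len, replace = TRUE),
              collapse = ""))
      expr <- if (i %in% yes_idx) {
        stats::rlnorm(1, meanlog = log(200), sdlog = 0.5)
      } else {
        stats::rlnorm(1, meanlog = log(50), sdlog = 1.5)
      }
      mir_rows[[length(mir_rows) + 1L]] <- tibble::tibble(
        name = sprintf("mir-%03d%s", i, letters[j]),
        mature_sequence = mature, expression = expr)
    }
  }
  mirnas <- do.call(rbind, mir_rows)
  families <- group_families(mirnas)
  fam_ids <- paste0("fam-", chartr("U", "T", seeds))
  yes_fams <- fam_ids[yes_idx]
  family_status <- tibble::tibble(
    family_id = families$family_id,
    regulates_target = families$family_id %in% yes_fams)
  # 8mer site per family (revcomp of seed + A), keyed by family id
  site8 <- stats::setNames(paste0(rna_revcomp_dna(seeds), "A"), fam_ids)

  target_gene <- "TARGET"
  gene_ids <- c(target_gene,
                sprintf("CERNA%02d", seq_len(spec$n_planted_cernas)),
                sprintf("BG%04d", seq_len(spec$n_background_genes)))
  n_genes <- length(gene_ids)
  lens <- sample(seq(spec$utr_length_range[1], spec$utr_length_range[2]),
                 n_genes, replace = TRUE)
  seqs <- vapply(lens, random_dna, character(1))

  planted <- vector("list", n_genes)  # per gene: data.frame(family, position)
  # target: 1-2 sites of every regulating family, uniform positions
  n_per <- sample(1:2, spec$n_target_families, replace = TRUE)
  fams_t <- rep(yes_fams, n_per)
  u_t <- sort(stats::runif(length(fams_t)))
  pos_t <- unit_to_offsets(u_t, lens[1], site_w)
  planted[[1]] <- data.frame(family = fams_t, position = pos_t)
  # planted ceRNAs: shared sites with spatial structure
  for (g in seq_len(spec$n_planted_cernas)) {
    i <- 1L + g
    m <- sample(seq(spec$shared_site_count_range[1],
                    spec$shared_site_count_range[2]), 1)
    fams <- if (m <= length(yes_fams)) sample(yes_fams, m) else
      c(yes_fams, sample(yes_fams, m - length(yes_fams), replace = TRUE))
    u <- placement_positions(m, spec$placement, spec$cluster_width)
    planted[[i]] <- data.frame(family = sample(fams),
                               position = unit_to_offsets(u, lens[i], site_w))
  }
  # background: Poisson number of random-family sites, uniform positions
  for (g in seq_len(spec$n_background_genes)) {
    i <- 1L + spec$n_planted_cernas + g
    m <- stats::rpois(1, spec$background_site_rate)
    if (m == 0L) { planted[[i]] <- data.frame(family = character(0),
                                              position = integer(0)); next }
    fams <- sample(fam_ids, m, replace = TRUE)
    u <- sort(stats::runif(m))
    planted[[i]] <- data.frame(family = fams,
                               position = unit_to_offsets(u, lens[i], site_w))
  }
  for (i in seq_len(n_genes)) {
    pl <- planted[[i]]
    if (nrow(pl)) {
      seqs[i] <- plant_sites(seqs[i], unname(site8[pl$family]), pl$position)
    }
  }
  utrs <- tibble::tibble(
    transcript_id = paste0(gene_ids, ".1"), gene_id = gene_ids,
    sequence = seqs, length = lens)

  peaks <- NULL
  if (spec$with_peaks) {
    pk_rows <- list()
    for (i in seq_len(n_genes)) {
      pl <- planted[[i]]
      if (nrow(pl)) {
        jit <- sample(5:15, nrow(pl), replace = TRUE)
        pk_rows[[length(pk_rows) + 1L]] <- data.frame(
          transcript_id = utrs$transcript_id[i],
          start = pmax(0L, pl$position - jit),
          end = pmin(lens[i], pl$position + site_w + jit))
      }
      n_decoy <- sample(0:2, 1)
      if (n_decoy > 0L) {
        st <- sample.int(max(1L, lens[i] - 40L), n_decoy) - 1L
        pk_rows[[length(pk_rows) + 1L]] <- data.frame(
          transcript_id = utrs$transcript_id[i],
          start = st, end = pmin(lens[i], st + 40L))
      }
    }
    peaks <- tibble::as_tibble(do.call(rbind, pk_rows))
  }

  mu <- numeric(n_genes)
  mu[1] <- spec$target_mean_expr
  if (spec$n_planted_cernas > 0) {
    mu[2:(1 + spec$n_planted_cernas)] <-
      spec$target_mean_expr * stats::runif(spec$n_planted_cernas, 0.5, 2)
  }
  bg_i <- seq_len(spec$n_background_genes) + 1L + spec$n_planted_cernas
  mu[bg_i] <- stats::rlnorm(spec$n_background_genes,
                            meanlog = log(spec$target_mean_expr), sdlog = 1.2)
  counts <- t(vapply(mu, function(m)
    stats::rnbinom(spec$n_samples, mu = m, size = 20), numeric(spec$n_samples)))
  gene_expr <- tibble::as_tibble(cbind(
    data.frame(gene_id = gene_ids),
    stats::setNames(as.data.frame(counts),
                    paste0("sample", seq_len(spec$n_samples)))))

  is_planted <- gene_ids[-1] %in% gene_ids[seq_len(spec$n_planted_cernas) + 1L]
  n_planted_sites <- vapply(planted[-1], nrow, integer(1))
  ground_truth <- tibble::tibble(
    gene_id = gene_ids[-1],
    planted = is_planted,
    n_planted_sites = n_planted_sites,
    placement = ifelse(is_planted, spec$placement, "uniform"))

  structure(list(utrs = utrs, mirnas = mirnas, families = families,
                 family_status = family_status, gene_expr = gene_expr,
                 peaks = peaks, ground_truth = ground_truth,
                 target_gene = target_gene, spec = spec),
            class = "cerna_fixture")
}

#' Write a fixture bundle to disk
#'
#' Emits `utrs.fa`, `mirnas.tsv`, `family_status.tsv`, `gene_expr.tsv`,
#' `ground_truth.tsv` and, when present, `peaks.bed` (transcript
#' coordinates, BED3 with the transcript id in the chrom column), plus a
#' ready-to-run `run.cfg`.
#'
#' @param fixture a `cerna_fixture` from [generate_fixture()].
#' @param outdir output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_fixture <- function(fixture, outdir) {
  stopifnot(inherits(fixture, "cerna_fixture"))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  tsv <- function(x, f) utils::write.table(
    x, file.path(outdir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  write_utr_fasta(fixture$utrs, file.path(outdir, "utrs.fa"))
  tsv(fixture$mirnas, "mirnas.tsv")
  tsv(data.frame(family_id = fixture$family_status$family_id,
                 regulates_target = ifelse(
                   fixture$family_status$regulates_target, "Yes", "No")),
      "family_status.tsv")
  tsv(fixture$gene_expr, "gene_expr.tsv")
  tsv(fixture$ground_truth, "ground_truth.tsv")
  cfg <- c("utr_fasta = utrs.fa", "mirna_table = mirnas.tsv",
           "family_status = family_status.tsv", "gene_expr = gene_expr.tsv",
           paste("target_gene =", fixture$target_gene))
  if (!is.null(fixture$peaks)) {
    utils::write.table(fixture$peaks, file.path(outdir, "peaks.bed"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    cfg <- c(cfg, "peaks_bed = peaks.bed", "peak_coords = transcript")
  }
  writeLines(cfg, file.path(outdir, "run.cfg"))
  invisible(outdir)
}

#' Run the pipeline directly on an in-memory fixture
#'
#' Scans the fixture's UTRs with its families (restricted to its peaks when
#' present) and calls [cerna_predict()] with default thresholds.
#'
#' @param fixture a `cerna_fixture`.
#' @param ... passed through to [cerna_predict()].
#' @return prediction table.
#' @export
predict_fixture <- function(fixture, ...) {
  stopifnot(inherits(fixture, "cerna_fixture"))
  mres <- scan_mres(fixture$utrs, fixture$families, peaks = fixture$peaks,
                    peak_coords = "transcript")
  cerna_predict(mres, fixture$mirnas, fixture$family_status,
                fixture$gene_expr, fixture$target_gene, ...)
}
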