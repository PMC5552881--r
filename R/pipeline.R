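# End-to-end orchestration: expression filters, candidate universe, both-
# orientation features, ranking and the upper-quantile cut.

#' Filter genes by minimum count
#'
#' A gene is removed only when its count is below `min_count` in every
#' sample; one adequately covered sample keeps it.
#'
#' @param expr expression table: id column (first) plus numeric sample
#'   columns.
#' @param min_count count threshold (default 10).
#' @return character vector of retained gene ids.
#' @export
filter_genes <- function(expr, min_count = 10) {
  if (is.null(expr) || nrow(expr) == 0L) stop("empty expression table",
                                              call. = FALSE)
  m <- as.matrix(expr[, -1, drop = FALSE])
  keep <- apply(m, 1L, function(x) any(x >= min_count))
  as.character(expr[[1]][keep])
}

#' Filter miRNAs by expression quantile
#'
#' miRNAs whose mean expression falls strictly below the `quantile` quantile
#' (linear interpolation, `stats::quantile` type 7) of all miRNAs' mean
#' expression are flagged not expressed.
#'
#' @param expr either a miRNA table with columns `name` and `expression`, or
#'   an expression table (id column + sample columns, averaged per row).
#' @param quantile expression quantile below which a miRNA is dropped
#'   (default 0.05).
#' @return character vector of expressed miRNA names.
#' @export
filter_mirnas <- function(expr, quantile = 0.05) {
  if ("expression" %in% names(expr)) {
    ids <- as.character(expr$name)
    vals <- as.numeric(expr$expression)
  } else {
    ids <- as.character(expr[[1]])
    vals <- rowMeans(as.matrix(expr[, -1, drop = FALSE]))
  }
  if (length(ids) < 20L) {
    warning("fewer than 20 miRNAs; the expression quantile is unstable",
            call. = FALSE)
  }
  thr <- stats::quantile(vals, probs = quantile, type = 7, names = FALSE)
  ids[!(vals < thr)]
}

#' Filter candidates to the expression window around the target
#'
#' ceRNA crosstalk is expected near equimolar abundance, so candidates are
#' kept only when their mean expression is within a `max_fold` fold window
#' of the target's mean (strict inequalities on both sides).
#'
#' @param expr expression table (id column + sample columns).
#' @param target_gene id of the target gene (must be present, nonzero mean).
#' @param max_fold fold-change window half-width (default 10).
#' @return character vector of retained candidate ids (the target itself is
#'   included when present).
#' @export
filter_fold_difference <- function(expr, target_gene, max_fold = 10) {
  ids <- as.character(expr[[1]])
  mu <- rowMeans(as.matrix(expr[, -1, drop = FALSE]))
  it <- match(target_gene, ids)
  if (is.na(it)) stop("target gene ", target_gene,
                      " not in expression table", call. = FALSE)
  if (mu[it] == 0) stop("target gene has zero mean expression", call. = FALSE)
  ratio <- mu / mu[it]
  ids[ratio > 1 / max_fold & ratio < max_fold]
}

#' Flag the upper score quantile
#'
#' @param predictions prediction table with a `score` column.
#' @param q score quantile (default 0.98 marks the top 2 percent).
#' @return `predictions` with logical column `passes_quantile`
#'   (`score >= quantile(score, q)`).
#' @export
quantile_cutoff <- function(predictions, q = 0.98) {
  stopifnot(nrow(predictions) > 0L)
  thr <- stats::quantile(predictions$score, probs = q, type = 7, names = FALSE)
  predictions$passes_quantile <- predictions$score >= thr
  predictions
}

#' Predict and rank candidate ceRNAs of a target gene
#'
#' Runs the full analysis on in-memory objects: miRNA expression filter and
#' family grouping, gene count and fold-window filters, per-candidate
#' features in both orientations (target as source, then roles flipped),
#' reciprocal combination, scoring, empirical p-values, ranking and the
#' upper-quantile flag.
#'
#' For the flipped orientation the candidate's regulating families are taken
#' to be every expressed family with at least one MRE on the candidate, and
#' its features are computed from the target UTR's MREs belonging to those
#' families.
#'
#' @param mres MRE table covering the target and all candidates (from
#'   [scan_mres()] or [read_mre_table()]); `unit_position` must be set.
#' @param mirnas miRNA table (`name`, `mature_sequence`, `expression`).
#' @param family_status table with `family_id` and `regulates_target`
#'   (logical or Yes/No) for the target gene.
#' @param gene_expr gene expression table (id column + sample columns).
#' @param target_gene target gene id.
#' @param min_count gene count filter threshold (default 10).
#' @param mirna_quantile miRNA expression quantile cut (default 0.05).
#' @param max_fold expression fold window around the target (default 10).
#' @param score_quantile upper score quantile to flag (default 0.98).
#' @param isoform_mode `"best"` keeps each gene's best-scoring isoform,
#'   `"all"` reports every transcript.
#' @return tibble of class `cerna_predictions`, sorted by decreasing score
#'   (ties broken by gene id): directional features `p1_gt..p5_gt` and
#'   `p1_tg..p5_tg`, combined `p1..p5`, `score`, `empirical_p`, `rank`,
#'   `passes_quantile`, `n_shared_sites`, `k_shared_families`. Empty (with a
#'   warning) when no candidate survives the filters.
#' @export
cerna_predict <- function(mres, mirnas, family_status, gene_expr, target_gene,
                          min_count = 10, mirna_quantile = 0.05,
                          max_fold = 10, score_quantile = 0.98,
                          isoform_mode = c("best", "all")) {
  isoform_mode <- match.arg(isoform_mode)
  if (!target_gene %in% mres$gene_id) {
    stop("target gene ", target_gene, " has no annotated MREs", call. = FALSE)
  }
  if (!"unit_position" %in% names(mres)) {
    stop("MRE table lacks unit_position; run normalize_positions()",
         call. = FALSE)
  }

  expressed_mirnas <- filter_mirnas(mirnas, quantile = mirna_quantile)
  families <- group_families(mirnas)
  families$expressed <- vapply(
    families$members, function(m) any(m %in% expressed_mirnas), logical(1))
  expressed_fams <- families$family_id[families$expressed]

  if (!is.logical(family_status$regulates_target)) {
    family_status$regulates_target <-
      toupper(as.character(family_status$regulates_target)) %in%
      c("YES", "TRUE", "1")
  }
  target_fams <- intersect(
    family_status$family_id[family_status$regulates_target], expressed_fams)
  if (length(target_fams) == 0L) {
    stop("no expressed family regulates ", target_gene, call. = FALSE)
  }

  kept_genes <- filter_genes(gene_expr, min_count = min_count)
  if (!target_gene %in% kept_genes) {
    stop("target gene ", target_gene, " fails the expression filter",
         call. = FALSE)
  }
  window_genes <- filter_fold_difference(
    gene_expr[gene_expr[[1]] %in% kept_genes, , drop = FALSE],
    target_gene, max_fold = max_fold)

  # target transcript: the isoform carrying the most regulating-family MREs
  tgt_tx_all <- unique(mres$transcript_id[mres$gene_id == target_gene])
  n_reg <- vapply(tgt_tx_all, function(tx) {
    sum(mres$transcript_id == tx & mres$family_id %in% target_fams)
  }, integer(1))
  if (max(n_reg) == 0L) {
    stop("target gene has no MRE from a regulating family", call. = FALSE)
  }
  target_tx <- tgt_tx_all[which.max(n_reg)]

  cand <- unique(mres[mres$gene_id %in% setdiff(window_genes, target_gene),
                      c("transcript_id", "gene_id")])
  if (nrow(cand) == 0L) {
    warning("no candidate transcripts survive the filters", call. = FALSE)
    return(empty_predictions())
  }

  mres_exp <- mres[mres$family_id %in% expressed_fams, , drop = FALSE]
  fam_by_tx <- split(mres_exp$family_id, mres_exp$transcript_id)

  rows <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    tx <- cand$transcript_id[i]
    prof_gt <- shared_site_profile(mres_exp, tx, target_fams, expressed_fams)
    fv_gt <- directional_features(prof_gt)
    cand_fams <- unique(fam_by_tx[[tx]]) %||% character(0)
    prof_tg <- shared_site_profile(mres_exp, target_tx, cand_fams,
                                   expressed_fams)
    fv_tg <- directional_features(prof_tg)
    pc <- combine_reciprocal(fv_gt, fv_tg)
    rows[[i]] <- c(fv_gt, fv_tg, pc,
                   score = cerna_score(pc),
                   n_shared_sites = prof_gt$n_shared_sites,
                   k_shared_families = prof_gt$k_shared_families)
  }
  mat <- do.call(rbind, rows)
  colnames(mat) <- c(paste0("p", 1:5, "_gt"), paste0("p", 1:5, "_tg"),
                     paste0("p", 1:5), "score",
                     "n_shared_sites", "k_shared_families")
  res <- cbind(cand, tibble::as_tibble(mat))

  if (isoform_mode == "best") {
    res <- res[order(res$gene_id, -res$score, res$transcript_id), ]
    res <- res[!duplicated(res$gene_id), , drop = FALSE]
  }
  res$empirical_p <- empirical_pvalues(res$score)
  res <- res[order(-res$score, res$gene_id), , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  res <- quantile_cutoff(res, q = score_quantile)
  rownames(res) <- NULL
  res <- tibble::as_tibble(res)
  class(res) <- c("cerna_predictions", class(res))
  res
}

empty_predictions <- function() {
  cols <- c("transcript_id", "gene_id", paste0("p", 1:5, "_gt"),
            paste0("p", 1:5, "_tg"), paste0("p", 1:5), "score",
            "n_shared_sites", "k_shared_families", "empirical_p", "rank",
            "passes_quantile")
  out <- tibble::as_tibble(stats::setNames(
    c(list(character(), character()),
      replicate(length(cols) - 2L, numeric(), simplify = FALSE)), cols))
  out$passes_quantile <- logical(0)
  class(out) <- c("cerna_predictions", class(out))
  out
}

#' Run the prediction pipeline from a configuration
#'
#' File-based front end to [cerna_predict()]: reads the inputs named in a
#' `key=value` configuration (or an equivalent named list), scans MREs when
#' a UTR FASTA is given instead of a precomputed MRE table, runs the
#' prediction, and writes a ranked TSV plus a JSON run manifest.
#'
#' Recognised keys: `utr_fasta` or `mre_table`; `mirna_table`;
#' `family_status`; `gene_expr`; `target_gene`; optional `peaks_bed`,
#' `peak_coords` (`transcript`|`genome`), `min_count`, `mirna_quantile`,
#' `max_fold`, `score_quantile`, `isoform_mode`, `out_prefix`.
#'
#' @param config path to a `key=value` text file, or a named list.
#' @param outdir output directory (created if missing); default `"."`.
#' @return the prediction table, invisibly.
#' @export
run_pipeline <- function(config, outdir = ".") {
  cfg <- if (is.character(config)) read_run_config(config) else config
  need <- c("mirna_table", "family_status", "gene_expr", "target_gene")
  missing_keys <- setdiff(need, names(cfg))
  if (length(missing_keys)) {
    stop("config lacks: ", paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  mirnas <- read_mirna_table(cfg$mirna_table)
  fam_status <- read_family_status(cfg$family_status)
  gene_expr <- read_expression_table(cfg$gene_expr)
  if (!is.null(cfg$mre_table)) {
    mres <- read_mre_table(cfg$mre_table)
    if (!"unit_position" %in% names(mres)) {
      stop("precomputed MRE table must contain unit_position", call. = FALSE)
    }
  } else if (!is.null(cfg$utr_fasta)) {
    utrs <- read_utr_fasta(cfg$utr_fasta)
    peaks <- if (!is.null(cfg$peaks_bed)) {
      pk <- read_peaks_bed(cfg$peaks_bed)
      if ((cfg$peak_coords %||% "transcript") == "transcript") {
        names(pk)[names(pk) == "chrom"] <- "transcript_id"
      }
      pk
    }
    mres <- scan_mres(utrs, group_families(mirnas), peaks = peaks,
                      peak_coords = cfg$peak_coords %||% "transcript")
  } else {
    stop("config needs utr_fasta or mre_table", call. = FALSE)
  }
  pred <- cerna_predict(
    mres, mirnas, fam_status, gene_expr, cfg$target_gene,
    min_count = as.numeric(cfg$min_count %||% 10),
    mirna_quantile = as.numeric(cfg$mirna_quantile %||% 0.05),
    max_fold = as.numeric(cfg$max_fold %||% 10),
    score_quantile = as.numeric(cfg$score_quantile %||% 0.98),
    isoform_mode = cfg$isoform_mode %||% "best")
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  prefix <- cfg$out_prefix %||% "cerna"
  out_tsv <- file.path(outdir, paste0(prefix, "_predictions.tsv"))
  utils::write.table(pred, out_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- list(
    package = "cernascan",
    version = as.character(utils::packageVersion("cernascan")),
    target_gene = cfg$target_gene,
    thresholds = list(
      min_count = as.numeric(cfg$min_count %||% 10),
      mirna_quantile = as.numeric(cfg$mirna_quantile %||% 0.05),
      max_fold = as.numeric(cfg$max_fold %||% 10),
      score_quantile = as.numeric(cfg$score_quantile %||% 0.98)),
    inputs = cfg[intersect(names(cfg), c("utr_fasta", "mre_table",
                                         "mirna_table", "family_status",
                                         "gene_expr", "peaks_bed"))],
    n_predictions = nrow(pred))
  jsonlite::write_json(manifest,
                       file.path(outdir, paste0(prefix, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(pred)
}

#' Read a key=value run configuration file
#'
#' Lines are `key = value`; blank lines and `#` comments are ignored.
#'
#' @param path configuration file.
#' @return named list of character values.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad)) stop("malformed config line: ", lines[bad][1], call. = FALSE)
  stats::setNames(lapply(kv, function(m) trimws(m[3])),
                  vapply(kv, function(m) trimws(m[2]), character(1)))
}
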