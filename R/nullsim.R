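# Uniform-placement null ensembles, Kolmogorov-Smirnov feature-relevance
# comparison, and the shuffled-UTR uniformity check behind the uniform null.

#' Simulate uniformly placed MREs matched to observed count and length
#' distributions
#'
#' For each simulated transcript, a site count is resampled from the
#' observed per-transcript MRE counts, a UTR length from the observed
#' lengths, and that many positions are drawn i.i.d. Uniform(0, 1).
#'
#' @param count_distribution integer vector of observed per-transcript MRE
#'   counts (resampled with replacement).
#' @param lengths numeric vector of observed UTR lengths (resampled; carried
#'   as metadata, positions are already unit-interval).
#' @param n_transcripts number of simulated transcripts.
#' @param seed integer seed; the ensemble is reproducible byte for byte.
#' @return object of class `null_ensemble`: list with `replicates` (list of
#'   sorted unit-position vectors), `counts`, `lengths`, `seed`.
#' @export
simulate_random_mres <- function(count_distribution, lengths, n_transcripts,
                                 seed) {
  if (length(count_distribution) == 0L) stop("empty count distribution",
                                             call. = FALSE)
  stopifnot(!missing(seed))
  set.seed(seed)
  counts <- sample(as.integer(count_distribution), n_transcripts,
                   replace = TRUE)
  lens <- sample(as.numeric(lengths), n_transcripts, replace = TRUE)
  reps <- lapply(counts, function(k) sort(stats::runif(k)))
  structure(list(replicates = reps, counts = counts, lengths = lens,
                 seed = seed),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat("null_ensemble:", length(x$replicates), "transcripts, mean",
      round(mean(x$counts), 2), "sites each (seed", paste0(x$seed, ")\n"))
  invisible(x)
}

#' Spatial feature p-values for every transcript of an ensemble
#'
#' @param ensemble a `null_ensemble`, or a plain list of unit-position
#'   vectors.
#' @return tibble with one row per transcript: `n_sites`, `span`,
#'   `distances`, `evenness` (the three spatial feature p-values).
#' @export
ensemble_features <- function(ensemble) {
  reps <- if (inherits(ensemble, "null_ensemble")) ensemble$replicates
          else ensemble
  mat <- t(vapply(reps, spatial_features, numeric(3)))
  tibble::tibble(n_sites = lengths(reps),
                 span = mat[, "span"],
                 distances = mat[, "distances"],
                 evenness = mat[, "evenness"])
}

#' Kolmogorov-Smirnov comparison of feature distributions
#'
#' Two-sample KS test per feature column between observed and null feature
#' tables, answering whether real site arrangements are distinguishable
#' from uniform placement.
#'
#' @param real_features,null_features data frames with matching numeric
#'   feature columns (e.g. from [ensemble_features()]); each needs >= 10
#'   rows.
#' @param features columns to compare; default: all shared numeric columns
#'   except `n_sites`.
#' @return tibble `feature`, `D`, `p_value`.
#' @export
ks_feature_comparison <- function(real_features, null_features,
                                  features = NULL) {
  if (is.null(features)) {
    features <- setdiff(
      intersect(names(real_features), names(null_features)), "n_sites")
    features <- features[vapply(real_features[features], is.numeric,
                                logical(1))]
  }
  if (nrow(real_features) < 10L || nrow(null_features) < 10L) {
    stop("need >= 10 observations per group", call. = FALSE)
  }
  rows <- lapply(features, function(f) {
    x <- real_features[[f]]; y <- null_features[[f]]
    if (length(unique(x)) == 1L && length(unique(y)) == 1L) {
      warning("feature ", f, " is constant in both samples", call. = FALSE)
    }
    kt <- suppressWarnings(stats::ks.test(
      x, y, exact = length(x) <= 25 && length(y) <= 25))
    tibble::tibble(feature = f, D = unname(kt$statistic),
                   p_value = kt$p.value)
  })
  do.call(rbind, rows)
}

#' Shuffled-UTR uniformity check for one site
#'
#' Support for the uniform null: shuffles a UTR sequence (mononucleotide
#' shuffle, exact composition preserved) `n_shuffles` times, scans each
#' shuffle for a site string (overlapping matches included), pools the
#' normalized match positions, and KS-tests them against Uniform(0, 1).
#'
#' @param utr_sequence DNA string.
#' @param site_string DNA site to scan for (e.g. a family's 7mer-m8 site).
#' @param n_shuffles number of shuffles (default 10000).
#' @param seed integer seed.
#' @return list with `positions` (pooled normalized match starts),
#'   `n_matches` (per shuffle), `ks_p`, `ks_D` (`NA` when no match at all).
#' @export
shuffle_utr_check <- function(utr_sequence, site_string, n_shuffles = 10000,
                              seed) {
  stopifnot(!missing(seed))
  utr_sequence <- toupper(utr_sequence)
  site_string <- toupper(site_string)
  w <- nchar(site_string)
  if (w > nchar(utr_sequence)) stop("site longer than sequence",
                                    call. = FALSE)
  set.seed(seed)
  chars <- strsplit(utr_sequence, "")[[1]]
  pat <- Biostrings::DNAString(site_string)
  max_start <- length(chars) - w  # 0-based starts span 0..max_start
  pos <- vector("list", n_shuffles)
  n_matches <- integer(n_shuffles)
  for (i in seq_len(n_shuffles)) {
    shuf <- Biostrings::DNAString(paste(sample(chars), collapse = ""))
    hits <- Biostrings::start(Biostrings::matchPattern(pat, shuf)) - 1L
    n_matches[i] <- length(hits)
    if (length(hits)) {
      pos[[i]] <- if (max_start > 0L) hits / max_start else rep(0, length(hits))
    }
  }
  pooled <- unlist(pos, use.names = FALSE)
  if (length(pooled) == 0L) {
    warning("site never found in any shuffle", call. = FALSE)
    return(list(positions = numeric(0), n_matches = n_matches,
                ks_p = NA_real_, ks_D = NA_real_))
  }
  kt <- suppressWarnings(stats::ks.test(pooled, "punif"))
  list(positions = pooled, n_matches = n_matches,
       ks_p = kt$p.value, ks_D = unname(kt$statistic))
}
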