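# Five directional significance features for a (source gene -> candidate
# transcript) pair, their reciprocal combination, the score, and empirical
# p-values. Notation: on the candidate's UTR, n is the number of shared
# (source-regulating-family) MREs mapped to [0,1]; d_1..d_{n-1} are the gaps
# between successive sorted positions.

#' Binomial test for the number of shared MREs
#'
#' Each MRE on the candidate transcript is a Bernoulli trial; a success is an
#' MRE whose miRNA family also regulates the source gene. The success
#' probability is the fraction of expressed families that regulate the
#' source, fixed per run.
#'
#' @param k observed number of shared MREs.
#' @param n total number of MREs on the transcript.
#' @param p success probability in (0, 1).
#' @return Upper-tail p-value `Pr(X >= k)` for `X ~ Binomial(n, p)`; 1 when
#'   `n = 0` (no evidence).
#' @export
binomial_shared_mre_pvalue <- function(k, n, p) {
  if (p <= 0 || p >= 1) stop("p must be in (0, 1)", call. = FALSE)
  if (n == 0L) return(1)
  stopifnot(k >= 0, k <= n)
  if (k == 0L) return(1)
  stats::pbinom(k - 1, size = n, prob = p, lower.tail = FALSE)
}

#' Hypergeometric test for the number of shared miRNA families
#'
#' Of `N` expressed miRNA families, `K` regulate the source gene; the
#' candidate transcript carries sites of `n` families, `k` of them shared
#' with the source. Significance is the upper tail
#' `Pr(X >= k) = sum_{i=k}^{min(K,n)} C(K,i) C(N-K,n-i) / C(N,n)`.
#'
#' @param k shared family count.
#' @param K source-regulating family count.
#' @param n candidate family count.
#' @param N expressed family universe size.
#' @return Upper-tail p-value in (0, 1].
#' @export
hypergeom_family_pvalue <- function(k, K, n, N) {
  if (k < 0 || k > min(K, n) || K > N || n > N) {
    stop("require 0 <= k <= min(K, n) and K, n <= N", call. = FALSE)
  }
  if (k == 0L) return(1)
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Span test for shared MRE positions
#'
#' Under the uniform null the span `S = X_(n) - X_(1)` of `n` unit-interval
#' positions has CDF `Pr(S <= s0) = n (1 - s0) s0^(n-1) + s0^n`; a small
#' value flags sites packed into a short stretch of the UTR.
#'
#' @param positions unit-interval positions of the shared MREs (any order).
#' @return `Pr(S <= s0)` with `s0` the observed span; 1 when fewer than two
#'   sites (feature undefined).
#' @export
span_pvalue <- function(positions) {
  n <- length(positions)
  if (n < 2L) return(1)
  stopifnot(all(positions >= 0), all(positions <= 1))
  s0 <- max(positions) - min(positions)
  clamp01(n * (1 - s0) * s0^(n - 1) + s0^n)
}

#' Successive-distance test for shared MRE positions
#'
#' Joint probability that every gap between successive order statistics of
#' `n` uniform points is at most its observed value:
#' `n! * prod(d_j) * (1 - sum(d_i) / 2)`, evaluated in log space and clamped
#' to \[0, 1\] (the product form can exceed 1 in corners of its domain).
#' Small values flag tightly clustered sites; a zero gap (two sites at one
#' offset) gives 0.
#'
#' @param d successive distances `d_1..d_{n-1}` (so `n = length(d) + 1`
#'   sites), each >= 0 with `sum(d) <= 1`.
#' @return p-value in \[0, 1\]; 1 when `d` is empty.
#' @export
distances_pvalue <- function(d) {
  if (length(d) == 0L) return(1)
  if (any(d < 0)) stop("distances must be non-negative", call. = FALSE)
  if (sum(d) > 1 + 1e-9) stop("distances must sum to at most 1", call. = FALSE)
  if (any(d == 0)) return(0)
  n <- length(d) + 1L
  lp <- lfactorial(n) + sum(log(d)) + log1p(-0.5 * sum(d))
  clamp01(exp(lp))
}

# Moments of Y_i = (U_i - 1/(n+1))^2 for one uniform spacing U_i ~ Beta(1, n).
spacing_moments <- function(n) {
  list(e_y = n / ((n + 1)^2 * (n + 2)),
       var_y = 4 * n * (2 * n^3 + 2 * n^2 - 3 * n + 3) /
         ((n + 1)^4 * (n + 2)^2 * (n + 3) * (n + 4)))
}

#' Evenness test for shared MRE positions
#'
#' Measures deviation from perfectly even spacing at `i/(n+1)`. With
#' `Y_i = (d_i - 1/(n+1))^2` summed over the `n - 1` observed gaps, a normal
#' approximation gives `z = (sum(Y) - (n-1) E[Y]) / sqrt((n-1) Var(Y))` with
#' `E[Y] = n / ((n+1)^2 (n+2))` and
#' `Var(Y) = 4n(2n^3 + 2n^2 - 3n + 3) / ((n+1)^4 (n+2)^2 (n+3) (n+4))`.
#' The lower tail `Phi(z)` is returned, so near-even spacing yields a small
#' p-value. The approximation treats gaps as independent; see the package
#' vignette for its calibration under the uniform null.
#'
#' @param d successive distances between sorted shared sites.
#' @param n number of shared sites (`length(d) + 1`).
#' @return Lower-tail normal p-value; 1 when `n < 3` (needs >= 2 gaps).
#' @export
evenness_pvalue <- function(d, n = length(d) + 1L) {
  if (n < 3L) return(1)
  stopifnot(length(d) == n - 1L, all(d >= 0))
  mom <- spacing_moments(n)
  s_y <- sum((d - 1 / (n + 1))^2)
  z <- (s_y - (n - 1) * mom$e_y) / sqrt((n - 1) * mom$var_y)
  stats::pnorm(z)
}

#' Build the shared-site profile for an ordered (source, candidate) pair
#'
#' Collects, from an MRE table, everything the five tests need for the pair:
#' the candidate's MREs belonging to families that regulate the source gene
#' (the shared MREs, with multiplicity), plus the family counts for the
#' hypergeometric test.
#'
#' @param mres MRE table (as from [scan_mres()], with `unit_position`).
#' @param transcript candidate transcript id.
#' @param source_families character vector of family ids regulating the
#'   source gene.
#' @param expressed_families the universe of expressed family ids (size `N`).
#' @return An object of class `shared_site_profile`: a list with
#'   `unit_positions` (sorted), `n_shared_sites`, `n_total_sites`,
#'   `k_shared_families`, `K_source_families`, `n_transcript_families`,
#'   `N_total_families`.
#' @export
shared_site_profile <- function(mres, transcript, source_families,
                                expressed_families) {
  source_families <- intersect(source_families, expressed_families)
  mt <- mres[mres$transcript_id == transcript &
               mres$family_id %in% expressed_families, , drop = FALSE]
  shared <- mt[mt$family_id %in% source_families, , drop = FALSE]
  structure(list(
    transcript = transcript,
    unit_positions = sort(shared$unit_position),
    n_shared_sites = nrow(shared),
    n_total_sites = nrow(mt),
    k_shared_families = length(unique(shared$family_id)),
    K_source_families = length(source_families),
    n_transcript_families = length(unique(mt$family_id)),
    N_total_families = length(expressed_families)),
    class = "shared_site_profile")
}

# p-value floor applied before logs so scores stay finite.
P_FLOOR <- 1e-300

#' Compute the five directional features for a profile
#'
#' @param profile a [shared_site_profile()].
#' @return named numeric vector `c(p1, p2, p3, p4, p5)`: binomial shared-MRE,
#'   hypergeometric shared-family, span, successive-distance and evenness
#'   p-values. Degenerate cases (too few shared sites, empty transcript)
#'   return 1 for the affected feature; values are floored at 1e-300.
#' @export
directional_features <- function(profile) {
  stopifnot(inherits(profile, "shared_site_profile"))
  N <- profile$N_total_families
  K <- profile$K_source_families
  pos <- profile$unit_positions
  d <- if (length(pos) >= 2L) diff(pos) else numeric(0)
  p <- c(
    p1 = if (K > 0 && K < N) {
      binomial_shared_mre_pvalue(profile$n_shared_sites,
                                 profile$n_total_sites, K / N)
    } else 1,
    p2 = hypergeom_family_pvalue(profile$k_shared_families, K,
                                 profile$n_transcript_families, N),
    p3 = span_pvalue(pos),
    p4 = if (length(pos) >= 2L) distances_pvalue(d) else 1,
    p5 = evenness_pvalue(d, n = length(pos)))
  pmin(pmax(p, P_FLOOR), 1)
}

#' Combine the two orientations of a pair
#'
#' Elementwise product of the features computed with the source gene as
#' target and with the roles flipped; symmetric in its arguments.
#'
#' @param fv_gt,fv_tg length-5 feature vectors from [directional_features()].
#' @return length-5 combined vector.
#' @export
combine_reciprocal <- function(fv_gt, fv_tg) {
  stopifnot(length(fv_gt) == 5L, length(fv_tg) == 5L)
  unname(fv_gt) * unname(fv_tg)
}

#' Score from combined features
#'
#' `s = -(1/5) * sum(log(p_i))` over the five combined features, with a
#' 1e-300 floor before the log.
#'
#' @param p_comb length-5 vector of combined feature p-values.
#' @return non-negative score; 0 iff all features equal 1.
#' @export
cerna_score <- function(p_comb) {
  stopifnot(length(p_comb) == 5L)
  -mean(log(pmax(P_FLOOR, pmin(1, p_comb))))
}

#' Empirical p-values from the score distribution
#'
#' `p_emp(t) = #\{t' : s(t') >= s(t)\} / M` over all M candidates, so the top
#' score gets `1/M` and ties share the more conservative value.
#'
#' @param scores numeric vector of candidate scores.
#' @return vector of empirical p-values in (0, 1].
#' @export
empirical_pvalues <- function(scores) {
  if (length(scores) == 0L) stop("empty score list", call. = FALSE)
  m <- length(scores)
  (m - rank(scores, ties.method = "min") + 1) / m
}

#' Spatial feature p-values for a bare position set
#'
#' Helper used by the null simulator and relevance checks: computes the
#' span, successive-distance and evenness p-values for one set of
#' unit-interval positions.
#'
#' @param positions unit-interval positions.
#' @return named vector `c(span=, distances=, evenness=)`.
#' @export
spatial_features <- function(positions) {
  pos <- sort(positions)
  d <- if (length(pos) >= 2L) diff(pos) else numeric(0)
  c(span = span_pvalue(pos),
    distances = if (length(d)) distances_pvalue(d) else 1,
    evenness = evenness_pvalue(d, n = length(pos)))
}
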