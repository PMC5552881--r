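test_that("binomial shared-MRE tail matches direct pmf summation", {
  expect_equal(binomial_shared_mre_pvalue(0, 10, 0.3), 1)
  expect_equal(binomial_shared_mre_pvalue(5, 0, 0.3), 1)
  expect_equal(binomial_shared_mre_pvalue(2, 2, 0.5), 0.25)
  expect_error(binomial_shared_mre_pvalue(1, 2, 1.2), "in \\(0, 1\\)")
  expect_error(binomial_shared_mre_pvalue(1, 2, 0), "in \\(0, 1\\)")

  # enumeration oracle: explicit choose() summation, independent of pbinom
  tail_sum <- function(k, n, p) {
    i <- k:n
    sum(choose(n, i) * p^i * (1 - p)^(n - i))
  }
  expect_equal(binomial_shared_mre_pvalue(3, 10, 0.2), tail_sum(3, 10, 0.2),
               tolerance = 1e-12)
  for (n in c(1, 5, 12, 20)) {
    for (p in c(0.1, 0.5, 0.8)) {
      for (k in 0:n) {
        expect_equal(binomial_shared_mre_pvalue(k, n, p), tail_sum(k, n, p),
                     tolerance = 1e-12)
      }
    }
  }
  # upper tail + complementary lower tail = 1
  expect_equal(binomial_shared_mre_pvalue(4, 9, 0.3) +
                 stats::pbinom(3, 9, 0.3), 1, tolerance = 1e-12)
})

test_that("hypergeometric shared-family tail matches exhaustive draws", {
  expect_equal(hypergeom_family_pvalue(0, 5, 3, 20), 1)
  expect_equal(hypergeom_family_pvalue(3, 3, 3, 3), 1)
  expect_equal(hypergeom_family_pvalue(2, 2, 2, 4), 1 / 6, tolerance = 1e-12)
  expect_error(hypergeom_family_pvalue(3, 2, 3, 10), "k <= min")
  expect_error(hypergeom_family_pvalue(1, 11, 3, 10), "N")

  # enumerate all C(N, n) draws; count overlap with the K marked families
  enum_tail <- function(k, K, n, N) {
    draws <- utils::combn(N, n)
    mean(colSums(draws <= K) >= k)
  }
  expect_equal(hypergeom_family_pvalue(2, 4, 3, 9), enum_tail(2, 4, 3, 9),
               tolerance = 1e-12)
  # full support sums to one
  N <- 10; K <- 4; n <- 5
  probs <- vapply(0:min(K, n), function(k)
    stats::dhyper(k, K, N - K, n), numeric(1))
  expect_equal(sum(probs), 1, tolerance = 1e-12)
  expect_equal(hypergeom_family_pvalue(0, K, n, N), 1)
})

test_that("span p-value follows the closed form", {
  expect_equal(span_pvalue(c(0, 1)), 1)
  expect_equal(span_pvalue(c(0.2, 0.7)), 0.75)          # n=2, s0=0.5
  expect_equal(span_pvalue(c(0.1, 0.35, 0.6)), 0.5)     # n=3: 3*.5*.25+.125
  expect_equal(span_pvalue(0.4), 1)                     # undefined below n=2
  expect_equal(span_pvalue(numeric(0)), 1)
  expect_error(span_pvalue(c(-0.1, 0.5)))
  # closed form for arbitrary n
  pos <- seq(0.1, 0.7, length.out = 6)
  s0 <- 0.6; n <- 6
  expect_equal(span_pvalue(pos), n * (1 - s0) * s0^(n - 1) + s0^n,
               tolerance = 1e-12)
})

test_that("successive-distance p-value evaluates the joint product form", {
  expect_equal(distances_pvalue(1), 1)                  # 2*1*(1-0.5)
  expect_equal(distances_pvalue(0.5), 0.75)             # 2*0.5*0.75
  expect_equal(distances_pvalue(c(0.2, 0, 0.1)), 0)     # vanishing gap
  expect_equal(distances_pvalue(numeric(0)), 1)
  expect_error(distances_pvalue(c(0.2, -0.1)), "non-negative")
  expect_error(distances_pvalue(c(0.8, 0.5)), "at most 1")
  # n=3 by hand: 3! * d1 * d2 * (1 - (d1+d2)/2)
  expect_equal(distances_pvalue(c(0.1, 0.2)),
               6 * 0.1 * 0.2 * (1 - 0.15), tolerance = 1e-12)
  # log-space evaluation stays finite and clamped for larger n
  set.seed(1)
  for (i in 1:50) {
    n <- sample(2:30, 1)
    d <- diff(sort(stats::runif(n)))
    p <- distances_pvalue(d)
    expect_true(is.finite(p) && p >= 0 && p <= 1)
  }
})

test_that("evenness moments match the printed formulas and integration", {
  mom3 <- cernascan:::spacing_moments(3)
  expect_equal(mom3$e_y, 3 / 80)        # 0.0375
  # cross-check E[Y] against numeric integration of f_U(t) = n (1-t)^(n-1)
  for (n in c(3, 5, 10)) {
    mom <- cernascan:::spacing_moments(n)
    ey_num <- stats::integrate(function(t)
      (t - 1 / (n + 1))^2 * n * (1 - t)^(n - 1), 0, 1)$value
    expect_equal(mom$e_y, ey_num, tolerance = 1e-8)
    ey2_num <- stats::integrate(function(t)
      ((t - 1 / (n + 1))^2 - mom$e_y)^2 * n * (1 - t)^(n - 1), 0, 1)$value
    expect_equal(mom$var_y, ey2_num, tolerance = 1e-8)
  }
})

test_that("evenness p-value rewards regular spacing", {
  n <- 8
  even <- (1:n) / (n + 1)
  p_even <- evenness_pvalue(diff(even), n = n)
  expect_lt(p_even, 0.5)               # minimum of the deviation statistic
  # clumped sites sit in the upper tail relative to even ones
  clumped <- c(0.01, 0.02, 0.03, 0.04, 0.9, 0.92, 0.94, 0.99)
  expect_gt(evenness_pvalue(diff(sort(clumped)), n = n), p_even)
  expect_equal(evenness_pvalue(numeric(0), n = 1), 1)
  expect_equal(evenness_pvalue(0.3, n = 2), 1)
})

test_that("directional features compose the per-test p-values", {
  mres <- make_mre_table(
    rep("t1.1", 5),
    c("famA", "famA", "famB", "famC", "famX"),
    c(0.10, 0.20, 0.30, 0.42, 0.80))
  expressed <- c("famA", "famB", "famC", "famX", "famY", "famZ")
  prof <- shared_site_profile(mres, "t1.1",
                              source_families = c("famA", "famB", "famC"),
                              expressed_families = expressed)
  expect_equal(prof$n_shared_sites, 4L)
  expect_equal(prof$n_total_sites, 5L)
  expect_equal(prof$k_shared_families, 3L)
  expect_equal(prof$K_source_families, 3L)
  expect_equal(prof$n_transcript_families, 4L)
  expect_equal(prof$N_total_families, 6L)

  fv <- directional_features(prof)
  pos <- c(0.10, 0.20, 0.30, 0.42)
  expect_equal(unname(fv["p1"]),
               binomial_shared_mre_pvalue(4, 5, 3 / 6))
  expect_equal(unname(fv["p2"]), hypergeom_family_pvalue(3, 3, 4, 6))
  expect_equal(unname(fv["p3"]), span_pvalue(pos))
  expect_equal(unname(fv["p4"]), distances_pvalue(diff(pos)))
  expect_equal(unname(fv["p5"]), evenness_pvalue(diff(pos), n = 4))

  # no shared sites -> completely uninformative vector
  prof0 <- shared_site_profile(mres, "t1.1",
                               source_families = "famQ",
                               expressed_families = c(expressed, "famQ"))
  expect_equal(unname(directional_features(prof0)), rep(1, 5))

  # discovery order does not matter
  prof_perm <- shared_site_profile(mres[c(4, 1, 5, 3, 2), ], "t1.1",
                                   source_families = c("famA", "famB", "famC"),
                                   expressed_families = expressed)
  expect_equal(directional_features(prof_perm), fv)
})

test_that("reciprocal combination is an elementwise symmetric product", {
  ones <- rep(1, 5)
  v <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  expect_equal(combine_reciprocal(ones, v), v)
  expect_equal(combine_reciprocal(c(0.1, ones[-1]), c(0.2, ones[-1]))[1],
               0.02)
  set.seed(3)
  for (i in 1:20) {
    a <- stats::runif(5); b <- stats::runif(5)
    expect_identical(combine_reciprocal(a, b), combine_reciprocal(b, a))
  }
})

test_that("the score is the average negative log of combined features", {
  expect_equal(cerna_score(rep(1, 5)), 0)
  expect_equal(cerna_score(rep(exp(-1), 5)), 1)
  expect_equal(cerna_score(rep(exp(-5), 5)), 5)
  # monotone: shrinking any entry raises the score
  p <- c(0.2, 0.4, 0.6, 0.8, 1)
  s0 <- cerna_score(p)
  for (i in 1:5) {
    q <- p; q[i] <- q[i] / 2
    expect_gt(cerna_score(q), s0)
  }
  # a zero entry is floored, not infinite
  expect_true(is.finite(cerna_score(c(0, 1, 1, 1, 1))))
})

test_that("empirical p-values count ties as at least as extreme", {
  expect_equal(empirical_pvalues(c(3, 2, 1)), c(1 / 3, 2 / 3, 1))
  expect_equal(empirical_pvalues(rep(2.5, 4)), rep(1, 4))
  expect_equal(empirical_pvalues(c(5, 5, 1))[1:2], rep(2 / 3, 2))
  expect_error(empirical_pvalues(numeric(0)), "empty")
  set.seed(4)
  s <- stats::rnorm(101)
  p <- empirical_pvalues(s)
  expect_true(all(p > 0 & p <= 1))
  expect_equal(p[which.max(s)], 1 / 101)
})
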