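test_that("miRNAs sharing a seed collapse into one family", {
  mirnas <- data.frame(
    name = c("mir-a", "mir-b", "mir-c"),
    mature_sequence = c("UAGCAGCACGUAAAUAUUGGCG",   # seed AGCAGCA
                        "UAGCAGCACAGAAUAAUGAAAA",   # same seed
                        "UUUGCACUAGAUGCACCAUUA"),   # different seed
    expression = c(10, 5, 2))
  fams <- group_families(mirnas)
  expect_equal(nrow(fams), 2L)
  shared <- fams[fams$seed == "AGCAGCA", ]
  expect_equal(shared$n_members, 2L)
  expect_setequal(shared$members[[1]], c("mir-a", "mir-b"))
  expect_equal(shared$expression, 15)

  # pairwise distinct seeds -> one family each
  distinct <- make_families(c("AAAAAAA", "CCCCCCC", "GGGGGGG", "UUUUUUU"))
  expect_equal(nrow(distinct), 4L)
  expect_true(all(distinct$n_members == 1L))
})

test_that("family grouping is deterministic and validates input", {
  mirnas <- data.frame(
    name = c("m1", "m2", "m3"),
    mature_sequence = c("UAGCAGCACGUAAAUAUUGGCG",
                        "UUUGCACUAGAUGCACCAUUA",
                        "UGAGGUAGUAGGUUGUAUAGUU"))
  f1 <- group_families(mirnas)
  f2 <- group_families(mirnas[c(3, 1, 2), ])
  expect_identical(f1, f2)

  short <- rbind(mirnas, data.frame(name = "tiny", mature_sequence = "UAGCA"))
  expect_warning(fams <- group_families(short), "shorter than 8")
  expect_equal(sum(unlist(lapply(fams$members, length))), 3L)

  expect_error(group_families(mirnas[0, ]), "empty")
  bad <- data.frame(name = "x", mature_sequence = "UAGXAGCACGUA")
  expect_error(group_families(bad), "non-RNA")
})

test_that("site patterns follow the three high-affinity classes", {
  pats <- site_patterns("AGCAGCA")
  expect_equal(nrow(pats), 3L)
  expect_equal(pats$site[pats$site_class == "7mer-m8"], "TGCTGCT")
  expect_equal(pats$site[pats$site_class == "7mer-A1"], "GCTGCTA")
  expect_equal(pats$site[pats$site_class == "8mer"], "TGCTGCTA")

  # always exactly three patterns, with distinct strings (lengths differ)
  for (seed in c("UUUGCAC", "AUAUAUA", "GCGCGCG")) {
    p <- site_patterns(seed)
    expect_equal(nrow(p), 3L)
    expect_equal(length(unique(p$site)), 3L)
  }
  expect_error(site_patterns("AGXAGCA"), "non-RNA")
  expect_error(site_patterns("AGCAGC"), "7-nt")
  # DNA-alphabet seed accepted via T -> U at the boundary
  expect_identical(site_patterns("UGUGCAA"), site_patterns("TGTGCAA"))
})

test_that("scanning finds seed-match sites and resolves overlapping classes", {
  fams <- make_families("UUUGCAC")  # 7mer-m8 site GTGCAAA, 8mer GTGCAAAA
  utr <- tibble::tibble(transcript_id = "t1", gene_id = "g1",
                        sequence = "AAAGTGCAAAAA")
  mres <- scan_utr(utr, fams)
  expect_equal(nrow(mres), 1L)           # 8mer absorbs both 7mer matches
  expect_equal(mres$position, 3L)
  expect_equal(mres$site_class, "8mer")
  expect_equal(mres$family_id, fams$family_id)
  expect_equal(mres$unit_position, 3 / 12)

  # reported site string matches the sequence at the reported offset
  pats <- site_patterns(fams$seed)
  site <- pats$site[pats$site_class == mres$site_class]
  expect_equal(substr(utr$sequence, mres$position + 1,
                      mres$position + nchar(site)), site)

  # a UTR shorter than 8 nt yields nothing
  expect_equal(nrow(scan_utr(tibble::tibble(
    transcript_id = "t2", gene_id = "g2", sequence = "GTGCAAA"), fams)), 0L)
})

test_that("peak restriction keeps only covered sites and is monotone", {
  fams <- make_families("UUUGCAC")
  utr <- tibble::tibble(transcript_id = "t1", gene_id = "g1",
                        sequence = "AAAGTGCAAAAA")
  off_peak <- data.frame(transcript_id = "t1", start = 0L, end = 3L)
  expect_equal(nrow(scan_utr(utr, fams, peaks = off_peak)), 0L)
  on_peak <- data.frame(transcript_id = "t1", start = 2L, end = 6L)
  expect_equal(nrow(scan_utr(utr, fams, peaks = on_peak)), 1L)

  # monotone subset property on random sequences
  set.seed(42)
  fams2 <- make_families(c("UUUGCAC", "AGCAGCA", "ACAUUCC"))
  for (i in 1:5) {
    utr_i <- tibble::tibble(transcript_id = "tx", gene_id = "g",
                            sequence = random_dna_str(3000))
    all_mres <- scan_utr(utr_i, fams2)
    pk <- data.frame(transcript_id = "tx",
                     start = sort(sample(0:2900, 3)))
    pk$end <- pk$start + 150L
    sub <- scan_utr(utr_i, fams2, peaks = pk)
    key <- function(m) paste(m$family_id, m$position, m$site_class)
    expect_true(all(key(sub) %in% key(all_mres)))
  }
})

test_that("match counts on random sequence agree with composition expectation", {
  # two families, uniform ACGT: per family the retained count is
  # #7mer-m8 + #7mer-A1 - #8mer, with expectations L/4^7, L/4^7, L/4^8
  set.seed(7)
  fams <- make_families(c("UUUGCAC", "AGCAGCA"))
  n_seq <- 120
  L <- 10000
  counts <- integer(n_seq)
  for (i in seq_len(n_seq)) {
    utr <- tibble::tibble(transcript_id = "t", gene_id = "g",
                          sequence = random_dna_str(L))
    counts[i] <- nrow(scan_utr(utr, fams))
  }
  expected <- 2 * (2 * (L - 6) / 4^7 - (L - 7) / 4^8)
  se <- stats::sd(counts) / sqrt(n_seq)
  expect_lt(abs(mean(counts) - expected), 4 * se + 1e-9)
})

test_that("scan output is deterministic and independent of row order", {
  set.seed(5)
  fams <- make_families(c("UUUGCAC", "AGCAGCA", "ACAUUCC"))
  utrs <- tibble::tibble(
    transcript_id = c("a", "b"), gene_id = c("ga", "gb"),
    sequence = c(random_dna_str(2000), random_dna_str(1500)))
  m1 <- scan_mres(utrs, fams)
  m2 <- scan_mres(utrs[2:1, ], fams[c(3, 1, 2), ])
  expect_identical(m1, m2)
})

test_that("genome-coordinate peaks map through the exon interval chain", {
  fams <- make_families("UUUGCAC")          # 8mer site GTGCAAAA
  seqc <- paste0(strrep("C", 12), "GTGCAAAA")  # site at offsets [12, 20)
  gi_plus <- data.frame(chrom = "chr1", start = c(100L, 200L),
                        end = c(110L, 210L), strand = "+")
  utr <- tibble::tibble(transcript_id = "t1", gene_id = "g1", sequence = seqc,
                        genomic_intervals = list(gi_plus))
  # footprint on + strand: transcript [12,20) -> genomic [202, 210)
  hit <- data.frame(chrom = "chr1", start = 205L, end = 207L)
  miss <- data.frame(chrom = "chr1", start = 100L, end = 112L)
  expect_equal(nrow(scan_mres(utr, fams, peaks = hit,
                              peak_coords = "genome")), 1L)
  expect_equal(nrow(scan_mres(utr, fams, peaks = miss,
                              peak_coords = "genome")), 0L)

  # minus strand: transcript [12,20) -> genomic [100, 108)
  gi_minus <- transform(gi_plus, strand = "-")
  utr$genomic_intervals <- list(gi_minus)
  hit_m <- data.frame(chrom = "chr1", start = 100L, end = 103L)
  miss_m <- data.frame(chrom = "chr1", start = 208L, end = 240L)
  expect_equal(nrow(scan_mres(utr, fams, peaks = hit_m,
                              peak_coords = "genome")), 1L)
  expect_equal(nrow(scan_mres(utr, fams, peaks = miss_m,
                              peak_coords = "genome")), 0L)
})

test_that("positions map to the unit interval preserving order", {
  mres <- make_mre_table(rep("t1", 3), c("f1", "f2", "f3"), c(0, 0.25, 0.5))
  mres$position <- c(0L, 500L, 900L)
  out <- normalize_positions(mres, utr_length = 1000)
  expect_equal(out$unit_position, c(0, 0.5, 0.9))
  expect_true(all(diff(out$unit_position) > 0))
  expect_error(normalize_positions(mres, utr_length = 0), "positive")
  # named length vector keyed by transcript
  out2 <- normalize_positions(mres, c(t1 = 2000))
  expect_equal(out2$unit_position, c(0, 0.25, 0.45))
})
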