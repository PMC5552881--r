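# internal sequence helpers ---------------------------------------------------

# Normalise a vector of miRNA/seed sequences to uppercase RNA (T -> U).
# Characters outside {A,C,G,U} raise an error when strict = TRUE.
normalize_rna <- function(x, strict = TRUE, what = "sequence") {
  x <- chartr("t", "u", toupper(x))
  x <- chartr("T", "U", x)
  if (strict) {
    bad <- grepl("[^ACGU]", x)
    if (any(bad)) {
      stop("non-RNA characters in ", what, ": ",
           paste(utils::head(x[bad], 3L), collapse = ", "), call. = FALSE)
    }
  }
  x
}

# Reverse complement of an RNA string, returned as DNA (the pattern boundary:
# seeds live in RNA space, UTR sequences and site patterns in DNA space).
rna_revcomp_dna <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::DNAString(
      Biostrings::reverseComplement(Biostrings::RNAString(s))))
  }, character(1), USE.NAMES = FALSE)
}

# Random DNA of length n (fixture generation and shuffling checks).
random_dna <- function(n, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Clamp a probability into [lo, 1]; lo = 0 allows exact zeros.
clamp01 <- function(p, lo = 0) pmin(1, pmax(lo, p))
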