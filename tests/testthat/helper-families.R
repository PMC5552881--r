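# Small builders shared across test files.

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Family table from raw RNA seeds; one synthetic miRNA per seed.
make_families <- function(seeds, expression = 100) {
  mirnas <- data.frame(
    name = sprintf("mir-%02d", seq_along(seeds)),
    mature_sequence = paste0("A", seeds,
                             strrep("U", 14)),
    expression = expression)
  group_families(mirnas)
}

# An MRE table row set built directly (skipping the scanner) for feature
# tests: unit positions are taken as given.
make_mre_table <- function(transcript_id, family_id, unit_position,
                           gene_id = sub("\\..*$", "", transcript_id)) {
  tibble::tibble(
    transcript_id = transcript_id,
    gene_id = gene_id,
    family_id = family_id,
    position = as.integer(round(unit_position * 1000)),
    site_class = "7mer-m8",
    unit_position = unit_position)
}
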