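# Shared test helpers: tables built from explicit codon counts, a cached
# synthetic fixture bundle, and random-sequence generators.

# Usage table whose counts are exactly `counts` (named integer vector of
# codons); realised by concatenating the codons into one in-frame CDS.
table_from_counts <- function(counts, ...) {
  cds <- paste(rep(names(counts), counts), collapse = "")
  build_usage_table(cds, ...)
}

# Glycine family from a worked example: GGC 60, GGT 30, GGA 6, GGG 4.
gly_counts <- c(GGC = 60L, GGT = 30L, GGA = 6L, GGG = 4L)

# One fixture bundle per test run (seed fixed, desk-scale).
fixture_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_fixtures(seed = 42L)
    cache
  }
})

random_protein <- function(len) {
  aas <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], character(0))
  paste0("M", paste(sample(aas, len - 1L, replace = TRUE), collapse = ""))
}

# Random in-frame DNA of `n_codons` sense codons (no stops anywhere).
random_cds <- function(n_codons, code = genetic_code()) {
  sense <- names(code)[code != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# Brute-force largest-remainder apportionment, independent of the package's
# implementation: returns the expected codon multiset for n occurrences.
oracle_apportion <- function(n, freqs) {
  exact <- n * freqs
  base <- floor(exact)
  rem <- exact - base
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(-rem, names(freqs))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  stats::setNames(as.integer(base), names(freqs))
}
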