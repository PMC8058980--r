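#' Synthetic fixture bundle
#'
#' Generates everything needed to exercise the toolkit without any
#' downloads: a biased synthetic CDS set, the usage table derived from it,
#' test proteins, and binned depth profiles for a panel of cassette copy
#' numbers echoing a typical transformant series (1, 6, 7 and 10 copies).
#' The same seed always yields a byte-identical bundle, and the CDS set is
#' padded so that every synonymous family has a nonzero count.
#'
#' @param dir Output directory (created if missing); `NULL` returns the
#'   objects without writing files.
#' @param seed Integer seed driving all randomness.
#' @param n_genes Number of synthetic CDS records (>= 50 by default).
#' @param protein_lengths Lengths of the test proteins.
#' @param copy_levels Cassette copy numbers to simulate depth for.
#' @return Invisibly (or visibly when `dir = NULL`), a list with `cds`
#'   (named character vector), `table` ([codon_usage_table]), `proteins`
#'   (named character vector), `profiles` (list of [depth_profile]) and,
#'   when files were written, `paths`.
#' @export
generate_fixtures <- function(dir = NULL, seed = 1L, n_genes = 50L,
                              protein_lengths = c(8L, 100L, 120L, 300L),
                              copy_levels = c(1L, 6L, 7L, 10L)) {
  code <- genetic_code()
  out <- with_seed(seed, {
    cds <- synth_cds_set(n_genes, code)
    proteins <- stats::setNames(
      vapply(protein_lengths, synth_protein, character(1L), code = code),
      paste0("protein_", protein_lengths, "aa"))
    list(cds = cds, proteins = proteins)
  })
  tab <- build_usage_table(out$cds, code, organism = "synthetic")
  ## depth panel: 500 kb augmented reference, 5 kb cassette, 200 bp bins
  profiles <- lapply(copy_levels, function(k) {
    simulate_depth(5e5, c(250000, 255000), copy_number = k,
                   mean_bin_depth = 40, dispersion = 1, bin_size = 200,
                   seed = seed + k)
  })
  names(profiles) <- paste0("copies_", copy_levels)

  bundle <- list(cds = out$cds, table = tab, proteins = out$proteins,
                 profiles = profiles)
  if (is.null(dir)) {
    return(bundle)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    cds = file.path(dir, "synthetic_cds.fasta"),
    table = file.path(dir, "synthetic_usage_table.tsv"),
    proteins = file.path(dir, "synthetic_proteins.fasta"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(out$cds), paths["cds"])
  write_usage_table(tab, paths["table"])
  Biostrings::writeXStringSet(Biostrings::AAStringSet(out$proteins),
                              paths["proteins"])
  for (nm in names(profiles)) {
    p <- file.path(dir, paste0("synthetic_depth_", nm, ".tsv"))
    write_depth_tsv(profiles[[nm]], p)
    paths[paste0("depth_", nm)] <- p
  }
  bundle$paths <- paths
  invisible(bundle)
}

## A CDS set with a strongly biased codon distribution: within each family
## codons get sampling weights proportional to 3^(-rank) in alphabetical
## order, so preferred/rare codons are unambiguous. A pad gene containing
## every sense codon once guarantees no family is empty.
synth_cds_set <- function(n_genes, code) {
  fams <- split(sense_codons(code), code[sense_codons(code)])
  probs <- lapply(fams, function(f) {
    f <- sort(f)
    w <- 3^-(seq_along(f) - 1L)
    stats::setNames(w / sum(w), f)
  })
  aas <- names(fams)
  stopcods <- stop_codons(code)
  genes <- vapply(seq_len(n_genes), function(i) {
    len <- sample(80:300, 1L)
    aa <- c("M", sample(aas, len - 1L, replace = TRUE))
    cods <- vapply(aa, function(a) {
      p <- probs[[a]]
      sample(names(p), 1L, prob = p)
    }, character(1L))
    paste0(paste(cods, collapse = ""), sample(stopcods, 1L))
  }, character(1L))
  pad <- paste0(paste(sense_codons(code), collapse = ""), "TAA")
  stats::setNames(c(genes, pad),
                  c(sprintf("gene_%03d", seq_len(n_genes)), "pad_all_codons"))
}

synth_protein <- function(len, code) {
  aas <- setdiff(sort(unique(code)), "*")
  paste0("M", paste(sample(aas, len - 1L, replace = TRUE), collapse = ""))
}
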