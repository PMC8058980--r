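#' Codon adaptation index
#'
#' Geometric mean of the relative-adaptiveness weights of a gene's codons.
#' The preferred codon of every family has weight 1, so a sequence built
#' exclusively from preferred codons scores exactly 1. Single-codon families
#' (Met, Trp) enter with weight 1; a terminal stop codon is permitted and
#' excluded from the score, internal stops are an error.
#'
#' @param dna In-frame DNA string.
#' @param table A [codon_usage_table].
#' @param code A [genetic_code()].
#' @return CAI in (0, 1].
#' @examples
#' tab <- build_usage_table(c("ATGAAAAAGAAGAAGTAA"))
#' cai("ATGAAA", tab)  # (1 * 1/3 / 1)^(1/2) on these counts
#' @export
cai <- function(dna, table, code = genetic_code()) {
  stopifnot(inherits(table, "codon_usage_table"))
  dna <- normalize_dna(dna)
  check_in_frame(dna)
  cod <- split_codons(dna)
  cod <- drop_terminal_stop(cod, code)
  if (length(cod) == 0L) {
    stop("sequence contains no sense codons", call. = FALSE)
  }
  stops <- which(code[cod] == "*")
  if (length(stops)) {
    stop("internal stop codon ", cod[stops[1L]], " at codon position ",
         stops[1L], call. = FALSE)
  }
  w <- weight_vector(table)[cod]
  exp(mean(log(w)))
}

drop_terminal_stop <- function(codons, code) {
  n <- length(codons)
  if (n > 0L && code[[codons[n]]] == "*") codons[-n] else codons
}

#' GC content
#'
#' Fraction of G or C bases, over all positions or only the third position
#' of each codon (GC3, the usual degenerate-site summary).
#'
#' @param dna DNA string (in frame when `positions = "third"`).
#' @param positions `"all"` or `"third"`.
#' @return Fraction in \[0, 1\].
#' @export
gc_content <- function(dna, positions = c("all", "third")) {
  positions <- match.arg(positions)
  dna <- normalize_dna(dna)
  if (nchar(dna) == 0L) stop("sequence is empty", call. = FALSE)
  bases <- strsplit(dna, "", fixed = TRUE)[[1L]]
  if (positions == "third") {
    check_in_frame(dna)
    bases <- bases[seq(3L, length(bases), 3L)]
  }
  mean(bases %in% c("G", "C"))
}

#' Distance between a sequence's codon usage and a table's average usage
#'
#' For each amino acid present in the sequence, the total-variation distance
#' between the observed within-family codon fractions and the table's family
#' frequencies, weighted by the amino acid's share of the sequence:
#' sum over amino acids a of (n_a / N) * (1/2) * sum over the family of
#' |observed fraction - family frequency|. Zero iff every family's usage
#' matches the table exactly; at most 1.
#'
#' @inheritParams cai
#' @return Fraction in \[0, 1\].
#' @export
usage_distance <- function(dna, table, code = genetic_code()) {
  stopifnot(inherits(table, "codon_usage_table"))
  dna <- normalize_dna(dna)
  check_in_frame(dna)
  cod <- drop_terminal_stop(split_codons(dna), code)
  if (length(cod) == 0L) {
    stop("sequence contains no sense codons", call. = FALSE)
  }
  if (any(code[cod] == "*")) {
    stop("internal stop codon in sequence", call. = FALSE)
  }
  aa <- unname(code[cod])
  n_total <- length(cod)
  d <- 0
  for (a in unique(aa)) {
    fam <- family_codons(a, code)
    obs <- table(factor(cod[aa == a], levels = fam))
    obs <- as.numeric(obs) / sum(obs)
    expct <- table$family_frequency[match(fam, table$codon)]
    d <- d + (sum(aa == a) / n_total) * 0.5 * sum(abs(obs - expct))
  }
  d
}

#' Per-site difference between two equal-length designs
#'
#' Hamming distance divided by length; the spec-level summary used to say
#' how much two codon-optimization strategies disagree on the same protein.
#'
#' @param dna_a,dna_b DNA strings of equal length.
#' @return Fraction of differing positions.
#' @export
sequence_difference <- function(dna_a, dna_b) {
  a <- normalize_dna(dna_a)
  b <- normalize_dna(dna_b)
  if (nchar(a) != nchar(b)) {
    stop("sequences have different lengths (", nchar(a), " vs ", nchar(b),
         ")", call. = FALSE)
  }
  if (nchar(a) == 0L) stop("sequences are empty", call. = FALSE)
  va <- strsplit(a, "", fixed = TRUE)[[1L]]
  vb <- strsplit(b, "", fixed = TRUE)[[1L]]
  mean(va != vb)
}
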