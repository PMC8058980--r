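#' Genetic code handling
#'
#' A `genetic_code` maps the 64 DNA triplets to one-letter amino acids, with
#' `"*"` marking stop codons. The standard code is taken from
#' [Biostrings::GENETIC_CODE] (RNA alphabet) and re-expressed over DNA.
#'
#' @param id Genetic code identifier understood by
#'   [Biostrings::getGeneticCode()]; defaults to the standard code.
#' @return A `genetic_code` object: a named character vector of length 64
#'   (names are DNA codons, values are amino-acid letters or `"*"`), with a
#'   `code_id` attribute.
#' @examples
#' gc <- genetic_code()
#' gc[["ATG"]]   # "M"
#' gc[["TAA"]]   # "*"
#' @export
genetic_code <- function(id = "1") {
  rna <- Biostrings::getGeneticCode(id)
  codons <- chartr("U", "T", names(rna))
  code <- stats::setNames(unname(rna), codons)
  stopifnot(length(code) == 64L)
  structure(code, code_id = id, class = "genetic_code")
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code", attr(x, "code_id"), "(", sum(x == "*"),
      "stop codons )\n")
  invisible(x)
}

## All 64 triplets, sorted; stable codon universe used throughout.
all_codons <- function() {
  b <- c("A", "C", "G", "T")
  sort(as.vector(outer(outer(b, b, paste0), b, paste0)))
}

sense_codons <- function(code) {
  names(code)[code != "*"]
}

stop_codons <- function(code) {
  names(code)[code == "*"]
}

## Synonymous family of an amino-acid letter.
family_codons <- function(aa, code) {
  names(code)[code == aa]
}

#' Translate an in-frame DNA sequence
#'
#' Straight table lookup against a [genetic_code()]; used for round-trip
#' verification of designed sequences.
#'
#' @param dna In-frame DNA string over A/C/G/T.
#' @param code A `genetic_code`.
#' @return Amino-acid string; stop codons appear as `"*"`.
#' @export
translate_dna <- function(dna, code = genetic_code()) {
  dna <- normalize_dna(dna)
  check_in_frame(dna)
  paste(code[split_codons(dna)], collapse = "")
}

## --- small shared helpers ------------------------------------------------

normalize_dna <- function(x) {
  x <- toupper(as.character(x))
  chartr("U", "T", x) # RNA input tolerated, normalized to DNA
}

check_in_frame <- function(dna, what = "sequence") {
  if (nchar(dna) == 0L) {
    stop(what, " is empty", call. = FALSE)
  }
  if (nchar(dna) %% 3L != 0L) {
    stop(what, " length (", nchar(dna), ") is not divisible by 3",
         call. = FALSE)
  }
  invisible(dna)
}

split_codons <- function(dna) {
  n <- nchar(dna)
  substring(dna, seq(1L, n, 3L), seq(3L, n, 3L))
}

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
## seed = NULL leaves the RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(code)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

## round-half-away-from-zero (base round() is banker's rounding)
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}
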