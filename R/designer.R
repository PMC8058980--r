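#' Codon pickers used by the design strategies
#'
#' `pick_hc_codon()` returns the family codon with the maximal count (the
#' organism-preferred codon); `pick_destabilized_codon()` the codon with the
#' minimal nonzero count (zero-count codons are excluded so the design never
#' uses a codon the organism avoids entirely);
#' `pick_start_context_codon()` the codon that best matches a translational
#' start consensus pattern at codon 2. All ties break alphabetically by
#' codon so designs are reproducible.
#'
#' @param aa One-letter amino acid.
#' @param table A [codon_usage_table].
#' @param code A [genetic_code()].
#' @return A single codon.
#' @examples
#' tab <- build_usage_table("ATGGGCGGCGGTTAA")
#' pick_hc_codon("G", tab)           # "GGC"
#' pick_destabilized_codon("G", tab) # "GGT"
#' @export
pick_hc_codon <- function(aa, table, code = genetic_code()) {
  fam <- family_rows(aa, table, code)
  if (all(fam$count == 0)) {
    stop("all counts are zero for amino acid '", aa,
         "'; build the table from a richer CDS set", call. = FALSE)
  }
  best <- fam$codon[fam$count == max(fam$count)]
  sort(best)[1L]
}

#' @rdname pick_hc_codon
#' @export
pick_destabilized_codon <- function(aa, table, code = genetic_code()) {
  fam <- family_rows(aa, table, code)
  if (nrow(fam) == 1L) {
    return(fam$codon) # no synonym, nothing to choose
  }
  nz <- fam[fam$count > 0, , drop = FALSE]
  if (nrow(nz) == 0L) {
    stop("all counts are zero for amino acid '", aa,
         "'; build the table from a richer CDS set", call. = FALSE)
  }
  best <- nz$codon[nz$count == min(nz$count)]
  sort(best)[1L]
}

#' @rdname pick_hc_codon
#' @param consensus_pattern Three-character pattern; non-`"*"` positions
#'   score 1 when the codon matches them. Ties break by higher usage count,
#'   then alphabetically.
#' @export
pick_start_context_codon <- function(aa, table,
                                     consensus_pattern = "G**",
                                     code = genetic_code()) {
  stopifnot(nchar(consensus_pattern) == 3L)
  pat <- strsplit(toupper(consensus_pattern), "", fixed = TRUE)[[1L]]
  fam <- family_rows(aa, table, code)
  if (all(fam$count == 0)) {
    stop("all counts are zero for amino acid '", aa,
         "'; build the table from a richer CDS set", call. = FALSE)
  }
  score <- vapply(fam$codon, function(cod) {
    b <- strsplit(cod, "", fixed = TRUE)[[1L]]
    sum(pat != "*" & b == pat)
  }, numeric(1L))
  ## best consensus score, then usage, then alphabetical
  ord <- order(-score, -fam$count, fam$codon)
  fam$codon[ord[1L]]
}

family_rows <- function(aa, table, code) {
  fam <- family_codons(aa, code)
  if (length(fam) == 0L) {
    stop("'", aa, "' is not a standard amino acid", call. = FALSE)
  }
  table[match(fam, table$codon), c("codon", "count", "family_frequency"),
        drop = FALSE]
}

#' Codons matching the organism's average usage
#'
#' Fills a run of amino acids with synonymous codons whose composition
#' mirrors the usage table. In `"quota"` mode each amino acid with n
#' occurrences receives codon counts by largest-remainder apportionment of
#' n times the family frequencies (remainder ties break alphabetically);
#' the codons are then laid out at that amino acid's positions by cycling
#' through the apportioned codons in descending-quota order. In
#' `"stochastic"` mode each occurrence samples a codon with the family
#' frequencies as probabilities; a fixed `seed` gives identical output.
#'
#' @param aa_segment Amino-acid string (or character vector of residues).
#' @param table A [codon_usage_table].
#' @param mode `"quota"` or `"stochastic"`.
#' @param seed Integer seed for stochastic mode (`NULL` uses the current
#'   RNG stream).
#' @param code A [genetic_code()].
#' @return Character vector of codons, one per residue.
#' @examples
#' tab <- build_usage_table("ATGAAAAAGAAGAAGTAA")
#' match_average_usage("KKKK", tab)  # 3 AAG + 1 AAA, interleaved
#' @export
match_average_usage <- function(aa_segment, table,
                                mode = c("quota", "stochastic"),
                                seed = NULL, code = genetic_code()) {
  mode <- match.arg(mode)
  aa <- as_residues(aa_segment)
  if (length(aa) == 0L) {
    stop("empty amino-acid segment", call. = FALSE)
  }
  check_residues(aa, code)
  out <- character(length(aa))

  if (mode == "stochastic") {
    out <- with_seed(seed, {
      o <- character(length(aa))
      for (a in unique(aa)) {
        idx <- which(aa == a)
        fam <- family_rows(a, table, code)
        if (sum(fam$family_frequency) == 0) {
          stop("all counts are zero for amino acid '", a, "'", call. = FALSE)
        }
        o[idx] <- sample(fam$codon, length(idx), replace = TRUE,
                         prob = fam$family_frequency)
      }
      o
    })
    return(out)
  }

  for (a in unique(aa)) {
    idx <- which(aa == a)
    seq_codons <- apportion_codons(a, length(idx), table, code)
    out[idx] <- seq_codons
  }
  out
}

## Largest-remainder apportionment of n occurrences over the family
## frequencies, returned already interleaved (cycle codons with remaining
## quota in descending initial-quota order, ties alphabetical).
apportion_codons <- function(aa, n, table, code) {
  fam <- family_rows(aa, table, code)
  f <- fam$family_frequency
  if (sum(f) == 0) {
    stop("all counts are zero for amino acid '", aa, "'", call. = FALSE)
  }
  exact <- n * f
  base <- floor(exact)
  rem <- exact - base
  short <- n - sum(base)
  if (short > 0) {
    ## hand out the leftover seats by descending remainder, ties alphabetical
    ord <- order(-rem, fam$codon)
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  quota <- stats::setNames(as.integer(base), fam$codon)
  quota <- quota[order(-quota, names(quota))]
  quota <- quota[quota > 0]
  out <- character(n)
  k <- 1L
  while (k <= n) {
    for (cod in names(quota)) {
      if (quota[[cod]] > 0L && k <= n) {
        out[k] <- cod
        quota[[cod]] <- quota[[cod]] - 1L
        k <- k + 1L
      }
    }
  }
  out
}

as_residues <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) {
    strsplit(toupper(x), "", fixed = TRUE)[[1L]]
  } else {
    toupper(as.character(x))
  }
}

check_residues <- function(aa, code, what = "protein") {
  ok <- aa %in% setdiff(unique(code), "*")
  if (!all(ok)) {
    bad <- which(!ok)[1L]
    stop(what, " contains non-standard amino acid '", aa[bad],
         "' at position ", bad, call. = FALSE)
  }
  invisible(aa)
}

#' High-CAI (HC) design
#'
#' Encodes every residue with the organism's most-used codon, the strategy
#' that simply maximizes the codon adaptation index: the output has CAI
#' exactly 1 whenever every required family has a nonzero count. The design
#' is fully deterministic.
#'
#' @param protein Amino-acid string.
#' @param table A [codon_usage_table].
#' @param append_stop Append the table's preferred stop codon (default TRUE).
#' @param require_met Require the first residue to be methionine
#'   (default TRUE).
#' @param code A [genetic_code()].
#' @return A `design_result` with fields `protein`, `dna`, `zone_map`,
#'   `metrics` (cai, gc, gc3, usage_distance), `strategy` and `seed`.
#' @examples
#' tab <- build_usage_table("ATGGGCGGCGGTAAGTAA")
#' design_hc("MGK", tab)$dna
#' @export
design_hc <- function(protein, table, append_stop = TRUE,
                      require_met = TRUE, code = genetic_code()) {
  aa <- prepare_protein(protein, require_met, code)
  fams <- unique(aa)
  picks <- vapply(fams, pick_hc_codon, character(1L),
                  table = table, code = code)
  codons <- unname(picks[aa])
  finish_design(aa, codons, zones = rep("HC", length(aa)),
                strategy = "HC", seed = NULL, table = table,
                append_stop = append_stop, code = code)
}

#' Zoned expression cassette optimization (ECO) design
#'
#' Implements the balanced five-zone strategy: ATG at codon 1, a
#' start-consensus codon at position 2, the rarest usable codons at
#' positions 3-10 (to weaken 5' mRNA secondary structure), the preferred
#' codon at positions 11-45 and over the last 50 codons, and average-usage
#' matched codons in between (see [zone_config()]).
#'
#' @inheritParams design_hc
#' @param cfg A [zone_config()].
#' @param seed Integer seed used when `cfg$middle_mode == "stochastic"`;
#'   ignored (and recorded as `NULL`) in quota mode.
#' @return A `design_result`; `zone_map` records the zone of every codon.
#' @examples
#' tab <- build_usage_table("ATGGGCGGCGGTAAGAAATAA")
#' d <- design_eco(strrep("MGK", 40), tab)
#' table(d$zone_map)
#' @export
design_eco <- function(protein, table, cfg = zone_config(), seed = NULL,
                       append_stop = TRUE, require_met = TRUE,
                       code = genetic_code()) {
  stopifnot(inherits(cfg, "zone_config"))
  aa <- prepare_protein(protein, require_met, code)
  L <- length(aa)
  zones <- zone_map(L, cfg)
  codons <- character(L)

  codons[1L] <- pick_hc_codon(aa[1L], table, code) # ATG for Met
  if (L >= 2L) {
    codons[2L] <- pick_start_context_codon(aa[2L], table,
                                           cfg$consensus_pattern, code)
  }
  for (i in which(zones == "DESTABILIZED")) {
    codons[i] <- pick_destabilized_codon(aa[i], table, code)
  }
  hc_idx <- which(zones %in% c("HEAD_HC", "TAIL_HC"))
  if (length(hc_idx)) {
    picks <- vapply(unique(aa[hc_idx]), pick_hc_codon, character(1L),
                    table = table, code = code)
    codons[hc_idx] <- unname(picks[aa[hc_idx]])
  }
  mid_idx <- which(zones == "MIDDLE")
  if (length(mid_idx)) {
    codons[mid_idx] <- match_average_usage(aa[mid_idx], table,
                                           mode = cfg$middle_mode,
                                           seed = seed, code = code)
  }
  finish_design(aa, codons, zones = zones, strategy = "ECO",
                seed = if (cfg$middle_mode == "stochastic") seed else NULL,
                table = table, append_stop = append_stop, code = code)
}

prepare_protein <- function(protein, require_met, code) {
  aa <- as_residues(protein)
  if (length(aa) == 0L) stop("protein is empty", call. = FALSE)
  check_residues(aa, code)
  if (require_met && aa[1L] != "M") {
    stop("first residue is '", aa[1L],
         "', not M; pass require_met = FALSE to permit", call. = FALSE)
  }
  aa
}

finish_design <- function(aa, codons, zones, strategy, seed, table,
                          append_stop, code) {
  dna <- paste(codons, collapse = "")
  stopifnot(translate_dna(dna, code) == paste(aa, collapse = ""))
  if (append_stop) {
    dna <- paste0(dna, attr(table, "preferred_stop"))
  }
  structure(list(protein = paste(aa, collapse = ""),
                 dna = dna,
                 zone_map = zones,
                 codons = codons,
                 metrics = list(
                   cai = cai(dna, table, code),
                   gc = gc_content(dna),
                   gc3 = gc_content(dna, "third"),
                   usage_distance = usage_distance(dna, table, code)),
                 strategy = strategy,
                 seed = seed),
            class = "design_result")
}

#' @export
print.design_result <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "%s design: %d aa -> %d nt | CAI %.4f | GC %.3f | GC3 %.3f | usage distance %.4f\n",
    x$strategy, nchar(x$protein), nchar(x$dna), m$cai, m$gc, m$gc3,
    m$usage_distance))
  invisible(x)
}

#' Write a design to FASTA, JSON and per-codon TSV reports
#'
#' @param design A `design_result`.
#' @param prefix Output path prefix; writes `<prefix>.fasta`,
#'   `<prefix>.json` and `<prefix>.tsv`.
#' @param name Sequence name for the FASTA record.
#' @param table A [codon_usage_table] used to annotate per-codon weights.
#' @return Invisibly, the three paths written.
#' @export
write_design <- function(design, prefix, name = "design", table = NULL) {
  stopifnot(inherits(design, "design_result"))
  fa <- paste0(prefix, ".fasta")
  js <- paste0(prefix, ".json")
  tsv <- paste0(prefix, ".tsv")
  dna <- Biostrings::DNAStringSet(stats::setNames(design$dna, name))
  Biostrings::writeXStringSet(dna, fa)
  spans <- split(seq_along(design$zone_map), design$zone_map)
  report <- list(
    name = name,
    strategy = design$strategy,
    seed = design$seed,
    length_aa = nchar(design$protein),
    zone_spans = lapply(spans, function(i) c(min(i), max(i))),
    metrics = design$metrics)
  jsonlite::write_json(report, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  w <- if (is.null(table)) rep(NA_real_, length(design$codons)) else
    unname(weight_vector(table)[design$codons])
  df <- data.frame(position = seq_along(design$codons),
                   amino_acid = strsplit(design$protein, "")[[1L]],
                   codon = design$codons,
                   zone = design$zone_map,
                   weight = w)
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fa, json = js, tsv = tsv))
}
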