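#' Codon usage tables
#'
#' A `codon_usage_table` holds per-codon counts for one organism together
#' with the statistics derived from them:
#'
#' * `family_frequency` -- the codon's fraction within its synonymous family
#'   (sums to 1 over each family with at least one count);
#' * `weight` -- relative adaptiveness, the family frequency divided by the
#'   family maximum, so the preferred codon of every family has weight 1.
#'   Zero-count codons receive a small positive floor (`pseudo_floor`,
#'   default 0.01) so that geometric-mean statistics such as CAI stay
#'   defined.
#'
#' Stop codons carry counts but no weights; the most frequent stop triplet
#' is recorded as the default stop codon appended to designs.
#'
#' @name codon_usage_table
NULL

new_usage_table <- function(counts, code, organism = "unknown",
                            pseudo_floor = 0.01) {
  stopifnot(pseudo_floor > 0)
  codons <- all_codons()
  cnt <- stats::setNames(integer(64L), codons)
  cnt[names(counts)] <- as.integer(counts)
  if (any(cnt < 0)) {
    stop("negative codon count for ",
         paste(names(cnt)[cnt < 0], collapse = ", "), call. = FALSE)
  }
  aa <- unname(code[codons])
  tab <- data.frame(codon = codons, amino_acid = aa, count = unname(cnt),
                    stringsAsFactors = FALSE)

  tab$family_frequency <- NA_real_
  tab$weight <- NA_real_
  sense <- tab$amino_acid != "*"
  for (a in unique(tab$amino_acid[sense])) {
    idx <- which(tab$amino_acid == a)
    tot <- sum(tab$count[idx])
    if (tot > 0) {
      f <- tab$count[idx] / tot
      tab$family_frequency[idx] <- f
      tab$weight[idx] <- pmax(f / max(f), pseudo_floor)
    } else {
      tab$family_frequency[idx] <- 0
      tab$weight[idx] <- pseudo_floor
    }
  }

  stops <- tab[tab$amino_acid == "*", ]
  preferred_stop <- if (any(stops$count > 0)) {
    cand <- stops$codon[stops$count == max(stops$count)]
    sort(cand)[1L]
  } else {
    sort(stops$codon)[1L] # TAA in the standard code
  }

  structure(tab,
            organism = organism,
            pseudo_floor = pseudo_floor,
            preferred_stop = preferred_stop,
            code_id = attr(code, "code_id"),
            class = c("codon_usage_table", "data.frame"))
}

#' Build a codon usage table from coding sequences
#'
#' Tallies every in-frame codon across a set of CDS records. Codons
#' containing `N` are skipped (draft gene sets are tolerated); RNA input is
#' normalized to DNA. Stop codons are counted separately from the sense
#' families and only determine the preferred stop triplet.
#'
#' @param cds Character vector of in-frame DNA sequences, a named character
#'   vector, or a [Biostrings::DNAStringSet].
#' @param code A [genetic_code()].
#' @param organism Free-text label stored on the table.
#' @param pseudo_floor Weight assigned to zero-count codons (default 0.01).
#' @return A `codon_usage_table` (a data frame with columns `codon`,
#'   `amino_acid`, `count`, `family_frequency`, `weight`).
#' @examples
#' tab <- build_usage_table(c("ATGAAAAAATAA"))
#' tab[tab$codon == "AAA", ]
#' @export
build_usage_table <- function(cds, code = genetic_code(),
                              organism = "unknown", pseudo_floor = 0.01) {
  if (inherits(cds, "XStringSet")) {
    cds <- stats::setNames(as.character(cds), names(cds))
  }
  if (length(cds) == 0L) {
    stop("no coding sequences supplied", call. = FALSE)
  }
  ids <- names(cds)
  if (is.null(ids)) ids <- paste0("record_", seq_along(cds))

  counts <- stats::setNames(integer(64L), all_codons())
  for (i in seq_along(cds)) {
    s <- normalize_dna(cds[[i]])
    if (nchar(s) == 0L || nchar(s) %% 3L != 0L) {
      stop("record '", ids[i], "' is not in frame (length ", nchar(s), ")",
           call. = FALSE)
    }
    if (grepl("[^ACGTN]", s)) {
      stop("record '", ids[i], "' contains characters outside {A,C,G,T,N}",
           call. = FALSE)
    }
    cod <- split_codons(s)
    cod <- cod[!grepl("N", cod, fixed = TRUE)]
    if (length(cod)) {
      t <- table(cod)
      counts[names(t)] <- counts[names(t)] + as.integer(t)
    }
  }
  new_usage_table(counts, code, organism = organism,
                  pseudo_floor = pseudo_floor)
}

#' @export
print.codon_usage_table <- function(x, ...) {
  cat("Codon usage table for", attr(x, "organism"), "--",
      sum(x$count[x$amino_acid != "*"]), "sense codons counted;",
      sum(x$count == 0 & x$amino_acid != "*"), "zero-count sense codons;",
      "preferred stop", attr(x, "preferred_stop"), "\n")
  NextMethod()
}

## weight lookup as a named vector over sense codons
weight_vector <- function(table) {
  sense <- table$amino_acid != "*"
  stats::setNames(table$weight[sense], table$codon[sense])
}

#' Relative synonymous codon usage (RSCU)
#'
#' RSCU of a codon is its count divided by the mean count over its
#' synonymous family, so the values in a family of degeneracy d sum to d.
#' Families with zero total count have undefined RSCU and are returned as
#' `NA`.
#'
#' @param table A [codon_usage_table].
#' @return Named numeric vector over the sense codons.
#' @examples
#' tab <- build_usage_table("ATGGGCGGTGGA")
#' compute_rscu(tab)[c("GGC", "GGT", "GGA", "GGG")]
#' @export
compute_rscu <- function(table) {
  stopifnot(inherits(table, "codon_usage_table"))
  sense <- table$amino_acid != "*"
  out <- stats::setNames(rep(NA_real_, sum(sense)), table$codon[sense])
  for (a in unique(table$amino_acid[sense])) {
    idx <- table$amino_acid == a & sense
    tot <- sum(table$count[idx])
    if (tot > 0) {
      out[table$codon[idx]] <- table$count[idx] / (tot / sum(idx))
    }
  }
  out
}

#' Read and write codon usage tables
#'
#' The native format is a tab-separated file with a header line and columns
#' `codon`, `amino_acid`, `count`. Codons absent from the file get count 0
#' (sparse tables are valid); duplicate rows, unknown triplets and negative
#' counts are errors. A reader for the whitespace-delimited
#' "codon frequency-per-thousand (count)" layout used by common usage-table
#' websites is available via `format = "kazusa"`: tokens look like
#' `UUU 26.1( 12345)` and only the codon and the parenthesised count are
#' used.
#'
#' `write_usage_table()` followed by `read_usage_table()` reproduces counts
#' exactly; derived statistics are recomputed on read.
#'
#' @param path File path.
#' @param format `"tsv"` (default) or `"kazusa"`.
#' @param code A [genetic_code()].
#' @param organism,pseudo_floor Passed to the table constructor.
#' @param table A [codon_usage_table] to write.
#' @return `read_usage_table()` returns a [codon_usage_table];
#'   `write_usage_table()` returns `path` invisibly.
#' @export
read_usage_table <- function(path, format = c("tsv", "kazusa"),
                             code = genetic_code(), organism = "unknown",
                             pseudo_floor = 0.01) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("codon", "amino_acid", "count")
    if (!all(need %in% names(df))) {
      stop("usage table must have header columns: ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    codons <- normalize_dna(df$codon)
    counts <- stats::setNames(df$count, codons)
  } else {
    txt <- paste(readLines(path, warn = FALSE), collapse = " ")
    m <- gregexpr("([ACGTUacgtu]{3})\\s+[0-9.]+\\s*\\(\\s*([0-9]+)\\s*\\)",
                  txt, perl = TRUE)
    hits <- regmatches(txt, m)[[1]]
    if (length(hits) == 0L) {
      stop("no codon entries found in '", path, "'", call. = FALSE)
    }
    codons <- normalize_dna(sub("^([A-Za-z]{3}).*", "\\1", hits))
    counts <- stats::setNames(
      as.integer(sub(".*\\(\\s*([0-9]+)\\s*\\).*", "\\1", hits)), codons)
  }
  if (anyDuplicated(names(counts))) {
    stop("duplicate codon rows: ",
         paste(unique(names(counts)[duplicated(names(counts))]),
               collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(names(counts), all_codons())
  if (length(unknown)) {
    stop("codons not in the genetic code: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  new_usage_table(counts, code, organism = organism,
                  pseudo_floor = pseudo_floor)
}

#' @rdname read_usage_table
#' @export
write_usage_table <- function(table, path) {
  stopifnot(inherits(table, "codon_usage_table"))
  df <- data.frame(codon = table$codon, amino_acid = table$amino_acid,
                   count = table$count)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
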