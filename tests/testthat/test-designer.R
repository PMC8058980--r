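test_that("zone maps follow the documented spans and precedence", {
  z <- zone_map(120)
  expect_equal(z[1], "START")
  expect_equal(z[2], "CONSENSUS")
  expect_equal(unique(z[3:10]), "DESTABILIZED")
  expect_equal(unique(z[11:45]), "HEAD_HC")
  expect_equal(unique(z[46:70]), "MIDDLE")
  expect_equal(unique(z[71:120]), "TAIL_HC")

  z100 <- zone_map(100)
  expect_equal(unique(z100[51:100]), "TAIL_HC")
  expect_equal(unique(z100[46:50]), "MIDDLE")

  z8 <- zone_map(8)
  expect_equal(z8, c("START", "CONSENSUS", rep("DESTABILIZED", 6)))
})

test_that("zone labels partition every length", {
  labels <- c("START", "CONSENSUS", "DESTABILIZED", "HEAD_HC", "MIDDLE",
              "TAIL_HC")
  for (L in 1:300) {
    z <- zone_map(L)
    expect_length(z, L)
    expect_true(all(z %in% labels))
    expect_equal(z[1], "START")
    if (L >= 2) expect_equal(z[2], "CONSENSUS")
  }
})

test_that("codon pickers implement argmax/argmin with alphabetical ties", {
  tab <- table_from_counts(gly_counts)
  expect_equal(pick_hc_codon("G", tab), "GGC")
  expect_equal(pick_destabilized_codon("G", tab), "GGG")
  expect_equal(pick_hc_codon("M", table_from_counts(c(ATG = 3L))), "ATG")
  expect_equal(pick_destabilized_codon("W", table_from_counts(c(TGG = 1L))),
               "TGG")

  ties <- table_from_counts(c(AAA = 5L, AAG = 5L))
  expect_equal(pick_hc_codon("K", ties), "AAA")

  # zero-count codons are never selected as the destabilized choice
  zer <- table_from_counts(c(AAA = 9L))
  expect_equal(pick_destabilized_codon("K", zer), "AAA")
  expect_error(pick_hc_codon("G", zer), "richer CDS set")
})

test_that("start-context codon rewards the consensus then usage", {
  # neither Lys codon starts with G -> usage tie-break
  tab <- table_from_counts(c(AAA = 5L, AAG = 3L))
  expect_equal(pick_start_context_codon("K", tab), "AAA")

  # both Asp codons start with G -> usage tie-break
  tab <- table_from_counts(c(GAC = 7L, GAT = 3L))
  expect_equal(pick_start_context_codon("D", tab), "GAC")

  # Ala codons all match "G**": falls through to the count argmax
  tab <- table_from_counts(c(GCA = 1L, GCC = 9L, GCG = 2L, GCT = 3L))
  expect_equal(pick_start_context_codon("A", tab), "GCC")

  # a matching codon beats a more frequent non-matching one
  tab <- table_from_counts(c(TTA = 50L, GGA = 1L, GGC = 1L))
  expect_equal(pick_start_context_codon("L", tab), "TTA") # no G-start Leu here
  tab2 <- table_from_counts(c(CTC = 50L, TTG = 2L))
  expect_equal(pick_start_context_codon("L", tab2, "C**"), "CTC")
})

test_that("quota mode reproduces largest-remainder apportionment", {
  tab <- table_from_counts(c(CTG = 5L, TTG = 3L, CTT = 2L))
  cods <- match_average_usage(strrep("L", 10), tab)
  expect_equal(vapply(c("CTG", "TTG", "CTT"),
                      function(cc) sum(cods == cc), integer(1)),
               c(CTG = 5L, TTG = 3L, CTT = 2L))

  expect_equal(match_average_usage("M", table_from_counts(c(ATG = 1L))),
               "ATG")

  # remainder tie resolves alphabetically: 3 x Lys at 0.5/0.5 -> AAA x2
  tab <- table_from_counts(c(AAA = 5L, AAG = 5L))
  cods <- match_average_usage("KKK", tab)
  expect_equal(sum(cods == "AAA"), 2L)
  expect_equal(sum(cods == "AAG"), 1L)
})

test_that("quota counts match the oracle across random segments", {
  tab <- fixture_bundle()$table
  code <- genetic_code()
  set.seed(21)
  for (i in 1:10) {
    seg <- paste(sample(setdiff(unique(code), "*"), 120, replace = TRUE),
                 collapse = "")
    cods <- match_average_usage(seg, tab)
    aa <- strsplit(seg, "")[[1]]
    for (a in unique(aa)) {
      fam <- sort(names(code)[code == a & code != "*"])
      freqs <- stats::setNames(
        tab$family_frequency[match(fam, tab$codon)], fam)
      want <- oracle_apportion(sum(aa == a), freqs)
      got <- vapply(fam, function(cc) sum(cods[aa == a] == cc), integer(1))
      expect_equal(got, want, ignore_attr = TRUE)
    }
  }
})

test_that("stochastic mode is seed-reproducible and leaves the RNG alone", {
  tab <- fixture_bundle()$table
  seg <- strrep("LSKGRAVE", 10)
  a <- match_average_usage(seg, tab, mode = "stochastic", seed = 7)
  b <- match_average_usage(seg, tab, mode = "stochastic", seed = 7)
  expect_identical(a, b)
  d <- match_average_usage(seg, tab, mode = "stochastic", seed = 8)
  expect_false(identical(a, d))

  set.seed(99)
  before <- .Random.seed
  invisible(match_average_usage(seg, tab, mode = "stochastic", seed = 7))
  expect_identical(.Random.seed, before)
})

test_that("HC designs use the preferred codon everywhere", {
  tab <- table_from_counts(c(ATG = 1L, GGC = 60L, GGT = 30L, GGA = 6L,
                             GGG = 4L, TAA = 2L))
  d <- design_hc("MG", tab)
  expect_equal(d$dna, "ATGGGCTAA")
  expect_equal(design_hc("MG", tab, append_stop = FALSE)$dna, "ATGGGC")
  expect_identical(d$metrics$cai, 1)

  expect_error(design_hc("MGXK", fixture_bundle()$table), "position 3")
  expect_error(design_hc("GMK", fixture_bundle()$table), "not M")
  expect_silent(design_hc("GMK", fixture_bundle()$table,
                          require_met = FALSE))
})

test_that("ECO designs respect their zones", {
  fx <- fixture_bundle()
  tab <- fx$table
  p <- fx$proteins[["protein_120aa"]]
  d <- design_eco(p, tab)
  aa <- strsplit(p, "")[[1]]
  expect_equal(d$codons[1], "ATG")
  expect_equal(d$zone_map, zone_map(120))
  for (i in 3:10) {
    expect_equal(d$codons[i], pick_destabilized_codon(aa[i], tab))
  }
  for (i in c(11:45, 71:120)) {
    expect_equal(d$codons[i], pick_hc_codon(aa[i], tab))
  }
  expect_equal(d$codons[2], pick_start_context_codon(aa[2], tab))
})

test_that("designs translate back to the input protein", {
  fx <- fixture_bundle()
  set.seed(31)
  for (i in 1:25) {
    p <- random_protein(sample(5:150, 1))
    for (d in list(design_hc(p, fx$table),
                   design_eco(p, fx$table, seed = i),
                   design_eco(p, fx$table,
                              cfg = zone_config(middle_mode = "stochastic"),
                              seed = i))) {
      core <- substr(d$dna, 1, nchar(d$dna) - 3) # drop appended stop
      expect_identical(translate_dna(core), p)
      # independent oracle for the translation round trip
      expect_identical(
        as.character(Biostrings::translate(Biostrings::DNAString(core))), p)
    }
  }
})

test_that("ECO is deterministic per mode and differs from HC", {
  fx <- fixture_bundle()
  p <- fx$proteins[["protein_100aa"]]
  expect_identical(design_eco(p, fx$table)$dna, design_eco(p, fx$table)$dna)
  cfg <- zone_config(middle_mode = "stochastic")
  expect_identical(design_eco(p, fx$table, cfg, seed = 5)$dna,
                   design_eco(p, fx$table, cfg, seed = 5)$dna)
  expect_gt(sequence_difference(design_hc(p, fx$table)$dna,
                                design_eco(p, fx$table)$dna), 0)
})

test_that("design reports are written as FASTA, JSON and per-codon TSV", {
  fx <- fixture_bundle()
  d <- design_eco(fx$proteins[["protein_100aa"]], fx$table)
  prefix <- file.path(withr::local_tempdir(), "design")
  paths <- write_design(d, prefix, name = "p100", table = fx$table)
  expect_true(all(file.exists(paths)))
  rep <- jsonlite::read_json(paths[["json"]])
  expect_equal(rep$strategy, "ECO")
  expect_equal(rep$length_aa, 100L)
  tsv <- read.delim(paths[["tsv"]])
  expect_equal(nrow(tsv), 100L)
  expect_equal(tsv$zone, zone_map(100))
  fa <- Biostrings::readDNAStringSet(paths[["fasta"]])
  expect_equal(as.character(fa[[1]]), d$dna)
})
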