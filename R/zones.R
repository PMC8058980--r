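#' Zone configuration for expression cassette optimization
#'
#' The zoned (ECO) design divides a protein of length L into five regions,
#' indexed 1-based and inclusive like the usual "codons 11 to 45" phrasing:
#'
#' * `START` -- codon 1, always ATG;
#' * `CONSENSUS` -- codon 2, chosen to approximate an optimal translational
#'   start (Kozak-type) context, by default rewarding a G immediately after
#'   the start codon (`consensus_pattern = "G**"`);
#' * `DESTABILIZED` -- codons 3-10, the rarest usable synonymous codons, to
#'   weaken mRNA secondary structure around the start;
#' * `HEAD_HC` (codons 11-45) and `TAIL_HC` (the last 50 codons) -- the
#'   organism-preferred codon at every position;
#' * `MIDDLE` -- everything else, matched to the organism's average usage.
#'
#' For short proteins the zones collide; overlaps are resolved by the fixed
#' precedence START > CONSENSUS > DESTABILIZED > TAIL_HC > HEAD_HC > MIDDLE
#' (the 5' rules are the most mechanistic, and the tail rule is stated
#' unconditionally, so it beats the head).
#'
#' @param destabilized_span Two integers, first/last destabilized codon
#'   (default `c(3, 10)`).
#' @param head_hc_span Two integers, first/last head high-CAI codon
#'   (default `c(11, 45)`).
#' @param tail_hc_length Number of trailing high-CAI codons (default 50).
#' @param consensus_pattern Three-character pattern for the codon-2 triplet;
#'   `"*"` positions are unscored.
#' @param middle_mode `"quota"` for deterministic largest-remainder
#'   matching of the average usage, `"stochastic"` for seeded sampling.
#' @return A `zone_config` list.
#' @export
zone_config <- function(destabilized_span = c(3L, 10L),
                        head_hc_span = c(11L, 45L),
                        tail_hc_length = 50L,
                        consensus_pattern = "G**",
                        middle_mode = c("quota", "stochastic")) {
  middle_mode <- match.arg(middle_mode)
  destabilized_span <- as.integer(destabilized_span)
  head_hc_span <- as.integer(head_hc_span)
  tail_hc_length <- as.integer(tail_hc_length)
  stopifnot(length(destabilized_span) == 2L, length(head_hc_span) == 2L,
            destabilized_span[1L] >= 3L,
            destabilized_span[1L] <= destabilized_span[2L],
            head_hc_span[1L] > destabilized_span[2L],
            head_hc_span[1L] <= head_hc_span[2L],
            tail_hc_length >= 0L,
            nchar(consensus_pattern) == 3L)
  structure(list(destabilized_span = destabilized_span,
                 head_hc_span = head_hc_span,
                 tail_hc_length = tail_hc_length,
                 consensus_pattern = toupper(consensus_pattern),
                 middle_mode = middle_mode),
            class = "zone_config")
}

#' Zone labels for a protein of given length
#'
#' @param protein_length Number of amino acids (>= 1).
#' @param cfg A [zone_config()].
#' @return Character vector of length `protein_length` with values in
#'   `START`, `CONSENSUS`, `DESTABILIZED`, `HEAD_HC`, `MIDDLE`, `TAIL_HC`;
#'   every position gets exactly one label.
#' @examples
#' table(zone_map(120))
#' @export
zone_map <- function(protein_length, cfg = zone_config()) {
  L <- as.integer(protein_length)
  stopifnot(L >= 1L)
  z <- rep("MIDDLE", L)
  span <- function(a, b) if (a <= min(b, L)) seq(a, min(b, L)) else integer()
  ## lowest precedence first; later assignments override earlier ones
  z[span(cfg$head_hc_span[1L], cfg$head_hc_span[2L])] <- "HEAD_HC"
  if (cfg$tail_hc_length > 0L) {
    z[span(max(1L, L - cfg$tail_hc_length + 1L), L)] <- "TAIL_HC"
  }
  z[span(cfg$destabilized_span[1L], cfg$destabilized_span[2L])] <- "DESTABILIZED"
  if (L >= 2L) z[2L] <- "CONSENSUS"
  z[1L] <- "START"
  z
}
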