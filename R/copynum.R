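#' Binned read-depth profiles
#'
#' A `depth_profile` is a data frame of non-overlapping bins (0-based,
#' half-open intervals with columns `chrom`, `start`, `end`, `count`) tiling
#' a reference that has been augmented with the integrated cassette
#' sequence, plus the cassette interval itself as an attribute. It is the
#' input to the ratio genotyper in [call_copy_number()].
#'
#' @name depth_profile
NULL

new_depth_profile <- function(bins, bin_size, cassette_region,
                              chrom = "ref") {
  stopifnot(all(bins$end > bins$start))
  structure(bins,
            bin_size = as.integer(bin_size),
            cassette_region = as.numeric(cassette_region),
            chrom = chrom,
            class = c("depth_profile", "data.frame"))
}

#' @export
print.depth_profile <- function(x, ...) {
  r <- attr(x, "cassette_region")
  cat("Depth profile:", nrow(x), "bins of", attr(x, "bin_size"),
      "bp; cassette", paste0(attr(x, "chrom"), ":", r[1L], "-", r[2L]), "\n")
  NextMethod()
}

#' Simulate a binned read-depth profile over an augmented reference
#'
#' Stands in for whole-genome resequencing of a transformant: background
#' bins are drawn around `mean_bin_depth`, while bins inside the cassette
#' region have their mean scaled by `copy_number` (a bin straddling the
#' cassette boundary is scaled by its overlap fraction). `dispersion` is the
#' variance-to-mean ratio: 1 gives Poisson counts, greater than 1 a
#' negative-binomial with the same mean.
#'
#' @param reference_length Reference length in bp.
#' @param cassette_region Numeric length-2, 0-based half-open cassette
#'   interval on the reference.
#' @param copy_number True cassette copies (>= 0, need not be integer).
#' @param mean_bin_depth Expected count per background bin (> 0).
#' @param dispersion Variance/mean ratio (>= 1; 1 = Poisson).
#' @param bin_size Bin width in bp; a trailing partial bin is truncated with
#'   a warning, never silently merged.
#' @param seed Integer seed; identical seeds give identical profiles.
#' @param chrom Reference name recorded on the profile.
#' @return A [depth_profile].
#' @examples
#' p <- simulate_depth(50000, c(20000, 25000), copy_number = 6,
#'                     mean_bin_depth = 40, seed = 1)
#' call_copy_number(p)
#' @export
simulate_depth <- function(reference_length, cassette_region, copy_number,
                           mean_bin_depth = 40, dispersion = 1,
                           bin_size = 200, seed = NULL, chrom = "ref") {
  reference_length <- as.numeric(reference_length)
  cassette_region <- as.numeric(cassette_region)
  stopifnot(length(cassette_region) == 2L,
            cassette_region[1L] >= 0,
            cassette_region[2L] > cassette_region[1L],
            cassette_region[2L] <= reference_length,
            copy_number >= 0, mean_bin_depth > 0, dispersion >= 1,
            bin_size >= 1)
  starts <- seq(0, reference_length - 1, by = bin_size)
  ends <- pmin(starts + bin_size, reference_length)
  partial <- ends - starts < bin_size
  if (any(partial)) {
    warning("truncated ", sum(partial), " partial bin(s) at the reference end",
            call. = FALSE)
    starts <- starts[!partial]
    ends <- ends[!partial]
  }
  ## per-bin expected count: background, scaled by copy number over the
  ## fraction of the bin covered by the cassette
  ov <- pmax(0, pmin(ends, cassette_region[2L]) -
                  pmax(starts, cassette_region[1L])) / (ends - starts)
  mu <- mean_bin_depth * (1 - ov + ov * copy_number)
  counts <- with_seed(seed, {
    if (dispersion > 1) {
      size <- mu / (dispersion - 1) # NB: var = mu + mu^2/size = dispersion*mu
      out <- integer(length(mu))
      pos <- mu > 0
      out[pos] <- stats::rnbinom(sum(pos), size = size[pos], mu = mu[pos])
      out
    } else {
      stats::rpois(length(mu), mu)
    }
  })
  bins <- data.frame(chrom = chrom, start = starts, end = ends,
                     count = as.numeric(counts))
  new_depth_profile(bins, bin_size, cassette_region, chrom)
}

#' Call the cassette copy-number genotype from a depth profile
#'
#' The genotyper exploits that the cassette interval is known a priori (the
#' reference is augmented with the transformation plasmid), so no
#' segmentation is needed: the cassette's mean per-bin depth is divided by a
#' robust baseline over all non-cassette bins (median by default), the ratio
#' is scaled by ploidy to a fractional copy estimate, and the genotype is
#' the estimate rounded half away from zero.
#'
#' @param profile A [depth_profile].
#' @param ploidy Genome copies per cell (default 1, the haploid
#'   R. toruloides context).
#' @param baseline `"median"` (robust to repeat regions, default) or
#'   `"mean"`.
#' @return A `region_call` list: `region`, `mean_region_depth`,
#'   `depth_ratio`, `copy_estimate`, `genotype`, `dispersion_sd` (sd of the
#'   cassette bin counts), `baseline`, `n_region_bins`, `n_baseline_bins`.
#' @export
call_copy_number <- function(profile, ploidy = 1,
                             baseline = c("median", "mean")) {
  stopifnot(inherits(profile, "depth_profile"))
  baseline <- match.arg(baseline)
  region <- attr(profile, "cassette_region")
  mid <- (profile$start + profile$end) / 2
  in_region <- mid >= region[1L] & mid < region[2L]
  n_bg <- sum(!in_region)
  n_reg <- sum(in_region)
  if (n_bg < 10L) {
    stop("need at least 10 non-cassette bins for a baseline (have ", n_bg,
         ")", call. = FALSE)
  }
  if (n_reg < 1L) {
    stop("no bins fall inside the cassette region", call. = FALSE)
  }
  base_stat <- if (baseline == "median") stats::median(profile$count[!in_region])
               else mean(profile$count[!in_region])
  if (base_stat <= 0) {
    stop("uncallable profile: baseline ", baseline, " depth is ", base_stat,
         call. = FALSE)
  }
  mean_depth <- mean(profile$count[in_region])
  ratio <- mean_depth / base_stat
  est <- ratio * ploidy
  structure(list(region = region,
                 chrom = attr(profile, "chrom"),
                 bin_size = attr(profile, "bin_size"),
                 mean_region_depth = mean_depth,
                 baseline_stat = base_stat,
                 baseline = baseline,
                 depth_ratio = ratio,
                 ploidy = ploidy,
                 copy_estimate = est,
                 genotype = as.integer(round_half_away(est)),
                 dispersion_sd = stats::sd(profile$count[in_region]),
                 n_region_bins = n_reg,
                 n_baseline_bins = n_bg),
            class = "region_call")
}

#' @export
print.region_call <- function(x, ...) {
  cat(sprintf(
    "Region %s:%d-%d (bin %d bp): depth ratio %.3f, copy estimate %.3f, genotype %d\n",
    x$chrom, x$region[1L], x$region[2L], x$bin_size, x$depth_ratio,
    x$copy_estimate, x$genotype))
  invisible(x)
}

#' Re-bin a depth profile into wider bins
#'
#' Aggregates counts of a fine-binned (or per-base) profile into bins of
#' `new_size`, which must be a multiple of the current bin size. The
#' cassette annotation is carried over.
#'
#' @param profile A [depth_profile].
#' @param new_size Target bin width in bp.
#' @return A [depth_profile] at the new bin size.
#' @export
rebin_profile <- function(profile, new_size) {
  stopifnot(inherits(profile, "depth_profile"))
  old <- attr(profile, "bin_size")
  new_size <- as.integer(new_size)
  if (new_size == old) return(profile)
  if (new_size < old || new_size %% old != 0L) {
    stop("new bin size (", new_size, ") must be a multiple of the current ",
         "bin size (", old, ")", call. = FALSE)
  }
  k <- new_size %/% old
  ord <- order(profile$start)
  n_full <- (nrow(profile) %/% k) * k
  if (n_full < nrow(profile)) {
    warning("truncated ", nrow(profile) - n_full,
            " trailing fine bin(s) not filling a ", new_size, " bp bin",
            call. = FALSE)
  }
  idx <- ord[seq_len(n_full)]
  bins <- data.frame(
    chrom = attr(profile, "chrom"),
    start = profile$start[idx][seq(1L, n_full, by = k)],
    end = profile$end[idx][seq(k, n_full, by = k)],
    count = colSums(matrix(profile$count[idx], nrow = k)))
  new_depth_profile(bins, new_size, attr(profile, "cassette_region"),
                    attr(profile, "chrom"))
}

#' Copy-number calls at several bin sizes
#'
#' Runs [call_copy_number()] on the same underlying depth at each requested
#' bin size (the profile is re-binned from its finest resolution) and
#' reports how far the copy estimates spread -- the consistency check
#' usually run at 100, 200 and 1000 bp bins.
#'
#' @param profile A [depth_profile] at the finest resolution of interest.
#' @param sizes Bin sizes in bp (each >= 50 and a multiple of the profile's
#'   bin size). Default `c(100, 200, 1000)`.
#' @param ploidy,baseline Passed to [call_copy_number()].
#' @return List with `calls` (one `region_call` per size, named by size) and
#'   `max_estimate_difference` (max pairwise copy-estimate difference).
#' @export
compare_bin_sizes <- function(profile, sizes = c(100L, 200L, 1000L),
                              ploidy = 1, baseline = "median") {
  stopifnot(length(sizes) >= 1L)
  if (any(sizes < 50)) {
    stop("bin sizes below 50 bp are not supported", call. = FALSE)
  }
  calls <- lapply(sizes, function(s) {
    call_copy_number(rebin_profile(profile, s), ploidy = ploidy,
                     baseline = baseline)
  })
  names(calls) <- as.character(sizes)
  ests <- vapply(calls, `[[`, numeric(1L), "copy_estimate")
  list(calls = calls,
       max_estimate_difference = max(ests) - min(ests))
}

#' Regression of product titer on cassette copy number
#'
#' Ordinary least squares of titer against copy number across a strain
#' panel, the dosage-response summary usually quoted as an R-squared and a
#' p-value for the slope (t test on the correlation with n - 2 degrees of
#' freedom).
#'
#' @param copy_number Numeric vector of cassette copies per strain.
#' @param titer Numeric vector of product titers (mg/L), same length.
#' @return A `titer_regression` list: `n`, `slope`, `intercept`,
#'   `r_squared`, `p_value`.
#' @examples
#' fit_copy_titer(c(1, 2, 3), c(100, 200, 300))
#' @export
fit_copy_titer <- function(copy_number, titer) {
  x <- as.numeric(copy_number)
  y <- as.numeric(titer)
  if (length(x) != length(y)) {
    stop("copy_number and titer lengths differ", call. = FALSE)
  }
  if (length(x) < 3L) {
    stop("need at least 3 strains (have ", length(x), ")", call. = FALSE)
  }
  if (length(unique(x)) == 1L) {
    stop("all copy numbers are equal; slope is undefined", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  ## summary.lm warns on an exactly colinear panel; the fit itself is fine
  sm <- suppressWarnings(summary(fit))
  r2 <- sm$r.squared
  ## exact colinearity leaves a zero residual t-test; report p = 0 then
  p <- if (r2 >= 1) 0 else sm$coefficients["x", "Pr(>|t|)"]
  structure(list(n = length(x),
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2,
                 p_value = unname(p)),
            class = "titer_regression")
}

#' @export
print.titer_regression <- function(x, ...) {
  cat(sprintf(
    "titer ~ copy number (n = %d): slope %.3f, intercept %.3f, R^2 = %.3f, p = %.3g\n",
    x$n, x$slope, x$intercept, x$r_squared, x$p_value))
  invisible(x)
}

#' Depth-profile I/O
#'
#' `write_depth_tsv()` writes a BED-like TSV (`chrom`, `start`, `end`,
#' `count`, 0-based half-open) with the bin size and cassette region stored
#' in `#`-prefixed header lines; `read_depth_tsv()` restores the profile.
#' `read_basewise_depth()` reads three-column per-base depth text
#' (chrom, 1-based position, depth, as produced by coverage tools) into a
#' 1-bp profile ready for [rebin_profile()]; the cassette interval must be
#' supplied as a `"chrom:start-end"` string (0-based half-open).
#'
#' @param profile A [depth_profile].
#' @param path File path.
#' @param region Cassette region string `"chrom:start-end"` (for
#'   `read_basewise_depth()`).
#' @return The profile (readers) or `path`, invisibly (writer).
#' @export
write_depth_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "depth_profile"))
  r <- attr(profile, "cassette_region")
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("#bin_size=", attr(profile, "bin_size")),
    paste0("#cassette_region=", attr(profile, "chrom"), ":",
           fmt(r[1L]), "-", fmt(r[2L])),
    paste(c("chrom", "start", "end", "count"), collapse = "\t"),
    paste(profile$chrom, fmt(profile$start), fmt(profile$end),
          fmt(profile$count), sep = "\t")), con)
  invisible(path)
}

#' @rdname write_depth_tsv
#' @export
read_depth_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  bs <- sub("^#bin_size=", "", hdr[startsWith(hdr, "#bin_size=")])
  reg <- sub("^#cassette_region=", "", hdr[startsWith(hdr, "#cassette_region=")])
  if (length(bs) != 1L || length(reg) != 1L) {
    stop("depth TSV lacks #bin_size= / #cassette_region= header lines",
         call. = FALSE)
  }
  parsed <- parse_region(reg)
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.delim(text = paste(body, collapse = "\n"),
                          stringsAsFactors = FALSE)
  new_depth_profile(df[, c("chrom", "start", "end", "count")],
                    as.integer(bs), c(parsed$start, parsed$end),
                    parsed$chrom)
}

#' @rdname write_depth_tsv
#' @export
read_basewise_depth <- function(path, region) {
  parsed <- parse_region(region)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("chrom", "pos", "depth"))
  bins <- data.frame(chrom = df$chrom, start = df$pos - 1, end = df$pos,
                     count = as.numeric(df$depth))
  new_depth_profile(bins, 1L, c(parsed$start, parsed$end), parsed$chrom)
}

parse_region <- function(region) {
  m <- regmatches(region,
                  regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1L]]
  if (length(m) != 4L) {
    stop("region must look like 'chrom:start-end', got '", region, "'",
         call. = FALSE)
  }
  list(chrom = m[2L], start = as.numeric(m[3L]), end = as.numeric(m[4L]))
}
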