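---
title: "Zoned codon optimization and cassette copy-number genotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zoned codon optimization and cassette copy-number genotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonopt)
```

## The problem

When a heterologous gene is expressed in a non-model host such as the
oleaginous yeast *Rhodosporidium toruloides*, two design questions dominate
the engineering loop. First, which synonymous codons should encode the
protein? Second, once the expression cassette has integrated at random loci
(as it does under *Agrobacterium*-mediated transformation), how many copies
landed in the genome — since product titer often scales with cassette dose?
`codonopt` addresses both at desk scale: a codon-usage and design toolkit,
and a read-depth ratio genotyper with a matching simulator.

## Codon usage tables and scores

A usage table is built by tallying in-frame codons over a CDS set
(`build_usage_table()`). For codon *c* in the synonymous family of amino
acid *a*, the within-family frequency is
$f_c = n_c / \sum_{c' \in a} n_{c'}$ and the relative adaptiveness is
$w_c = f_c / \max_{c' \in a} f_{c'}$, so the preferred codon of every family
has $w = 1$. The codon adaptation index of a gene is the geometric mean
$\mathrm{CAI} = (\prod_i w_{c_i})^{1/L}$ over its sense codons; RSCU is the
count divided by the family mean and sums to the family degeneracy. Two
further scores characterise designs: GC content (overall and third-position)
and `usage_distance()`, an amino-acid-composition-weighted total-variation
distance between a gene's within-family codon fractions and the table's.

Numerical choices worth knowing:

* **Zero-count codons** get a pseudo-floor weight (default `0.01`,
  configurable) so CAI stays defined on sparse tables; a geometric mean
  with a literal zero would collapse to zero on a single unseen codon.
* **Stop codons** carry no weight and are excluded from CAI and
  usage distance; the most frequent stop triplet in the table is recorded
  and appended to designs by default.
* **Met and Trp** (single-codon families) enter CAI with weight 1. They
  cannot change the ranking of designs but do change the absolute score,
  so the convention is fixed rather than optional.
* Codons containing `N` are skipped during tallying (draft CDS sets are
  usable); RNA input is normalised to DNA.

## The two design strategies

**HC (high-CAI)** encodes every residue with the family's maximal-count
codon. It is deterministic and its output scores CAI = 1 whenever every
required family has counts.

**ECO (expression cassette optimization)** is the zoned strategy. For a
protein of length $L$ (1-based codon positions):

| zone | positions (defaults) | rule |
|---|---|---|
| START | 1 | ATG |
| CONSENSUS | 2 | best match to a start-context pattern |
| DESTABILIZED | 3–10 | minimal nonzero-count synonym |
| HEAD_HC | 11–45 | maximal-count synonym |
| MIDDLE | remainder | match average usage |
| TAIL_HC | last 50 | maximal-count synonym |

The rationale: the 5' rules reduce mRNA secondary structure near the start
codon (rare codons tend to be AT-richer here and the region stays
unstructured), the head and tail get the translationally preferred codons,
and the middle mirrors the host's average usage so the design does not
deplete any one tRNA pool.

Design decisions that were genuinely open:

* **Zone precedence for short proteins.** Nothing pins down how zones
  interact when $L < 95$. The precedence used is
  START > CONSENSUS > DESTABILIZED > TAIL_HC > HEAD_HC > MIDDLE: the 5'
  rules are the most mechanistic so they win, and the tail rule is stated
  unconditionally so it beats the head. An 8-residue protein is therefore
  START, CONSENSUS, then six DESTABILIZED positions.
* **"Less frequently used"** is read as the minimal *nonzero*-count codon:
  a codon the organism never uses is plausibly unusable, not merely
  destabilizing.
* **Start context.** The consensus behind codon 2 is not printed anywhere
  authoritative, so it is a configurable three-character pattern; the
  default `"G**"` rewards a G immediately after ATG, the strongest and most
  widely conserved Kozak-type preference. Ties resolve by usage count, then
  alphabetically.
* **Middle-region filling** comes in two modes because either could have
  been intended. `quota` (default) apportions each family's positions by
  largest remainder on $n \cdot f_c$ — exact to ±1 and fully deterministic,
  with remainder ties and placement order fixed alphabetically/by
  descending quota. `stochastic` samples each occurrence at the family
  frequencies under a caller-supplied seed; the RNG state of the session is
  saved and restored around the draw.
* **The last 50 codons** exclude the appended stop codon.
* All tie-breaks everywhere are alphabetical by codon, so repeated runs are
  byte-identical.

```{r design}
fx <- generate_fixtures(seed = 42)
p <- fx$proteins[["protein_120aa"]]
design_hc(p, fx$table)
design_eco(p, fx$table)
```

## Read-depth copy-number genotyping

The genotyper assumes the reference was augmented with the cassette
sequence, so the interval of interest is known a priori and no segmentation
is needed. Read counts are binned (default 200 bp, 0-based half-open bins;
partial bins at contig ends are truncated with a warning); the cassette's
mean per-bin depth is divided by the **median** depth of all non-cassette
bins; the ratio times the ploidy (default 1, a haploid host) is the
fractional copy estimate; the genotype is that estimate rounded half away
from zero (so 6.5 calls as 7 — no rounding convention is standard here, so
it is documented rather than assumed). The median baseline is deliberately
robust: 1% of bins at 10× depth (a collapsed repeat, say) moves it by well
under 2%, which is why it is preferred over the mean.

`simulate_depth()` is the matching generator: background bins are Poisson
(or negative-binomial when the variance/mean ratio `dispersion` exceeds 1)
around `mean_bin_depth`, cassette bins have their mean scaled by the true
copy number, and bins straddling the cassette boundary are scaled by their
overlap fraction. The study conditions used throughout the tests and the
acceptance script are a 500 kb reference, a 5 kb cassette, 200 bp bins,
mean bin depth 40 and Poisson noise, with true copies spanning 1–10 — the
range a transformant panel actually shows (single-copy through ~10-copy
strains, with a 6-copy second cassette a realistic mid-range dose). Under
these conditions the integer genotype is recovered in ≥ 99% of seeded
replicates, and estimates at 100 vs 200 bp bins agree within half a copy —
which is what "the bin size does not matter much" should look like when the
signal is this strong.

What the simulator does *not* emulate: mappability variation, GC bias,
duplicated reads, partial cassette integrations and boundary effects of
real alignments. Passing the recovery tests therefore validates the ratio
estimator and its robustness to counting noise, not concordance with a full
CNV caller on real sequencing runs.

```{r copynum}
prof <- simulate_depth(5e5, c(250000, 255000), copy_number = 6,
                       mean_bin_depth = 40, bin_size = 200, seed = 1)
call_copy_number(prof)
```

## Copy number versus titer

`fit_copy_titer()` is ordinary least squares of titer on copy number with
$R^2$ the squared Pearson correlation and the p-value from the
$t = r\sqrt{(n-2)/(1-r^2)}$ statistic. It requires at least three strains
and non-constant copy numbers; an exactly colinear panel returns
$R^2 = 1$ and $p = 0$. The acceptance script exercises it on a synthetic
20-strain panel whose titers rise ~300 mg/L per copy with one
copy-equivalent (sd = 300 mg/L) of Gaussian noise — a noise level chosen to
emulate biological replicate scatter in small-culture titer screens, set
once in the generator and not revisited.

```{r titer}
fit_copy_titer(c(1, 3, 5, 7, 10), c(310, 890, 1620, 2050, 3110))
```

## The synthetic fixture generator

`generate_fixtures()` makes the whole toolkit testable offline: ≥ 50 CDS
records whose within-family codon probabilities fall off as $3^{-\text{rank}}$
(a strong, unambiguous bias so "preferred" and "rare" are never ties), a
pad record containing every sense codon once (guaranteeing no empty
family), proteins of 8, 100, 120 and 300 residues, and depth profiles at
copies 1, 6, 7 and 10 echoing a transformant panel. One seed drives
everything and identical seeds give byte-identical bundles. Because the
bias is synthetic, fixture CAI values say nothing about real
*R. toruloides* genes; users supply their own CDS set or table for real
designs.

## Problem sizes

The shipped tests run the designers on proteins up to 300 residues, the
CAI oracle on 1,000 random 100-codon genes, the stochastic matcher at
10,000 draws per family, and the genotyper on 200 replicates per check of
the 2,500-bin reference — sizes at which every statistical assertion is
far from its threshold while the whole suite stays quick on a laptop.

## Known limitations

* No restriction-site, homopolymer or splice-motif avoidance, and no
  thermodynamic folding score — the 5' rule operates purely through codon
  frequency.
* The genotyper calls one known region per profile; it is not a
  genome-wide CNV scanner.
* Usage tables treat the CDS set as one pool; no expression weighting of
  genes is applied when counting.
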