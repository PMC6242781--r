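---
title: "Nucleotide signatures for species authentication: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nucleotide signatures for species authentication: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucsig)
```

## The problem

Herbal products such as Cistanches Herba (the dried stems of *Cistanche
deserticola* or *Cistanche tubulosa*) are routinely adulterated with
cheaper look-alike species (*Cynomorium songaricum*, *Cistanche sinensis*,
*Boschniakia rossica*, *Orobanche coerulescens*). Full-length DNA barcodes
such as ITS2 (~230 bp plus primers) often fail on processed products -
pills, extracts, decoctions - because manufacturing fragments the DNA.
A *nucleotide signature* is a short (~30-40 bp) subsequence containing one
or more species-diagnostic SNPs and absent from every other species in the
reference universe; being short, it remains amplifiable from degraded
material when paired with primers that flank a 70-140 bp product.

`nucsig` implements that workflow end to end: panel alignment, diagnostic
SNP calling, signature extraction with uniqueness verification, primer-pair
design with an in-silico PCR specificity screen, qPCR sensitivity
modeling, and product classification, plus seeded synthetic data so each
stage is testable without any external database.

## Diagnostic sites and signatures

Given a labeled alignment and a target species, a column is **diagnostic**
when

1. at least a fraction `fixedness` (default 1.0) of the target rows share
   one concrete allele - rows showing a gap or `N` are excluded from the
   denominator and reported in `n_excluded`;
2. no non-target row can carry that allele: a concrete match disqualifies
   the column, and so does an ambiguity code whose set contains the allele
   (conservative: `R` in a non-target row blocks both `A` and `G`);
3. the target allele is a real base, never a gap.

Diagnosticity is allele-presence-based, not frequency-based: one
non-target occurrence vetoes the column. That matches the absolute
specificity a diagnostic assay needs - a "mostly absent" allele is not a
basis for an authentication claim.

**Signature extraction** scans windows on a representative target row (the
first one in alignment order, fixed for determinism) in ungapped
coordinates: shortest admissible length first (`L_min` = 30 bp by default,
growing to `L_max` = 40), leftmost start first. A window qualifies when it
contains at least `min_sites` diagnostic sites and passes the uniqueness
check: a seed-and-extend search of the window against every non-target
panel sequence must find no hit with identity at or above `max_ident`
(default 1.0) over full query coverage. The first qualifying window wins;
ties cannot occur because the scan order is total. The window bounds are
therefore reproducible but not unique in principle - the source data never
states how the published window bounds were chosen, so we fix our own
deterministic rule rather than guess theirs.

## Alignment

Signature discovery needs a columnwise view of the panel. Pre-aligned
FASTA is accepted directly; unaligned panels go through a
Needleman-Wunsch/Gotoh pairwise aligner and a star-progressive multiple
alignment:

* scheme defaults: match +1, mismatch -2, gap open -5, gap extend -2; a
  gap run of length L costs `open + L * ext`. Barcode-scale congeneric
  sequences carry mostly substitutions and few indels, so gaps are made
  expensive relative to mismatches.
* ambiguity handling mirrors the diagnostic rule: a pair scores as a match
  only when one side is a concrete base contained in the other side's
  IUPAC set; two ambiguity codes (even equal ones) score as a mismatch.
* traceback ties resolve diagonal > up > left, making output byte-stable.
* the star MSA picks the center sequence by maximal summed pairwise score
  and merges pairwise alignments under "once a gap, always a gap". For
  congeneric ITS2-scale divergence (a few percent) iterative refinement
  buys nothing; sequences of equal length with no indels come out
  gap-free, which is the common case for this marker.

All coordinates in the package are 1-based and closed, the native
R/Bioconductor (IRanges) convention; mixing conventions inside an R
package is a richer source of bugs than either convention itself.

## Local search and significance

Uniqueness checks use an ungapped seed-and-extend search: exact 7-mer
seeds on both strands, x-drop extension (drop tolerance 10 score units),
per-subject best non-overlapping hits. Raw scores are normalized to bit
scores via the Karlin-Altschul transform

$$S' = \frac{\lambda S - \ln K}{\ln 2}, \qquad E = m\,n\,2^{-S'}$$

with defaults `lambda_ka` = 1.28 and `k_ka` = 0.46, appropriate for the
+1/-2 scoring system; both are exposed because any published verification
against an external database depends on unstated program parameters and a
moving database, which is why external score tables are not reproduction
targets here. The E-value uses the raw m x n search space with no
edge-effect (length) correction - a documented simplification that is
conservative for the 30-40 bp queries this package serves. Gapped
extension is deliberately absent: a 30-40 bp diagnostic hit interrupted by
an indel is not the kind of near-identity that threatens uniqueness at the
`max_ident` = 1.0 default.

## In-silico PCR and primer design

Wet-lab specificity is modeled by a 3'-anchored mismatch policy: a primer
binds a template site when it has at most `max_mismatch` (default 2)
mismatches overall and none in its `three_prime_anchor` (default 3)
3'-terminal bases - polymerase extension is far more sensitive to
3'-terminal mismatches than to internal ones. The forward primer is
matched on the forward strand, the reverse primer as its reverse
complement downstream, non-overlapping, and every product between
`min_amplicon` and `max_amplicon` is reported. These tolerances are
modeling choices: the wet-lab work demonstrates specificity but never
parameterizes it.

Primer design enumerates candidate windows on the signature's reference
record (lengths 18-21 nt and amplicons 70-140 bp by default, spanning the
packaged assays' 71-134 bp), requires the amplicon to contain a diagnostic
site, filters on a Tm window (45-65 degC) and Tm balance (<= 5 degC), and
applies a minimal self-dimer screen (a primer whose 3'-terminal 5-mer can
anneal perfectly within itself is rejected). Surviving pairs are ranked by
specificity margin - the smallest combined number of primer mismatches
against any non-target - then Tm balance, then position; candidates are
screened for cross-amplification in rank order, so the returned list is
the head of the fully screened ranking. A pair whose margin is zero (both
primers match some non-target perfectly) is rejected outright.

Melting temperatures use the SantaLucia (1998) unified nearest-neighbor
parameters with the entropy salt correction `0.368 (N-1) ln[Na+]` at 50 mM
monovalent salt and a 0.25 uM total oligo concentration (`CT/4` in the
two-state model); sequences under 14 nt fall back to the Wallace rule.
The implementation is cross-checked in the test suite against a frozen
value from an independent published-parameter calculator (52.7487 degC for
the first packaged forward primer), with agreement well inside 0.5 degC.

## qPCR sensitivity

Detection sensitivity follows the standard dilution-series model: mean
quantification cycle versus log10 of the weight ratio,

$$C_q = a + b \log_{10} r,$$

fitted by ordinary least squares over the detected points.
"Not detected" ratios are censored - excluded from the fit rather than
imputed at a ceiling, because the instrument's censoring cycle is unknown.
A weighted (1/sd^2) fit is available but off by default; the packaged
table's replicate SDs are small and near-homoscedastic. Amplification
efficiency is `E = 10^(1/|b|) - 1` and the limit-of-detection ratio is the
dilution at which the fitted line crosses a Cq cutoff,
`r = 10^((cutoff - a)/b)`. The default cutoff of 37 cycles sits between
the largest Cq printed in the packaged table (37.08) and typical
instrument ceilings; it is a documented guess and configurable. On the
packaged table the fitted lines cross 37 somewhat *beyond* each series'
observed censoring boundary - the predicted Cq at the first censored ratio
falls between 34 and 37 in every row - so observed censoring is slightly
more aggressive than a Cq-37 rule; the test suite asserts exactly that
bracketing. One printed pair in the *O. coerulescens* row decreases by
0.22 cycles between adjacent dilutions; that dip is well inside its
replicate SDs, so the monotonicity check tolerates decreases up to the sum
of the two SDs instead of asserting something the table itself violates.

## Product classification

A product's detected-species set maps to one of five mutually exclusive
categories: `authentic` (only official species), `adulterated_mixture`
(official together with adulterant - or, by this package's choice, any
non-official - species), `substituted` (adulterants without officials),
`nonpanel_substituted` (only species outside both sets, such as a
*Salvia miltiorrhiza* slice sold as Cistanches Herba), and `no_detection`.
The headline adulteration rate counts mixtures plus panel substitutions;
non-panel substitutions are surfaced in their own count because the
packaged survey's printed rates exclude them, and hiding that arithmetic
would make the discrepancy invisible. Rates are rounded half-up to one
decimal to match printed style; raw fractions are also returned.

## Synthetic data

The generator emulates what matters statistically about a congeneric
ITS2 panel: a shared ancestor (default 230 bp), per-species divergence
(default 0.05 substitutions/site), light within-species variation
(default 0.005), and planted diagnostic SNPs that are written into every
member of their species and scrubbed from all others. Substitutions are
uniform (Jukes-Cantor-like); there are no indels by default because the
signature caller excludes gap columns anyway, and no secondary-structure
or PCR-chimera realism. Mixture pools draw fragment source species
proportional to mass fractions; fragment starts are uniform and lengths
geometric - a one-parameter model chosen because the only degradation
data available are band presence/absence. Decoction pools shrink the mean
fragment length exponentially, `lambda(t) = lambda0 exp(-k t)` with
defaults `lambda0` = 500 bp and `k` = 0.015/min chosen so that a 123-bp
assay remains detectable through ~150 min of boiling and disappears by
210-240 min, the qualitative pattern reported for boiled samples. All
generators are pure functions of (spec, seed) and restore the caller's
RNG state.

Because the generator plants truth by construction, passing tests show
that the algorithms recover what was planted under the stated noise
model - they do not show robustness to alignment error, indel-rich
markers, chimeric amplicons, or sequencing noise, none of which the
generator emulates.

## Numerical and testing choices

* Dynamic-programming matrices store exact integer-valued doubles;
  "minus infinity" is a large finite constant (-1e15) so traceback
  equality tests stay exact.
* All tie-breaks (traceback direction, window order, candidate ranking,
  representative-row choice) are total orders, making every pipeline
  output deterministic.
* Monte-Carlo checks (mixture composition, decoction detection decay) use
  fixed seed grids and binomial tolerance bands; the decoction
  monotonicity check allows adjacent increases up to 0.1 in estimated
  probability, the noise floor of 30 replicates.
* Test problem sizes - panels of 4 species x 3 sequences x 200-230 bp,
  pools of 150-10000 fragments, 200 qPCR replicates - keep the full suite
  under a minute while leaving each statistical assertion well-powered;
  they are the sizes at which the brute-force oracles (exhaustive
  alignment enumeration, quadratic local-alignment scans, naive column
  scans) remain exact and fast.

## Known limitations

* Ungapped uniqueness checking can miss gapped near-copies; irrelevant at
  `max_ident` = 1 but worth knowing if you lower it.
* The star MSA has no refinement pass; for markers with heavy indel
  activity, align externally and supply the aligned FASTA.
* The E-value lacks finite-size correction and is therefore mildly
  anti-conservative for very short subjects.
* In-silico PCR treats primer binding as mismatch counting; it knows
  nothing about duplex thermodynamics, secondary structure or multiplex
  interactions.
* The qPCR limit of detection extrapolates a fitted line; it inherits the
  cutoff guess and says nothing about the instrument's true censoring
  rule.
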