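# nucsig

Species-diagnostic nucleotide signatures for authenticating herbal
products from degraded DNA.

## The problem

Cistanches Herba — the dried stems of *Cistanche deserticola* or
*Cistanche tubulosa* — is widely adulterated with cheaper look-alikes
(*Cynomorium songaricum*, *Cistanche sinensis*, *Boschniakia rossica*,
*Orobanche coerulescens*). Standard DNA barcodes such as full-length ITS2
cannot be amplified from heavily processed products (pills, extracts,
decoctions) because manufacturing fragments the DNA. The way out is a
**nucleotide signature**: a short (~30–40 bp) window around one or more
diagnostic SNPs that occurs in exactly one species of the reference
panel, paired with species-specific primers producing a 70–140 bp
amplicon that survives degradation.

`nucsig` is a toolkit for that workflow, aimed at lab scientists and
bioinformaticians doing molecular authentication:

* **seqio / align** — labeled FASTA panels, pairwise (Needleman–Wunsch /
  Gotoh, affine gaps) and star-progressive multiple alignment;
* **signatures** — diagnostic-site calling (an alignment column where the
  target allele is absent from every non-target row) and minimal unique
  window extraction;
* **search** — ungapped seed-and-extend local search with
  Karlin–Altschul statistics, `S' = (λS − ln K)/ln 2`, `E = m·n·2^(−S')`,
  used to verify signature uniqueness;
* **assay** — nearest-neighbor Tm (SantaLucia 1998 unified parameters),
  primer-pair design with a cross-species specificity screen, and
  in-silico PCR with a 3'-anchored mismatch policy (≤ 2 mismatches per
  primer, none in the 3'-terminal 3 bases);
* **quant** — qPCR sensitivity: `Cq = a + b·log10(ratio)` by OLS,
  amplification efficiency `E = 10^(1/|b|) − 1`, limit-of-detection ratio
  at a Cq cutoff;
* **survey** — classification of products as authentic / adulterated
  mixture / substituted from detected-species sets, with aggregate rates;
* **synthetic** — seeded generators for ITS2-like panels with planted
  SNPs, weighted mixture pools, and decoction-style degraded pools.

The package ships the Cistanches Herba reference fixtures as plain-text
data: the four published signatures (30/34/37/31 bp), the six primer
pairs with expected amplicons (123/132/134/131/72/71 bp), the full
qPCR sensitivity table (Cq versus weight ratio, 10:1 … 60000:1), and the
66-product market survey.

## Worked example

```r
library(nucsig)

## 1. The packaged survey: 66 commercial products
summarize_survey(load_survey_fixture())
#> Survey of 66 products
#>   authentic:             41
#>   adulterated (mixture): 13
#>   substituted (panel):   11
#>   substituted (other):   1
#>   no detection:          0
#>   adulteration rate:     36.4%  (mixture 19.7%, substitution 16.7%)
```

36.4% of products contain something other than the official species: 13
official/adulterant mixtures (19.7%), 11 substitutions with panel
adulterants (16.7%), plus one slice substituted with a species outside
the panel entirely (*Salvia miltiorrhiza*), counted separately.

```r
## 2. A packaged assay and its expected product
a <- load_assays()[[1]]
a
#> Assay SYF1/SYR1 -> Cynomorium songaricum (123 bp)
#>   F 5'-CTCAATGTGCTGCTGCTT-3'  Tm 52.7 degC
#>   R 5'-AGACTTACCGCTCACAATG-3'  Tm 51.5 degC
insilico_pcr(a, assay_template(a))$length
#> [1] 123

## 3. qPCR sensitivity for one adulterant
fit_cq_model(load_cq_table()[["Boschniakia rossica"]])
#> Cq = 13.007 + 4.9429 * log10(ratio)   [Boschniakia rossica]
#>   r^2 = 0.9761, efficiency = 59.3%, LOD ratio at Cq 37 = 71435:1
```

The Cq of the *B. rossica* assay rises log-linearly as the adulterant is
diluted against genuine material; the series stays detectable through
the 30000:1 mixture, and the fitted line crosses a Cq-37 ceiling around
a 71000:1 dilution.

```r
## 4. Discovery on a synthetic panel with two planted diagnostic SNPs
spec <- panel_spec(n_species = 4, n_per_species = 3,
                   interspecies_divergence = 0.05,
                   intraspecies_divergence = 0,
                   planted_sites = list(sp2 = list(position = c(100, 112),
                                                   allele = c("G", "T"))),
                   seed = 1)
panel <- simulate_panel(spec)
aln   <- build_msa(panel$records)
sites <- find_diagnostic_sites(aln, panel, "sp2")
extract_signature(aln, panel, "sp2", sites)
#> Nucleotide signature for sp2
#>   ATGACAGGCCGGAAACCGCGCGAAAACAAC (30 bp)
#>   ref sp2_1:1-30, diagnostic offsets: 18, 21
```

Both planted columns (100 and 112) are recovered among the called sites,
and the extracted window is the shortest, leftmost 30-mer containing a
diagnostic site that occurs in no other species of the panel.

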