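test_that("melting temperatures follow Wallace and nearest-neighbor models", {
  expect_equal(primer_tm("ACGT"), 12)  # 2*2 + 4*2
  expect_equal(primer_tm("AATT"), 8)
  ## GC monotonicity at equal length
  expect_gt(primer_tm("GCGCGCGCGCGCGC"), primer_tm("ATATATATATATAT"))
  ## frozen external oracle (Biopython MeltingTemp, SantaLucia 1998 unified,
  ## Na = 50 mM, CT/4 = 62.5 nM): SYF1 = 52.7487 degC
  expect_equal(primer_tm("CTCAATGTGCTGCTGCTT"), 52.7487, tolerance = 0.5)
  expect_equal(primer_tm("AGACTTACCGCTCACAATG"), 51.5481, tolerance = 0.5)
  expect_equal(primer_tm("CCTTTAGGGTGATACTTAGGT"), 49.9752, tolerance = 0.5)
  expect_error(primer_tm("ACGTN"), "parameter error")
})

test_that("primer and assay constructors enforce their invariants", {
  expect_error(primer("p", "ACGTACGTACGT"), "length")       # 12 nt
  expect_error(primer("p", "ACGTRACGTACGTACGTA"), "A/C/G/T")
  f <- primer("F", "CTCAATGTGCTGCTGCTT")
  r <- primer("R", "AGACTTACCGCTCACAATG")
  expect_equal(f$length, 18L)
  expect_error(assay(f, r, "X", expected_amplicon = 20), "shorter")
  a <- assay(f, r, "Cy. songaricum", 123)
  expect_equal(a$target_species, "Cynomorium songaricum")
})

test_that("packaged assays re-validate with the printed amplicon sizes", {
  assays <- load_assays()
  expect_length(assays, 6L)
  expect_equal(vapply(assays, `[[`, 0L, "expected_amplicon"),
               c(123L, 132L, 134L, 131L, 72L, 71L))
  for (a in assays) {
    tpl <- assay_template(a)
    hits <- insilico_pcr(a, tpl)
    expect_equal(nrow(hits), 1L)
    expect_equal(hits$length, a$expected_amplicon)
    expect_equal(hits$f_mismatches + hits$r_mismatches, 0L)
  }
})

test_that("amplicon length arithmetic is exact on constructed templates", {
  a <- load_assays()[[1]]  # SYF1/SYR1, 18 + 86 + 19 = 123
  tpl <- paste0(a$forward$seq, random_dna(86), revcomp(a$reverse$seq))
  hits <- insilico_pcr(a, tpl)
  expect_equal(hits$length, 18L + 86L + 19L)
  expect_equal(c(hits$start, hits$end), c(1L, 123L))
  ## absent reverse site yields no product
  tpl2 <- paste0(a$forward$seq, random_dna(120))
  expect_equal(nrow(insilico_pcr(a, tpl2)), 0L)
})

test_that("mismatch tolerance is 3'-anchored", {
  a <- load_assays()[[1]]
  rc <- revcomp(a$reverse$seq)
  flip <- function(s, pos) {
    substr(s, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                   substr(s, pos, pos))[1]
    s
  }
  insert <- random_dna(86)
  ## internal mismatch on the reverse site: tolerated, counted
  rc_mid <- flip(rc, 10)
  hits <- insilico_pcr(a, paste0(a$forward$seq, insert, rc_mid),
                       pcr_params(max_mismatch = 2))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$r_mismatches, 1L)
  ## the same mismatch at the reverse primer's 3' terminus (leftmost base of
  ## the reverse-complement on the template): rejected
  rc_3p <- flip(rc, 1)
  hits2 <- insilico_pcr(a, paste0(a$forward$seq, insert, rc_3p),
                        pcr_params(max_mismatch = 2))
  expect_equal(nrow(hits2), 0L)
  ## three internal mismatches exceed max_mismatch = 2
  rc_3mm <- flip(flip(flip(rc, 8), 10), 12)
  hits3 <- insilico_pcr(a, paste0(a$forward$seq, insert, rc_3mm),
                        pcr_params(max_mismatch = 2))
  expect_equal(nrow(hits3), 0L)
  ## forward primer 3' terminus is its rightmost base
  f_3p <- flip(a$forward$seq, a$forward$length)
  hits4 <- insilico_pcr(a, paste0(f_3p, insert, rc))
  expect_equal(nrow(hits4), 0L)
})

test_that("species detection on pools mirrors the mixture validation", {
  assays <- load_assays()
  mk_template <- function(a) assay_template(a, flank = random_dna(20))
  set.seed(1)
  ## three-species mixture with the three matching assays
  three <- assays[1:3]
  pool3 <- do.call(rbind, lapply(three, mk_template))
  class(pool3) <- c("seq_records", "data.frame")
  res <- detect_species(pool3, three)
  expect_true(all(vapply(res, `[[`, TRUE, "present")))

  ## empty pool: all absent
  res0 <- detect_species(pool3[0, ], three)
  expect_false(any(vapply(res0, `[[`, TRUE, "present")))

  ## six-species pool, six assays: all present, evidence only from the
  ## assay's own template (no cross-species amplification)
  pool6 <- do.call(rbind, lapply(assays, mk_template))
  class(pool6) <- c("seq_records", "data.frame")
  res6 <- detect_species(pool6, assays)
  expect_true(all(vapply(res6, `[[`, TRUE, "present")))
  for (i in seq_along(assays)) {
    ev <- res6[[i]]$evidence
    expect_true(all(ev$template_id ==
                      paste0("template_", assays[[i]]$forward$name)))
  }
})

test_that("designed pairs are specific and straddle a diagnostic site", {
  panel <- make_planted_panel(8, seq_length = 230,
                              positions = c(100L, 112L))
  aln <- build_msa(panel$records)
  sites <- find_diagnostic_sites(aln, panel, "sp2")
  sig <- extract_signature(aln, panel, "sp2", sites)
  cons <- design_constraints(max_pairs = 5)
  assays <- design_primer_pairs(panel, "sp2", sig, cons)
  expect_gt(length(assays), 0)
  ref <- degap(panel$records$seq[panel$records$id == sig$ref_record])
  site_pos <- sig$start + sig$site_offsets - 1L
  for (a in assays) {
    hits <- insilico_pcr(a, ref, cons$pcr)
    expect_equal(nrow(hits), 1L)
    expect_equal(hits$length, a$expected_amplicon)
    expect_true(any(site_pos >= hits$start & site_pos <= hits$end))
    ## no product on any non-target record
    for (nt in which(panel$records$species != "sp2")) {
      expect_equal(nrow(insilico_pcr(a, panel$records[nt, ], cons$pcr)), 0L)
    }
  }
})

test_that("design fails loudly when target and non-target are identical", {
  shared <- random_dna(230)
  recs <- seq_records(c("t1", "n1"), c(shared, shared),
                      species = c("A", "B"))
  panel <- reference_panel(recs)
  sig <- nucleotide_signature("A", substr(shared, 100, 129), "t1",
                              100, 129, 15L)
  expect_error(design_primer_pairs(panel, "A", sig), "design failure")
})
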