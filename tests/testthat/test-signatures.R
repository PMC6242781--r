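test_that("no sites are called when target equals background", {
  recs <- seq_records(paste0("s", 1:4), rep(random_dna(60), 4),
                      species = c("A", "A", "B", "C"), is_gapped = TRUE)
  panel <- reference_panel(recs)
  sites <- find_diagnostic_sites(dna_alignment(recs), panel, "A")
  expect_equal(nrow(sites), 0L)
  expect_error(find_diagnostic_sites(dna_alignment(recs), panel, "Z"),
               "lookup error")
})

test_that("site calling equals the brute-force column scan on synthetic panels", {
  for (seed in c(3, 17, 31)) {
    panel <- make_planted_panel(seed)
    aln <- build_msa(panel$records)
    sites <- find_diagnostic_sites(aln, panel, "sp2")
    want <- oracle_diagnostic_columns(aln$records$seq, aln$records$species,
                                      "sp2")
    expect_identical(sites$column, as.integer(want))
    expect_true(all(c(80L, 95L) %in% sites$column))
  }
})

test_that("fixedness threshold gates a deviant target row", {
  ## 5 target rows, one carrying the background allele at the planted column
  base <- random_dna(80)
  alter <- function(s, pos, b) { substr(s, pos, pos) <- b; s }
  tgt <- alter(base, 40, "G")
  recs <- seq_records(paste0("s", 1:7),
                      c(rep(tgt, 4), alter(base, 40, "A"),
                        alter(base, 40, "A"), alter(base, 40, "A")),
                      species = c(rep("A", 5), "B", "B"), is_gapped = TRUE)
  ## force the background allele A at col 40 (rows 6-7 and deviant row 5)
  panel <- reference_panel(recs)
  aln <- dna_alignment(recs)
  strict <- find_diagnostic_sites(aln, panel, "A",
                                  signature_constraints(fixedness = 1.0))
  relaxed <- find_diagnostic_sites(aln, panel, "A",
                                   signature_constraints(fixedness = 0.8))
  expect_false(40L %in% strict$column)
  expect_true(40L %in% relaxed$column)
  expect_false(relaxed$fixed_in_target[relaxed$column == 40L])
  ## monotonicity: relaxing fixedness never removes sites
  expect_true(all(strict$column %in% relaxed$column))
})

test_that("ambiguity codes in non-targets disqualify a column", {
  base <- random_dna(60)
  alter <- function(s, pos, b) { substr(s, pos, pos) <- b; s }
  tgt <- alter(base, 30, "G")
  amb <- alter(base, 30, "R")  # R = A/G could denote the target allele
  recs <- seq_records(c("t1", "t2", "b1"), c(tgt, tgt, amb),
                      species = c("A", "A", "B"), is_gapped = TRUE)
  sites <- find_diagnostic_sites(dna_alignment(recs), reference_panel(recs),
                                 "A")
  expect_false(30L %in% sites$column)
})

test_that("extraction recovers the printed signature from a planted panel", {
  fx <- make_printed_sig_panel()
  sites <- find_diagnostic_sites(fx$aln, fx$panel, "Cynomorium songaricum")
  expect_identical(sites$column, fx$snp_cols)
  sig <- extract_signature(fx$aln, fx$panel, "Cynomorium songaricum", sites,
                           signature_constraints(min_sites = 2))
  expect_identical(sig$seq, "CAATTATTTGAGGTGCATTGTAAGAAGCGT")
  expect_equal(nchar(sig$seq), 30L)
  expect_equal(c(sig$start, sig$end), c(100L, 129L))
  expect_identical(sig$site_offsets, c(1L, 30L))
})

test_that("a single diagnostic site yields the leftmost minimal window", {
  panel <- make_planted_panel(5, positions = 120L, alleles = "G")
  aln <- build_msa(panel$records)
  sites <- find_diagnostic_sites(aln, panel, "sp2")
  cons <- signature_constraints(L_min = 30, L_max = 40)
  sig <- extract_signature(aln, panel, "sp2", sites, cons)
  expect_equal(nchar(sig$seq), cons$L_min)
  expect_true(length(sig$site_offsets) >= 1)
  ## signature containment invariant
  ref <- degap(panel$records$seq[panel$records$id == sig$ref_record])
  expect_identical(substr(ref, sig$start, sig$end), sig$seq)
})

test_that("window choice equals the exhaustive window oracle", {
  for (seed in c(2, 23)) {
    panel <- make_planted_panel(seed, seq_length = 200,
                                positions = c(90L, 104L))
    aln <- build_msa(panel$records)
    sites <- find_diagnostic_sites(aln, panel, "sp2")
    sig <- extract_signature(aln, panel, "sp2", sites)
    rep_row <- which(aln$records$species == "sp2")[1]
    u <- col_to_ungapped(aln, rep_row)
    ref <- degap(aln$records$seq[rep_row])
    pos <- sort(unique(u[sites$column][!is.na(u[sites$column])]))
    nt <- degap(panel$records$seq[panel$records$species != "sp2"])
    want <- oracle_signature_window(ref, pos, nt)
    expect_equal(unname(want["start"]), sig$start)
    expect_equal(unname(want["length"]), nchar(sig$seq))
  }
})

test_that("raising L_max never loses a previously found signature", {
  panel <- make_planted_panel(13)
  aln <- build_msa(panel$records)
  sites <- find_diagnostic_sites(aln, panel, "sp2")
  s1 <- extract_signature(aln, panel, "sp2", sites,
                          signature_constraints(L_min = 30, L_max = 34))
  s2 <- extract_signature(aln, panel, "sp2", sites,
                          signature_constraints(L_min = 30, L_max = 40))
  expect_identical(s1$seq, s2$seq)
})

test_that("uniqueness flags planted copies with mismatch arithmetic", {
  fx <- make_printed_sig_panel()
  sig <- nucleotide_signature("Cynomorium songaricum", fx$sig, "cy1",
                              100, 129, c(1L, 30L))
  ## verbatim copy planted into a non-target record
  rec2 <- fx$panel$records
  rec2$seq[rec2$id == "cd1"] <-
    paste0(fx$sig, substr(rec2$seq[rec2$id == "cd1"], 31, 230))
  bad_panel <- reference_panel(rec2)
  chk <- verify_uniqueness(sig, bad_panel)
  expect_false(chk$unique)
  expect_equal(nrow(chk$offenders), 1L)
  expect_equal(chk$offenders$identity[1], 100)

  ## panel containing only the target species is trivially unique
  only_t <- reference_panel(
    fx$panel$records[fx$panel$records$species == "Cynomorium songaricum", ])
  expect_true(verify_uniqueness(sig, only_t)$unique)

  ## one internal mismatch: 29/30 = 96.7% identity over full coverage
  mism <- fx$sig
  substr(mism, 15, 15) <- setdiff(c("A", "C", "G", "T"),
                                  substr(mism, 15, 15))[1]
  rec3 <- fx$panel$records
  rec3$seq[rec3$id == "ct1"] <-
    paste0(mism, substr(rec3$seq[rec3$id == "ct1"], 31, 230))
  near_panel <- reference_panel(rec3)
  expect_true(verify_uniqueness(sig, near_panel, max_ident = 1.0)$unique)
  chk2 <- verify_uniqueness(sig, near_panel, max_ident = 0.96)
  expect_false(chk2$unique)
  expect_equal(chk2$offenders$identity[1], 100 * 29 / 30, tolerance = 1e-9)
})
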