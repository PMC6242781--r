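test_that("panel generation is deterministic and respects zero divergence", {
  spec0 <- panel_spec(n_species = 3, n_per_species = 2, seq_length = 120,
                      interspecies_divergence = 0,
                      intraspecies_divergence = 0, seed = 9)
  p <- simulate_panel(spec0)
  expect_equal(length(unique(p$records$seq)), 1L)
  ## same seed twice: byte-identical
  spec <- panel_spec(seed = 31)
  p1 <- simulate_panel(spec)
  p2 <- simulate_panel(spec)
  expect_identical(p1$records$seq, p2$records$seq)
  ## different seed differs
  p3 <- simulate_panel(panel_spec(seed = 32))
  expect_false(identical(p1$records$seq, p3$records$seq))
  ## generators do not disturb the caller's RNG stream
  set.seed(77); before <- runif(1)
  set.seed(77); invisible(simulate_panel(panel_spec(seed = 5)))
  expect_identical(runif(1), before)
})

test_that("planted sites are guaranteed and recovered by site calling", {
  for (seed in c(4, 44, 444)) {
    panel <- make_planted_panel(seed, positions = c(60L, 75L),
                                alleles = c("G", "T"))
    mat <- do.call(rbind, strsplit(panel$records$seq, ""))
    tgt <- panel$records$species == "sp2"
    expect_true(all(mat[tgt, 60] == "G"), label = paste("seed", seed))
    expect_true(all(mat[!tgt, 60] != "G"))
    expect_true(all(mat[tgt, 75] == "T"))
    expect_true(all(mat[!tgt, 75] != "T"))
    ## exact recovery when intraspecies divergence is zero
    aln <- build_msa(panel$records)
    sites <- find_diagnostic_sites(aln, panel, "sp2")
    expect_true(all(c(60L, 75L) %in% sites$column))
  }
})

test_that("panel spec validates divergences, positions and seed", {
  expect_error(panel_spec(interspecies_divergence = 0.6, seed = 1),
               "divergences")
  expect_error(panel_spec(planted_sites = list(
    sp1 = list(position = 500L, allele = "A")), seed = 1), "within")
  expect_error(panel_spec(planted_sites = list(
    zz = list(position = 5L, allele = "A")), seed = 1), "not in panel")
  expect_error(panel_spec(), "seed")
})

test_that("mixture pools draw species proportional to weights", {
  panel <- make_planted_panel(12)
  pool <- simulate_mixture_pool(panel, c(sp1 = 1), n_fragments = 50,
                                seed = 3)
  expect_true(all(pool$fragments$species == "sp1"))
  ## 50/50 weights: counts within the binomial 99% interval
  pool2 <- simulate_mixture_pool(panel, c(sp1 = 0.5, sp2 = 0.5),
                                 n_fragments = 10000, seed = 3)
  n1 <- sum(pool2$fragments$species == "sp1")
  ci <- qbinom(c(0.005, 0.995), 10000, 0.5)
  expect_gte(n1, ci[1]); expect_lte(n1, ci[2])
  ## fragment intervals lie within their source template
  src_len <- nchar(panel$records$seq[
    match(pool2$fragments$source_id, panel$records$id)])
  expect_true(all(pool2$fragments$source_start >= 1))
  expect_true(all(pool2$fragments$source_end <= src_len))
  expect_error(simulate_mixture_pool(panel, c(sp1 = 0.7), seed = 1),
               "sum to 1")
})

test_that("a minor component appears at the closed-form rate", {
  panel <- make_planted_panel(15)
  w <- 1e-3; n <- 2000
  p_present <- 1 - (1 - w)^n      # ~0.865
  hits <- 0; reps <- 60
  for (r in seq_len(reps)) {
    pool <- simulate_mixture_pool(panel, c(sp1 = 1 - w, sp2 = w),
                                  n_fragments = n, seed = 5000 + r)
    hits <- hits + any(pool$fragments$species == "sp2")
  }
  ## 99.9% binomial band around the closed-form expectation
  band <- qbinom(c(5e-4, 1 - 5e-4), reps, p_present)
  expect_gte(hits, band[1]); expect_lte(hits, band[2])
})

test_that("decoction pools shrink with boil time and stay seeded", {
  ## template long enough that end-truncation of fragments is negligible
  tpl <- seq_records("t1", random_dna(50000))
  p0 <- simulate_decoction(tpl, t = 0, lambda0 = 300, k_deg = 0.02,
                           n_fragments = 2000, seed = 6)
  lens <- nchar(p0$fragments$seq)
  expect_equal(p0$mean_len, 300)
  se <- stats::sd(lens) / sqrt(length(lens))
  expect_lt(abs(mean(lens) - 300), 3 * se + 5)
  ## k_deg = 0: pools identical across boil times under the same seed
  pa <- simulate_decoction(tpl, t = 30, lambda0 = 300, k_deg = 0,
                           n_fragments = 100, seed = 11)
  pb <- simulate_decoction(tpl, t = 240, lambda0 = 300, k_deg = 0,
                           n_fragments = 100, seed = 11)
  expect_identical(pa$fragments$seq, pb$fragments$seq)
  ## exponential decay of the target mean
  pc <- simulate_decoction(tpl, t = 120, lambda0 = 300, k_deg = 0.02,
                           n_fragments = 10, seed = 2)
  expect_equal(pc$mean_len, 300 * exp(-0.02 * 120))
})

test_that("detection of a 123-bp assay fades monotonically with boiling", {
  a <- load_assays()[[1]]
  tpl <- assay_template(a, flank = random_dna(60))
  times <- c(30, 60, 90, 120, 150, 180, 210, 240)
  reps <- 30
  phat <- vapply(seq_along(times), function(ti) {
    det <- 0
    for (r in seq_len(reps)) {
      pool <- simulate_decoction(tpl, times[ti], n_fragments = 150,
                                 seed = 20000 + ti + r * 16L)
      res <- detect_species(pool, list(a), collect_evidence = FALSE)
      det <- det + res[[1]]$present
    }
    det / reps
  }, numeric(1))
  ## non-increasing within Monte-Carlo noise, with a clear early/late gap
  expect_true(all(diff(phat) <= 0.1))
  expect_gt(phat[1], 0.9)
  expect_lt(phat[length(phat)], 0.1)
})
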