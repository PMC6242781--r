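## Independent oracles used to validate the package's own implementations.
## These deliberately use naive algorithms (exhaustive enumeration, quadratic
## scans, closed forms) and never share code with the package internals.

## -- exhaustive global-alignment oracle --------------------------------------
## Enumerates every alignment (no gap-gap columns) of two short strings and
## scores it with affine run costs: each maximal per-row gap run costs
## gap_open + len * gap_extend.
oracle_align_score <- function(a, b, match = 1, mismatch = -2,
                               gap_open = -5, gap_extend = -2) {
  ach <- strsplit(a, "")[[1]]
  bch <- strsplit(b, "")[[1]]
  n <- length(ach); m <- length(bch)
  score_path <- function(top, bot) {
    sc <- 0
    for (k in seq_along(top)) {
      if (top[k] != "-" && bot[k] != "-") {
        sc <- sc + if (top[k] == bot[k]) match else mismatch
      }
    }
    for (row in list(top, bot)) {
      r <- rle(row == "-")
      runs <- r$lengths[r$values]
      sc <- sc + sum(gap_open + runs * gap_extend)
    }
    sc
  }
  best <- -Inf
  rec <- function(i, j, top, bot) {
    if (i > n && j > m) {
      best <<- max(best, score_path(top, bot))
      return(invisible())
    }
    if (i <= n && j <= m) rec(i + 1, j + 1, c(top, ach[i]), c(bot, bch[j]))
    if (i <= n) rec(i + 1, j, c(top, ach[i]), c(bot, "-"))
    if (j <= m) rec(i, j + 1, c(top, "-"), c(bot, bch[j]))
  }
  rec(1L, 1L, character(0), character(0))
  best
}

## -- naive diagnostic-site oracle --------------------------------------------
## Column-by-column scan re-deriving the diagnostic definition from scratch.
oracle_diagnostic_columns <- function(seqs, species, target, fixedness = 1) {
  mat <- do.call(rbind, strsplit(seqs, ""))
  tgt <- which(species == target)
  bkg <- which(species != target)
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))
  found <- integer(0)
  for (col in seq_len(ncol(mat))) {
    tv <- mat[tgt, col]
    tv <- tv[!(tv %in% c("-", "N"))]
    if (!length(tv)) next
    for (a in c("A", "C", "G", "T")) {
      if (sum(tv == a) / length(tv) < fixedness || !any(tv == a)) next
      bad <- FALSE
      for (b in mat[bkg, col]) {
        if (b != "-" && a %in% sets[[b]]) { bad <- TRUE; break }
      }
      if (!bad) { found <- c(found, col); break }
    }
  }
  found
}

## -- quadratic-scan ungapped local alignment oracle --------------------------
## Best ungapped local score between q and s on both strands: per diagonal,
## the maximum-sum contiguous subarray of per-position scores (Kadane).
oracle_local_score <- function(q, s, match = 1, mismatch = -2) {
  best <- 0
  for (qs in c(q, revcomp(q))) {
    qch <- strsplit(qs, "")[[1]]
    sch <- strsplit(s, "")[[1]]
    m <- length(qch); L <- length(sch)
    for (d in (1L - m):(L - 1L)) {
      lo <- max(1L, 1L - d); hi <- min(m, L - d)
      if (lo > hi) next
      sc <- ifelse(qch[lo:hi] == sch[(lo:hi) + d], match, mismatch)
      cur <- 0
      for (v in sc) {
        cur <- max(0, cur + v)
        best <- max(best, cur)
      }
    }
  }
  best
}

## -- closed-form OLS oracle ---------------------------------------------------
oracle_ols <- function(x, y) {
  xb <- mean(x); yb <- mean(y)
  b <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  c(intercept = yb - b * xb, slope = b)
}

## -- brute-force signature-window oracle --------------------------------------
## First (shortest, then leftmost) window on the reference containing at least
## `min_sites` of `site_pos` whose sequence is not an exact substring of any
## non-target sequence (max_ident = 1 uniqueness, both strands).
oracle_signature_window <- function(ref_seq, site_pos, nontarget_seqs,
                                    L_min = 30, L_max = 40, min_sites = 1) {
  L_ref <- nchar(ref_seq)
  for (L in L_min:L_max) {
    if (L > L_ref) break
    for (start in 1:(L_ref - L + 1)) {
      end <- start + L - 1
      if (sum(site_pos >= start & site_pos <= end) < min_sites) next
      w <- substr(ref_seq, start, end)
      planted <- any(vapply(nontarget_seqs, function(s) {
        grepl(w, s, fixed = TRUE) || grepl(revcomp(w), s, fixed = TRUE)
      }, logical(1)))
      if (!planted) return(c(start = start, length = L))
    }
  }
  NULL
}

## -- shared synthetic fixtures ------------------------------------------------
## An alignment-free panel carrying the printed 30-bp signature of
## Cynomorium songaricum at columns 100-129 of an otherwise shared
## background; its first and last bases act as the two diagnostic SNPs.
make_printed_sig_panel <- function() {
  sig <- "CAATTATTTGAGGTGCATTGTAAGAAGCGT"
  set.seed(101)
  bg <- paste(sample(c("A", "C", "G", "T"), 230, replace = TRUE),
              collapse = "")
  with_sig <- paste0(substr(bg, 1, 99), sig, substr(bg, 130, 230))
  alter <- function(s, pos, base) {
    substr(s, pos, pos) <- base
    s
  }
  ## non-targets carry different alleles at the window's first/last base
  other <- alter(alter(with_sig, 100, "T"), 129, "G")
  recs <- seq_records(
    id = c("cy1", "cy2", "cd1", "ct1"),
    seq = c(with_sig, with_sig, other, other),
    species = c("Cynomorium songaricum", "Cynomorium songaricum",
                "Cistanche deserticola", "Cistanche tubulosa"),
    role = c("adulterant", "adulterant", "official", "official"),
    is_gapped = TRUE)
  list(panel = reference_panel(recs),
       aln = dna_alignment(recs),
       sig = sig, snp_cols = c(100L, 129L))
}

## A small random panel with planted diagnostic sites for a chosen species.
make_planted_panel <- function(seed, n_species = 4, n_per_species = 3,
                               seq_length = 200, inter = 0.05, intra = 0,
                               positions = c(80L, 95L),
                               alleles = c("G", "T"), target = "sp2") {
  spec <- panel_spec(
    n_species = n_species, n_per_species = n_per_species,
    seq_length = seq_length,
    interspecies_divergence = inter, intraspecies_divergence = intra,
    planted_sites = stats::setNames(
      list(list(position = positions, allele = alleles)), target),
    seed = seed)
  simulate_panel(spec)
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
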