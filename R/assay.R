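## Species-specific PCR assays: oligo melting temperature, in-silico PCR with
## a 3'-anchored mismatch-tolerance policy, species presence calls on
## fragment pools, and primer-pair design around a nucleotide signature.

## SantaLucia (1998) unified nearest-neighbor parameters:
## dH in kcal/mol, dS in cal/(mol K), keyed by the 5'->3' top-strand
## dinucleotide. Duplex initiation is charged per terminal base.
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
NN_INIT_AT <- c(dh = 2.3, ds = 4.1)
NN_INIT_GC <- c(dh = 0.1, ds = -2.8)
GAS_CONSTANT <- 1.987  # cal/(mol K)

#' Melting-temperature model parameters
#'
#' @param monovalent_salt monovalent cation concentration in mM.
#' @param oligo_conc total oligo concentration in uM.
#' @param nn_table nearest-neighbor parameter set identifier (only
#'   `"santalucia1998"` is shipped).
#' @return a `tm_params` list.
#' @export
tm_params <- function(monovalent_salt = 50, oligo_conc = 0.25,
                      nn_table = "santalucia1998") {
  if (monovalent_salt <= 0 || oligo_conc <= 0) {
    stop("parameter error: concentrations must be positive", call. = FALSE)
  }
  if (!identical(nn_table, "santalucia1998")) {
    stop("parameter error: unknown nn_table '", nn_table, "'", call. = FALSE)
  }
  structure(list(monovalent_salt = monovalent_salt, oligo_conc = oligo_conc,
                 nn_table = nn_table), class = "tm_params")
}

#' Oligo melting temperature
#'
#' Nearest-neighbor Tm from summed duplex dH/dS with the entropy salt
#' correction `0.368 (N-1) ln[Na+]` at the stated oligo concentration
#' (`CT/4` for non-self-complementary duplexes). Sequences shorter than
#' 14 nt use the Wallace rule `2(A+T) + 4(G+C)`.
#'
#' @param seq unambiguous DNA string (A/C/G/T only).
#' @param p a [tm_params()].
#' @return melting temperature in degrees Celsius.
#' @examples
#' primer_tm("ACGT")  # Wallace rule: 12
#' @export
primer_tm <- function(seq, p = tm_params()) {
  seq <- toupper(seq)
  ch <- seq_chars(seq)
  if (!all(ch %in% c("A", "C", "G", "T"))) {
    stop("parameter error: Tm requires an unambiguous A/C/G/T sequence",
         call. = FALSE)
  }
  n <- length(ch)
  if (n < 14L) {
    return(2 * sum(ch %in% c("A", "T")) + 4 * sum(ch %in% c("G", "C")))
  }
  nn <- paste0(ch[-n], ch[-1])
  dh <- sum(NN_DH[nn])
  ds <- sum(NN_DS[nn])
  for (term in ch[c(1L, n)]) {
    init <- if (term %in% c("A", "T")) NN_INIT_AT else NN_INIT_GC
    dh <- dh + init[["dh"]]
    ds <- ds + init[["ds"]]
  }
  selfcomp <- identical(seq, revcomp(seq))
  if (selfcomp) ds <- ds - 1.4
  ds <- ds + 0.368 * (n - 1) * log(p$monovalent_salt / 1000)
  ct <- p$oligo_conc * 1e-6
  k <- if (selfcomp) ct else ct / 4
  1000 * dh / (ds + GAS_CONSTANT * log(k)) - 273.15
}

#' Construct a primer
#'
#' @param name primer name.
#' @param seq 5'->3' sequence, unambiguous, 15-30 nt.
#' @param tm_p a [tm_params()] used to annotate the melting temperature.
#' @return a `primer` list with `name`, `seq`, `length`, `tm`, `gc`.
#' @export
primer <- function(name, seq, tm_p = tm_params()) {
  seq <- toupper(seq)
  ch <- seq_chars(seq)
  if (!all(ch %in% c("A", "C", "G", "T"))) {
    stop("primer error: '", name, "' must contain only A/C/G/T", call. = FALSE)
  }
  if (nchar(seq) < 15L || nchar(seq) > 30L) {
    stop("primer error: '", name, "' length must be 15-30 nt", call. = FALSE)
  }
  structure(list(name = name, seq = seq, length = nchar(seq),
                 tm = primer_tm(seq, tm_p),
                 gc = 100 * sum(ch %in% c("G", "C")) / nchar(seq)),
            class = "primer")
}

#' Construct an assay (primer pair)
#'
#' @param forward,reverse [primer()] objects (both written 5'->3').
#' @param target_species species the assay is diagnostic for.
#' @param expected_amplicon expected product length in bp (>= sum of primer
#'   lengths).
#' @param anneal_temp annealing temperature metadata in degC (not used by the
#'   matching model).
#' @return an `assay` list.
#' @export
assay <- function(forward, reverse, target_species, expected_amplicon,
                  anneal_temp = 50) {
  stopifnot(inherits(forward, "primer"), inherits(reverse, "primer"))
  if (expected_amplicon < forward$length + reverse$length) {
    stop("assay error: expected_amplicon shorter than the two primers",
         call. = FALSE)
  }
  structure(list(forward = forward, reverse = reverse,
                 target_species = normalize_species(target_species),
                 expected_amplicon = as.integer(expected_amplicon),
                 anneal_temp = anneal_temp),
            class = "assay")
}

#' @export
print.assay <- function(x, ...) {
  cat("Assay ", x$forward$name, "/", x$reverse$name, " -> ",
      x$target_species, " (", x$expected_amplicon, " bp)\n",
      "  F 5'-", x$forward$seq, "-3'  Tm ", sprintf("%.1f", x$forward$tm),
      " degC\n  R 5'-", x$reverse$seq, "-3'  Tm ",
      sprintf("%.1f", x$reverse$tm), " degC\n", sep = "")
  invisible(x)
}

#' In-silico PCR matching policy
#'
#' @param max_mismatch mismatches tolerated per primer.
#' @param three_prime_anchor number of 3'-terminal bases in which no mismatch
#'   is tolerated.
#' @param min_amplicon,max_amplicon reported product length bounds in bp.
#' @return a `pcr_params` list.
#' @export
pcr_params <- function(max_mismatch = 2L, three_prime_anchor = 3L,
                       min_amplicon = 50L, max_amplicon = 2000L) {
  if (min_amplicon >= max_amplicon) {
    stop("parameter error: need min_amplicon < max_amplicon", call. = FALSE)
  }
  if (three_prime_anchor < 0L || max_mismatch < 0L) {
    stop("parameter error: negative tolerance", call. = FALSE)
  }
  structure(list(max_mismatch = as.integer(max_mismatch),
                 three_prime_anchor = as.integer(three_prime_anchor),
                 min_amplicon = as.integer(min_amplicon),
                 max_amplicon = as.integer(max_amplicon)),
            class = "pcr_params")
}

## mismatch count of `pch` against every template offset, restricted to
## primer positions `ks` (defaults to all); returns a vector over offsets
mm_profile <- function(tch, pch, ks = seq_along(pch)) {
  L <- length(tch); lp <- length(pch)
  n <- L - lp + 1L
  if (n < 1L) return(integer(0))
  mm <- integer(n)
  for (k in ks) mm <- mm + (tch[k:(k + n - 1L)] != pch[k])
  mm
}

empty_amplicons <- function() {
  out <- data.frame(template_id = character(0), start = integer(0),
                    end = integer(0), length = integer(0),
                    f_mismatches = integer(0), r_mismatches = integer(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("amplicon_hits", "data.frame")
  out
}

#' Predict PCR products on a template
#'
#' The forward primer is matched on the forward strand and the reverse primer
#' as its reverse complement downstream, each with at most `max_mismatch`
#' mismatches and none within the 3'-terminal `three_prime_anchor` bases.
#' All products within the length bounds are reported; an empty result means
#' no product.
#'
#' @param a an [assay()].
#' @param template one-row `seq_records` or ungapped DNA string.
#' @param p a [pcr_params()].
#' @return an `amplicon_hits` data frame sorted by start: `template_id`,
#'   `start`, `end` (1-based closed on the template forward strand),
#'   `length`, `f_mismatches`, `r_mismatches`.
#' @export
insilico_pcr <- function(a, template, p = pcr_params()) {
  template <- as_record(template, "template")
  if (grepl("-", template$seq[1], fixed = TRUE)) {
    stop("alphabet error: template must be ungapped", call. = FALSE)
  }
  t_anchor <- p$three_prime_anchor
  if (t_anchor > min(a$forward$length, a$reverse$length)) {
    stop("parameter error: three_prime_anchor exceeds primer length",
         call. = FALSE)
  }
  tch <- seq_chars(template$seq[1])
  fch <- seq_chars(a$forward$seq)
  rch <- seq_chars(revcomp(a$reverse$seq))
  lf <- length(fch); lr <- length(rch)
  mm_f <- mm_profile(tch, fch)
  mm_r <- mm_profile(tch, rch)
  if (!length(mm_f) || !length(mm_r)) return(empty_amplicons())
  ## 3' anchor: last bases of the forward primer; first bases of the
  ## reverse-complemented reverse primer (its 3' end points left)
  anc_f <- if (t_anchor > 0) mm_profile(tch, fch, (lf - t_anchor + 1L):lf)
           else integer(length(mm_f)) * 0L
  anc_r <- if (t_anchor > 0) mm_profile(tch, rch, 1:t_anchor)
           else integer(length(mm_r)) * 0L
  f_pos <- which(mm_f <= p$max_mismatch & anc_f == 0L)
  r_pos <- which(mm_r <= p$max_mismatch & anc_r == 0L)
  if (!length(f_pos) || !length(r_pos)) return(empty_amplicons())
  grid <- expand.grid(fi = f_pos, rj = r_pos)
  len <- grid$rj + lr - grid$fi
  ok <- grid$rj >= grid$fi + lf &             # primers must not overlap
    len >= p$min_amplicon & len <= p$max_amplicon
  grid <- grid[ok, , drop = FALSE]
  if (!nrow(grid)) return(empty_amplicons())
  out <- data.frame(template_id = template$id[1],
                    start = as.integer(grid$fi),
                    end = as.integer(grid$rj + lr - 1L),
                    length = as.integer(grid$rj + lr - grid$fi),
                    f_mismatches = as.integer(mm_f[grid$fi]),
                    r_mismatches = as.integer(mm_r[grid$rj]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("amplicon_hits", "data.frame")
  out
}

#' Call species presence in a fragment pool
#'
#' A species is present when any pool fragment yields at least one amplicon
#' for its assay.
#'
#' @param pool a `seq_records` data frame or a `fragment_pool`.
#' @param assays list of [assay()] objects targeting distinct species.
#' @param p a [pcr_params()].
#' @param collect_evidence when `FALSE`, stop at the first supporting
#'   amplicon per assay (faster for detection-probability simulations).
#' @return named list (by target species) of `list(present, evidence)`.
#' @export
detect_species <- function(pool, assays, p = pcr_params(),
                           collect_evidence = TRUE) {
  if (inherits(pool, "fragment_pool")) pool <- pool$fragments
  targets <- vapply(assays, function(a) a$target_species, character(1))
  if (anyDuplicated(targets)) {
    stop("assay error: assays must target distinct species", call. = FALSE)
  }
  out <- vector("list", length(assays))
  names(out) <- targets
  for (ai in seq_along(assays)) {
    evidence <- empty_amplicons()
    present <- FALSE
    for (fi in seq_len(nrow(pool))) {
      hits <- insilico_pcr(assays[[ai]], pool[fi, , drop = FALSE], p)
      if (nrow(hits)) {
        present <- TRUE
        evidence <- rbind(evidence, hits)
        if (!collect_evidence) break
      }
    }
    class(evidence) <- c("amplicon_hits", "data.frame")
    out[[ai]] <- list(present = present, evidence = evidence)
  }
  out
}

#' Primer-pair design constraints
#'
#' @param primer_len candidate primer lengths in nt.
#' @param tm_range acceptable primer Tm window in degC.
#' @param max_tm_diff maximum |Tm(F) - Tm(R)| in degC.
#' @param amplicon_range product length bounds in bp (defaults span the
#'   packaged assays' 71-134 bp).
#' @param pcr a [pcr_params()] used for the cross-species specificity screen.
#' @param tm a [tm_params()].
#' @param max_pairs maximum number of ranked assays to return.
#' @return a `design_constraints` list.
#' @export
design_constraints <- function(primer_len = 18:21, tm_range = c(45, 65),
                               max_tm_diff = 5, amplicon_range = c(70, 140),
                               pcr = pcr_params(), tm = tm_params(),
                               max_pairs = 10L) {
  structure(list(primer_len = as.integer(primer_len), tm_range = tm_range,
                 max_tm_diff = max_tm_diff,
                 amplicon_range = as.integer(amplicon_range), pcr = pcr,
                 tm = tm, max_pairs = as.integer(max_pairs)),
            class = "design_constraints")
}

## reject primers whose 3'-terminal 5-mer can anneal perfectly within the
## primer itself (minimal self-dimer/hairpin sanity screen)
self_dimer_3p <- function(seq, k = 5L) {
  n <- nchar(seq)
  if (n < k) return(FALSE)
  tail_k <- substr(seq, n - k + 1L, n)
  grepl(revcomp(tail_k), seq, fixed = TRUE)
}

#' Design species-specific primer pairs around a signature
#'
#' Enumerates candidate forward/reverse windows on the signature's reference
#' record such that the amplicon contains at least one diagnostic site,
#' filters on primer length, Tm window, Tm balance and a 3' self-dimer
#' screen, discards any pair that amplifies a non-target panel sequence
#' under the in-silico PCR policy, and ranks the survivors by specificity
#' margin (minimal non-target primer mismatches, descending), then Tm
#' balance. Ordering is deterministic.
#'
#' @param panel a `reference_panel`.
#' @param target target species.
#' @param sig a [nucleotide_signature()] discovered on a panel record.
#' @param constraints a [design_constraints()].
#' @return list of [assay()] objects, best first.
#' @export
design_primer_pairs <- function(panel, target, sig,
                                constraints = design_constraints()) {
  target <- normalize_species(target)
  ref_i <- match(sig$ref_record, panel$records$id)
  if (is.na(ref_i)) {
    stop("lookup error: signature reference record not in panel", call. = FALSE)
  }
  ref <- degap(panel$records$seq[ref_i])
  L <- nchar(ref)
  pos <- sig$start + sig$site_offsets - 1L
  amp_lo <- constraints$amplicon_range[1]; amp_hi <- constraints$amplicon_range[2]
  lens <- constraints$primer_len
  nt <- panel$records[panel$records$species != target, , drop = FALSE]
  nt_chars <- lapply(degap(nt$seq), seq_chars)

  window_ok <- function(seq) {
    ch <- seq_chars(seq)
    all(ch %in% c("A", "C", "G", "T")) && !self_dimer_3p(seq)
  }
  ## candidate forward primers: anchored at the amplicon 5' end
  f_lo <- max(1L, min(pos) - amp_hi + 1L)
  f_hi <- max(pos)
  fw <- list()
  for (fs in f_lo:f_hi) {
    for (fl in lens) {
      if (fs + fl - 1L > L) next
      s <- substr(ref, fs, fs + fl - 1L)
      if (!window_ok(s)) next
      tm <- primer_tm(s, constraints$tm)
      if (tm < constraints$tm_range[1] || tm > constraints$tm_range[2]) next
      fw[[length(fw) + 1L]] <- list(start = fs, len = fl, seq = s, tm = tm)
    }
  }
  ## candidate reverse primers: anchored at the amplicon 3' end
  r_lo <- min(pos)
  r_hi <- min(L, max(pos) + amp_hi - 1L)
  rv <- list()
  for (re in r_lo:r_hi) {
    for (rl in lens) {
      if (re - rl + 1L < 1L) next
      s <- revcomp(substr(ref, re - rl + 1L, re))
      if (!window_ok(s)) next
      tm <- primer_tm(s, constraints$tm)
      if (tm < constraints$tm_range[1] || tm > constraints$tm_range[2]) next
      rv[[length(rv) + 1L]] <- list(end = re, len = rl, seq = s, tm = tm)
    }
  }
  if (!length(fw) || !length(rv)) {
    stop("design failure: no primer window satisfies the Tm/length",
         " constraints", call. = FALSE)
  }
  ## per-primer minimal mismatch count against each non-target (on the
  ## forward strand of the reference, which is where both binding sites live)
  nt_min_mm <- function(seq) {
    pch <- seq_chars(seq)
    vapply(nt_chars, function(tc) {
      prof <- mm_profile(tc, pch)
      if (length(prof)) min(prof) else length(pch)
    }, numeric(1))
  }
  f_mm <- lapply(fw, function(f) nt_min_mm(f$seq))
  r_mm <- lapply(rv, function(r) nt_min_mm(revcomp(r$seq)))

  ## vectorized pair enumeration
  fs <- vapply(fw, `[[`, 0, "start"); fl <- vapply(fw, `[[`, 0, "len")
  ftm <- vapply(fw, `[[`, 0, "tm")
  re <- vapply(rv, `[[`, 0, "end"); rl <- vapply(rv, `[[`, 0, "len")
  rtm <- vapply(rv, `[[`, 0, "tm")
  grid <- expand.grid(fi = seq_along(fw), ri = seq_along(rv))
  amp <- re[grid$ri] - fs[grid$fi] + 1L
  has_site <- Reduce(`|`, lapply(pos, function(p) {
    fs[grid$fi] <= p & re[grid$ri] >= p
  }))
  ok <- amp >= amp_lo & amp <= amp_hi &
    (re[grid$ri] - rl[grid$ri] + 1L) > (fs[grid$fi] + fl[grid$fi] - 1L) &
    abs(ftm[grid$fi] - rtm[grid$ri]) <= constraints$max_tm_diff &
    has_site
  grid <- grid[ok, , drop = FALSE]
  if (!nrow(grid)) {
    stop("design failure: no primer pair satisfies the amplicon/Tm",
         " constraints", call. = FALSE)
  }
  amp <- re[grid$ri] - fs[grid$fi] + 1L
  ## specificity margin: fewest combined primer mismatches on any non-target
  margin <- if (nrow(nt)) {
    vapply(seq_len(nrow(grid)), function(k) {
      min(f_mm[[grid$fi[k]]] + r_mm[[grid$ri[k]]])
    }, numeric(1))
  } else rep(Inf, nrow(grid))
  worst_nt <- if (nrow(nt)) {
    vapply(seq_len(nrow(grid)), function(k) {
      nt$id[which.min(f_mm[[grid$fi[k]]] + r_mm[[grid$ri[k]]])]
    }, character(1))
  } else rep(NA_character_, nrow(grid))
  ord <- order(-margin, abs(ftm[grid$fi] - rtm[grid$ri]), fs[grid$fi], amp,
               rl[grid$ri], fl[grid$fi])
  ## screen candidates for cross-amplification in rank order; the ranking
  ## keys do not depend on the screen, so the first `max_pairs` survivors
  ## are exactly the head of the fully screened ranking
  out <- list()
  blocking <- NULL
  for (k in ord) {
    if (margin[k] == 0) {
      ## both primers match a non-target perfectly: never species-specific
      if (is.null(blocking)) blocking <- worst_nt[k]
      next
    }
    f <- fw[[grid$fi[k]]]; r <- rv[[grid$ri[k]]]
    cand <- assay(primer(sprintf("F_%d_%d", f$start, f$len), f$seq,
                         constraints$tm),
                  primer(sprintf("R_%d_%d", r$end, r$len), r$seq,
                         constraints$tm),
                  target_species = target,
                  expected_amplicon = r$end - f$start + 1L)
    cross <- FALSE
    for (ni in seq_len(nrow(nt))) {
      hits <- insilico_pcr(cand, nt[ni, , drop = FALSE], constraints$pcr)
      if (nrow(hits)) {
        cross <- TRUE
        if (is.null(blocking)) blocking <- nt$id[ni]
        break
      }
    }
    if (cross) next
    out[[length(out) + 1L]] <- cand
    if (length(out) >= constraints$max_pairs) break
  }
  if (!length(out)) {
    stop("design failure: no species-specific pair found",
         if (!is.null(blocking))
           paste0("; binding non-target: ", blocking), call. = FALSE)
  }
  out
}

#' Construct a template carrying an assay's binding sites
#'
#' Builds `forward + insert + revcomp(reverse)` so that in-silico PCR yields
#' exactly the expected amplicon; useful for assay validation and demos.
#'
#' @param a an [assay()].
#' @param insert optional insert sequence; defaults to a deterministic
#'   ACGT-repeat of the length implied by `expected_amplicon`.
#' @param flank optional flanking sequence added on both sides.
#' @return a one-row `seq_records` template.
#' @export
assay_template <- function(a, insert = NULL, flank = "") {
  gap_len <- a$expected_amplicon - a$forward$length - a$reverse$length
  if (is.null(insert)) {
    insert <- chars_seq(rep_len(c("A", "C", "G", "T"), gap_len))
  }
  if (nchar(insert) != gap_len) {
    stop("template error: insert must have length ", gap_len, call. = FALSE)
  }
  seqv <- paste0(flank, a$forward$seq, insert, revcomp(a$reverse$seq), flank)
  seq_records(paste0("template_", a$forward$name), seqv,
              species = a$target_species)
}
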