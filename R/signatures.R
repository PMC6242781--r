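## Species-diagnostic SNP calling on a labeled alignment and extraction of
## minimal unique nucleotide-signature windows around those SNPs.

#' Signature extraction constraints
#'
#' @param L_min,L_max window length bounds in bp (defaults 30 and 40; the
#'   packaged signatures span 30-37 bp).
#' @param min_sites minimum number of diagnostic sites a window must contain.
#' @param fixedness fraction of target rows (gap/N rows excluded from the
#'   denominator) that must share the target allele for a site to count as
#'   fixed; 1.0 demands strict fixation.
#' @return a `signature_constraints` list.
#' @export
signature_constraints <- function(L_min = 30L, L_max = 40L, min_sites = 1L,
                                  fixedness = 1.0) {
  if (!(L_min > 0 && L_min <= L_max)) {
    stop("config error: need 0 < L_min <= L_max", call. = FALSE)
  }
  if (min_sites < 1L) stop("config error: min_sites must be >= 1",
                           call. = FALSE)
  if (!(fixedness > 0 && fixedness <= 1)) {
    stop("config error: fixedness must be in (0, 1]", call. = FALSE)
  }
  structure(list(L_min = as.integer(L_min), L_max = as.integer(L_max),
                 min_sites = as.integer(min_sites), fixedness = fixedness),
            class = "signature_constraints")
}

#' Call species-diagnostic SNP columns
#'
#' A column is diagnostic for `target` when (i) at least `fixedness` of the
#' target rows carry one concrete allele (rows with gaps or N excluded from
#' the denominator and counted in `n_excluded`), (ii) no non-target row
#' carries that allele - an ambiguity code whose set contains the allele
#' disqualifies the column - and (iii) the allele is not a gap.
#'
#' @param aln a `dna_alignment` whose rows carry species labels present in
#'   `panel`.
#' @param panel a `reference_panel` (used for species lookup/validation).
#' @param target target species name.
#' @param constraints a [signature_constraints()].
#' @return a `diagnostic_sites` data frame: `column` (1-based alignment
#'   column), `target_allele`, `background_alleles` (collapsed string),
#'   `fixed_in_target`, `target_fraction`, `n_excluded`; sorted by column.
#' @export
find_diagnostic_sites <- function(aln, panel, target,
                                  constraints = signature_constraints()) {
  target <- normalize_species(target)
  sp <- aln$records$species
  if (!all(sp %in% names(panel$roles))) {
    stop("lookup error: alignment rows not all present in panel", call. = FALSE)
  }
  if (!any(sp == target)) {
    stop("lookup error: target species '", target,
         "' absent from alignment", call. = FALSE)
  }
  tgt <- which(sp == target)
  bkg <- which(sp != target)
  mat <- do.call(rbind, lapply(aln$records$seq, seq_chars))
  out <- list()
  for (col in seq_len(aln$width)) {
    tv <- mat[tgt, col]
    excluded <- tv %in% c("-", "N")
    tv_eff <- tv[!excluded]
    if (!length(tv_eff)) next
    bv <- mat[bkg, col]
    best <- NULL
    for (a in c("A", "C", "G", "T")) {
      frac <- sum(tv_eff == a) / length(tv_eff)
      if (frac < constraints$fixedness || frac == 0) next
      ## allele must be absent from every non-target row, including via
      ## ambiguity codes that could denote it
      carries <- vapply(bv, function(b) {
        b != "-" && a %in% iupac_set(b)
      }, logical(1))
      if (any(carries)) next
      if (is.null(best) || frac > best$frac) {
        best <- list(allele = a, frac = frac)
      }
    }
    if (!is.null(best)) {
      out[[length(out) + 1L]] <- data.frame(
        column = col,
        target_allele = best$allele,
        background_alleles = paste(sort(unique(bv[bv != "-"])), collapse = ""),
        fixed_in_target = best$frac == 1,
        target_fraction = best$frac,
        n_excluded = sum(excluded),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(column = integer(0), target_allele = character(0),
               background_alleles = character(0),
               fixed_in_target = logical(0), target_fraction = numeric(0),
               n_excluded = integer(0), stringsAsFactors = FALSE)
  res <- res[order(res$column), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("diagnostic_sites", "data.frame")
  res
}

#' Construct a nucleotide signature object
#'
#' @param species target species.
#' @param seq ungapped signature sequence.
#' @param ref_record id of the reference record the window was taken from.
#' @param start,end 1-based closed coordinates on the ungapped reference.
#' @param site_offsets 1-based offsets of diagnostic sites within `seq`.
#' @return a `nucleotide_signature` list.
#' @export
nucleotide_signature <- function(species, seq, ref_record, start, end,
                                 site_offsets) {
  seq <- validate_dna(seq, allow_gap = FALSE, id = "signature")
  if (end - start + 1L != nchar(seq)) {
    stop("signature error: coordinates do not match sequence length",
         call. = FALSE)
  }
  if (!length(site_offsets) || any(site_offsets < 1) ||
      any(site_offsets > nchar(seq))) {
    stop("signature error: site_offsets must be non-empty and within the",
         " signature", call. = FALSE)
  }
  structure(list(species = normalize_species(species), seq = seq,
                 ref_record = ref_record, start = as.integer(start),
                 end = as.integer(end),
                 site_offsets = as.integer(site_offsets)),
            class = "nucleotide_signature")
}

#' @export
print.nucleotide_signature <- function(x, ...) {
  cat("Nucleotide signature for ", x$species, "\n  ", x$seq, " (",
      nchar(x$seq), " bp)\n  ref ", x$ref_record, ":", x$start, "-", x$end,
      ", diagnostic offsets: ", paste(x$site_offsets, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Verify that a signature is unique to its target species
#'
#' Runs the seed-and-extend search of the signature against every non-target
#' panel sequence; the signature fails when any hit reaches `max_ident`
#' identity over full query coverage.
#'
#' @param sig a [nucleotide_signature()].
#' @param panel a `reference_panel`.
#' @param max_ident identity fraction at/above which a full-coverage hit
#'   counts as an offender (default 1.0 = exact copies only).
#' @param p optional [search_params()].
#' @return list with `unique` (logical) and `offenders` (a `search_hits`
#'   data frame sorted by identity, descending).
#' @export
verify_uniqueness <- function(sig, panel, max_ident = 1.0,
                              p = search_params()) {
  db <- panel_records(panel, sig$species, negate = TRUE)
  if (!nrow(db)) {
    hits <- seed_extend_search(sig$seq, panel$records[0, ], p = p)
    return(list(unique = TRUE, offenders = hits))
  }
  hits <- seed_extend_search(seq_records("sig", sig$seq), db, p = p)
  tol <- 1e-9
  off <- hits[hits$query_cover >= 100 - tol &
                hits$identity >= 100 * max_ident - tol, , drop = FALSE]
  off <- off[order(-off$identity, off$subject_id), , drop = FALSE]
  rownames(off) <- NULL
  list(unique = nrow(off) == 0L, offenders = off)
}

#' Extract a minimal unique signature window around diagnostic sites
#'
#' Scans windows on the first target row (by alignment order), shortest
#' length first and leftmost first, and returns the first window that
#' contains at least `min_sites` diagnostic sites and passes
#' [verify_uniqueness()] against the panel. Window bounds are reported in
#' ungapped coordinates on that reference row.
#'
#' @param aln a `dna_alignment`.
#' @param panel a `reference_panel`.
#' @param target target species.
#' @param sites a `diagnostic_sites` data frame from
#'   [find_diagnostic_sites()]; must be non-empty.
#' @param constraints a [signature_constraints()].
#' @param max_ident passed to [verify_uniqueness()].
#' @return a `nucleotide_signature`.
#' @export
extract_signature <- function(aln, panel, target, sites,
                              constraints = signature_constraints(),
                              max_ident = 1.0) {
  target <- normalize_species(target)
  if (!nrow(sites)) stop("discovery failure: no diagnostic sites supplied",
                         call. = FALSE)
  rep_row <- which(aln$records$species == target)[1]
  if (is.na(rep_row)) {
    stop("lookup error: target species absent from alignment", call. = FALSE)
  }
  ref_id <- aln$records$id[rep_row]
  u <- col_to_ungapped(aln, rep_row)
  ref_seq <- degap(aln$records$seq[rep_row])
  L_ref <- nchar(ref_seq)
  ## diagnostic site positions on the ungapped reference row
  pos <- u[sites$column]
  pos <- sort(unique(pos[!is.na(pos)]))
  if (!length(pos)) {
    stop("discovery failure: no diagnostic site maps onto the reference row",
         call. = FALSE)
  }
  blocking <- NULL
  for (L in constraints$L_min:constraints$L_max) {
    if (L > L_ref) break
    for (start in 1:(L_ref - L + 1L)) {
      end <- start + L - 1L
      inside <- pos[pos >= start & pos <= end]
      if (length(inside) < constraints$min_sites) next
      cand <- nucleotide_signature(target,
                                   substr(ref_seq, start, end),
                                   ref_id, start, end,
                                   inside - start + 1L)
      chk <- verify_uniqueness(cand, panel, max_ident = max_ident)
      if (chk$unique) return(cand)
      if (is.null(blocking) && nrow(chk$offenders)) {
        blocking <- chk$offenders$subject_id[1]
      }
    }
  }
  stop("discovery failure: no window of length ", constraints$L_min, "-",
       constraints$L_max, " bp with >= ", constraints$min_sites,
       " diagnostic site(s) is unique",
       if (!is.null(blocking)) paste0("; blocking panel hit: ", blocking),
       call. = FALSE)
}
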