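## Pairwise global alignment (Needleman-Wunsch/Gotoh with affine gaps) and a
## star-progressive multiple alignment, sufficient for barcode-scale panels
## (ITS2-like, few hundred bp, congeneric divergence). Pre-aligned FASTA can
## bypass this module entirely.

NEG_SCORE <- -1e15  # effectively -Inf, but exact under double arithmetic

#' Alignment scoring scheme
#'
#' Affine gap model: a gap run of length L costs `gap_open + L * gap_extend`.
#'
#' @param match positive integer reward per identical pair.
#' @param mismatch negative integer penalty per non-identical pair.
#' @param gap_open non-positive integer, charged once per gap run.
#' @param gap_extend non-positive integer, charged per gapped position.
#' @return a `scoring_scheme` list.
#' @export
scoring_scheme <- function(match = 1L, mismatch = -2L, gap_open = -5L,
                           gap_extend = -2L) {
  if (!(match > 0)) stop("config error: match reward must be > 0", call. = FALSE)
  if (!(mismatch < 0)) stop("config error: mismatch penalty must be < 0",
                            call. = FALSE)
  if (gap_open > 0 || gap_extend > 0) {
    stop("config error: gap penalties must be <= 0", call. = FALSE)
  }
  structure(list(match = as.numeric(match), mismatch = as.numeric(mismatch),
                 gap_open = as.numeric(gap_open),
                 gap_extend = as.numeric(gap_extend)),
            class = "scoring_scheme")
}

## Substitution lookup over the 15 IUPAC codes. A pair scores `match` only
## when one side is a concrete base contained in the other side's ambiguity
## set (two equal ambiguity codes stay a mismatch: conservative for
## diagnosticity).
subst_matrix <- function(s) {
  n <- length(IUPAC_CHARS)
  m <- matrix(s$mismatch, n, n, dimnames = list(IUPAC_CHARS, IUPAC_CHARS))
  concrete <- c("A", "C", "G", "T")
  for (x in IUPAC_CHARS) {
    for (y in IUPAC_CHARS) {
      if ((x %in% concrete && x %in% iupac_set(y)) ||
          (y %in% concrete && y %in% iupac_set(x))) {
        m[x, y] <- s$match
      }
    }
  }
  m
}

## Core Gotoh DP, vectorized row-by-row. Returns the three DP matrices and
## the optimal score; traceback is done separately.
gotoh_fill <- function(ac, bc, smat, open, ext) {
  n <- length(ac); m <- length(bc)
  M  <- matrix(NEG_SCORE, n + 1L, m + 1L)
  Ix <- matrix(NEG_SCORE, n + 1L, m + 1L)
  Iy <- matrix(NEG_SCORE, n + 1L, m + 1L)
  M[1L, 1L] <- 0
  if (m > 0L) Iy[1L, 2L:(m + 1L)] <- open + ext * (1:m)
  if (n > 0L) Ix[2L:(n + 1L), 1L] <- open + ext * (1:n)
  if (n > 0L && m > 0L) {
    for (i in 1:n) {
      sv <- smat[ac[i], bc]
      prevM <- M[i, ]; prevIx <- Ix[i, ]; prevIy <- Iy[i, ]
      best_prev <- pmax(prevM, prevIx, prevIy)
      M[i + 1L, 2L:(m + 1L)] <- best_prev[1:m] + sv
      M[i + 1L, 1L] <- NEG_SCORE
      Ix[i + 1L, ] <- pmax(prevM + open + ext, prevIy + open + ext,
                           prevIx + ext)
      B <- pmax(M[i + 1L, ], Ix[i + 1L, ])
      h <- B[1:m] + open - ext * (0:(m - 1L))
      Iy[i + 1L, 2L:(m + 1L)] <- cummax(h) + ext * (1:m)
      Iy[i + 1L, 1L] <- NEG_SCORE
    }
  } else if (n > 0L) {
    ## m == 0: only the Ix column exists (already initialized)
  }
  list(M = M, Ix = Ix, Iy = Iy,
       score = max(M[n + 1L, m + 1L], Ix[n + 1L, m + 1L], Iy[n + 1L, m + 1L]))
}

## Deterministic traceback; tie-break diagonal > up (gap in b) > left
## (gap in a) at every choice point.
gotoh_traceback <- function(fill, ac, bc, smat, open, ext) {
  M <- fill$M; Ix <- fill$Ix; Iy <- fill$Iy
  n <- length(ac); m <- length(bc)
  i <- n; j <- m
  vals <- c(M[i + 1L, j + 1L], Ix[i + 1L, j + 1L], Iy[i + 1L, j + 1L])
  state <- c("M", "Ix", "Iy")[which.max(vals)]  # which.max keeps first on tie
  arow <- character(0); brow <- character(0)
  while (i > 0L || j > 0L) {
    if (state == "M") {
      arow <- c(IUPAC_CHARS[ac[i]], arow); brow <- c(IUPAC_CHARS[bc[j]], brow)
      val <- M[i + 1L, j + 1L] - smat[ac[i], bc[j]]
      state <- if (M[i, j] == val) "M" else if (Ix[i, j] == val) "Ix" else "Iy"
      i <- i - 1L; j <- j - 1L
    } else if (state == "Ix") {
      arow <- c(IUPAC_CHARS[ac[i]], arow); brow <- c("-", brow)
      val <- Ix[i + 1L, j + 1L]
      state <- if (M[i, j + 1L] + open + ext == val) "M"
               else if (Ix[i, j + 1L] + ext == val) "Ix" else "Iy"
      i <- i - 1L
    } else {
      arow <- c("-", arow); brow <- c(IUPAC_CHARS[bc[j]], brow)
      val <- Iy[i + 1L, j + 1L]
      state <- if (M[i + 1L, j] + open + ext == val) "M"
               else if (Ix[i + 1L, j] + open + ext == val) "Ix" else "Iy"
      j <- j - 1L
    }
  }
  list(a = chars_seq(arow), b = chars_seq(brow))
}

as_record <- function(x, default_id = "seq") {
  if (is.character(x) && length(x) == 1L) {
    if (!nzchar(x)) {  # empty sequence: permitted here, aligns to all-gaps
      out <- data.frame(id = default_id, species = "unknown",
                        role = "unknown", seq = "", is_gapped = FALSE,
                        stringsAsFactors = FALSE)
      class(out) <- c("seq_records", "data.frame")
      return(out)
    }
    return(seq_records(default_id, x))
  }
  if (inherits(x, "data.frame")) {
    if (nrow(x) != 1L) stop("expected a single sequence record", call. = FALSE)
    return(x)
  }
  stop("expected a sequence record or DNA string", call. = FALSE)
}

#' Global pairwise alignment with affine gaps
#'
#' Optimal Needleman-Wunsch/Gotoh alignment under `scheme`. The traceback is
#' deterministic: ties resolve diagonal over up (gap in `b`) over left (gap
#' in `a`). Empty sequences are allowed and align against all-gaps.
#'
#' @param a,b ungapped sequence records (one-row `seq_records`) or DNA strings.
#' @param scheme a [scoring_scheme()].
#' @return list with `alignment` (a 2-row `dna_alignment`) and `score`.
#' @export
global_align <- function(a, b, scheme = scoring_scheme()) {
  if (!inherits(scheme, "scoring_scheme")) {
    stop("config error: 'scheme' must be a scoring_scheme", call. = FALSE)
  }
  a <- as_record(a, "a"); b <- as_record(b, "b")
  if (isTRUE(a$is_gapped[1]) || isTRUE(b$is_gapped[1]) ||
      grepl("-", a$seq[1], fixed = TRUE) || grepl("-", b$seq[1], fixed = TRUE)) {
    stop("alignment error: inputs must be ungapped", call. = FALSE)
  }
  ac <- match(seq_chars(a$seq[1]), IUPAC_CHARS)
  bc <- match(seq_chars(b$seq[1]), IUPAC_CHARS)
  if (!nzchar(a$seq[1])) ac <- integer(0)
  if (!nzchar(b$seq[1])) bc <- integer(0)
  smat <- subst_matrix(scheme)
  fill <- gotoh_fill(ac, bc, smat, scheme$gap_open, scheme$gap_extend)
  tb <- gotoh_traceback(fill, ac, bc, smat, scheme$gap_open, scheme$gap_extend)
  ids <- make.unique(c(a$id[1], b$id[1]))
  rows <- seq_records(ids, c(tb$a, tb$b),
                      species = c(a$species[1], b$species[1]),
                      role = c(a$role[1], b$role[1]), is_gapped = TRUE)
  list(alignment = dna_alignment(rows), score = fill$score)
}

#' Construct an alignment object from equal-width gapped records
#'
#' @param records a `seq_records` data frame with `is_gapped = TRUE` rows of
#'   equal width.
#' @return a `dna_alignment` (list with `records` and `width`).
#' @export
dna_alignment <- function(records) {
  w <- unique(nchar(records$seq))
  if (length(w) != 1L) {
    stop("alignment error: rows must have equal width", call. = FALSE)
  }
  structure(list(records = records, width = w), class = "dna_alignment")
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat("DNA alignment: ", nrow(x$records), " rows x ", x$width, " columns\n",
      sep = "")
  invisible(x)
}

#' Map alignment columns to ungapped positions for one row
#'
#' @param aln a `dna_alignment`.
#' @param row row index or record id.
#' @return integer vector of length `aln$width`: the 1-based ungapped position
#'   of each column on that row's input sequence, `NA` at gap columns.
#' @export
col_to_ungapped <- function(aln, row) {
  if (is.character(row)) row <- match(row, aln$records$id)
  ch <- seq_chars(aln$records$seq[row])
  out <- cumsum(ch != "-")
  out[ch == "-"] <- NA_integer_
  as.integer(out)
}

## sum-of-pairs center selection for the star alignment
pairwise_score_matrix <- function(records, scheme) {
  n <- nrow(records)
  smat <- subst_matrix(scheme)
  codes <- lapply(records$seq, function(s) match(seq_chars(s), IUPAC_CHARS))
  sc <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      f <- gotoh_fill(codes[[i]], codes[[j]], smat,
                      scheme$gap_open, scheme$gap_extend)
      sc[i, j] <- sc[j, i] <- f$score
    }
  }
  sc
}

#' Star-progressive multiple sequence alignment
#'
#' The center sequence is the record maximizing the summed pairwise global
#' alignment score against all others; every other record is aligned to the
#' center and merged under the "once a gap, always a gap" rule. Row order is
#' preserved. Adequate for congeneric barcode panels; pre-aligned input can
#' skip this step.
#'
#' @param records a `seq_records` data frame of >= 2 ungapped records (a
#'   single record yields a trivial alignment with a warning).
#' @param scheme a [scoring_scheme()].
#' @return a `dna_alignment`.
#' @export
build_msa <- function(records, scheme = scoring_scheme()) {
  n <- nrow(records)
  if (n == 0L) stop("alignment error: no records", call. = FALSE)
  if (any(grepl("-", records$seq, fixed = TRUE))) {
    stop("alignment error: inputs must be ungapped", call. = FALSE)
  }
  if (n == 1L) {
    warning("single record: returning trivial 1-row alignment")
    rows <- seq_records(records$id, records$seq, species = records$species,
                        role = records$role, is_gapped = TRUE)
    return(dna_alignment(rows))
  }
  sc <- pairwise_score_matrix(records, scheme)
  center <- which.max(rowSums(sc))
  Lc <- nchar(records$seq[center])
  others <- setdiff(seq_len(n), center)

  ins <- integer(Lc + 1L)          # master insertion length per slot 0..Lc
  slot_chars <- vector("list", n)  # per record: list of per-slot insertions
  res_char <- vector("list", n)    # per record: char aligned to each center residue
  for (i in others) {
    pa <- global_align(records[center, ], records[i, ], scheme)
    cg <- seq_chars(pa$alignment$records$seq[1])
    rg <- seq_chars(pa$alignment$records$seq[2])
    sl <- replicate(Lc + 1L, character(0), simplify = FALSE)
    rc <- rep("-", Lc)
    cpos <- 0L
    for (k in seq_along(cg)) {
      if (cg[k] == "-") {
        sl[[cpos + 1L]] <- c(sl[[cpos + 1L]], rg[k])
      } else {
        cpos <- cpos + 1L
        rc[cpos] <- rg[k]
      }
    }
    slot_chars[[i]] <- sl
    res_char[[i]] <- rc
    ins <- pmax(ins, lengths(sl))
  }
  cch <- seq_chars(records$seq[center])
  build_row <- function(sl, rc) {
    parts <- character(0)
    for (k in 0:Lc) {
      seg <- if (is.null(sl)) character(0) else sl[[k + 1L]]
      parts <- c(parts, seg, rep("-", ins[k + 1L] - length(seg)),
                 if (k < Lc) rc[k + 1L])
    }
    chars_seq(parts)
  }
  seqs <- character(n)
  for (i in seq_len(n)) {
    if (i == center) {
      seqs[i] <- build_row(NULL, cch)
    } else {
      seqs[i] <- build_row(slot_chars[[i]], res_char[[i]])
    }
  }
  rows <- seq_records(records$id, seqs, species = records$species,
                      role = records$role, is_gapped = TRUE)
  aln <- dna_alignment(rows)
  attr(aln, "center") <- records$id[center]
  aln
}

#' Degap every row of an alignment back to input sequences
#' @param aln a `dna_alignment`.
#' @return a `seq_records` data frame of ungapped sequences.
#' @export
degap_alignment <- function(aln) {
  seq_records(aln$records$id, degap(aln$records$seq),
              species = aln$records$species, role = aln$records$role,
              is_gapped = FALSE)
}
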