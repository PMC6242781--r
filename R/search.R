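## Local similarity search of short queries (signatures) against a sequence
## set: exact word seeding on both strands, ungapped x-drop extension,
## Karlin-Altschul bit scores and E-values. Intended for 30-40 bp queries
## against barcode-scale panels; gapped and translated search are out of
## scope.

#' Search parameters
#'
#' @param word_size exact-seed length (>= 4).
#' @param match,mismatch per-position scores (+1/-2 by default; the default
#'   Karlin-Altschul `lambda_ka`/`k_ka` are calibrated for this pair).
#' @param x_drop terminate extension when the running score falls this far
#'   below the best seen (score units).
#' @param lambda_ka,k_ka Karlin-Altschul parameters for the scoring system.
#' @param db_length_n,query_length_m search-space sizes in bp; when `NULL`
#'   they are filled in from the actual database and query at search time.
#' @return a `search_params` list.
#' @export
search_params <- function(word_size = 7L, match = 1L, mismatch = -2L,
                          x_drop = 10, lambda_ka = 1.28, k_ka = 0.46,
                          db_length_n = NULL, query_length_m = NULL) {
  if (word_size < 4L) stop("parameter error: word_size must be >= 4",
                           call. = FALSE)
  if (lambda_ka <= 0) stop("parameter error: lambda_ka must be > 0",
                           call. = FALSE)
  if (k_ka <= 0 || k_ka >= 1) stop("parameter error: k_ka must be in (0, 1)",
                                   call. = FALSE)
  structure(list(word_size = as.integer(word_size), match = as.numeric(match),
                 mismatch = as.numeric(mismatch), x_drop = as.numeric(x_drop),
                 lambda_ka = lambda_ka, k_ka = k_ka,
                 db_length_n = db_length_n, query_length_m = query_length_m),
            class = "search_params")
}

#' Karlin-Altschul bit score
#'
#' Normalizes a raw alignment score: `S' = (lambda * S - ln K) / ln 2`.
#'
#' @param S raw score (>= 0).
#' @param p a [search_params()] supplying `lambda_ka` and `k_ka`.
#' @return bit score (float).
#' @export
bit_score <- function(S, p = search_params()) {
  if (any(S < 0)) stop("parameter error: raw score must be >= 0", call. = FALSE)
  (p$lambda_ka * S - log(p$k_ka)) / log(2)
}

#' Expectation value for a bit score
#'
#' `E = m * n * 2^(-S')` over the raw `m x n` search space (no edge-effect
#' correction).
#'
#' @param S_prime bit score.
#' @param p a [search_params()] supplying `query_length_m` and `db_length_n`.
#' @return E-value.
#' @export
evalue <- function(S_prime, p) {
  m <- p$query_length_m; n <- p$db_length_n
  if (is.null(m) || is.null(n) || m <= 0 || n <= 0) {
    stop("parameter error: query_length_m and db_length_n must be > 0",
         call. = FALSE)
  }
  m * n * 2^(-S_prime)
}

## rolling base-4 word codes; NA where the window touches a non-ACGT char
word_codes <- function(codes4, w) {
  n <- length(codes4)
  if (n < w) return(integer(0))
  out <- integer(n - w + 1L)
  pow <- 4^((w - 1L):0)
  for (i in seq_len(n - w + 1L)) {
    win <- codes4[i:(i + w - 1L)]
    out[i] <- if (anyNA(win)) NA_integer_ else sum(win * pow)
  }
  out
}

encode_acgt <- function(seq) {
  ch <- seq_chars(seq)
  m <- match(ch, c("A", "C", "G", "T")) - 1L
  m
}

## x-drop ungapped extension along one diagonal. qv, sv: per-position score
## vector products are formed from the full diagonal overlap; seed occupies
## [seed_q_start, seed_q_end] on the query.
extend_hsp <- function(qch, sch, d, seed_qs, seed_qe, match, mismatch,
                       x_drop) {
  m <- length(qch); L <- length(sch)
  ## query positions on this diagonal with valid subject partner
  q_lo <- max(1L, 1L - d); q_hi <- min(m, L - d)
  idx <- q_lo:q_hi
  sc <- ifelse(qch[idx] == sch[idx + d], match, mismatch)
  ## extend right of the seed
  right_end <- seed_qe - q_lo + 1L
  best_r <- 0; cur <- 0
  k <- right_end
  while (k < length(idx)) {
    k <- k + 1L
    cur <- cur + sc[k]
    if (cur > best_r) { best_r <- cur; right_best <- k }
    if (cur < best_r - x_drop) break
  }
  right_ext <- if (best_r > 0) right_best else right_end
  ## extend left of the seed
  left_start <- seed_qs - q_lo + 1L
  best_l <- 0; cur <- 0
  k <- left_start
  while (k > 1L) {
    k <- k - 1L
    cur <- cur + sc[k]
    if (cur > best_l) { best_l <- cur; left_best <- k }
    if (cur < best_l - x_drop) break
  }
  left_ext <- if (best_l > 0) left_best else left_start
  span <- left_ext:right_ext
  score <- sum(sc[span])
  n_match <- sum(sc[span] == match)
  list(q_start = idx[left_ext], q_end = idx[right_ext],
       s_start = idx[left_ext] + d, s_end = idx[right_ext] + d,
       score = score, n_match = n_match, length = length(span))
}

search_one_strand <- function(qseq, qid, db, p, strand, m_orig) {
  w <- p$word_size
  qch <- seq_chars(qseq)
  q4 <- encode_acgt(qseq)
  qwords <- word_codes(q4, w)
  hits <- list()
  for (si in seq_len(nrow(db))) {
    sseq <- db$seq[si]
    s4 <- encode_acgt(sseq)
    if (length(s4) < w) next
    swords <- word_codes(s4, w)
    ## map word code -> subject positions
    ok <- !is.na(swords)
    if (!any(ok)) next
    smap <- split(which(ok), swords[ok])
    sch <- seq_chars(sseq)
    seen_diag <- integer(0)
    for (qi in seq_along(qwords)) {
      code <- qwords[qi]
      if (is.na(code)) next
      spos <- smap[[as.character(code)]]
      if (is.null(spos)) next
      for (sj in spos) {
        d <- sj - qi
        if (d %in% seen_diag) next
        seen_diag <- c(seen_diag, d)
        h <- extend_hsp(qch, sch, d, qi, qi + w - 1L,
                        p$match, p$mismatch, p$x_drop)
        h$subject_id <- db$id[si]
        h$subject_species <- db$species[si]
        h$strand <- strand
        hits[[length(hits) + 1L]] <- h
      }
    }
  }
  if (!length(hits)) return(NULL)
  df <- data.frame(
    subject_id = vapply(hits, `[[`, "", "subject_id"),
    subject_species = vapply(hits, `[[`, "", "subject_species"),
    strand = vapply(hits, `[[`, "", "strand"),
    q_start = vapply(hits, `[[`, 0, "q_start"),
    q_end = vapply(hits, `[[`, 0, "q_end"),
    s_start = vapply(hits, `[[`, 0, "s_start"),
    s_end = vapply(hits, `[[`, 0, "s_end"),
    score = vapply(hits, `[[`, 0, "score"),
    n_match = vapply(hits, `[[`, 0, "n_match"),
    aln_length = vapply(hits, `[[`, 0, "length"),
    stringsAsFactors = FALSE)
  if (strand == "-") {
    ## coordinates computed on revcomp(query); map back to the original query
    qs <- df$q_start; qe <- df$q_end
    df$q_start <- m_orig - qe + 1L
    df$q_end <- m_orig - qs + 1L
  }
  df
}

#' Seed-and-extend local search
#'
#' Exact `word_size`-mers seed ungapped x-drop extensions on both strands;
#' per subject, the best non-overlapping hits are kept, annotated with
#' identity, query coverage, bit score and E-value, and sorted by bit score.
#'
#' @param query one-row `seq_records` or ungapped DNA string, length >=
#'   `word_size`.
#' @param db a `seq_records` data frame (gapped rows are degapped).
#' @param p a [search_params()].
#' @return a `search_hits` data frame (possibly 0 rows).
#' @export
seed_extend_search <- function(query, db, p = search_params()) {
  query <- as_record(query, "query")
  qseq <- degap(query$seq[1])
  m <- nchar(qseq)
  if (m < p$word_size) {
    stop("parameter error: query shorter than word_size", call. = FALSE)
  }
  db <- as.data.frame(db)
  db$seq <- degap(db$seq)
  if (is.null(p$query_length_m)) p$query_length_m <- m
  if (is.null(p$db_length_n)) p$db_length_n <- sum(nchar(db$seq))
  fwd <- search_one_strand(qseq, query$id[1], db, p, "+", m)
  rev <- search_one_strand(revcomp(qseq), query$id[1], db, p, "-", m)
  df <- rbind(fwd, rev)
  empty <- data.frame(query_id = character(0), subject_id = character(0),
                      subject_species = character(0), strand = character(0),
                      q_start = integer(0), q_end = integer(0),
                      s_start = integer(0), s_end = integer(0),
                      score = numeric(0), bit_score = numeric(0),
                      evalue = numeric(0), identity = numeric(0),
                      query_cover = numeric(0), aln_length = integer(0),
                      n_mismatch = integer(0), stringsAsFactors = FALSE)
  class(empty) <- c("search_hits", "data.frame")
  if (is.null(df) || !nrow(df)) return(empty)
  ## keep best non-overlapping hits per subject/strand (greedy by score,
  ## ties to the leftmost subject interval)
  df <- df[order(df$subject_id, df$strand, -df$score, df$s_start), ]
  keep <- logical(nrow(df))
  for (grp in split(seq_len(nrow(df)),
                    paste(df$subject_id, df$strand))) {
    taken_s <- integer(0)
    for (i in grp) {
      iv <- df$s_start[i]:df$s_end[i]
      if (!any(iv %in% taken_s)) {
        keep[i] <- TRUE
        taken_s <- c(taken_s, iv)
      }
    }
  }
  df <- df[keep, , drop = FALSE]
  df$query_id <- query$id[1]
  df$bit_score <- bit_score(pmax(df$score, 0), p)
  df$evalue <- evalue(df$bit_score, p)
  df$identity <- 100 * df$n_match / df$aln_length
  df$query_cover <- 100 * (df$q_end - df$q_start + 1) / m
  df$n_mismatch <- df$aln_length - df$n_match
  df <- df[order(-df$bit_score, df$subject_id, df$s_start),
           c("query_id", "subject_id", "subject_species", "strand",
             "q_start", "q_end", "s_start", "s_end", "score", "bit_score",
             "evalue", "identity", "query_cover", "aln_length", "n_mismatch")]
  rownames(df) <- NULL
  class(df) <- c("search_hits", "data.frame")
  df
}

#' Write hits as a BLAST outfmt-6-like TSV
#'
#' Columns: qid, sid, pident, length, mismatches, qstart, qend, sstart, send,
#' evalue, bitscore.
#'
#' @param hits a `search_hits` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  out <- data.frame(qid = hits$query_id, sid = hits$subject_id,
                    pident = sprintf("%.2f", hits$identity),
                    length = hits$aln_length, mismatches = hits$n_mismatch,
                    qstart = hits$q_start, qend = hits$q_end,
                    sstart = hits$s_start, send = hits$s_end,
                    evalue = format(hits$evalue, digits = 3),
                    bitscore = sprintf("%.1f", hits$bit_score))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
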