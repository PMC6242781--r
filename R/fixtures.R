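## Loaders for the packaged Cistanches Herba reference fixtures: the four
## species-diagnostic signatures, the six species-specific primer pairs, and
## the qPCR sensitivity (Cq versus weight-ratio) table.

#' Load the packaged nucleotide signatures
#'
#' Four short signatures, one per adulterant species of the Cistanches Herba
#' panel: Cynomorium songaricum (30 bp), Cistanche sinensis (34 bp),
#' Boschniakia rossica (37 bp) and Orobanche coerulescens (31 bp).
#'
#' @return a `seq_records` data frame with 4 rows.
#' @export
load_signatures <- function() {
  read_fasta(fixture_path("signatures.fasta"))
}

#' Load the packaged species-specific assays
#'
#' The six primer pairs (SYF1/SYR1, HMRCF/HMRCR, GHRCF/GHRCR, SCRF/SCRR,
#' CCRF/CCRR, LDF/LDR) targeting the two official Cistanche species and the
#' four adulterants, with expected amplicon sizes 123, 132, 134, 131, 72 and
#' 71 bp and a 50 degC annealing step.
#'
#' @param path optional path to an assay JSON file with fields `name_f`,
#'   `seq_f`, `name_r`, `seq_r`, `target_species`, `amplicon_size` (and
#'   optionally `anneal_temp`); defaults to the packaged table.
#' @return a list of `assay` objects.
#' @export
load_assays <- function(path = NULL) {
  if (is.null(path)) path <- fixture_path("primers.json")
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (!is.data.frame(raw)) stop("format error: assay JSON must be an array",
                                call. = FALSE)
  need <- c("name_f", "seq_f", "name_r", "seq_r", "target_species",
            "amplicon_size")
  if (!all(need %in% names(raw))) {
    stop("format error: assay JSON lacks fields ",
         paste(setdiff(need, names(raw)), collapse = ", "), call. = FALSE)
  }
  lapply(seq_len(nrow(raw)), function(i) {
    assay(forward = primer(raw$name_f[i], raw$seq_f[i]),
          reverse = primer(raw$name_r[i], raw$seq_r[i]),
          target_species = raw$target_species[i],
          expected_amplicon = raw$amplicon_size[i],
          anneal_temp = if ("anneal_temp" %in% names(raw))
            raw$anneal_temp[i] else 50)
  })
}

#' Load the packaged qPCR sensitivity table
#'
#' Cq values (mean of three technical replicates, with standard deviation)
#' for two-species mixtures in which the detected species is diluted against
#' a genuine background at weight ratios from 10:1 to 60000:1. Ratios at
#' which no amplification was observed are recorded as censored.
#'
#' @return a named list of `qpcr_curve` objects, one per detected species,
#'   in table order.
#' @export
load_cq_table <- function() {
  df <- utils::read.csv(fixture_path("cq_table.csv"), stringsAsFactors = FALSE)
  out <- lapply(split(df, factor(df$detected_species,
                                 levels = unique(df$detected_species))),
                function(d) {
                  qpcr_curve(detected_species = d$detected_species[1],
                             mixture_label = d$mixture[1],
                             ratio = d$ratio,
                             cq_mean = d$cq_mean,
                             cq_sd = d$cq_sd,
                             detected = d$detected)
                })
  out[unique(df$detected_species)]
}
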