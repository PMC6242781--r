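## Sequence/panel input-output: FASTA in/out, record and panel containers,
## species-name normalization, product tables.

ROLE_LEVELS <- c("official", "adulterant", "other", "unknown")
DOSE_FORMS  <- c("slice", "powder", "extract", "pill", "capsule", "particle")

## The reference taxa: Cistanches Herba officials and their known adulterants,
## with the genus abbreviations commonly used for them.
SPECIES_SYNONYMS <- c(
  "Ci. deserticola"  = "Cistanche deserticola",
  "C. deserticola"   = "Cistanche deserticola",
  "Ci. tubulosa"     = "Cistanche tubulosa",
  "C. tubulosa"      = "Cistanche tubulosa",
  "Ci. sinensis"     = "Cistanche sinensis",
  "C. sinensis"      = "Cistanche sinensis",
  "Ci. salsa"        = "Cistanche salsa",
  "Cy. songaricum"   = "Cynomorium songaricum",
  "C. songaricum"    = "Cynomorium songaricum",
  "B. rossica"       = "Boschniakia rossica",
  "O. coerulescens"  = "Orobanche coerulescens",
  "S. miltiorrhiza"  = "Salvia miltiorrhiza"
)

#' Normalize a species name to its full binomial
#'
#' Maps the genus abbreviations used for the Cistanches Herba panel
#' ("Cy. songaricum", "Ci. deserticola", ...) to full binomials; names not in
#' the synonym table are returned unchanged (trimmed).
#'
#' @param x character vector of species names.
#' @return character vector of normalized names.
#' @export
normalize_species <- function(x) {
  x <- trimws(x)
  hit <- match(x, names(SPECIES_SYNONYMS))
  x[!is.na(hit)] <- SPECIES_SYNONYMS[hit[!is.na(hit)]]
  x
}

#' Construct a table of sequence records
#'
#' The package's working container for labeled sequences: a data frame with
#' columns `id`, `species`, `role`, `seq`, `is_gapped`, one row per record.
#'
#' @param id character vector of unique record identifiers.
#' @param seq character vector of IUPAC DNA strings (upper-cased on input).
#' @param species species labels (normalized via [normalize_species()]);
#'   defaults to `"unknown"`.
#' @param role one of `"official"`, `"adulterant"`, `"other"`, `"unknown"`.
#' @param is_gapped logical; when `TRUE` the `-` character is permitted and all
#'   sequences must have equal width (aligned dialect).
#' @return a `seq_records` data frame.
#' @export
seq_records <- function(id, seq, species = "unknown", role = "unknown",
                        is_gapped = FALSE) {
  id <- as.character(id)
  if (anyDuplicated(id)) {
    stop("format error: duplicate record id '", id[duplicated(id)][1], "'",
         call. = FALSE)
  }
  seq <- vapply(seq_along(seq), function(i) {
    validate_dna(seq[[i]], allow_gap = is_gapped, id = id[[i]])
  }, character(1))
  if (is_gapped && length(unique(nchar(seq))) > 1L) {
    stop("format error: aligned records must all have equal width",
         call. = FALSE)
  }
  species <- normalize_species(rep_len(as.character(species), length(id)))
  role <- rep_len(as.character(role), length(id))
  if (!all(role %in% ROLE_LEVELS)) {
    stop("format error: role must be one of ",
         paste(ROLE_LEVELS, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(id = id, species = species, role = role, seq = seq,
                    is_gapped = rep_len(is_gapped, length(id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("seq_records", "data.frame")
  out
}

#' Read a FASTA file into sequence records
#'
#' Headers are parsed as `>id key=value key=value ...`; recognized keys are
#' `species` and `role`. Lowercase input is upper-cased. If any record
#' contains `-` the file is treated as the aligned dialect and all records
#' must have equal width; otherwise gaps are rejected.
#'
#' @param path path to a FASTA file (any line wrapping).
#' @param role_map optional named character vector mapping species to roles,
#'   overriding roles parsed from headers.
#' @return a `seq_records` data frame in file order.
#' @export
read_fasta <- function(path, role_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("format error: no FASTA records in ", path,
                              call. = FALSE)
  headers <- names(set)
  seqs <- toupper(as.character(set))
  ids <- character(length(headers))
  species <- rep("unknown", length(headers))
  role <- rep("unknown", length(headers))
  for (i in seq_along(headers)) {
    toks <- strsplit(trimws(headers[i]), "\\s+")[[1]]
    ids[i] <- toks[1]
    kv <- grep("=", toks[-1], fixed = TRUE, value = TRUE)
    ## re-join values containing spaces: header uses key=Genus_species form or
    ## quoted-free 'species=Cynomorium songaricum' split across tokens; we
    ## rejoin tokens following a key=value token that carry no '=' themselves.
    rest <- toks[-1]
    j <- 1L
    while (j <= length(rest)) {
      if (grepl("=", rest[j], fixed = TRUE)) {
        key <- sub("=.*$", "", rest[j])
        val <- sub("^[^=]*=", "", rest[j])
        k <- j + 1L
        while (k <= length(rest) && !grepl("=", rest[k], fixed = TRUE)) {
          val <- paste(val, rest[k])
          k <- k + 1L
        }
        if (key == "species") species[i] <- gsub("_", " ", val)
        if (key == "role") role[i] <- val
        j <- k
      } else {
        j <- j + 1L
      }
    }
  }
  gapped <- any(grepl("-", seqs, fixed = TRUE))
  species <- normalize_species(species)
  if (!is.null(role_map)) {
    names(role_map) <- normalize_species(names(role_map))
    hit <- match(species, names(role_map))
    role[!is.na(hit)] <- role_map[hit[!is.na(hit)]]
  }
  role[!role %in% ROLE_LEVELS] <- "unknown"
  seq_records(ids, seqs, species = species, role = role, is_gapped = gapped)
}

#' Write sequence records to FASTA
#'
#' Headers carry `species=` and `role=` key-value pairs (spaces in species
#' names written as underscores); sequences wrapped at 70 columns.
#'
#' @param records a `seq_records` data frame.
#' @param path output path.
#' @param extra optional named list (per-record character vectors) of
#'   additional `key=value` header fields.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, extra = NULL) {
  hdr <- paste0(records$id,
                " species=", gsub(" ", "_", records$species),
                " role=", records$role)
  if (!is.null(extra)) {
    for (key in names(extra)) {
      hdr <- paste0(hdr, " ", key, "=", extra[[key]])
    }
  }
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Assemble a reference panel
#'
#' A reference panel is the universe against which diagnosticity is defined:
#' labeled sequence records plus a species-to-role map.
#'
#' @param records a `seq_records` data frame.
#' @param species_roles optional named character vector species -> role; when
#'   missing, roles are taken from the records (first occurrence wins).
#' @return a `reference_panel` object (list with `records` and `roles`).
#' @export
reference_panel <- function(records, species_roles = NULL) {
  stopifnot(inherits(records, "data.frame"))
  if (is.null(species_roles)) {
    sp <- unique(records$species)
    species_roles <- records$role[match(sp, records$species)]
    names(species_roles) <- sp
  } else {
    names(species_roles) <- normalize_species(names(species_roles))
    if (!all(records$species %in% names(species_roles))) {
      missing_sp <- setdiff(unique(records$species), names(species_roles))
      stop("panel error: species without a role: ",
           paste(missing_sp, collapse = ", "), call. = FALSE)
    }
    records$role <- unname(species_roles[records$species])
  }
  if (!all(species_roles %in% ROLE_LEVELS)) {
    stop("panel error: roles must be one of ",
         paste(ROLE_LEVELS, collapse = ", "), call. = FALSE)
  }
  out <- list(records = records, roles = species_roles)
  class(out) <- "reference_panel"
  out
}

#' @export
print.reference_panel <- function(x, ...) {
  cat("Reference panel: ", nrow(x$records), " records, ",
      length(x$roles), " species\n", sep = "")
  tab <- table(x$records$species)
  for (sp in names(x$roles)) {
    cat(sprintf("  %-28s %-10s n=%d\n", sp, x$roles[[sp]],
                if (sp %in% names(tab)) tab[[sp]] else 0L))
  }
  invisible(x)
}

#' Records of a panel belonging (or not) to a target species
#' @param panel a `reference_panel`.
#' @param target species name (normalized).
#' @param negate return the non-target records instead.
#' @return a `seq_records` subset.
#' @export
panel_records <- function(panel, target, negate = FALSE) {
  target <- normalize_species(target)
  keep <- panel$records$species == target
  if (negate) keep <- !keep
  panel$records[keep, , drop = FALSE]
}

#' Construct product records
#'
#' One row per commercial product with its set of detected species.
#'
#' @param product_id unique identifiers.
#' @param label declared product name.
#' @param dose_form one of slice, powder, extract, pill, capsule, particle.
#' @param detected_species list of character vectors (may be empty), or a
#'   character vector of semicolon-separated names.
#' @return a `product_records` data frame with list-column `detected_species`.
#' @export
product_records <- function(product_id, label, dose_form, detected_species) {
  product_id <- as.character(product_id)
  if (anyDuplicated(product_id)) {
    stop("format error: duplicate product_id", call. = FALSE)
  }
  if (!all(dose_form %in% DOSE_FORMS)) {
    stop("format error: dose_form must be one of ",
         paste(DOSE_FORMS, collapse = ", "), call. = FALSE)
  }
  if (!is.list(detected_species)) {
    detected_species <- lapply(strsplit(as.character(detected_species), ";"),
                               function(v) v[nzchar(trimws(v))])
  }
  detected_species <- lapply(detected_species,
                             function(v) unique(normalize_species(v)))
  out <- data.frame(product_id = product_id,
                    label = as.character(label),
                    dose_form = as.character(dose_form),
                    stringsAsFactors = FALSE)
  out$detected_species <- detected_species
  class(out) <- c("product_records", "data.frame")
  out
}

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "nucsig")
  if (!nzchar(p) || !file.exists(p)) {
    stop("packaging error: fixture '", file, "' not found", call. = FALSE)
  }
  p
}

read_product_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("product_id", "label", "dose_form", "detected_species")
  if (!all(need %in% names(df))) {
    stop("packaging error: product table lacks columns ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  product_records(df$product_id, df$label, df$dose_form, df$detected_species)
}

#' Load the packaged market-survey product tables
#'
#' The packaged survey comprises 66 Cistanches Herba products: 35 slices,
#' powders and extracts plus 31 Chinese patent medicines, each with the set of
#' species detected by signature-based assays.
#'
#' @param which `"all"` (default), `"crude"` (35 slices/powders/extracts) or
#'   `"patent"` (31 patent medicines).
#' @return a `product_records` data frame.
#' @export
load_survey_fixture <- function(which = c("all", "crude", "patent")) {
  which <- match.arg(which)
  t1 <- read_product_csv(fixture_path("survey_table1.csv"))
  t2 <- read_product_csv(fixture_path("survey_table2.csv"))
  out <- switch(which, crude = t1, patent = t2, all = {
    a <- t1; class(a) <- "data.frame"
    b <- t2; class(b) <- "data.frame"
    both <- rbind(a, b)
    class(both) <- c("product_records", "data.frame")
    both
  })
  out
}
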