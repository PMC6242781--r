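## Seeded generators for ITS2-like reference panels with planted diagnostic
## SNPs, weighted mixture fragment pools, and heat-degraded (decoction-style)
## fragment pools. All generators are pure functions of (spec, seed): the
## global RNG state is saved and restored.

with_seed <- function(seed, code) {
  if (is.null(seed)) stop("spec error: seed is mandatory", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

BASES <- c("A", "C", "G", "T")

#' Specification of a synthetic reference panel
#'
#' Emulates the statistical structure of a congeneric ITS2 panel: a shared
#' ancestor, per-species divergence, light within-species variation, and a
#' few planted species-diagnostic SNPs.
#'
#' @param n_species number of species.
#' @param n_per_species sequences per species.
#' @param seq_length sequence length in bp (default 230, a typical aligned
#'   ITS2 length for this panel).
#' @param interspecies_divergence substitutions per site between a species
#'   and the ancestor (in [0, 0.5)).
#' @param intraspecies_divergence substitutions per site within a species.
#' @param planted_sites named list, species -> data.frame/list of
#'   `position`, `allele`: alleles forced into all members of that species
#'   and guaranteed absent there in all other species.
#' @param species_names optional species names (defaults `sp1`, `sp2`, ...).
#' @param roles optional roles per species (default: first species
#'   `official`, the rest `adulterant`).
#' @param seed mandatory integer seed.
#' @return a `panel_spec` list.
#' @export
panel_spec <- function(n_species = 4L, n_per_species = 3L, seq_length = 230L,
                       interspecies_divergence = 0.05,
                       intraspecies_divergence = 0.005,
                       planted_sites = list(), species_names = NULL,
                       roles = NULL, seed) {
  if (missing(seed)) stop("spec error: seed is mandatory", call. = FALSE)
  if (interspecies_divergence < 0 || interspecies_divergence >= 0.5 ||
      intraspecies_divergence < 0 || intraspecies_divergence >= 0.5) {
    stop("spec error: divergences must be in [0, 0.5)", call. = FALSE)
  }
  if (is.null(species_names)) {
    species_names <- paste0("sp", seq_len(n_species))
  }
  if (is.null(roles)) {
    roles <- c("official", rep("adulterant", n_species - 1L))
  }
  for (sp in names(planted_sites)) {
    ps <- planted_sites[[sp]]
    if (any(ps$position < 1L) || any(ps$position > seq_length)) {
      stop("spec error: planted positions must lie within the sequence",
           call. = FALSE)
    }
    if (!sp %in% species_names) {
      stop("spec error: planted species '", sp, "' not in panel", call. = FALSE)
    }
  }
  structure(list(n_species = as.integer(n_species),
                 n_per_species = as.integer(n_per_species),
                 seq_length = as.integer(seq_length),
                 interspecies_divergence = interspecies_divergence,
                 intraspecies_divergence = intraspecies_divergence,
                 planted_sites = planted_sites,
                 species_names = species_names,
                 roles = roles, seed = as.integer(seed)),
            class = "panel_spec")
}

mutate_seq <- function(ch, rate) {
  if (rate <= 0) return(ch)
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) {
    ch[i] <- sample(setdiff(BASES, ch[i]), 1L)
  }
  ch
}

#' Simulate a labeled reference panel
#'
#' An ancestor sequence is mutated once per species (interspecies rate), then
#' once per individual (intraspecies rate); planted diagnostic alleles are
#' written into every member of their species and forced absent at those
#' positions in every other species. Byte-identical output for a given spec.
#'
#' @param spec a [panel_spec()].
#' @return a `reference_panel`.
#' @export
simulate_panel <- function(spec) {
  with_seed(spec$seed, {
    anc <- sample(BASES, spec$seq_length, replace = TRUE)
    ids <- character(0); seqs <- character(0); species <- character(0)
    planted <- spec$planted_sites
    sp_cons <- list()
    for (si in seq_len(spec$n_species)) {
      sp <- spec$species_names[si]
      cons <- mutate_seq(anc, spec$interspecies_divergence)
      sp_cons[[sp]] <- cons
    }
    ## plant alleles, and scrub them from every other species' consensus
    for (sp in names(planted)) {
      ps <- planted[[sp]]
      for (k in seq_along(ps$position)) {
        pos <- ps$position[k]; allele <- toupper(ps$allele[k])
        sp_cons[[sp]][pos] <- allele
        for (other in setdiff(spec$species_names, sp)) {
          if (sp_cons[[other]][pos] == allele) {
            sp_cons[[other]][pos] <- setdiff(BASES, allele)[1]
          }
        }
      }
    }
    for (si in seq_len(spec$n_species)) {
      sp <- spec$species_names[si]
      keep <- if (sp %in% names(planted)) planted[[sp]]$position else integer(0)
      ## positions other species must keep clear of the planted alleles
      avoid <- list()
      for (osp in setdiff(names(planted), sp)) {
        ps <- planted[[osp]]
        for (k in seq_along(ps$position)) {
          avoid[[length(avoid) + 1L]] <- c(ps$position[k], ps$allele[k])
        }
      }
      for (ind in seq_len(spec$n_per_species)) {
        ch <- mutate_seq(sp_cons[[sp]], spec$intraspecies_divergence)
        ch[keep] <- sp_cons[[sp]][keep]          # planted sites stay fixed
        for (av in avoid) {                       # and stay absent elsewhere
          pos <- as.integer(av[1])
          if (ch[pos] == av[2]) ch[pos] <- sp_cons[[sp]][pos]
          if (ch[pos] == av[2]) ch[pos] <- setdiff(BASES, av[2])[1]
        }
        ids <- c(ids, paste0(sp, "_", ind))
        seqs <- c(seqs, chars_seq(ch))
        species <- c(species, sp)
      }
    }
    roles <- stats::setNames(spec$roles, spec$species_names)
    recs <- seq_records(ids, seqs, species = species,
                        role = unname(roles[species]))
    reference_panel(recs, roles)
  })
}

new_fragment_pool <- function(fragments, mean_len, boil_time = NA_real_,
                              decay_rate = NA_real_) {
  structure(list(fragments = fragments, mean_len = mean_len,
                 boil_time = boil_time, decay_rate = decay_rate),
            class = "fragment_pool")
}

#' @export
print.fragment_pool <- function(x, ...) {
  cat("Fragment pool: ", nrow(x$fragments), " fragments, target mean length ",
      sprintf("%.1f", x$mean_len), " bp\n", sep = "")
  invisible(x)
}

## draw fragments from a set of templates: start uniform, length geometric
## with the given mean, truncated at the template end
draw_fragments <- function(templates, n_fragments, mean_len, prefix) {
  tlen <- nchar(templates$seq)
  ti <- sample.int(nrow(templates), n_fragments, replace = TRUE,
                   prob = templates$weight)
  starts <- integer(n_fragments); ends <- integer(n_fragments)
  for (i in seq_len(n_fragments)) {
    L <- tlen[ti[i]]
    s <- sample.int(L, 1L)
    len <- 1L + stats::rgeom(1L, prob = min(1, 1 / mean_len))
    starts[i] <- s
    ends[i] <- min(L, s + len - 1L)
  }
  frag_seq <- substr(templates$seq[ti], starts, ends)
  df <- seq_records(paste0(prefix, seq_len(n_fragments)), frag_seq,
                    species = templates$species[ti])
  df$source_id <- templates$id[ti]
  df$source_start <- starts
  df$source_end <- ends
  df
}

#' Simulate a weighted mixture fragment pool
#'
#' Fragment source species are drawn proportional to mass-fraction weights;
#' within a species, source records are equally likely. Fragment starts are
#' uniform and lengths geometric with mean `mean_len`, truncated at the
#' template end.
#'
#' @param panel a `reference_panel`.
#' @param weights named numeric vector species -> mass fraction (sums to 1).
#' @param n_fragments number of fragments (>= 1).
#' @param mean_len mean fragment length in bp.
#' @param seed integer seed.
#' @return a `fragment_pool`.
#' @export
simulate_mixture_pool <- function(panel, weights, n_fragments = 1000L,
                                  mean_len = 150, seed) {
  if (missing(seed)) stop("spec error: seed is mandatory", call. = FALSE)
  names(weights) <- normalize_species(names(weights))
  if (abs(sum(weights) - 1) > 1e-8) {
    stop("spec error: weights must sum to 1", call. = FALSE)
  }
  if (n_fragments < 1L) stop("spec error: n_fragments must be >= 1",
                             call. = FALSE)
  if (!all(names(weights) %in% names(panel$roles))) {
    stop("spec error: weight species not all in panel", call. = FALSE)
  }
  recs <- panel$records[panel$records$species %in% names(weights), ,
                        drop = FALSE]
  ## per-record draw probability: species weight split evenly within species
  n_by_sp <- table(recs$species)
  recs$weight <- unname(weights[recs$species] /
                          as.integer(n_by_sp[recs$species]))
  with_seed(seed, {
    frags <- draw_fragments(recs, n_fragments, mean_len, "frag")
    new_fragment_pool(frags, mean_len)
  })
}

#' Simulate a decoction (boiling-degraded) fragment pool
#'
#' The mean fragment length decays exponentially with boil time:
#' `mean_len(t) = lambda0 * exp(-k_deg * t)`; fragments are then sampled as
#' in [simulate_mixture_pool()]. Longer boils leave fewer fragments long
#' enough to span a given amplicon, so detection of longer targets fades
#' and eventually disappears.
#'
#' @param template one-row `seq_records` (or DNA string) to fragment.
#' @param t boil time in minutes (>= 0).
#' @param lambda0 mean fragment length at t = 0, in bp.
#' @param k_deg degradation rate per minute.
#' @param n_fragments number of fragments.
#' @param seed integer seed.
#' @return a `fragment_pool` with `boil_time` and `decay_rate` recorded.
#' @export
simulate_decoction <- function(template, t, lambda0 = 500, k_deg = 0.015,
                               n_fragments = 200L, seed) {
  if (missing(seed)) stop("spec error: seed is mandatory", call. = FALSE)
  if (t < 0) stop("spec error: boil time must be >= 0", call. = FALSE)
  template <- as_record(template, "template")
  template$weight <- 1
  mean_len <- lambda0 * exp(-k_deg * t)
  with_seed(seed, {
    frags <- draw_fragments(template, n_fragments, mean_len, "dfrag")
    new_fragment_pool(frags, mean_len, boil_time = t, decay_rate = k_deg)
  })
}
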