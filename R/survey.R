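## Product classification from detected-species sets and market-survey
## aggregate statistics.

SURVEY_CATEGORIES <- c("authentic", "adulterated_mixture", "substituted",
                       "nonpanel_substituted", "no_detection")

#' Product classification policy
#'
#' @param official_set species accepted as the genuine ingredient.
#' @param adulterant_set known adulterant species.
#' @return a `classification_policy` list; the sets must be disjoint and
#'   non-empty.
#' @export
classification_policy <- function(
    official_set = c("Cistanche deserticola", "Cistanche tubulosa"),
    adulterant_set = c("Cynomorium songaricum", "Cistanche sinensis",
                       "Boschniakia rossica", "Orobanche coerulescens")) {
  official_set <- normalize_species(official_set)
  adulterant_set <- normalize_species(adulterant_set)
  if (!length(official_set) || !length(adulterant_set)) {
    stop("policy error: both sets must be non-empty", call. = FALSE)
  }
  if (length(intersect(official_set, adulterant_set))) {
    stop("policy error: official and adulterant sets must be disjoint",
         call. = FALSE)
  }
  structure(list(official_set = official_set,
                 adulterant_set = adulterant_set),
            class = "classification_policy")
}

#' Classify one product from its detected species
#'
#' Categories: `authentic` (only official species, at least one),
#' `adulterated_mixture` (official and adulterant species together),
#' `substituted` (adulterant species, no official), `nonpanel_substituted`
#' (only species outside both sets), `no_detection` (empty set). The
#' categories are mutually exclusive and exhaustive.
#'
#' @param detected character vector of detected species (may be empty).
#' @param policy a [classification_policy()].
#' @return one of the category names.
#' @export
classify_product <- function(detected, policy = classification_policy()) {
  detected <- unique(normalize_species(detected))
  detected <- detected[nzchar(detected)]
  has_off <- any(detected %in% policy$official_set)
  has_adu <- any(detected %in% policy$adulterant_set)
  if (!length(detected)) return("no_detection")
  if (has_off && has_adu) return("adulterated_mixture")
  if (has_adu) return("substituted")
  if (has_off && all(detected %in% policy$official_set)) return("authentic")
  if (has_off) return("adulterated_mixture")  # official + non-panel species
  "nonpanel_substituted"
}

round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Summarize a market survey
#'
#' Classifies every product and aggregates counts and rates. The headline
#' adulteration rate counts mixtures plus substitutions with known panel
#' adulterants; substitutions with species outside the panel are reported in
#' their own count and excluded from that rate.
#'
#' @param products a `product_records` data frame.
#' @param policy a [classification_policy()].
#' @param subset optional logical/integer index or predicate function
#'   applied to `products` before summarizing.
#' @return a `survey_summary` list: per-category counts, rates (percent,
#'   half-up rounded to 1 decimal, with raw fractions), per-species
#'   detection counts and the per-product classifications.
#' @export
summarize_survey <- function(products, policy = classification_policy(),
                             subset = NULL) {
  if (!is.null(subset)) {
    idx <- if (is.function(subset)) subset(products) else subset
    products <- products[idx, , drop = FALSE]
  }
  n <- nrow(products)
  if (!n) stop("survey error: no products", call. = FALSE)
  cls <- vapply(products$detected_species, classify_product,
                character(1), policy = policy)
  counts <- vapply(SURVEY_CATEGORIES, function(k) sum(cls == k), integer(1))
  n_adulterated <- counts[["adulterated_mixture"]] + counts[["substituted"]]
  sp_all <- unlist(products$detected_species)
  per_species <- if (length(sp_all)) {
    tab <- table(sp_all)
    stats::setNames(as.integer(tab), names(tab))
  } else integer(0)
  out <- structure(list(
    n_products = n,
    n_authentic = counts[["authentic"]],
    n_adulterated_mixture = counts[["adulterated_mixture"]],
    n_substituted = counts[["substituted"]],
    n_nonpanel_substituted = counts[["nonpanel_substituted"]],
    n_no_detection = counts[["no_detection"]],
    rate_adulteration = round_half_up(100 * n_adulterated / n),
    rate_mixture = round_half_up(100 * counts[["adulterated_mixture"]] / n),
    rate_substitution = round_half_up(100 * counts[["substituted"]] / n),
    raw_fraction_adulteration = n_adulterated / n,
    raw_fraction_mixture = counts[["adulterated_mixture"]] / n,
    raw_fraction_substitution = counts[["substituted"]] / n,
    per_species_detection_counts = per_species,
    classifications = stats::setNames(cls, products$product_id)),
    class = "survey_summary")
  out
}

#' @export
print.survey_summary <- function(x, ...) {
  cat("Survey of ", x$n_products, " products\n",
      "  authentic:             ", x$n_authentic, "\n",
      "  adulterated (mixture): ", x$n_adulterated_mixture, "\n",
      "  substituted (panel):   ", x$n_substituted, "\n",
      "  substituted (other):   ", x$n_nonpanel_substituted, "\n",
      "  no detection:          ", x$n_no_detection, "\n",
      "  adulteration rate:     ", x$rate_adulteration, "%  (mixture ",
      x$rate_mixture, "%, substitution ", x$rate_substitution, "%)\n",
      sep = "")
  invisible(x)
}
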