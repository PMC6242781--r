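## qPCR detection-sensitivity modeling: Cq versus log10 weight ratio by
## ordinary least squares, amplification efficiency from the slope, and the
## limit-of-detection ratio at a Cq cutoff.

#' Construct a qPCR dilution curve
#'
#' Points are (weight ratio, mean Cq, Cq sd); ratios at which no
#' amplification was observed are recorded as censored and excluded from
#' fitting.
#'
#' @param detected_species species the assay detects.
#' @param mixture_label label of the mixture series.
#' @param ratio positive, strictly increasing weight ratios (background :
#'   detected species).
#' @param cq_mean,cq_sd mean and standard deviation of Cq at each ratio;
#'   `NA` marks a censored (not detected) ratio.
#' @param detected optional logical vector; defaults to `!is.na(cq_mean)`.
#' @return a `qpcr_curve` list with `points` and `censored`.
#' @export
qpcr_curve <- function(detected_species, mixture_label, ratio, cq_mean,
                       cq_sd = NULL, detected = NULL) {
  if (is.null(detected)) detected <- !is.na(cq_mean)
  if (is.null(cq_sd)) cq_sd <- rep(NA_real_, length(ratio))
  if (any(ratio <= 0)) stop("curve error: ratios must be positive",
                            call. = FALSE)
  if (is.unsorted(ratio, strictly = TRUE)) {
    stop("curve error: ratios must be strictly increasing", call. = FALSE)
  }
  if (any(cq_sd[detected] < 0, na.rm = TRUE)) {
    stop("curve error: cq_sd must be >= 0", call. = FALSE)
  }
  if (any(detected) && any(!detected) &&
      min(ratio[!detected]) < max(ratio[detected])) {
    stop("curve error: censored ratios must exceed the largest detected",
         " ratio", call. = FALSE)
  }
  pts <- data.frame(ratio = ratio[detected], cq_mean = cq_mean[detected],
                    cq_sd = cq_sd[detected])
  structure(list(detected_species = normalize_species(detected_species),
                 mixture_label = mixture_label, points = pts,
                 censored = ratio[!detected]),
            class = "qpcr_curve")
}

#' @export
print.qpcr_curve <- function(x, ...) {
  cat("qPCR curve: ", x$detected_species, " in ", x$mixture_label, "\n  ",
      nrow(x$points), " detected points, ", length(x$censored),
      " censored ratios\n", sep = "")
  invisible(x)
}

#' Fit the log-linear Cq model
#'
#' Ordinary least squares of `cq_mean` on `log10(ratio)` over the detected
#' points (censored ratios excluded, not imputed). A weighted fit (1/sd^2)
#' is available; the default is unweighted.
#'
#' @param curve a [qpcr_curve()] with >= 3 detected points.
#' @param weighted use 1/sd^2 weights.
#' @param cq_cutoff Cq ceiling used for the limit-of-detection annotation.
#' @return a `qpcr_fit` list: `intercept`, `slope` (cycles per log10 ratio),
#'   `r_squared`, `efficiency`, `lod_ratio`, `cq_cutoff`, `n_points`,
#'   `noninformative`.
#' @export
fit_cq_model <- function(curve, weighted = FALSE, cq_cutoff = 37) {
  pts <- curve$points
  if (nrow(pts) < 3L) {
    stop("fit error: need >= 3 detected points", call. = FALSE)
  }
  x <- log10(pts$ratio)
  w <- if (weighted) 1 / pts$cq_sd^2 else NULL
  fit <- stats::lm(pts$cq_mean ~ x, weights = w)
  a <- unname(stats::coef(fit)[1])
  b <- unname(stats::coef(fit)[2])
  noninf <- isTRUE(all.equal(b, 0)) || stats::var(pts$cq_mean) == 0
  r2 <- if (noninf) NA_real_ else {
    1 - sum(stats::residuals(fit)^2) /
      sum((pts$cq_mean - mean(pts$cq_mean))^2)
  }
  out <- structure(list(detected_species = curve$detected_species,
                        intercept = a, slope = b, r_squared = r2,
                        efficiency = if (noninf) NA_real_ else
                          10^(1 / abs(b)) - 1,
                        cq_cutoff = cq_cutoff,
                        lod_ratio = NA_real_,
                        n_points = nrow(pts),
                        noninformative = noninf,
                        lm = fit),
                   class = "qpcr_fit")
  if (!noninf && b > 0) out$lod_ratio <- lod_ratio(out, cq_cutoff)
  out
}

#' @export
print.qpcr_fit <- function(x, ...) {
  cat("Cq = ", sprintf("%.3f", x$intercept), " + ",
      sprintf("%.4f", x$slope), " * log10(ratio)   [", x$detected_species,
      "]\n", sep = "")
  if (x$noninformative) {
    cat("  non-informative fit (flat response)\n")
  } else {
    cat("  r^2 = ", sprintf("%.4f", x$r_squared), ", efficiency = ",
        sprintf("%.1f", 100 * x$efficiency), "%, LOD ratio at Cq ",
        x$cq_cutoff, " = ", sprintf("%.0f", x$lod_ratio), ":1\n", sep = "")
  }
  invisible(x)
}

#' Amplification efficiency from a fitted slope
#'
#' `E = 10^(1/|slope|) - 1`; a slope magnitude of 3.32 cycles per log10 unit
#' corresponds to 100% efficiency (perfect doubling each cycle).
#'
#' @param fit a `qpcr_fit`.
#' @return efficiency as a fraction (1.0 = 100%).
#' @export
efficiency <- function(fit) {
  b <- fit$slope
  if (fit$noninformative || b == 0) {
    stop("fit error: efficiency undefined for a flat fit", call. = FALSE)
  }
  10^(1 / abs(b)) - 1
}

#' Limit-of-detection ratio at a Cq cutoff
#'
#' The largest dilution ratio whose predicted Cq stays at or below
#' `cq_cutoff`: `10^((cq_cutoff - intercept) / slope)`.
#'
#' @param fit a `qpcr_fit` with positive slope.
#' @param cq_cutoff Cq ceiling in cycles (default 37).
#' @return the ratio (e.g. 20000 means 20000:1).
#' @export
lod_ratio <- function(fit, cq_cutoff = 37) {
  b <- fit$slope
  if (is.na(b) || b <= 0) {
    stop("fit error: LOD requires a positive slope", call. = FALSE)
  }
  r <- 10^((cq_cutoff - fit$intercept) / b)
  if (r < 1) warning("cq_cutoff below the fitted intercept: LOD ratio < 1")
  r
}
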