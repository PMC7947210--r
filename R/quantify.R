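# Standard curves and the C-T transforming equation ---------------------

# R^2 computed directly from the residuals (summary.lm warns on exact fits)
r_squared_of <- function(fit, y) {
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(1)
  max(0, 1 - sum(stats::residuals(fit)^2) / sst)
}

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10(known amount) over a dilution
#' series, giving the slope (cycles per decade), intercept (Ct at one unit
#' of amount), R-squared, and the PCR amplification efficiency
#' `10^(-1/slope) - 1` (1.0 = perfect doubling each cycle).  The amount unit
#' is whatever the calibrator is stated in (ng for a genomic standard,
#' copies/ul for synthetic indicators); quantities read off the curve carry
#' that unit.
#'
#' @param amount Known input amounts, > 0, at least 3 distinct values.
#' @param ct Observed Ct values (cycles), all numeric.
#' @param channel Channel label recorded on the curve (one of
#'   [bisque_channels()]), for bookkeeping.
#' @param unit Amount unit label (`"ng"` or `"copies"`), for bookkeeping.
#' @return An object of class `standard_curve` with elements `slope`,
#'   `intercept`, `r_squared`, `efficiency`, `channel`, `unit`, `n`.
#' @export
#' @examples
#' amt <- c(10, 2, 0.4, 0.08, 0.016)
#' fit_standard_curve(amt, -3.3219 * log10(amt) + 30, "SHORT_C")
fit_standard_curve <- function(amount, ct, channel = NA_character_,
                               unit = "ng") {
  if (anyNA(ct)) stop("all standard Ct values must be numeric", call. = FALSE)
  if (any(amount <= 0)) stop("standard amounts must be > 0", call. = FALSE)
  if (length(unique(amount)) < 3) {
    stop("insufficient standards: need >= 3 distinct amounts, got ",
         length(unique(amount)), call. = FALSE)
  }
  x <- log10(amount)
  fit <- stats::lm(ct ~ x)
  slope <- unname(coef(fit)[2])
  if (slope >= 0) {
    stop("invalid standard curve: slope must be negative (got ",
         signif(slope, 4), ")", call. = FALSE)
  }
  r2 <- r_squared_of(fit, ct)
  structure(list(slope = slope,
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2,
                 efficiency = 10^(-1 / slope) - 1,
                 channel = channel, unit = unit, n = length(ct)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve %s> Ct = %.4f log10(%s) + %.4f  (R^2 = %.4f, eff = %.1f%%)\n",
    x$channel, x$slope, x$unit, x$intercept, x$r_squared, 100 * x$efficiency))
  invisible(x)
}

#' Fit the short-T to short-C Ct transforming equation
#'
#' The converted (short-T) amplicon has no standard curve of its own: human
#' genomic standard DNA yields no short-T signal.  Synthetic C/T indicator
#' oligos carrying a degenerate Y base at the discrimination site produce
#' both signals at every dilution, and a least-squares fit of the paired Cts
#' across the dilution series gives the linear transform
#' `ct_C_equiv = alpha * ct_T + beta` that maps a short-T Ct onto the
#' short-C scale.  The fit's R-squared is a run-level reliability gate: a
#' run whose transform has R-squared below `r2_min` is flagged unreliable.
#'
#' @param ct_short_c,ct_short_t Paired Cts of the two channels, one pair per
#'   indicator dilution (>= 2 dilutions; the nominal design uses four, at
#'   1e6..1e3 copies/ul).
#' @param copies Optional dilution labels (copies/ul), used only in error
#'   messages.
#' @param r2_min Reliability threshold on R-squared (default 0.99).
#' @return An object of class `ct_transform` with `alpha`, `beta`,
#'   `r_squared`, `reliable`, `n`.
#' @export
fit_ct_transform <- function(ct_short_c, ct_short_t, copies = NULL,
                             r2_min = 0.99) {
  if (length(ct_short_c) != length(ct_short_t)) {
    stop("short-C and short-T Ct vectors must be paired", call. = FALSE)
  }
  bad <- is.na(ct_short_c) | is.na(ct_short_t)
  if (any(bad)) {
    lab <- if (!is.null(copies)) paste(copies[bad], collapse = ", ")
           else paste(which(bad), collapse = ", ")
    stop("undetermined indicator Ct at dilution(s): ", lab, call. = FALSE)
  }
  if (length(ct_short_c) < 2) {
    stop("need >= 2 indicator dilutions to fit the transform", call. = FALSE)
  }
  fit <- stats::lm(ct_short_c ~ ct_short_t)
  r2 <- r_squared_of(fit, ct_short_c)
  structure(list(alpha = unname(coef(fit)[2]),
                 beta = unname(coef(fit)[1]),
                 r_squared = r2,
                 reliable = r2 >= r2_min,
                 n = length(ct_short_c)),
            class = "ct_transform")
}

#' @export
print.ct_transform <- function(x, ...) {
  cat(sprintf(
    "<ct_transform> Ct_C = %.4f Ct_T + %.4f  (R^2 = %.4f, %s)\n",
    x$alpha, x$beta, x$r_squared,
    if (x$reliable) "reliable" else "UNRELIABLE"))
  invisible(x)
}

#' Identity short-T transform
#'
#' Convenience constructor for `alpha = 1`, `beta = 0` (short-T Ct used on
#' the short-C curve unchanged), mainly for tests and degenerate designs.
#' @return A `ct_transform`.
#' @export
identity_transform <- function() {
  structure(list(alpha = 1, beta = 0, r_squared = 1, reliable = TRUE, n = 0L),
            class = "ct_transform")
}

# Ct -> amount -----------------------------------------------------------

#' Convert Ct values to amounts via a standard curve
#'
#' `amount = 10^((ct - intercept) / slope)` in the curve's unit, per
#' reaction (1 ul of template).  Undetermined Ct (`NA`) maps to amount 0:
#' no amplification within the protocol means no detectable template.
#'
#' @param ct Ct values (cycles); `NA` = undetermined.
#' @param curve A [fit_standard_curve()] result.
#' @return Numeric vector of amounts (>= 0), same length as `ct`.
#' @export
quantify <- function(ct, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  out <- 10^((ct - curve$intercept) / curve$slope)
  out[is.na(ct)] <- 0
  out
}

#' Quantify the converted (short-T) signal against the short-C curve
#'
#' Applies the C-T transforming equation to a short-T Ct and reads the
#' transformed Ct off the short-C standard curve:
#' `quantify(alpha * ct_t + beta, shortC_curve)`.
#'
#' @param ct_t Short-T Ct values; `NA` = undetermined (amount 0).
#' @param transform A [fit_ct_transform()] result.
#' @param shortc_curve The short-C [fit_standard_curve()] result.
#' @return Numeric vector of short-C-equivalent amounts.
#' @export
quantify_short_t <- function(ct_t, transform, shortc_curve) {
  stopifnot(inherits(transform, "ct_transform"))
  quantify(transform$alpha * ct_t + transform$beta, shortc_curve)
}

#' Export fitted curves and transform as JSON
#'
#' Writes the run-level fits (per-channel slope, intercept, R-squared, PCR
#' efficiency, and the transform with its reliability flag) to a JSON file.
#'
#' @param curves Named list of `standard_curve` objects.
#' @param transform A `ct_transform` (or `NULL`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fits_json <- function(curves, transform, path) {
  x <- list(
    standard_curves = lapply(curves, function(cv) {
      list(channel = cv$channel, unit = cv$unit, slope = cv$slope,
           intercept = cv$intercept, r_squared = cv$r_squared,
           pcr_efficiency = cv$efficiency, n_points = cv$n)
    }),
    ct_transform = if (is.null(transform)) NULL else list(
      alpha = transform$alpha, beta = transform$beta,
      r_squared = transform$r_squared, reliable = transform$reliable)
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
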