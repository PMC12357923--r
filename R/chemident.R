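# Monoisotopic atomic masses (Da). C is exactly 12 by definition of the
# unified atomic mass unit; the others are CODATA/IUPAC values pinned as
# constants so mass arithmetic is bit-stable across platforms.
ATOMIC_MASS <- c(
  C = 12,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069,
  P = 30.97376151
)

PROTON_MASS   <- 1.007276  # Da, mass of H+
H_ATOM_MASS   <- 1.0078250319  # Da, neutral hydrogen atom
ELECTRON_MASS <- 0.000549  # Da

# Round half up at `digits` decimals (base round() is round-half-even,
# which disagrees with how printed m/z values are conventionally rounded).
round_half_up <- function(x, digits) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# Round half away from zero, used for 1-dp ppm errors.
round_half_away <- function(x, digits) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Parse a molecular formula in Hill notation
#'
#' Accepts plain element-count strings such as `"C19H17O11"` or `"H2O"`.
#' Isotope labels, charges and parentheses are not supported; every element
#' symbol must be one of C, H, N, O, S, P.
#'
#' @param text A single formula string.
#' @return A named integer vector of element counts with class
#'   `"molecular_formula"`; `format()` restores the canonical Hill string
#'   (C first, then H, then remaining elements alphabetically).
#' @examples
#' parse_formula("C19H17O11")
#' format(parse_formula("H2O"))
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  pattern <- "([A-Z][a-z]?)([0-9]*)"
  m <- gregexpr(pattern, text, perl = TRUE)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (sum(nchar(tokens)) != nchar(text)) {
    bad <- sum(nchar(tokens))
    stop("malformed formula '", text, "' near position ", bad + 1L)
  }
  counts <- integer(0)
  pos <- 1L
  for (tok in tokens) {
    sym <- gsub("[0-9]+$", "", tok)
    if (!sym %in% names(ATOMIC_MASS)) {
      stop("unknown element symbol '", sym, "' at position ", pos,
           " in formula '", text, "'")
    }
    n_str <- substring(tok, nchar(sym) + 1L)
    n <- if (nzchar(n_str)) as.integer(n_str) else 1L
    if (is.na(n) || n < 1L) {
      stop("invalid count for element '", sym, "' at position ", pos)
    }
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
    pos <- pos + nchar(tok)
  }
  structure(counts, class = "molecular_formula")
}

#' @export
format.molecular_formula <- function(x, ...) {
  counts <- unclass(x)
  ord <- c(
    intersect(c("C", "H"), names(counts)),
    sort(setdiff(names(counts), c("C", "H")))
  )
  paste0(
    vapply(ord, function(s) {
      paste0(s, if (counts[[s]] > 1L) counts[[s]] else "")
    }, character(1)),
    collapse = ""
  )
}

#' @export
print.molecular_formula <- function(x, ...) {
  cat("<molecular_formula> ", format(x), "\n", sep = "")
  invisible(x)
}

as_formula_counts <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  stopifnot(inherits(formula, "molecular_formula"))
  unclass(formula)
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum of count-weighted monoisotopic atomic masses. For comparison against
#' printed 4-decimal values use `round_mz()` (round half up at 4 dp).
#'
#' @param formula A formula string or [parse_formula()] result.
#' @return Mass in Da (full precision).
#' @examples
#' monoisotopic_mass("C19H17O11")
#' @export
monoisotopic_mass <- function(formula) {
  counts <- as_formula_counts(formula)
  sum(ATOMIC_MASS[names(counts)] * counts)
}

#' Round an m/z value for display at four decimals (half up)
#'
#' @param mz Numeric m/z value(s).
#' @return m/z rounded half up to 4 decimals.
#' @export
round_mz <- function(mz) round_half_up(mz, 4)

#' Theoretical adduct m/z under the reporting convention of HRESIMS tables
#'
#' The formula given is the *ion composition as printed*: for `[M-H]-` the
#' already-deprotonated composition (e.g. C19H17O11 for mangiferin), for
#' `[M+H]+` the protonated composition (e.g. C19H19O11). The convention is
#' asymmetric: negative-mode m/z is the plain formula mass with no
#' electron-mass correction, while positive-mode m/z subtracts one electron
#' mass. `physical = TRUE` switches to electron-corrected arithmetic in both
#' modes (add the electron in negative mode as well).
#'
#' @param formula Ion composition, string or [parse_formula()] result.
#' @param mode `"neg"` for `[M-H]-`, `"pos"` for `[M+H]+`.
#' @param physical Apply the electron-mass correction in both modes.
#' @param digits Decimals for the returned value (half-up); `NULL` for full
#'   precision.
#' @return Theoretical m/z.
#' @examples
#' adduct_mz("C19H17O11", "neg")  # 421.0771
#' adduct_mz("C19H19O11", "pos")  # 423.0922
#' @export
adduct_mz <- function(formula, mode = c("neg", "pos"), physical = FALSE,
                      digits = 4) {
  mode <- match.arg(mode)
  mass <- monoisotopic_mass(formula)
  mz <- switch(mode,
    neg = if (physical) mass + ELECTRON_MASS else mass,
    pos = mass - ELECTRON_MASS
  )
  if (is.null(digits)) mz else round_half_up(mz, digits)
}

#' Relative mass error in parts per million
#'
#' @param observed_mz,calculated_mz Observed and theoretical m/z.
#' @param digits Decimals for the returned ppm (half away from zero);
#'   `NULL` for full precision.
#' @return `(observed - calculated) / calculated * 1e6`.
#' @examples
#' ppm_error(421.0776, 421.0771)  # 1.2
#' @export
ppm_error <- function(observed_mz, calculated_mz, digits = 1) {
  stopifnot(all(calculated_mz > 0))
  ppm <- (observed_mz - calculated_mz) / calculated_mz * 1e6
  if (is.null(digits)) ppm else round_half_away(ppm, digits)
}

#' Batch adduct m/z and ppm error for a compound table
#'
#' @param data A data frame with columns `formula` (ion composition),
#'   `mode` (`"neg"`/`"pos"`) and `observed_mz`.
#' @return The input as a tibble with `calculated_mz` (4 dp) and
#'   `delta_ppm` (1 dp) appended.
#' @export
annotate_ions <- function(data) {
  stopifnot(all(c("formula", "mode", "observed_mz") %in% names(data)))
  data <- tibble::as_tibble(data)
  data$calculated_mz <- purrr::map2_dbl(data$formula, data$mode, adduct_mz)
  data$delta_ppm <- ppm_error(data$observed_mz, data$calculated_mz)
  data
}

#' Fit an external-standard calibration line
#'
#' Ordinary least squares of peak area on standard concentration, the model
#' behind UHPLC-PDA external quantification.
#'
#' @param data Data frame with columns `concentration` (ug/mL) and `area`.
#' @return An object of class `"calibration_fit"` wrapping the `lm` fit,
#'   with `slope`, `intercept`, `r_squared` and the calibrated
#'   concentration `range`. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' std <- tibble::tibble(concentration = c(50, 100, 200, 400),
#'                       area = 178.02 * c(50, 100, 200, 400) - 1001.4)
#' fit_calibration(std)
#' @export
fit_calibration <- function(data) {
  stopifnot(all(c("concentration", "area") %in% names(data)))
  data <- tibble::as_tibble(data)
  if (length(unique(data$concentration)) < 2L) {
    stop("calibration needs at least 2 distinct concentrations")
  }
  fit <- stats::lm(area ~ concentration, data = data)
  co <- stats::coef(fit)
  structure(
    list(
      fit = fit,
      data = data,
      slope = unname(co[["concentration"]]),
      intercept = unname(co[["(Intercept)"]]),
      r_squared = summary(fit)$r.squared,
      range = range(data$concentration)
    ),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(
    "<calibration_fit> y = %.6g x %+.6g  (R^2 = %.4f, range %g-%g ug/mL)\n",
    x$slope, x$intercept, x$r_squared, x$range[1], x$range[2]
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.calibration_fit <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = co[, "Estimate"],
    std.error = co[, "Std. Error"]
  )
}

#' @export
glance.calibration_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    sigma = summary(x$fit)$sigma,
    nobs = nrow(x$data),
    conc.min = x$range[1],
    conc.max = x$range[2]
  )
}

#' Quantify an analyte from peak area via a calibration line
#'
#' Inverts the calibration (`conc = (area - intercept) / slope`) and
#' expresses the result as percent weight-by-weight of the sample.
#'
#' @param area Observed peak area.
#' @param curve A [fit_calibration()] result, or a list with `slope`,
#'   `intercept` and optionally `range` elements.
#' @param sample_conc Sample concentration in mg/mL as injected.
#' @param dilution Dilution factor applied to the sample (default 1).
#' @return A tibble with `analyte_conc` (ug/mL in the injected solution),
#'   `pct_ww` (% w/w of the sample) and `extrapolated` (TRUE when the area
#'   falls outside the calibrated concentration range).
#' @examples
#' std <- tibble::tibble(concentration = c(50, 100, 200, 400),
#'                       area = 178.02 * c(50, 100, 200, 400) - 1001.4)
#' quantify_analyte(34602.6, fit_calibration(std), sample_conc = 1)
#' @export
quantify_analyte <- function(area, curve, sample_conc, dilution = 1) {
  stopifnot(is.numeric(area), sample_conc > 0, dilution > 0)
  slope <- curve$slope
  intercept <- curve$intercept
  if (is.null(slope) || slope == 0) stop("calibration slope must be nonzero")
  conc <- (area - intercept) / slope  # ug/mL
  extrapolated <- if (!is.null(curve$range)) {
    conc < curve$range[1] | conc > curve$range[2]
  } else {
    rep(NA, length(conc))
  }
  # sample_conc is mg/mL = 1000 ug/mL of total material
  pct <- conc / (sample_conc * 1000 * dilution) * 100
  tibble::tibble(
    area = area,
    analyte_conc = conc,
    pct_ww = pct,
    extrapolated = extrapolated
  )
}
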