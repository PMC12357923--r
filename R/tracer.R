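#' Tissue tracer uptake normalized to weight
#'
#' Scintillation counts of phosphorylated 2-deoxyglucose trapped in a
#' tissue, divided by the initial tissue weight.
#'
#' @param tissue_dpm Decays per minute counted in the tissue lysate.
#' @param tissue_weight Initial tissue weight in mg.
#' @return DPM per mg tissue.
#' @examples
#' tissue_uptake(1000, 100)  # 10 DPM/mg
#' @export
tissue_uptake <- function(tissue_dpm, tissue_weight) {
  stopifnot(is.numeric(tissue_dpm), all(tissue_dpm >= 0))
  if (any(tissue_weight <= 0)) stop("tissue weight must be positive")
  tissue_dpm / tissue_weight
}

#' Detect the steady-state window of a euglycemic clamp trace
#'
#' Scans backwards from the end of the trace for the latest contiguous
#' window spanning at least `window_min` minutes in which the glucose
#' infusion rate (GIR) is stable (coefficient of variation at most
#' `gir_cv_max`) and mean blood glucose sits within `glucose_tol` of the
#' clamp target. This formalizes the bench rule of recording steady state
#' once GIR holds with only minor deviations for 15-20 min at target
#' glycemia.
#'
#' @param trace Data frame with columns `time` (min, strictly increasing),
#'   `glucose` (mM) and `gir` (mg/kg/min). The clamp target is taken from
#'   a `target_glucose` column or attribute if present, else from the
#'   `target_glucose` argument.
#' @param window_min Minimum window span in minutes (default 15).
#' @param gir_cv_max Maximum allowed GIR coefficient of variation within
#'   the window (default 0.05).
#' @param glucose_tol Allowed deviation of mean window glucose from target,
#'   mM (default 0.5).
#' @param target_glucose Clamp target in mM (default 6), used when the
#'   trace carries none.
#' @return A one-row tibble with `t_start`, `t_end`, `gir_ss` (mean GIR
#'   over the window) and `steady` (logical). When no window qualifies the
#'   times and `gir_ss` are `NA` and `steady` is `FALSE`.
#' @export
detect_steady_state <- function(trace, window_min = 15, gir_cv_max = 0.05,
                                glucose_tol = 0.5, target_glucose = 6) {
  stopifnot(all(c("time", "glucose", "gir") %in% names(trace)))
  if (nrow(trace) == 0) stop("empty clamp trace")
  if (is.unsorted(trace$time, strictly = TRUE)) {
    stop("trace times must be strictly increasing")
  }
  if (!is.null(trace[["target_glucose"]])) {
    target_glucose <- trace[["target_glucose"]][1]
  }
  span <- max(trace$time) - min(trace$time)
  if (span < window_min) stop("trace spans less than the minimum window")
  time <- trace$time
  n <- nrow(trace)
  no_ss <- tibble::tibble(t_start = NA_real_, t_end = NA_real_,
                          gir_ss = NA_real_, steady = FALSE)
  for (j in n:1) {
    # latest start index giving a span >= window_min ending at time[j]
    i <- max(which(time <= time[j] - window_min), 0L)
    if (i == 0L) next
    idx <- i:j
    g <- trace$gir[idx]
    m <- mean(g)
    cv <- if (m == 0) {
      if (stats::sd(g) == 0) 0 else Inf
    } else {
      stats::sd(g) / m
    }
    if (cv <= gir_cv_max &&
        abs(mean(trace$glucose[idx]) - target_glucose) <= glucose_tol) {
      return(tibble::tibble(t_start = time[i], t_end = time[j],
                            gir_ss = m, steady = TRUE))
    }
  }
  no_ss
}

#' Whole-body glucose turnover from continuous tracer infusion
#'
#' At isotopic steady state the rate of glucose appearance equals the
#' tracer infusion rate divided by the plasma glucose specific activity.
#' With no exogenous glucose infusion this Ra is the endogenous glucose
#' production; under a clamp, Rd = Ra.
#'
#' @param tracer_infusion_rate Tracer infusion rate, DPM per min per kg.
#' @param plasma_specific_activity Plasma specific activity, DPM per mg
#'   glucose.
#' @return Ra in mg/kg/min.
#' @examples
#' glucose_turnover(1000, 25)  # 40 mg/kg/min
#' @export
glucose_turnover <- function(tracer_infusion_rate, plasma_specific_activity) {
  stopifnot(all(tracer_infusion_rate >= 0))
  if (any(plasma_specific_activity <= 0)) {
    stop("plasma specific activity must be positive")
  }
  tracer_infusion_rate / plasma_specific_activity
}

#' Endogenous glucose production
#'
#' `EGP = Ra - GIR`. At basal (no glucose infusion) EGP equals Ra; under a
#' hyperinsulinemic clamp it quantifies residual hepatic output. Negative
#' values are returned as-is with a warning, since they flag data problems
#' (e.g. tracer underestimation) that should stay visible.
#'
#' @param ra Rate of glucose appearance, mg/kg/min.
#' @param gir Exogenous glucose infusion rate, mg/kg/min.
#' @return EGP in mg/kg/min.
#' @examples
#' egp(40, 36.3)  # 3.7
#' @export
egp <- function(ra, gir) {
  stopifnot(all(is.finite(ra)), all(is.finite(gir)))
  out <- ra - gir
  if (any(out < 0)) warning("negative EGP computed; check Ra and GIR inputs")
  out
}

#' Tissue glucose uptake rate from a 2-deoxyglucose bolus
#'
#' Combines tissue counts of phosphorylated 2-DG with the time-integral of
#' plasma tracer specific activity over the sampling period:
#' `Rg = tissue_dpm_per_g / integral(SA(t) dt)` with
#' `SA(t) = plasma_dpm(t) / plasma_glucose(t)`. The integral is evaluated
#' by the trapezoid rule on the observed sample grid (typically samples at
#' 0, 2, 15, 25 and 35 min after the bolus); no curve is fitted. No
#' lumped-constant correction is applied unless one is supplied.
#'
#' @param tissue_dpm_per_g Phospho-2-DG counts per g tissue.
#' @param plasma Data frame with columns `time` (min, strictly increasing,
#'   at least 3 rows) and `plasma_dpm` (DPM per volume).
#' @param plasma_glucose Plasma glucose, mM (or any concentration unit;
#'   Rg comes out per that unit). Scalar or one value per sample.
#' @param lumped_constant Optional divisor correcting for the kinetic
#'   difference between 2-DG and glucose (default 1, i.e. none).
#' @return Rg, glucose (concentration unit) per g per min.
#' @examples
#' pl <- tibble::tibble(time = c(0, 10, 20), plasma_dpm = c(100, 100, 100))
#' rg_from_bolus(2000, pl, plasma_glucose = 5)  # 2000 / (20 * 20) = 5
#' @export
rg_from_bolus <- function(tissue_dpm_per_g, plasma, plasma_glucose,
                          lumped_constant = 1) {
  stopifnot(all(c("time", "plasma_dpm") %in% names(plasma)),
            all(tissue_dpm_per_g >= 0), all(plasma_glucose > 0),
            lumped_constant > 0)
  if (nrow(plasma) < 3) stop("need at least 3 plasma samples")
  if (is.unsorted(plasma$time, strictly = TRUE)) {
    stop("plasma sample times must be strictly increasing")
  }
  sa <- plasma$plasma_dpm / plasma_glucose
  integral <- pracma::trapz(plasma$time, sa)
  if (integral <= 0) stop("non-positive specific-activity integral")
  tissue_dpm_per_g / integral / lumped_constant
}

#' Glycolytic flux from tritiated-water release
#'
#' Background-corrected counts divided by the medium glucose specific
#' activity, incubation time and protein content. Background exceeding the
#' sample is clipped to zero (pure counting noise).
#'
#' @param sample_dpm Counts from the sample well.
#' @param background_dpm Counts from empty (background) wells.
#' @param medium_specific_activity DPM per pmol glucose in the labelling
#'   medium.
#' @param hours Incubation time in hours.
#' @param protein_mg Protein content of the well in mg.
#' @return Flux in pmol glucose per hour per mg protein.
#' @examples
#' glycolytic_flux(1500, 500, 2, 2, 0.1)  # 2500
#' @export
glycolytic_flux <- function(sample_dpm, background_dpm,
                            medium_specific_activity, hours, protein_mg) {
  stopifnot(all(sample_dpm >= 0), all(background_dpm >= 0))
  if (any(medium_specific_activity <= 0)) {
    stop("medium specific activity must be positive")
  }
  if (any(hours <= 0) || any(protein_mg <= 0)) {
    stop("hours and protein must be positive")
  }
  pmax(sample_dpm - background_dpm, 0) /
    medium_specific_activity / hours / protein_mg
}

#' Glycolysis metrics from an extracellular-acidification stress test
#'
#' A glycolytic stress test injects glucose, then oligomycin, then
#' 2-deoxyglucose into the assay medium, with a block of ECAR measurements
#' after each injection. From the normalized ECAR series:
#' glycolysis = max(post-glucose) - last(pre-glucose baseline);
#' glycolytic capacity = max(post-oligomycin) - last(baseline);
#' glycolytic reserve = capacity - glycolysis.
#'
#' @param data Data frame with columns `ecar` and `phase`, where `phase`
#'   takes values `"basal"`, `"glucose"`, `"oligomycin"` (and optionally
#'   `"2dg"`), in measurement order.
#' @return A one-row tibble with `glycolysis`, `glycolytic_capacity` and
#'   `glycolytic_reserve`, in the units of `ecar`.
#' @examples
#' ecar_metrics(tibble::tibble(
#'   ecar = c(8, 9, 10, 28, 30, 29, 44, 45, 43, 12, 11, 10),
#'   phase = rep(c("basal", "glucose", "oligomycin", "2dg"), each = 3)
#' ))
#' @export
ecar_metrics <- function(data) {
  stopifnot(all(c("ecar", "phase") %in% names(data)))
  need <- c("basal", "glucose", "oligomycin")
  missing <- setdiff(need, unique(data$phase))
  if (length(missing) > 0) {
    stop("missing measurement phase(s): ", paste(missing, collapse = ", "))
  }
  baseline <- dplyr::last(data$ecar[data$phase == "basal"])
  glycolysis <- max(data$ecar[data$phase == "glucose"]) - baseline
  capacity <- max(data$ecar[data$phase == "oligomycin"]) - baseline
  tibble::tibble(
    glycolysis = glycolysis,
    glycolytic_capacity = capacity,
    glycolytic_reserve = capacity - glycolysis
  )
}

#' Baseline-referenced area of the curve for tolerance tests
#'
#' Signed trapezoidal integral of the excursion from each subject's own
#' baseline, `integral of (value(t) - baseline) dt`. Positive for glucose
#' excursions above baseline in a glucose tolerance test, negative for the
#' drop in an insulin tolerance test; the sign is retained, and adding a
#' constant to both values and baseline leaves the result unchanged.
#'
#' @param times Sampling times in min, strictly increasing, at least 2.
#' @param values Measured values (e.g. blood glucose, mM) at `times`.
#' @param baseline Reference value; defaults to the value at the first
#'   time point.
#' @return Signed area in value-units x min.
#' @examples
#' aoc(c(0, 60, 120), c(5, 10, 5))  # 300
#' @export
aoc <- function(times, values, baseline = values[1]) {
  stopifnot(length(times) >= 2, length(times) == length(values),
            all(is.finite(times)), all(is.finite(values)),
            is.finite(baseline))
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing")
  }
  pracma::trapz(times, values - baseline)
}
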