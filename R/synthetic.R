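# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Specification for a synthetic two-channel plate image
#'
#' Describes a field of cells rendered as a nuclear-stain channel plus a
#' target-protein channel. Each cell is a filled nuclear disk surrounded by
#' a cytosolic annulus; a known fraction of cells carries nuclear target
#' signal above the cytosolic level (translocated), the rest at parity.
#'
#' @param width,height Canvas size in pixels.
#' @param n_cells Number of cells to place (nuclei may not overlap).
#' @param nucleus_radius_range Two integers >= 3 px, inclusive radius range.
#' @param translocated_fraction Fraction of cells with nuclear-shifted
#'   target signal, in `[0, 1]`. Exactly `round(fraction * n_cells)` cells
#'   are flagged.
#' @param nuclear_intensity_pos,nuclear_intensity_neg Target-channel
#'   intensity added over background inside translocated / non-translocated
#'   nuclei (arbitrary fluorescence units).
#' @param cytosol_intensity Target-channel intensity of the cytosolic
#'   annulus.
#' @param cytosol_width Annulus width in px beyond the nuclear radius.
#' @param nucleus_stain_intensity Nuclei-channel intensity of nuclear disks.
#' @param background_level Intensity added everywhere in both channels.
#' @param noise_sd Gaussian noise SD added to both channels (0 = exact
#'   deterministic render).
#' @param seed Integer RNG seed; fixed seed gives bit-identical output.
#' @return A validated list of class `"image_spec"`.
#' @export
image_spec <- function(width = 600, height = 600, n_cells = 200,
                       nucleus_radius_range = c(6, 9),
                       translocated_fraction = 0.5,
                       nuclear_intensity_pos = 5000,
                       nuclear_intensity_neg = 1000,
                       cytosol_intensity = 1000,
                       cytosol_width = 6,
                       nucleus_stain_intensity = 4000,
                       background_level = 100,
                       noise_sd = 30,
                       seed = 1L) {
  stopifnot(
    width >= 16, height >= 16,
    n_cells >= 0,
    length(nucleus_radius_range) == 2,
    nucleus_radius_range[1] >= 3,
    nucleus_radius_range[2] >= nucleus_radius_range[1],
    translocated_fraction >= 0, translocated_fraction <= 1,
    nuclear_intensity_pos >= 0, nuclear_intensity_neg >= 0,
    cytosol_intensity >= 0, cytosol_width >= 1,
    nucleus_stain_intensity > 0, background_level >= 0, noise_sd >= 0
  )
  structure(as.list(environment()), class = "image_spec")
}

disk_offsets <- function(r) {
  d <- seq(-r, r)
  g <- expand.grid(dy = d, dx = d)
  g[g$dx^2 + g$dy^2 <= r^2, , drop = FALSE]
}

paint <- function(img, cx, cy, offsets, value) {
  x <- cx + offsets$dx
  y <- cy + offsets$dy
  ok <- x >= 1 & x <= ncol(img) & y >= 1 & y <= nrow(img)
  img[cbind(y[ok], x[ok])] <- value
  img
}

#' Render a synthetic two-channel cell image with ground truth
#'
#' Places `n_cells` non-overlapping nuclear disks by rejection sampling,
#' assigns exactly `round(translocated_fraction * n_cells)` of them as
#' translocated, and renders (1) a nuclei channel of nuclear disks over
#' background and (2) a target channel with a cytosolic annulus per cell
#' plus nuclear signal at the positive or negative level according to the
#' truth flag. Gaussian noise of the specified SD is then added to both
#' channels. Output is bit-identical for a fixed seed.
#'
#' @param spec An [image_spec()].
#' @param max_attempts Rejection-sampling cap per image before placement is
#'   declared infeasible.
#' @return A list of class `"cell_image_sim"` with elements `nuclei` and
#'   `target` (numeric matrices, rows = y) and `truth`, a tibble with one
#'   row per cell: `cell`, `x`, `y`, `radius`, `translocated`.
#' @examples
#' sim <- simulate_cell_image(image_spec(n_cells = 5, seed = 3))
#' sim$truth
#' @export
simulate_cell_image <- function(spec, max_attempts = 5000 * max(spec$n_cells, 1)) {
  stopifnot(inherits(spec, "image_spec"))
  with_seed(spec$seed, {
    n <- spec$n_cells
    margin <- spec$nucleus_radius_range[2] + spec$cytosol_width + 2
    if (n > 0 && (spec$width <= 2 * margin || spec$height <= 2 * margin)) {
      stop("canvas too small for the requested cell geometry")
    }
    radii <- if (n > 0) {
      sample(seq(spec$nucleus_radius_range[1], spec$nucleus_radius_range[2]),
             n, replace = TRUE)
    } else {
      integer(0)
    }
    xs <- ys <- numeric(0)
    attempts <- 0L
    sep <- 6  # extra px between nuclear borders so perinuclear rings stay clean
    for (i in seq_len(n)) {
      repeat {
        attempts <- attempts + 1L
        if (attempts > max_attempts) {
          stop("infeasible packing: could not place ", n, " cells on a ",
               spec$width, "x", spec$height, " canvas")
        }
        cx <- stats::runif(1, margin, spec$width - margin)
        cy <- stats::runif(1, margin, spec$height - margin)
        if (i == 1 ||
            all(sqrt((xs - cx)^2 + (ys - cy)^2) > radii[seq_len(i - 1)] + radii[i] + sep)) {
          xs <- c(xs, cx); ys <- c(ys, cy)
          break
        }
      }
    }
    xs <- round(xs); ys <- round(ys)
    k <- round(spec$translocated_fraction * n)
    translocated <- c(rep(TRUE, k), rep(FALSE, n - k))
    ord <- if (n > 0) sample.int(n) else integer(0)

    nuclei <- matrix(spec$background_level, spec$height, spec$width)
    target <- matrix(spec$background_level, spec$height, spec$width)
    for (i in seq_len(n)) {
      cyto <- disk_offsets(radii[i] + spec$cytosol_width)
      nuc <- disk_offsets(radii[i])
      target <- paint(target, xs[i], ys[i], cyto,
                      spec$background_level + spec$cytosol_intensity)
      nuc_level <- if (translocated[i]) spec$nuclear_intensity_pos else
        spec$nuclear_intensity_neg
      target <- paint(target, xs[i], ys[i], nuc,
                      spec$background_level + nuc_level)
      nuclei <- paint(nuclei, xs[i], ys[i], nuc,
                      spec$background_level + spec$nucleus_stain_intensity)
    }
    if (spec$noise_sd > 0) {
      nuclei <- nuclei + matrix(stats::rnorm(length(nuclei), 0, spec$noise_sd),
                                nrow(nuclei))
      target <- target + matrix(stats::rnorm(length(target), 0, spec$noise_sd),
                                nrow(target))
    }
    truth <- tibble::tibble(
      cell = seq_len(n),
      x = xs[ord],
      y = ys[ord],
      radius = radii[ord],
      translocated = translocated[ord]
    )
    structure(list(nuclei = nuclei, target = target, truth = truth),
              class = "cell_image_sim")
  })
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' Write a simulated image pair as 16-bit grayscale TIFFs
#'
#' One single-channel file per channel, intensities rounded to integers and
#' stored on the 16-bit scale, plus the truth table as CSV.
#'
#' @param sim A [simulate_cell_image()] result.
#' @param dir Output directory (created if needed).
#' @param id Basename stem for the three files.
#' @return Invisibly, a named character vector of the paths written.
#' @export
write_image_pair <- function(sim, dir, id = "image") {
  stopifnot(inherits(sim, "cell_image_sim"))
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required to write TIFF output")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    nuclei = file.path(dir, paste0(id, "_nuclei.tif")),
    target = file.path(dir, paste0(id, "_target.tif")),
    truth = file.path(dir, paste0(id, "_truth.csv"))
  )
  to16 <- function(m) pmin(pmax(round(m), 0), 65535) / 65535
  tiff::writeTIFF(to16(sim$nuclei), paths[["nuclei"]], bits.per.sample = 16)
  tiff::writeTIFF(to16(sim$target), paths[["target"]], bits.per.sample = 16)
  utils::write.csv(sim$truth, paths[["truth"]], row.names = FALSE)
  invisible(paths)
}

#' Specification for a synthetic euglycemic clamp trace
#'
#' @param basal_duration,clamp_duration Minutes of basal (no glucose
#'   infusion) and clamped recording; both may be generous since steady
#'   state is detected, not assumed.
#' @param target_glucose Clamp target, mM (6 mM by convention here).
#' @param basal_glucose Pre-clamp blood glucose, mM.
#' @param plateau_gir Asymptotic glucose infusion rate, mg/kg/min.
#' @param approach_rate Exponential approach rate to the plateau, 1/min;
#'   `Inf` gives a constant GIR at plateau from clamp start.
#' @param sampling_interval Minutes between samples.
#' @param glucose_noise_sd,gir_noise_sd Gaussian noise SDs (mM, mg/kg/min).
#' @param seed Integer RNG seed.
#' @return A validated list of class `"clamp_spec"`.
#' @export
clamp_spec <- function(basal_duration = 0, clamp_duration = 120,
                       target_glucose = 6, basal_glucose = 8.5,
                       plateau_gir = 36.3, approach_rate = 0.08,
                       sampling_interval = 2.5,
                       glucose_noise_sd = 0.15, gir_noise_sd = 0.8,
                       seed = 1L) {
  stopifnot(basal_duration >= 0, clamp_duration > 0, target_glucose > 0,
            basal_glucose > 0, plateau_gir >= 0, approach_rate > 0,
            sampling_interval > 0, glucose_noise_sd >= 0, gir_noise_sd >= 0)
  structure(as.list(environment()), class = "clamp_spec")
}

#' Simulate a hyperinsulinemic-euglycemic clamp trace
#'
#' GIR rises as an exponential approach to the plateau once the clamp
#' starts; blood glucose relaxes from the basal level to the target at the
#' same rate and then fluctuates around it. With zero noise the trace is
#' exactly its deterministic model.
#'
#' @param spec A [clamp_spec()].
#' @return A tibble with columns `time` (min), `glucose` (mM), `gir`
#'   (mg/kg/min) and `target_glucose`.
#' @examples
#' tr <- simulate_clamp_trace(clamp_spec(glucose_noise_sd = 0, gir_noise_sd = 0))
#' tail(tr)
#' @export
simulate_clamp_trace <- function(spec) {
  stopifnot(inherits(spec, "clamp_spec"))
  with_seed(spec$seed, {
    total <- spec$basal_duration + spec$clamp_duration
    time <- seq(0, total, by = spec$sampling_interval)
    tc <- pmax(time - spec$basal_duration, 0)  # time since clamp start
    on_clamp <- time >= spec$basal_duration
    rise <- if (is.infinite(spec$approach_rate)) {
      as.numeric(on_clamp)
    } else {
      ifelse(on_clamp, 1 - exp(-spec$approach_rate * tc), 0)
    }
    gir <- spec$plateau_gir * rise
    glucose <- spec$target_glucose +
      (spec$basal_glucose - spec$target_glucose) * (1 - rise)
    if (spec$gir_noise_sd > 0) {
      gir <- pmax(gir + stats::rnorm(length(gir), 0, spec$gir_noise_sd), 0)
    }
    if (spec$glucose_noise_sd > 0) {
      glucose <- glucose + stats::rnorm(length(glucose), 0, spec$glucose_noise_sd)
    }
    tibble::tibble(time = time, glucose = glucose, gir = gir,
                   target_glucose = spec$target_glucose)
  })
}

#' Specification for a synthetic 2-deoxyglucose bolus experiment
#'
#' Plasma tracer decays biexponentially after the bolus,
#' `A1 exp(-k1 t) + A2 exp(-k2 t)`; each tissue accumulates phospho-2-DG at
#' a known true uptake rate. Defaults emulate a fast mixing phase on top of
#' slow clearance with plasma sampled at 0, 2, 15, 25 and 35 min.
#'
#' @param a1,k1 Fast-phase amplitude (DPM per mL) and rate (1/min).
#' @param a2,k2 Slow-phase amplitude and rate. `k = 0` is allowed for a
#'   constant component.
#' @param sample_times Plasma sampling times, min, strictly increasing
#'   from 0.
#' @param true_rg Named numeric vector of true tissue uptake rates
#'   (glucose-concentration units per g per min).
#' @param plasma_glucose Plasma glucose, mM, assumed constant (clamped).
#' @param plasma_noise_frac Multiplicative lognormal-free Gaussian noise
#'   fraction on observed plasma DPM (0 = exact).
#' @param grid_dt Fine-grid step (min) used for the ground-truth
#'   specific-activity integral.
#' @param seed Integer RNG seed.
#' @return A validated list of class `"tracer_spec"`.
#' @export
tracer_spec <- function(a1 = 2e5, k1 = 0.2, a2 = 6e5, k2 = 0.03,
                        sample_times = c(0, 2, 15, 25, 35),
                        true_rg = c(iWAT = 0.8, eWAT = 0.4, soleus = 2.5,
                                    gastrocnemius = 1.8, iBAT = 6, liver = 1),
                        plasma_glucose = 6,
                        plasma_noise_frac = 0.02,
                        grid_dt = 0.005,
                        seed = 1L) {
  stopifnot(a1 >= 0, a2 >= 0, k1 >= 0, k2 >= 0, a1 + a2 > 0,
            length(sample_times) >= 3, sample_times[1] == 0,
            !is.unsorted(sample_times, strictly = TRUE),
            all(true_rg >= 0), plasma_glucose > 0,
            plasma_noise_frac >= 0, grid_dt > 0)
  structure(as.list(environment()), class = "tracer_spec")
}

biexp <- function(t, a1, k1, a2, k2) a1 * exp(-k1 * t) + a2 * exp(-k2 * t)

#' Simulate plasma decay and tissue accumulation after a 2-DG bolus
#'
#' Plasma DPM at the sampling times follows the biexponential model (with
#' optional multiplicative observation noise); each tissue's phospho-2-DG
#' count equals `true_rg` times the specific-activity integral of the
#' *noiseless* plasma curve evaluated by trapezoid on a fine grid, so that
#' a downstream uptake estimator can be tested for recovery of the truth.
#'
#' @param spec A [tracer_spec()].
#' @return A list of class `"tracer_sim"` with `plasma` (tibble: `time`,
#'   `plasma_dpm`, `plasma_glucose`), `tissues` (tibble: `tissue`,
#'   `true_rg`, `tissue_dpm_per_g`) and `sa_integral` (the fine-grid
#'   integral of plasma specific activity, DPM/mM-glucose x min).
#' @examples
#' sim <- simulate_tracer_curve(tracer_spec(seed = 2))
#' sim$tissues
#' @export
simulate_tracer_curve <- function(spec) {
  stopifnot(inherits(spec, "tracer_spec"))
  with_seed(spec$seed, {
    t_end <- max(spec$sample_times)
    grid <- seq(0, t_end, by = spec$grid_dt)
    sa_grid <- biexp(grid, spec$a1, spec$k1, spec$a2, spec$k2) /
      spec$plasma_glucose
    sa_integral <- pracma::trapz(grid, sa_grid)
    dpm <- biexp(spec$sample_times, spec$a1, spec$k1, spec$a2, spec$k2)
    if (spec$plasma_noise_frac > 0) {
      dpm <- dpm * (1 + stats::rnorm(length(dpm), 0, spec$plasma_noise_frac))
      dpm <- pmax(dpm, 0)
    }
    plasma <- tibble::tibble(
      time = spec$sample_times,
      plasma_dpm = dpm,
      plasma_glucose = spec$plasma_glucose
    )
    tissues <- tibble::tibble(
      tissue = names(spec$true_rg) %||% paste0("tissue", seq_along(spec$true_rg)),
      true_rg = unname(spec$true_rg),
      tissue_dpm_per_g = unname(spec$true_rg) * sa_integral
    )
    structure(list(plasma = plasma, tissues = tissues,
                   sa_integral = sa_integral),
              class = "tracer_sim")
  })
}
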