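test_that("tissue uptake is count per weight with guarded inputs", {
  expect_equal(tissue_uptake(1000, 100), 10)
  expect_equal(tissue_uptake(0, 50), 0)
  set.seed(3)
  dpm <- runif(20, 0, 5e4); wt <- runif(20, 20, 300)
  expect_equal(tissue_uptake(dpm, wt), dpm / wt, tolerance = 1e-15)
  expect_error(tissue_uptake(100, 0), "positive")
})

test_that("steady-state detection finds plateaus and rejects ramps", {
  # constant GIR at target glucose: full-trace window, exact mean
  flat <- tibble::tibble(time = seq(0, 60, 2.5), glucose = 6,
                         gir = 36.3, target_glucose = 6)
  ss <- detect_steady_state(flat)
  expect_true(ss$steady)
  expect_equal(ss$gir_ss, 36.3)
  expect_equal(ss$t_end, 60)
  # linear ramp violates any tight CV bound
  ramp <- tibble::tibble(time = seq(0, 60, 2.5),
                         glucose = 6,
                         gir = seq(0, 60, 2.5), target_glucose = 6)
  expect_false(detect_steady_state(ramp, gir_cv_max = 0.01)$steady)
  # off-target glucose disqualifies an otherwise flat window
  offtarget <- tibble::tibble(time = seq(0, 60, 2.5), glucose = 8,
                              gir = 36.3, target_glucose = 6)
  expect_false(detect_steady_state(offtarget)$steady)
  expect_error(detect_steady_state(flat[0, ]), "empty")
  expect_error(detect_steady_state(flat[1:3, ]), "spans less")
})

test_that("noiseless generator plateau returns the plateau value exactly", {
  tr <- simulate_clamp_trace(clamp_spec(plateau_gir = 36.3,
                                        approach_rate = Inf,
                                        glucose_noise_sd = 0,
                                        gir_noise_sd = 0))
  ss <- detect_steady_state(tr)
  expect_true(ss$steady)
  expect_identical(ss$gir_ss, 36.3)
})

test_that("noisy plateau mean is within the standard-error bound", {
  spec <- clamp_spec(plateau_gir = 36.3, approach_rate = 0.3,
                     gir_noise_sd = 0.8, seed = 21)
  tr <- simulate_clamp_trace(spec)
  last20 <- tr[tr$time >= max(tr$time) - 20, ]
  se_bound <- 2 * spec$gir_noise_sd / sqrt(nrow(last20))
  # approach term is negligible after 100 min at rate 0.3/min
  expect_lt(abs(mean(last20$gir) - 36.3), se_bound + 1e-6)
})

test_that("glucose turnover and EGP identities hold exactly", {
  expect_equal(glucose_turnover(1000, 25), 40)
  expect_equal(glucose_turnover(1000, 50), 20)  # doubling SA halves Ra
  expect_error(glucose_turnover(1000, 0), "positive")
  expect_equal(egp(40, 36.3), 3.7)
  expect_identical(egp(33, 0), 33)       # basal identity: EGP = Ra
  expect_equal(egp(30, 30), 0)
  expect_warning(neg <- egp(30, 35), "negative EGP")
  expect_equal(neg, -5)
  # clamp identity: EGP + GIR recomposes Rd exactly
  rd <- 43.0; gir <- 36.3
  expect_identical(egp(rd, gir) + gir, rd)
})

test_that("bolus Rg matches the closed form for constant specific activity", {
  pl <- tibble::tibble(time = c(0, 10, 20, 35), plasma_dpm = 600)
  # SA = 600/6 = 100 DPM/mM over 35 min -> integral 3500
  expect_equal(rg_from_bolus(7000, pl, plasma_glucose = 6), 2)
  expect_equal(rg_from_bolus(0, pl, plasma_glucose = 6), 0)
  expect_error(rg_from_bolus(100, pl[1:2, ], 6), "at least 3")
  expect_error(rg_from_bolus(100, tibble::tibble(time = c(0, 5, 5),
                                                 plasma_dpm = 1),
                             6), "strictly increasing")
})

test_that("generator fine-grid integral agrees with the analytic biexponential", {
  spec <- tracer_spec(plasma_noise_frac = 0, seed = 5)
  sim <- simulate_tracer_curve(spec)
  analytic <- oracle_biexp_integral(spec$a1, spec$k1, spec$a2, spec$k2,
                                    max(spec$sample_times)) / spec$plasma_glucose
  expect_equal(sim$sa_integral, analytic, tolerance = 1e-3)
  # degenerate constant-plasma case: tissue count = rg * SA * T
  const <- tracer_spec(a1 = 500, k1 = 0, a2 = 0, k2 = 0.1,
                       true_rg = c(t1 = 2), plasma_glucose = 5,
                       plasma_noise_frac = 0)
  csim <- simulate_tracer_curve(const)
  expect_equal(csim$tissues$tissue_dpm_per_g, 2 * (500 / 5) * 35,
               tolerance = 1e-9)
  # zero uptake accumulates nothing
  z <- simulate_tracer_curve(tracer_spec(true_rg = c(t1 = 0),
                                         plasma_noise_frac = 0))
  expect_identical(z$tissues$tissue_dpm_per_g, 0)
})

test_that("Rg recovery stays within 5% across seeded biexponential fixtures", {
  errs <- vapply(1:50, function(s) {
    sim <- simulate_tracer_curve(tracer_spec(seed = s))
    rg <- rg_from_bolus(sim$tissues$tissue_dpm_per_g[1], sim$plasma,
                        sim$plasma$plasma_glucose[1])
    abs(rg - sim$tissues$true_rg[1]) / sim$tissues$true_rg[1]
  }, numeric(1))
  expect_lte(stats::median(errs), 0.05)
})

test_that("glycolytic flux is background-corrected and normalized", {
  expect_equal(glycolytic_flux(500, 500, 2, 2, 0.1), 0)
  expect_equal(glycolytic_flux(1500, 500, 2, 2, 0.1), 2500)
  # doubling protein halves flux
  expect_equal(glycolytic_flux(1500, 500, 2, 2, 0.2), 1250)
  # background above sample clips to zero, not negative
  expect_equal(glycolytic_flux(400, 500, 2, 2, 0.1), 0)
  expect_error(glycolytic_flux(1, 0, 0, 2, 1), "positive")
})

test_that("ECAR stress-test metrics follow their definitions", {
  flat <- tibble::tibble(ecar = rep(10, 12),
                         phase = rep(c("basal", "glucose", "oligomycin", "2dg"),
                                     each = 3))
  expect_equal(unlist(ecar_metrics(flat)), c(glycolysis = 0,
                                             glycolytic_capacity = 0,
                                             glycolytic_reserve = 0))
  dat <- tibble::tibble(
    ecar = c(9, 9.5, 10, 28, 30, 29, 44, 45, 43, 12, 11, 10),
    phase = rep(c("basal", "glucose", "oligomycin", "2dg"), each = 3)
  )
  m <- ecar_metrics(dat)
  expect_equal(m$glycolysis, 20)
  expect_equal(m$glycolytic_capacity, 35)
  expect_equal(m$glycolytic_reserve, 15)
  expect_equal(m$glycolytic_reserve, m$glycolytic_capacity - m$glycolysis)
  expect_error(ecar_metrics(dat[dat$phase != "oligomycin", ]), "missing")
})

test_that("AOC is the signed baseline-referenced trapezoid", {
  expect_equal(aoc(c(0, 30, 60), c(7, 7, 7)), 0)
  expect_equal(aoc(c(0, 60, 120), c(5, 10, 5)), 300)
  # ITT-style drop gives a negative area
  expect_lt(aoc(c(0, 30, 60), c(9, 5, 6)), 0)
  # invariance to uniform shifts and linearity in values
  t <- c(0, 15, 30, 60, 90, 120)
  v <- c(6, 11, 9, 8, 7, 6.5)
  expect_equal(aoc(t, v + 3, baseline = v[1] + 3), aoc(t, v),
               tolerance = 1e-12)
  expect_equal(aoc(t, 2 * v, baseline = 2 * v[1]), 2 * aoc(t, v),
               tolerance = 1e-12)
  expect_error(aoc(c(0, 60, 30), c(1, 2, 3)), "increasing")
})
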