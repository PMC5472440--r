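make_trace <- function(f, t = seq(0, 100, by = 1), kind = "sliding_fret")
  assay_trace(t, f(t), kind)

test_that("initial_rate recovers slopes of linear and constant traces", {
  tr <- make_trace(function(t) 500 - 3.2 * t)
  r <- initial_rate(tr)
  expect_equal(r$rate, 3.2, tolerance = 1e-10)
  expect_equal(r$direction, -1)
  r2 <- initial_rate(make_trace(function(t) rep(7, length(t))))
  expect_equal(r2$rate, 0)
})

test_that("initial_rate of an early exponential window matches the derivative", {
  # closed form: d/dt A exp(-t/tau) at t=0 is -A/tau
  tau <- 50; A <- 1000
  tr <- make_trace(function(t) A * exp(-t / tau), t = seq(0, 250, by = 0.5))
  r <- initial_rate(tr, window = c(0, 0.05 * tau))
  expect_equal(r$rate, A / tau, tolerance = 0.05)
  expect_equal(r$direction, -1)
})

test_that("initial_rate validates its window", {
  tr <- make_trace(function(t) t)
  expect_error(initial_rate(tr, window = c(90, 200)), "outside")
  expect_error(initial_rate(tr, window = 1.5), "fractional window")
})

test_that("nadh_to_atp converts signal slope through the ADP standard", {
  std <- adp_standard(-5, 200)
  tr <- make_trace(function(t) 4000 - 10 * t, kind = "atpase_nadh")
  out <- nadh_to_atp(tr, std)
  expect_equal(out$atp_rate, 2, tolerance = 1e-10)  # 10 FU/s over 5 FU/uM
  expect_equal(nadh_to_atp(make_trace(function(t) rep(1000, length(t)),
                                      kind = "atpase_nadh"), std)$atp_rate, 0)
  per <- nadh_to_atp(tr, std, enzyme_conc = 0.4)
  expect_equal(per$per_enzyme_rate, 5, tolerance = 1e-10)
  expect_error(adp_standard(0), "nonzero")
})

test_that("NADH generation and conversion round-trip the ATPase rate", {
  tr <- gen_kinetic_traces("analytic", atp_rate = 0.37, noise = 0, seed = 1)
  out <- nadh_to_atp(tr$atpase, tr$standard, window = c(0, 50))
  expect_equal(out$atp_rate, 0.37, tolerance = 1e-6)
  # and with noise, within a few percent
  trn <- gen_kinetic_traces("analytic", atp_rate = 0.37, noise = 0.02, seed = 2)
  outn <- nadh_to_atp(trn$atpase, trn$standard, window = c(0, 150))
  expect_equal(outn$atp_rate, 0.37, tolerance = 0.05)
})

test_that("rate titrations reduce to the Hill fitter with a zero baseline", {
  P <- c(12.5, 25, 50, 100, 200, 400, 800)
  titr <- titration(P, hill_response(P, 100, 1.9, 0, 50), ligand_conc = 100)
  f1 <- fit_rate_titration(titr)
  f2 <- fit_hill(titr, free_fmin = FALSE)
  expect_s3_class(f1, "sigmoidal_fit")
  expect_equal(f1$h, f2$h, tolerance = 1e-10)
  expect_equal(f1$K_half, f2$K_half, tolerance = 1e-10)
  expect_equal(f1$V_max, f2$F_max, tolerance = 1e-10)
})

test_that("linear titrations are reported as linear, flat ones as zero activity", {
  set.seed(5)
  lin <- gen_rate_titration("basal_atpase", "WT", seed = 6)
  fl <- fit_rate_titration(lin)
  expect_s3_class(fl, "linear_rate_fit")
  expect_equal(fl$slope, attr(lin, "truth")$slope, tolerance = 0.05)
  dead <- gen_rate_titration("sliding", "WT", mix = species_mix(c(EA = 1)),
                             seed = 7)
  fd <- fit_rate_titration(dead)
  expect_s3_class(fd, "zero_activity_fit")
  expect_equal(fd$V_max, 0)
})

test_that("coupling efficiency divides ATP by base pairs and flags zero sliding", {
  expect_equal(coupling_efficiency(400, 50)$efficiency, 8)
  expect_equal(coupling_efficiency(123, 123)$efficiency, 1)
  set.seed(8)
  for (i in 1:10) {
    atp <- runif(1, 1, 1000); bp <- runif(1, 1, 100)
    expect_equal(coupling_efficiency(atp, bp)$efficiency, atp / bp)
  }
  expect_identical(coupling_efficiency(100, 0)$efficiency, "fully uncoupled")
  expect_error(coupling_efficiency(-1, 10), "nonnegative")
})

test_that("completion fraction is clamped, anchored and monotone", {
  tr <- make_trace(function(t) 1000 * exp(-t / 10) + 100,
                   t = seq(0, 120, by = 1))
  expect_equal(completion_fraction(tr, 0), 0)
  expect_equal(completion_fraction(tr, 120), 1, tolerance = 0.01)
  ts <- seq(5, 115, by = 10)
  cf <- vapply(ts, function(t) completion_fraction(tr, t), numeric(1))
  expect_true(all(diff(cf) >= -1e-9))
  expect_error(completion_fraction(tr, 500), "outside")
  ramp <- make_trace(function(t) t, t = seq(0, 100))
  expect_error(completion_fraction(ramp, 50), "plateau")
})

test_that("assay traces round-trip through the delimited format", {
  tr <- assay_trace(seq(0, 30, by = 2), 100 * exp(-seq(0, 30, by = 2) / 9),
                    kind = "atpase_nadh", meta = list(substrate = "0N100"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  back <- read_trace(path)
  expect_equal(back$time, tr$time)
  expect_equal(back$signal, tr$signal, tolerance = 1e-12)
  expect_equal(attr(back, "kind"), "atpase_nadh")
})

test_that("sliding traces can be normalised to the assay full scale", {
  tr <- assay_trace(0:19, 50 * exp(-(0:19) / 5), scale_to = 1e5)
  expect_equal(tr$signal[1], 1e5)
  expect_equal(attr(tr, "scale_factor"), 2000)
})
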