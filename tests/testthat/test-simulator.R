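test_that("degenerate rates behave as the rate law dictates", {
  # no stepping: position constant, ATP accrues at k_atp per motor
  ens <- simulate_sliding("0N100", params = sim_params("WT", k_step0 = 0),
                          t_end = 100, n_molecules = 60, seed = 1)
  expect_true(all(ens$disp == 0))
  atp_end <- ens$atp[, ncol(ens$atp)]
  expect_equal(mean(atp_end), 2 * 2.2 * 100, tolerance = 0.05)
  # dead-motor homodimer: no displacement and no ATP at all
  ea <- simulate_sliding("0N100", dimer = dimer_spec("EA", "EA"),
                         t_end = 100, n_molecules = 40, seed = 2)
  expect_true(all(ea$disp == 0))
  expect_true(all(ea$atp == 0))
})

test_that("flank conservation and the ATP ledger hold for every molecule", {
  ens <- simulate_sliding("20N120", t_end = 400, n_molecules = 150, seed = 3)
  total <- 140
  l_path <- ens$disp + 20
  # dyad never leaves the DNA: both flanks nonnegative at all recorded times
  expect_true(all(l_path >= 0 & l_path <= total))
  expect_equal(ens$final_left_flank, l_path[, ncol(l_path)])
  # ATP ledger dominates steps, and cumulative ATP is nondecreasing
  expect_true(all(ens$atp[, ncol(ens$atp)] >= ens$steps))
  expect_true(all(apply(ens$atp, 1, function(a) all(diff(a) >= 0))))
  # and the number of steps bounds the recorded |displacement|
  expect_true(all(ens$steps >= abs(ens$disp[, ncol(ens$disp)])))
})

test_that("mirrored substrates give mirrored end-point distributions", {
  a <- simulate_sliding("30N80", t_end = 600, n_molecules = 500, seed = 4)
  b <- simulate_sliding("80N30", t_end = 600, n_molecules = 500, seed = 5)
  ks <- suppressWarnings(stats::ks.test(a$disp[, ncol(a$disp)],
                                        -b$disp[, ncol(b$disp)]))
  expect_gt(ks$p.value, 0.01)
})

test_that("end-positioned nucleosomes centre without overshoot", {
  ens <- simulate_sliding("0N100", t_end = 600, n_molecules = 400, seed = 6)
  fin <- ens$disp[, ncol(ens$disp)]
  # centre is at +50: never beyond one well past it
  expect_true(all(fin <= 50 + ens$params$well_period))
  expect_gt(mean(fin), 45)
  bp <- band_pattern(ens)
  expect_equal(nrow(bp$bands), 1)
  expect_equal(bp$bands$offset_bp, 0)
})

test_that("centred substrates stay centred for wild type but not dCTD", {
  wt <- simulate_sliding("50N50", t_end = 3600, n_molecules = 250, seed = 7)
  expect_lt(mean_abs_displacement(wt), 2)
  d <- simulate_sliding("50N50", dimer = dimer_spec("WTdCTD", "WTdCTD"),
                        params = sim_params("WTdCTD"), t_end = 3600,
                        n_molecules = 250, seed = 8)
  expect_gt(mean_abs_displacement(d), 2)
})

test_that("band ladders grow by one band per extra 20 bp of overhang", {
  counts <- vapply(c("0N100", "0N120", "0N140"), function(s) {
    ens <- simulate_sliding(s, t_end = 1800, n_molecules = 400,
                            seed = 9 + nchar(s))
    nrow(band_pattern(ens)$bands)
  }, numeric(1))
  expect_equal(unname(counts), c(1, 2, 3))
})

test_that("band reduction agrees with the brute-force histogram oracle", {
  ens <- simulate_sliding("0N140", t_end = 1800, n_molecules = 300, seed = 10)
  bp <- band_pattern(ens, occupancy_threshold = 0.04)
  ref <- oracle_bands(ens$final_left_flank, 0, 140,
                      ens$params$well_period, 0.04)
  expect_equal(bp$bands$offset_bp, ref$offset_bp)
  expect_equal(bp$bands$occupancy, ref$occupancy)
  # all molecules in one place -> one band
  one <- fake_ensemble(matrix(0L, 30, 5), substrate = "50N50")
  expect_equal(nrow(band_pattern(one)$bands), 1)
})

test_that("the FRET proxy is flat for stationary and exact for tiny ensembles", {
  still <- fake_ensemble(matrix(0L, 10, 12))
  tr <- fret_proxy(still)
  expect_true(all(tr$signal == 1))
  # two molecules at distances 0 and 20 bp from the labelled left end after
  # the first sample: signal is the mean of exp(0) and exp(-2), normalised
  # to the t = 0 value
  disp <- rbind(rep(0L, 12), c(0L, rep(20L, 11)))
  two <- fake_ensemble(disp, substrate = "0N100")
  tr2 <- fret_proxy(two, decay = 10)
  expect_equal(tr2$signal[1], 1)
  expect_equal(tr2$signal[12],
               mean(exp(-c(0, 20) / 10)) / mean(exp(-c(0, 0) / 10)))
})

test_that("sliding of an end-positioned nucleosome completes within 200 s", {
  ens <- simulate_sliding("0N100", t_end = 300, n_molecules = 300, seed = 11)
  tr <- fret_proxy(ens)
  # monotone decay (small tolerance for sampling noise near the plateau)
  expect_true(all(diff(tr$signal) <= 0.005))
  expect_gte(completion_fraction(tr, 200), 0.99)
})

test_that("initial sliding rate rises with overhang length and saturates", {
  # displacement over the first 10 s, before any substrate nears its end
  # point, is proportional to the initial sliding rate
  disp10 <- vapply(c(20, 40, 60, 80, 100), function(b) {
    ens <- simulate_sliding(sprintf("0N%d", b), t_end = 10,
                            n_molecules = 400, seed = 12 + b, n_out = 2L)
    mean(ens$disp[, 2])
  }, numeric(1))
  # monotone nondecreasing up to the sensing range (small noise allowance)
  expect_true(all(diff(disp10) > -0.5))
  expect_gt(disp10[5], 10 * max(disp10[1], 0.1))
  # saturation: 80 and 100 bp overhangs start at indistinguishable rates
  expect_lt(abs(disp10[5] - disp10[4]), 0.15 * disp10[5])
})

test_that("the sensing detector round-trips an arbitrary sensing midpoint", {
  p <- sim_params("WT", s_sense = 30)
  sr <- sensing_range(p, flank_grid = seq(20, 60, by = 10),
                      n_molecules = 200, t_end = 2400, seed = 13)
  expect_equal(as.integer(sr), 30L)
})

test_that("single-motor heterodimers slide in half of their bindings", {
  ens <- simulate_sliding("0N100", dimer = dimer_spec("WT", "EA"),
                          t_end = 400, n_molecules = 600, seed = 14)
  expect_equal(mean(ens$productive), 0.5, tolerance = 0.12)
  fin <- ens$disp[, ncol(ens$disp)]
  expect_true(all(fin[!ens$productive] == 0))
  expect_gt(mean(fin[ens$productive]), 45)
  # fixed productive orientation slides every molecule
  ori <- simulate_sliding("0N100", dimer = dimer_spec("WT", "EA",
                                                      orientation = "a_leads"),
                          t_end = 400, n_molecules = 100, seed = 15)
  expect_gt(mean(ori$disp[, ncol(ori$disp)]), 45)
})

test_that("simulation is reproducible under a fixed seed", {
  e1 <- simulate_sliding("0N120", t_end = 200, n_molecules = 50, seed = 99)
  e2 <- simulate_sliding("0N120", t_end = 200, n_molecules = 50, seed = 99)
  expect_identical(e1$disp, e2$disp)
  expect_identical(e1$atp, e2$atp)
  e3 <- simulate_sliding("0N120", t_end = 200, n_molecules = 50, seed = 100)
  expect_false(identical(e1$disp, e3$disp))
})

test_that("substrates shorter than the footprint are rejected", {
  expect_error(simulate_sliding(structure(list(left_flank = 0, right_flank = 0,
                                               footprint = 147, dna_length = 100,
                                               name = "bad"),
                                          class = "nucleosome_substrate")),
               "footprint")
})
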