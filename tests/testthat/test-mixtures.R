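test_that("random pairing reproduces the Punnett square", {
  d <- dimer_distribution(c(WT = 0.5, EA = 0.5))$table
  expect_equal(d$prob[d$dimer == "WT:WT"], 0.25)
  expect_equal(d$prob[d$dimer == "EA:WT"], 0.50)
  expect_equal(d$prob[d$dimer == "EA:EA"], 0.25)
  pure <- dimer_distribution(c(WT = 1))$table
  expect_equal(pure$prob, 1)
  skew <- dimer_distribution(c(WT = 0.3, EA = 0.7))$table
  expect_equal(skew$prob[skew$dimer == "WT:WT"], 0.09)
  expect_equal(skew$prob[skew$dimer == "EA:WT"], 0.42)
  expect_equal(skew$prob[skew$dimer == "EA:EA"], 0.49)
})

test_that("dimer probabilities sum to one and match pair enumeration", {
  set.seed(20)
  species <- c("WT", "EA", "WTdCTD", "EAdCTD")
  for (i in 1:8) {
    f <- stats::runif(4); f <- f / sum(f); names(f) <- species
    d <- dimer_distribution(f)$table
    expect_equal(sum(d$prob), 1, tolerance = 1e-12)
    ref <- oracle_dimer_probs(as.list(f))
    expect_equal(d$prob, unname(ref[d$dimer]), tolerance = 1e-12)
  }
})

test_that("invalid mixtures are rejected", {
  expect_error(species_mix(c(WT = 0.6, EA = 0.6)), "sum to 1")
  expect_error(species_mix(c(WT = 1.2, EA = -0.2)), ">= 0")
  expect_error(species_mix(c(WT = 0.5, ZZ = 0.5)), "unknown species")
})

test_that("expected activities follow the default per-dimer rules", {
  # equimolar WT:EA -> half the pure wild-type sliding rate
  p <- predict_activity(dimer_distribution(c(WT = 0.5, EA = 0.5)))
  expect_equal(p$sliding, 0.5)
  expect_equal(p$atpase, 0.5)
  # pure dead complex -> nothing
  expect_equal(predict_activity(dimer_distribution(c(EA = 1)))$sliding, 0)
  # 30:70 brute-force expectation: 0.09*1 + 0.42*0.5 + 0.49*0 = 0.30
  p3 <- predict_activity(dimer_distribution(c(WT = 0.3, EA = 0.7)))
  expect_equal(p3$sliding, 0.30, tolerance = 1e-12)
  # dCTD homodimers: 5-fold lower sliding, 2-fold higher ATPase
  pd <- predict_activity(dimer_distribution(c(WTdCTD = 1)))
  expect_equal(pd$sliding, 0.2)
  expect_equal(pd$atpase, 2)
})

test_that("predicted activity is linear in dimer probabilities and bounded", {
  set.seed(21)
  for (i in 1:6) {
    f <- stats::runif(2); f <- f / sum(f)
    mix <- c(WT = f[1], EA = f[2])
    d <- dimer_distribution(mix)
    rules <- activity_rules(d)
    p <- predict_activity(d, rules)
    by_hand <- sum(d$table$prob *
                     rules$table$sliding[match(d$table$dimer,
                                               rules$table$dimer)])
    expect_equal(p$sliding, by_hand, tolerance = 1e-12)
    expect_lte(p$sliding, max(rules$table$sliding))
  }
})

test_that("both heterodimer readings give the same ensemble expectation", {
  d <- dimer_distribution(c(WT = 0.5, EA = 0.5))
  a <- predict_activity(d, activity_rules(d, heterodimer_mode = "orientation"))
  b <- predict_activity(d, activity_rules(d, heterodimer_mode = "uniform"))
  expect_equal(a$sliding, b$sliding)
})

test_that("missing rules for an occurring dimer type are an error", {
  d <- dimer_distribution(c(WT = 0.5, EA = 0.5))
  rules <- activity_rules(dimer_distribution(c(WT = 1)))
  expect_error(predict_activity(d, rules), "missing activity rule")
})

test_that("mixture titrations compose occupancy with predicted activity", {
  # pure WT reproduces the reference curve
  ref <- activity_preset("WT", "sliding")
  t_wt <- mixture_titration(c(WT = 1))
  expect_equal(t_wt$response,
               hill_response(t_wt$conc, ref$K_half, ref$h, 0, ref$V_max))
  # equimolar WT:EA plateau is half the WT plateau
  t_mix <- mixture_titration(c(WT = 0.5, EA = 0.5))
  expect_equal(attr(t_mix, "truth")$V_max, 0.5 * ref$V_max)
  expect_equal(t_mix$response, 0.5 * t_wt$response, tolerance = 1e-12)
  # fitted plateau matches the closed-form expectation
  fit <- fit_rate_titration(t_mix)
  expect_equal(fit$V_max, 0.5 * ref$V_max, tolerance = 1e-4)
})

test_that("halving the ensemble rate doubles the time to completion", {
  tr_full <- gen_kinetic_traces("analytic", tau_slide = 30, noise = 0, seed = 1)
  tr_half <- gen_kinetic_traces("analytic", tau_slide = 60, noise = 0, seed = 1,
                                t_end = 600, n_time = 301)
  t90 <- function(tr) {
    f <- function(t) completion_fraction(tr$sliding, t) - 0.9
    stats::uniroot(f, c(1, max(tr$sliding$time) * 0.9))$root
  }
  expect_equal(t90(tr_half) / t90(tr_full), 2, tolerance = 0.2)
})
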