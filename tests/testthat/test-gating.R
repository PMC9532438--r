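test_that("DNA-axis calibration recovers the 2C anchor", {
  probs <- c(dead = 0, diploid_G1 = 1, diploid_cycling = 0,
             polyploid_4C_G1 = 0, polyploid_cycling_4C = 0,
             polyploid_cycling_8C = 0)
  ev <- simulate_fucci_events(fucci_sim_config(
    500, class_probs = probs, dna_cv = 0, induction_rate = 1,
    doublet_rate = 0, seed = 1))
  # explicit thresholds: the auto background estimate assumes a mixed
  # population, not a channel where every event is positive
  fixed <- gating_config(mcherry_threshold = 50, mvenus_threshold = 50)
  expect_equal(calibrate_dna_axis(ev, fixed), 200)

  ev2 <- simulate_fucci_events(fucci_sim_config(10000, seed = 8))
  anchor <- calibrate_dna_axis(ev2)
  expect_lt(abs(anchor - 200) / 200, 0.06)
})

test_that("calibration fails without enough mCherry-only events", {
  ev <- simulate_fucci_events(fucci_sim_config(200, seed = 1))
  ev$mcherry <- 1  # wipe the mCherry channel
  expect_error(calibrate_dna_axis(ev), class = "ploidyscope_data_error")
})

test_that("canonical reporter/DNA combinations map to their categories", {
  base <- data.frame(mcherry = 10, mvenus = 10, dna = 200, width = 50)
  mk <- function(mch, mv, dna) {
    ev <- base
    ev$mcherry <- if (mch) 1000 else 10
    ev$mvenus <- if (mv) 1000 else 10
    ev$dna <- dna
    ev
  }
  cases <- rbind(
    cbind(mk(TRUE, FALSE, 400), expected = "polyploid_noncycling"),
    cbind(mk(FALSE, TRUE, 400), expected = "cycling"),
    cbind(mk(TRUE, TRUE, 100), expected = "dead"),
    cbind(mk(TRUE, FALSE, 200), expected = "diploid_G1"),
    cbind(mk(TRUE, TRUE, 200), expected = "cycling"),
    cbind(mk(TRUE, TRUE, 400), expected = "polyploid_cycling"),
    cbind(mk(FALSE, TRUE, 800), expected = "polyploid_cycling"),
    cbind(mk(FALSE, TRUE, 200), expected = "cycling"),
    cbind(mk(FALSE, FALSE, 400), expected = "non_induced"))
  cfg <- gating_config(mcherry_threshold = 50, mvenus_threshold = 50,
                       c2_anchor = 200, doublet_width_max = 75)
  calls <- classify_events(cases, cfg)
  expect_equal(as.character(calls$class), cases$expected)
  # width gate dominates everything else
  wide <- mk(TRUE, TRUE, 400); wide$width <- 200
  expect_equal(as.character(classify_events(wide, cfg)$class),
               "doublet_excluded")
})

test_that("classification is exhaustive and deterministic", {
  ev <- simulate_fucci_events(fucci_sim_config(5000, seed = 13))
  c1 <- classify_events(ev)
  c2 <- classify_events(ev)
  expect_identical(c1$class, c2$class)
  expect_false(any(is.na(c1$class)))
  expect_equal(nrow(c1), nrow(ev))
})

test_that("noise-free gating reproduces generator truth exactly", {
  ev <- simulate_fucci_events(fucci_sim_config(
    5000, dna_cv = 0, doublet_rate = 0, induction_rate = 1,
    width_cv = 0, seed = 2))
  calls <- classify_events(ev)
  expect_equal(gating_accuracy(ev, calls), 1)
})

test_that("noisy gating stays above the 95% accuracy bar and recovers fractions", {
  ev <- simulate_fucci_events(fucci_sim_config(
    10000, dna_cv = 0.06, doublet_rate = 0.05, seed = 11))
  calls <- classify_events(ev)
  expect_gte(gating_accuracy(ev, calls), 0.95)

  s <- summarize_sample(calls)
  truth <- truth_fractions(ev)
  for (k in c("dead", "diploid_G1", "cycling"))
    expect_lt(abs(s[[k]] - truth[[k]]), 0.01)
  expect_lt(abs(s$polyploid_total -
                (truth[["polyploid_noncycling"]] +
                 truth[["polyploid_cycling"]])), 0.01)
})

test_that("summary fractions are over induced singlets and sum to one", {
  ev <- simulate_fucci_events(fucci_sim_config(5000, seed = 21))
  calls <- classify_events(ev)
  s <- summarize_sample(calls)
  expect_equal(s$dead + s$diploid_G1 + s$cycling + s$polyploid_total, 1,
               tolerance = 1e-9)
  expect_equal(s$polyploid_total,
               s$polyploid_noncycling + s$polyploid_cycling)
  expect_lt(s$n_events, nrow(ev))  # non-induced and doublets removed

  only_g1 <- data.frame(class = factor(rep("diploid_G1", 10),
                                       levels = levels(calls$class)))
  s0 <- summarize_sample(only_g1)
  expect_equal(s0$polyploid_total, 0)
  expect_equal(s0$cycling, 0)

  empty <- data.frame(class = factor(rep("non_induced", 5),
                                     levels = levels(calls$class)))
  expect_error(summarize_sample(empty), class = "ploidyscope_data_error")
})

test_that("reported polyploidy increases with simulated polyploid mass", {
  poly_mass <- c(0.05, 0.15, 0.30)
  for (seed in 1:5) {
    got <- vapply(poly_mass, function(m) {
      probs <- c(dead = 0.05, diploid_G1 = 0.65 - m, diploid_cycling = 0.30,
                 polyploid_4C_G1 = m * 0.6, polyploid_cycling_4C = m * 0.3,
                 polyploid_cycling_8C = m * 0.1)
      ev <- simulate_fucci_events(fucci_sim_config(
        10000, class_probs = probs, seed = seed))
      summarize_sample(classify_events(ev))$polyploid_total
    }, numeric(1))
    expect_true(all(diff(got) > 0))
  }
})

test_that("cycling-pool redistribution follows the day-2 to day-3 accounting", {
  r <- redistribute_cycling(0.398, 0.17, 0.196)
  expect_equal(sum(r), 1, tolerance = 1e-12)
  expect_equal(unname(r["became_polyploid"]), 0.17 / 0.398, tolerance = 1e-12)
  expect_equal(unname(r["died"]), 0.196 / 0.398, tolerance = 1e-12)
  expect_equal(round(unname(r), 3),
               c(0.080, 0.492, 0.427))  # still_cycling, died, became_polyploid

  expect_equal(unname(redistribute_cycling(0.4, 0, 0)), c(1, 0, 0))
  expect_equal(unname(redistribute_cycling(0.4, 0.4, 0)), c(0, 0, 1))
  expect_error(redistribute_cycling(0, 0.1, 0.1),
               class = "ploidyscope_config_error")
  # over-allocated fates are clipped and renormalized
  r2 <- redistribute_cycling(0.2, 0.15, 0.15)
  expect_equal(sum(r2), 1)
  expect_equal(unname(r2["still_cycling"]), 0)
})
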