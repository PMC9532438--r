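test_that("half-life fit is exact on noise-free exponentials", {
  tt <- seq(0, 90, by = 2)
  curve <- data.frame(time_min = tt,
                      fluorescence = 500 * exp(-log(2) * tt / 30))
  expect_equal(fit_halflife(curve), 30, tolerance = 1e-6)

  # definition of half-life holds in the generated curve
  cfg <- decay_sim_config(gfr_true = 14616.8 * 25 / 100 / 30,
                          body_weight = 25, noise_sd = 0,
                          distribution_weight = 0)
  sim <- simulate_decay(cfg)
  f0 <- sim$fluorescence[sim$time_min == 0]
  f30 <- sim$fluorescence[sim$time_min == 30]
  expect_equal(f30 / f0, 0.5, tolerance = 1e-9)

  flat <- data.frame(time_min = tt, fluorescence = rep(100, length(tt)))
  expect_error(fit_halflife(flat), class = "ploidyscope_data_error")
  short <- curve[1:5, ]
  expect_error(fit_halflife(short), class = "ploidyscope_data_error")
})

test_that("embedded elimination half-life inverts the GFR conversion", {
  cfg <- decay_sim_config(gfr_true = 250, body_weight = 25)
  expect_equal(cfg$elimination_halflife, 14616.8 / 250 * 25 / 100)
  expect_equal(cfg$elimination_halflife, 14.6168)
  curve <- simulate_decay(cfg)
  expect_equal(attr(curve, "true_halflife_min"), 14.6168)
})

test_that("half-life recovery from noisy bi-exponential curves is within 5%", {
  for (seed in 1:4) {
    curve <- simulate_decay(decay_sim_config(
      gfr_true = 250, body_weight = 25, seed = seed))
    truth <- attr(curve, "true_halflife_min")
    expect_lt(abs(fit_halflife(curve, discard_initial = 10) - truth) / truth,
              0.05)
    expect_lt(abs(fit_halflife(curve, method = "biexp") - truth) / truth,
              0.05)
  }
})

test_that("GFR conversion formula and its monotonicity properties hold", {
  expect_identical(gfr_from_halflife(14616.8, 100), 1)
  expect_equal(gfr_from_halflife(14.6168, 25), 250)
  set.seed(42)
  for (i in 1:20) {
    th <- runif(1, 5, 60); bw <- runif(1, 15, 40)
    expect_equal(gfr_from_halflife(th, 2 * bw), 2 * gfr_from_halflife(th, bw))
    expect_gt(gfr_from_halflife(th, bw), gfr_from_halflife(th * 1.1, bw))
  }
  expect_error(gfr_from_halflife(0, 25), class = "ploidyscope_config_error")
  expect_error(gfr_from_halflife(10, -1), class = "ploidyscope_config_error")
})

test_that("baseline/sham normalization has the right fixed points", {
  series <- data.frame(
    animal_id = rep(c("s1", "s2", "i1"), each = 2),
    group = rep(c("sham", "sham", "injured"), each = 2),
    time = rep(c(0, 2), 3),
    gfr = c(250, 250, 250, 250, 250, 125))
  out <- normalize_gfr(series)
  expect_equal(out$gfr_norm[out$animal_id == "s1"], c(1, 1))
  expect_equal(out$gfr_norm[out$animal_id == "i1" & out$time == 2], 0.5)

  series$gfr[1] <- 0
  expect_error(normalize_gfr(series), class = "ploidyscope_data_error")
})

test_that("a simulated 40% injury drop is recovered after normalization", {
  coh <- simulate_gfr_cohort(n_per_group = 4, injury_drop = 0.4, seed = 6)
  nrm <- normalize_gfr(coh)
  day2 <- nrm$gfr_norm[nrm$group == "injured" & nrm$time == 2]
  expect_lt(abs(mean(day2) - 0.6), 0.03)
  sham2 <- nrm$gfr_norm[nrm$group == "sham" & nrm$time == 2]
  expect_equal(mean(sham2), 1, tolerance = 1e-9)  # sham mean ratio is the divisor
})

test_that("ChIP fold enrichment reproduces hand arithmetic and cancels dilution", {
  expect_equal(chip_fold_enrichment(chip_sample(25, 20, 10, "specific"),
                                    chip_sample(27, 20, 10, "IgG")), 4)
  # equal delta-Ct means no enrichment
  expect_equal(chip_fold_enrichment(chip_sample(25, 20, 10, "specific"),
                                    chip_sample(25, 20, 10, "IgG")), 1)
  # one cycle earlier doubles the enrichment
  expect_equal(chip_fold_enrichment(chip_sample(24, 20, 10, "specific"),
                                    chip_sample(27, 20, 10, "IgG")), 8)
  # shared dilution factor cancels exactly
  set.seed(7)
  for (i in 1:20) {
    d <- runif(1, 1, 100)
    expect_equal(
      chip_fold_enrichment(chip_sample(25, 20, d, "specific"),
                           chip_sample(27, 20, d, "IgG")),
      4, tolerance = 1e-12)
  }
  expect_equal(chip_delta_ct(chip_sample(25, 20, 10)), 5 + log2(10))
})

test_that("simulated ChIP tables embed the requested true enrichment", {
  chip <- simulate_chip(true_fr = 6, noise_sd = 0, seed = 1)
  spec <- chip[chip$antibody == "specific", ][1, ]
  igg <- chip[chip$antibody == "IgG", ][1, ]
  fr <- chip_fold_enrichment(
    chip_sample(spec$ct_bound, spec$ct_input, spec$dilution_factor, "specific"),
    chip_sample(igg$ct_bound, igg$ct_input, igg$dilution_factor, "IgG"))
  expect_equal(fr, 6, tolerance = 1e-9)
})
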