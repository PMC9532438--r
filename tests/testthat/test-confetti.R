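test_that("two-draw distinct-colour probability matches enumeration", {
  expect_equal(p_bicoloured(3), 2 / 3)
  expect_equal(p_bicoloured(2), 1 / 2)
  # independent oracle: enumerate all ordered pairs of 4 equiprobable colours
  pairs <- expand.grid(a = 1:4, b = 1:4)
  expect_equal(p_bicoloured(4), mean(pairs$a != pairs$b))  # 12/16 = 3/4
  expect_error(p_bicoloured(1), class = "ploidyscope_config_error")
})

test_that("efficiency correction reproduces the printed arithmetic", {
  expect_equal(round(correct_for_efficiency(13.3, 0.847), 1), 15.7)
  expect_equal(correct_for_efficiency(12.0, 1.0), 12.0)
  expect_equal(correct_for_efficiency(10.0, 0.5), 20.0)
  # scale equivariance
  expect_equal(correct_for_efficiency(2 * 7.1, 0.8),
               2 * correct_for_efficiency(7.1, 0.8))
  expect_error(correct_for_efficiency(10, 0),
               class = "ploidyscope_config_error")
})

test_that("expected outcome fractions match a brute-force pair enumeration", {
  # all-polyploid, equiprobable countable colours: 2/3 bi-coloured, 1/3 duplicates
  cfg <- confetti_sim_config(100, polyploid_fraction = 1,
                             colour_probs = equal_ryc, seed = 1)
  et <- expected_tally(cfg)
  expect_equal(unname(et["poly_bicoloured_counted"]), 2 / 3)
  expect_equal(unname(et["poly_duplicate"]), 1 / 3)

  # no polyploids: no bi-coloured cells at all
  cfg0 <- confetti_sim_config(100, polyploid_fraction = 0, seed = 1)
  expect_equal(unname(expected_tally(cfg0)["bicoloured_any"]), 0)

  # rare GFP: check against enumeration of the 16 ordered colour pairs
  cp <- c(RFP = 0.33, YFP = 0.33, CFP = 0.33, GFP = 0.01)
  cfg2 <- confetti_sim_config(100, polyploid_fraction = 0.2,
                              colour_probs = cp, seed = 1)
  et2 <- expected_tally(cfg2)
  grid <- expand.grid(a = names(cp), b = names(cp))
  w <- cp[grid$a] * cp[grid$b]
  distinct <- grid$a != grid$b
  has_gfp <- grid$a == "GFP" | grid$b == "GFP"
  expect_equal(unname(et2["bicoloured_any"]), 0.2 * sum(w[distinct]))
  expect_equal(unname(et2["poly_bicoloured_counted"]),
               0.2 * sum(w[distinct & !has_gfp]))
  expect_equal(unname(et2["poly_pair_with_gfp"]), 0.2 * sum(w[has_gfp]))
  expect_equal(unname(et2["poly_duplicate"]),
               0.2 * sum(w[!distinct & !has_gfp]))

  # disjoint outcomes sum to one
  disjoint <- setdiff(names(et2), "bicoloured_any")
  expect_equal(sum(et2[disjoint]), 1, tolerance = 1e-12)
})

test_that("simulated outcome frequencies agree with the closed form", {
  set.seed(99)
  for (i in 1:10) {
    ryc <- runif(3, 0.2, 0.4)
    cp <- c(ryc, runif(1, 0.001, 0.05))
    cp <- cp / sum(cp)
    names(cp) <- c("RFP", "YFP", "CFP", "GFP")
    p <- runif(1, 0.05, 0.6)
    n <- 20000
    cfg <- confetti_sim_config(n, polyploid_fraction = p,
                               induction_efficiency = 1,
                               colour_probs = cp, seed = 1000 + i)
    cells <- simulate_confetti(cfg)
    et <- expected_tally(cfg)

    bi_any <- !is.na(cells$colour2) & cells$colour2 != cells$colour1
    obs <- mean(bi_any)
    exp_b <- unname(et["bicoloured_any"])
    expect_lt(abs(obs - exp_b), 4 * sqrt(exp_b * (1 - exp_b) / n))

    dup <- !is.na(cells$colour2) & cells$colour2 == cells$colour1 &
      cells$colour1 != "GFP"
    exp_d <- unname(et["poly_duplicate"])
    expect_lt(abs(mean(dup) - exp_d), 4 * sqrt(exp_d * (1 - exp_d) / n))
  }
})

test_that("diploid-only simulations contain no bi-coloured cells", {
  cells <- simulate_confetti(confetti_sim_config(
    5000, polyploid_fraction = 0, seed = 2))
  expect_true(all(is.na(cells$colour2)))
  expect_equal(tally_confetti(cells)$n_bicoloured, 0L)
})

test_that("estimator recovers the polyploid fraction and handles edges", {
  cells <- simulate_confetti(confetti_sim_config(
    50000, polyploid_fraction = 0.30, induction_efficiency = 1,
    colour_probs = equal_ryc, seed = 5))
  est <- estimate_polyploid_fraction(tally_confetti(cells), seed = 5)
  expect_gt(est$p_hat, 0.28)
  expect_lt(est$p_hat, 0.32)
  expect_true(est$ci_low <= 0.30 && 0.30 <= est$ci_high)

  # no bi-coloured cells: zero estimate, CI floor at zero
  est0 <- estimate_polyploid_fraction(confetti_tally(100, 80, 0), seed = 1)
  expect_equal(est0$p_hat, 0)
  expect_equal(est0$ci_low, 0)

  # b_obs = 2/3 is the all-polyploid boundary (clipped)
  est1 <- estimate_polyploid_fraction(confetti_tally(400, 300, 200), seed = 1)
  expect_equal(est1$p_hat, 1)

  expect_error(estimate_polyploid_fraction(confetti_tally(10, 0, 0)),
               class = "ploidyscope_data_error")
  expect_error(confetti_tally(10, 20, 5), class = "ploidyscope_config_error")
})

test_that("estimator bias shrinks with sample size", {
  p <- 0.2
  bias_at <- function(n, reps = 5) {
    e <- vapply(seq_len(reps), function(r) {
      cells <- simulate_confetti(confetti_sim_config(
        n, polyploid_fraction = p, induction_efficiency = 1,
        colour_probs = equal_ryc, seed = 300 * r + n %% 1000))
      estimate_polyploid_fraction(tally_confetti(cells), n_bootstrap = 100,
                                  seed = r)$p_hat
    }, numeric(1))
    abs(mean(e) - p)
  }
  b <- c(bias_at(1e3), bias_at(1e4), bias_at(1e5))
  expect_lt(b[3], 0.01)
  expect_lt(b[3], b[1] + 0.005)
})

test_that("plug-in colour mode matches the equiprobable factor when colours are equal", {
  tly <- confetti_tally(1000, 900, 120)
  e1 <- estimate_polyploid_fraction(tly, seed = 1)
  e2 <- estimate_polyploid_fraction(tly, seed = 1, colour_mode = "plugin",
                                    colour_freqs = c(1, 1, 1))
  expect_equal(e1$p_hat, e2$p_hat)
  # skewed colours raise the inversion factor (less chance to differ)
  e3 <- estimate_polyploid_fraction(tly, seed = 1, colour_mode = "plugin",
                                    colour_freqs = c(0.6, 0.3, 0.1))
  expect_gt(e3$p_hat, e1$p_hat)
})
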