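#' Confetti tally of coloured and bi-coloured cells
#'
#' Counts from a scored tissue region. GFP-containing cells are excluded
#' from both `n_coloured` and `n_bicoloured`; bi-coloured counts cover only
#' the RFP+YFP, RFP+CFP and YFP+CFP combinations.
#'
#' @param n_total_tc total tubular cells scored in the region.
#' @param n_coloured Confetti-coloured cells after GFP exclusion.
#' @param n_bicoloured bi-coloured cells among `n_coloured`.
#' @param n_gfp_excluded GFP-containing cells removed before counting.
#' @param region region label (e.g. `"cortex"`, `"OSOM"`).
#' @return object of class `confetti_tally`.
#' @export
confetti_tally <- function(n_total_tc, n_coloured, n_bicoloured,
                           n_gfp_excluded = 0L, region = "cortex") {
  for (nm in c("n_total_tc", "n_coloured", "n_bicoloured", "n_gfp_excluded")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v != floor(v))
      stop_config("`%s` must be a non-negative integer", nm)
  }
  if (n_bicoloured > n_coloured || n_coloured > n_total_tc)
    stop_config("counts must satisfy n_bicoloured <= n_coloured <= n_total_tc")
  structure(list(n_total_tc = as.integer(n_total_tc),
                 n_coloured = as.integer(n_coloured),
                 n_bicoloured = as.integer(n_bicoloured),
                 n_gfp_excluded = as.integer(n_gfp_excluded),
                 region = region),
            class = "confetti_tally")
}

#' Probability that a polyploid cell appears bi-coloured
#'
#' A 4C cell recombines its reporter twice, independently, drawing each
#' time uniformly from `n_colours` equiprobable fluorochromes. The two
#' draws differ with probability `(n_colours - 1) / n_colours`: with the
#' three countable Confetti colours, 2/3 of polyploid cells appear
#' bi-coloured and 1/3 recombine the same colour twice, indistinguishable
#' from mono-coloured diploids.
#'
#' @param n_colours number of equiprobable colours (>= 2).
#' @return probability of two distinct colours.
#' @examples
#' p_bicoloured(3)  # 2/3
#' @export
p_bicoloured <- function(n_colours) {
  if (!is.numeric(n_colours) || length(n_colours) != 1L ||
      n_colours != floor(n_colours) || n_colours < 2)
    stop_config("`n_colours` must be an integer >= 2")
  (n_colours - 1) / n_colours
}

#' Normalize an observed bi-coloured percentage for recombination efficiency
#'
#' Divides the observed bi-coloured percentage by the fraction of tubular
#' cells in which the reporter recombined at all, e.g.
#' `correct_for_efficiency(13.3, 0.847)` gives 15.7.
#'
#' @param b_obs_pct observed bi-coloured percentage (of coloured cells).
#' @param efficiency recombination efficiency as a fraction in (0, 1].
#' @return efficiency-normalized percentage.
#' @export
correct_for_efficiency <- function(b_obs_pct, efficiency) {
  check_positive(b_obs_pct, "b_obs_pct", strict = FALSE)
  if (!is.numeric(efficiency) || length(efficiency) != 1L ||
      is.na(efficiency) || efficiency <= 0 || efficiency > 1)
    stop_config("`efficiency` must be in (0, 1]")
  b_obs_pct / efficiency
}

#' Estimate the polyploid fraction from a Confetti tally
#'
#' Inverts the two-draw colour model: with three equiprobable countable
#' colours a polyploid cell is bi-coloured with probability 2/3, so the
#' polyploid fraction among coloured cells is `p_hat = (3/2) * b_obs`,
#' clipped to `[0, 1]`. A percentile bootstrap over cells (resampling
#' `n_coloured` Bernoulli outcomes) gives the 95% interval. With
#' `colour_mode = "plugin"`, the 3/2 factor is replaced by
#' `1 / sum_{i != j} c_i c_j` with colour frequencies `c_i` supplied via
#' `colour_freqs`, guarding against unequal recombination probabilities.
#'
#' @param tally a [confetti_tally()].
#' @param n_bootstrap bootstrap resamples.
#' @param seed integer seed for the bootstrap.
#' @param colour_mode `"equiprobable"` (default) or `"plugin"`.
#' @param colour_freqs colour frequencies over the countable colours, used
#'   only in plug-in mode; normalized internally.
#' @return object of class `confetti_estimate`: a list with `b_obs`,
#'   `efficiency` (`n_coloured / n_total_tc`), `b_corrected_pct`
#'   (efficiency-normalized percentage), `p_hat`, `ci_low`, `ci_high`,
#'   `region`, `n_coloured`.
#' @examples
#' est <- estimate_polyploid_fraction(
#'   confetti_tally(1000, 847, 113), seed = 1)
#' est$p_hat
#' @export
estimate_polyploid_fraction <- function(tally, n_bootstrap = 2000, seed = 1L,
                                        colour_mode = c("equiprobable", "plugin"),
                                        colour_freqs = NULL) {
  if (!inherits(tally, "confetti_tally"))
    stop_config("`tally` must be built with confetti_tally()")
  colour_mode <- match.arg(colour_mode)
  if (tally$n_coloured == 0)
    stop_data("cannot estimate from zero coloured cells")
  n_bootstrap <- check_count(n_bootstrap, "n_bootstrap")

  inv_factor <- if (colour_mode == "equiprobable") {
    1 / p_bicoloured(3)
  } else {
    if (is.null(colour_freqs) || length(colour_freqs) < 2)
      stop_config("plug-in mode needs `colour_freqs` over >= 2 colours")
    cf <- colour_freqs / sum(colour_freqs)
    1 / (1 - sum(cf^2))
  }

  b_obs <- tally$n_bicoloured / tally$n_coloured
  p_hat <- min(max(inv_factor * b_obs, 0), 1)
  set.seed(seed)
  # percentile bootstrap over cells: resampling n Bernoulli(b_obs) outcomes
  # with replacement is a binomial draw
  b_star <- stats::rbinom(n_bootstrap, tally$n_coloured, b_obs) /
    tally$n_coloured
  p_star <- pmin(pmax(inv_factor * b_star, 0), 1)
  ci <- stats::quantile(p_star, c(0.025, 0.975), names = FALSE)

  structure(list(b_obs = b_obs,
                 efficiency = tally$n_coloured / tally$n_total_tc,
                 b_corrected_pct = correct_for_efficiency(
                   100 * b_obs, tally$n_coloured / tally$n_total_tc),
                 p_hat = p_hat,
                 ci_low = ci[1], ci_high = ci[2],
                 region = tally$region,
                 n_coloured = tally$n_coloured),
            class = "confetti_estimate")
}

#' @export
print.confetti_estimate <- function(x, ...) {
  cat(sprintf("Confetti polyploidy estimate (%s, n = %d coloured cells)\n",
              x$region, x$n_coloured))
  cat(sprintf("  bi-coloured:            %.1f%%\n", 100 * x$b_obs))
  cat(sprintf("  recombination efficiency: %.1f%%\n", 100 * x$efficiency))
  cat(sprintf("  efficiency-normalized:  %.1f%%\n", x$b_corrected_pct))
  cat(sprintf("  polyploid fraction (3/2 x bi-coloured): %.1f%% [%.1f, %.1f]\n",
              100 * x$p_hat, 100 * x$ci_low, 100 * x$ci_high))
  invisible(x)
}

#' Closed-form expected Confetti outcome fractions
#'
#' Exact multinomial expectations among induced cells, partitioned into
#' disjoint outcomes: mono-coloured diploids (GFP or not), polyploid pairs
#' containing GFP, countable bi-coloured pairs (two distinct colours among
#' RFP/YFP/CFP) and same-colour duplicates. The convenience entry
#' `bicoloured_any` (two distinct colours over all four fluorochromes,
#' `p * (1 - sum c_i^2)`) overlaps the partition and is excluded from the
#' sum-to-one identity.
#'
#' @param cfg a [confetti_sim_config()].
#' @return named numeric vector of expected fractions among induced cells:
#'   `diploid_mono_other`, `diploid_mono_gfp`, `poly_pair_with_gfp`,
#'   `poly_bicoloured_counted`, `poly_duplicate`, plus `bicoloured_any`.
#' @export
expected_tally <- function(cfg) {
  if (!inherits(cfg, "confetti_sim_config"))
    stop_config("`cfg` must be built with confetti_sim_config()")
  p <- cfg$polyploid_fraction
  cp <- cfg$colour_probs
  cg <- cp[["GFP"]]
  ryc <- cp[c("RFP", "YFP", "CFP")]
  out <- c(
    diploid_mono_other = (1 - p) * (1 - cg),
    diploid_mono_gfp = (1 - p) * cg,
    poly_pair_with_gfp = p * (1 - (1 - cg)^2),
    poly_bicoloured_counted = p * (sum(ryc)^2 - sum(ryc^2)),
    poly_duplicate = p * sum(ryc^2),
    bicoloured_any = p * (1 - sum(cp^2)))
  out
}
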