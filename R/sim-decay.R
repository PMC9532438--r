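#' FITC-sinistrin decay-curve simulation configuration
#'
#' Transcutaneous GFR devices record skin fluorescence after an intravenous
#' FITC-sinistrin bolus. The kinetics follow a two-compartment model: a fast
#' distribution phase and a slower renal elimination phase. The elimination
#' half-life embedded in the curve is derived from the requested true GFR by
#' inverting the standard conversion
#' `GFR [ul/min] = 14616.8 / t_half [min] * bw [g] / 100`.
#'
#' @param gfr_true true glomerular filtration rate (ul/min).
#' @param body_weight animal body weight (g).
#' @param sampling_interval time between samples (min).
#' @param duration recording length (min); should exceed three elimination
#'   half-lives for a stable fit.
#' @param distribution_halflife half-life of the fast distribution
#'   compartment (min).
#' @param distribution_weight fraction of the signal amplitude in the fast
#'   compartment, in `[0, 1)`.
#' @param amplitude fluorescence at time zero (a.u.).
#' @param noise_sd additive Gaussian noise (a.u.).
#' @param conversion_factor empirical conversion constant (ul); see
#'   [gfr_from_halflife()].
#' @param seed integer seed.
#' @return object of class `decay_sim_config`.
#' @export
decay_sim_config <- function(gfr_true,
                             body_weight = 25,
                             sampling_interval = 1,
                             duration = 75,
                             distribution_halflife = 2,
                             distribution_weight = 0.25,
                             amplitude = 1000,
                             noise_sd = 2,
                             conversion_factor = 14616.8,
                             seed = 1L) {
  check_positive(gfr_true, "gfr_true")
  check_positive(body_weight, "body_weight")
  check_positive(sampling_interval, "sampling_interval")
  check_positive(duration, "duration")
  check_positive(distribution_halflife, "distribution_halflife")
  if (!is.numeric(distribution_weight) || distribution_weight < 0 ||
      distribution_weight >= 1)
    stop_config("`distribution_weight` must be in [0, 1)")
  check_positive(amplitude, "amplitude")
  check_positive(noise_sd, "noise_sd", strict = FALSE)
  check_positive(conversion_factor, "conversion_factor")
  t_elim <- conversion_factor / gfr_true * body_weight / 100
  structure(list(gfr_true = gfr_true, body_weight = body_weight,
                 sampling_interval = sampling_interval, duration = duration,
                 distribution_halflife = distribution_halflife,
                 distribution_weight = distribution_weight,
                 amplitude = amplitude, noise_sd = noise_sd,
                 conversion_factor = conversion_factor,
                 elimination_halflife = t_elim,
                 seed = as.integer(seed)),
            class = "decay_sim_config")
}

#' Simulate a bi-exponential FITC-sinistrin decay curve
#'
#' @param cfg a [decay_sim_config()].
#' @return data.frame with columns `time_min` and `fluorescence`, and
#'   attributes `body_weight_g` and `true_halflife_min` (the embedded
#'   elimination half-life).
#' @examples
#' curve <- simulate_decay(decay_sim_config(gfr_true = 250, seed = 2))
#' attr(curve, "true_halflife_min")  # 14616.8 / 250 * 25 / 100
#' @export
simulate_decay <- function(cfg) {
  if (!inherits(cfg, "decay_sim_config"))
    stop_config("`cfg` must be built with decay_sim_config()")
  set.seed(cfg$seed)
  tt <- seq(0, cfg$duration, by = cfg$sampling_interval)
  w <- cfg$distribution_weight
  f <- cfg$amplitude * (w * exp(-log(2) * tt / cfg$distribution_halflife) +
                        (1 - w) * exp(-log(2) * tt / cfg$elimination_halflife))
  if (cfg$noise_sd > 0) f <- f + stats::rnorm(length(tt), 0, cfg$noise_sd)
  structure(data.frame(time_min = tt, fluorescence = f),
            body_weight_g = cfg$body_weight,
            true_halflife_min = cfg$elimination_halflife,
            class = c("decay_curve", "data.frame"))
}

#' Simulate a longitudinal GFR cohort
#'
#' Builds per-animal decay curves at several time points for a sham group
#' (stable GFR) and an injured group whose GFR drops by `injury_drop` at all
#' post-baseline time points, then returns the fitted per-animal GFR table
#' ready for [normalize_gfr()].
#'
#' @param n_per_group animals per group.
#' @param times study time points (days); the first is baseline.
#' @param gfr_baseline true baseline GFR (ul/min).
#' @param injury_drop fractional GFR reduction in the injured group after
#'   baseline (0.4 = 40% drop).
#' @param body_weight body weight (g) shared by all animals.
#' @param noise_sd decay-curve noise passed to [simulate_decay()].
#' @param animal_cv between-animal lognormal CV on true GFR.
#' @param seed integer seed.
#' @return data.frame with columns `animal_id`, `group` (`"sham"`/`"injured"`),
#'   `time`, `gfr`, `true_gfr`.
#' @export
simulate_gfr_cohort <- function(n_per_group = 4,
                                times = c(0, 2, 7),
                                gfr_baseline = 250,
                                injury_drop = 0.4,
                                body_weight = 25,
                                noise_sd = 2,
                                animal_cv = 0.05,
                                seed = 1L) {
  check_count(n_per_group, "n_per_group")
  check_prob(injury_drop, "injury_drop")
  set.seed(seed)
  rows <- list()
  k <- 0L
  for (grp in c("sham", "injured")) {
    for (a in seq_len(n_per_group)) {
      k <- k + 1L
      animal_gfr <- gfr_baseline * rlnorm_cv1(1, animal_cv)
      for (tp in times) {
        true_gfr <- animal_gfr *
          (if (grp == "injured" && tp > times[1]) 1 - injury_drop else 1)
        curve <- simulate_decay(decay_sim_config(
          gfr_true = true_gfr, body_weight = body_weight,
          noise_sd = noise_sd,
          seed = (seed + 7919L * k + 101L * match(tp, times)) %% .Machine$integer.max))
        fit <- fit_halflife(curve)
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = sprintf("%s_%d", grp, a), group = grp, time = tp,
          gfr = gfr_from_halflife(fit, body_weight), true_gfr = true_gfr)
      }
    }
  }
  do.call(rbind, rows)
}

#' Simulate ChIP-qPCR Ct triplets with a known true enrichment
#'
#' Generates matched specific-antibody and IgG samples whose noise-free
#' fold enrichment equals `true_fr`: the IgG pulldown sits `igg_delta_ct`
#' cycles above the dilution-corrected input, and the specific antibody
#' sits `log2(true_fr)` cycles below the IgG.
#'
#' @param true_fr true fold enrichment of the specific antibody over IgG.
#' @param n_replicates replicate sample pairs.
#' @param ct_input input-chromatin Ct.
#' @param dilution_factor input dilution factor.
#' @param igg_delta_ct IgG delta-Ct above corrected input (cycles).
#' @param noise_sd Gaussian noise on each Ct (cycles).
#' @param locus locus label.
#' @param seed integer seed.
#' @return data.frame with columns `sample_id`, `antibody`
#'   (`"specific"`/`"IgG"`), `locus`, `ct_bound`, `ct_input`,
#'   `dilution_factor`, `true_fr`.
#' @export
simulate_chip <- function(true_fr = 4,
                          n_replicates = 3,
                          ct_input = 20,
                          dilution_factor = 10,
                          igg_delta_ct = 8,
                          noise_sd = 0.1,
                          locus = "CTGF",
                          seed = 1L) {
  check_positive(true_fr, "true_fr")
  n_replicates <- check_count(n_replicates, "n_replicates")
  check_positive(dilution_factor, "dilution_factor")
  check_positive(noise_sd, "noise_sd", strict = FALSE)
  set.seed(seed)
  base_bound_igg <- ct_input - log2(dilution_factor) + igg_delta_ct
  base_bound_spec <- base_bound_igg - log2(true_fr)
  mk <- function(antibody, base) data.frame(
    sample_id = sprintf("%s_%s_%d", locus, antibody, seq_len(n_replicates)),
    antibody = antibody, locus = locus,
    ct_bound = base + stats::rnorm(n_replicates, 0, noise_sd),
    ct_input = ct_input + stats::rnorm(n_replicates, 0, noise_sd),
    dilution_factor = dilution_factor, true_fr = true_fr)
  rbind(mk("specific", base_bound_spec), mk("IgG", base_bound_igg))
}
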