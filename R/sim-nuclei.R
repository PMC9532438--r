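#' Per-nucleus DNA-intensity simulation configuration
#'
#' Emulates confocal PicoGreen quantification on tissue sections: each
#' outlined nucleus yields a mean intensity equal to a local background plus
#' a signal proportional to its DNA content (C-value), with multiplicative
#' lognormal noise. A designated subset of pure-diploid tubular nuclei plays
#' the role of the healthy-biopsy internal control used for calibration.
#'
#' @param n_nuclei number of study nuclei (the diploid-reference nuclei are
#'   generated in addition).
#' @param ploidy_mix named probability vector over C-classes `2C`, `4C`,
#'   `8C` for marker-negative nuclei.
#' @param gain intensity per C-unit (a.u.).
#' @param background_mean,background_sd local background level (a.u.).
#' @param intensity_cv coefficient of variation of the nuclear signal.
#' @param marker_effect named probability vector over the same C-classes
#'   used for marker-positive nuclei (e.g. a YAP1-positive mix shifted
#'   toward 4C), or `NULL` to use `ploidy_mix` for both groups.
#' @param marker_rate fraction of study nuclei that are marker-positive.
#' @param n_reference number of diploid internal-control nuclei.
#' @param seed integer seed.
#' @return object of class `nuclei_sim_config`.
#' @export
nuclei_sim_config <- function(n_nuclei,
                              ploidy_mix = c(`2C` = 0.85, `4C` = 0.12,
                                             `8C` = 0.03),
                              gain = 100,
                              background_mean = 50,
                              background_sd = 5,
                              intensity_cv = 0.05,
                              marker_effect = NULL,
                              marker_rate = 0.5,
                              n_reference = 50,
                              seed = 1L) {
  n_nuclei <- check_count(n_nuclei, "n_nuclei")
  cls <- c("2C", "4C", "8C")
  ploidy_mix <- check_prob_vector(ploidy_mix, "ploidy_mix", cls)
  check_positive(gain, "gain")
  check_positive(background_mean, "background_mean", strict = FALSE)
  check_positive(background_sd, "background_sd", strict = FALSE)
  check_positive(intensity_cv, "intensity_cv", strict = FALSE)
  if (!is.null(marker_effect))
    marker_effect <- check_prob_vector(marker_effect, "marker_effect", cls)
  check_prob(marker_rate, "marker_rate")
  n_reference <- check_count(n_reference, "n_reference")
  structure(list(n_nuclei = n_nuclei, ploidy_mix = ploidy_mix, gain = gain,
                 background_mean = background_mean,
                 background_sd = background_sd,
                 intensity_cv = intensity_cv,
                 marker_effect = marker_effect, marker_rate = marker_rate,
                 n_reference = n_reference, seed = as.integer(seed)),
            class = "nuclei_sim_config")
}

#' Simulate a per-nucleus PicoGreen intensity table
#'
#' @param cfg a [nuclei_sim_config()].
#' @return data.frame with columns `nucleus_id`, `intensity`, `background`,
#'   `marker_positive`, `tubular`, `reference_diploid`, and the ground-truth
#'   `true_c` (C-value). Reference nuclei are all tubular, marker-negative
#'   and exactly diploid.
#' @examples
#' nuc <- simulate_nuclei(nuclei_sim_config(200, seed = 5))
#' aggregate(intensity ~ true_c, nuc, mean)
#' @export
simulate_nuclei <- function(cfg) {
  if (!inherits(cfg, "nuclei_sim_config"))
    stop_config("`cfg` must be built with nuclei_sim_config()")
  set.seed(cfg$seed)
  cvals <- c(`2C` = 2, `4C` = 4, `8C` = 8)
  n <- cfg$n_nuclei
  marker <- stats::runif(n) < cfg$marker_rate
  mix_pos <- cfg$marker_effect %||% cfg$ploidy_mix
  cls <- character(n)
  cls[!marker] <- sample(names(cfg$ploidy_mix), sum(!marker), replace = TRUE,
                         prob = cfg$ploidy_mix)
  cls[marker] <- sample(names(mix_pos), sum(marker), replace = TRUE,
                        prob = mix_pos)
  true_c <- c(cvals[cls], rep(2, cfg$n_reference))
  marker <- c(marker, rep(FALSE, cfg$n_reference))
  reference <- c(rep(FALSE, n), rep(TRUE, cfg$n_reference))
  m <- n + cfg$n_reference
  bg <- stats::rnorm(m, cfg$background_mean, cfg$background_sd)
  bg <- pmax(bg, 0)
  intensity <- bg + cfg$gain * true_c * rlnorm_cv1(m, cfg$intensity_cv)
  data.frame(nucleus_id = seq_len(m),
             intensity = intensity,
             background = bg,
             marker_positive = marker,
             tubular = TRUE,
             reference_diploid = reference,
             true_c = true_c)
}
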