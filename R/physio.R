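# Transcutaneous GFR (FITC-sinistrin kinetics) and ChIP-qPCR enrichment.

#' Fit the FITC-sinistrin elimination half-life
#'
#' Isolates the renal elimination phase by discarding an initial window
#' dominated by the distribution compartment, then fits log-fluorescence
#' against time by ordinary least squares; `t_half = ln 2 / |slope|`.
#' With `method = "biexp"` the full two-compartment model
#' `A * (w * exp(-k1 t) + (1 - w) * exp(-k2 t))` is fitted instead
#' (Levenberg-Marquardt) and the slower rate defines the half-life.
#'
#' @param curve data.frame with columns `time_min` and `fluorescence`
#'   (e.g. from [simulate_decay()]).
#' @param discard_initial initial window to drop (min); only used by the
#'   log-linear method.
#' @param method `"loglinear"` (default) or `"biexp"`.
#' @return elimination half-life (min).
#' @examples
#' curve <- simulate_decay(decay_sim_config(gfr_true = 250, noise_sd = 0))
#' fit_halflife(curve)
#' @export
fit_halflife <- function(curve, discard_initial = 10,
                         method = c("loglinear", "biexp")) {
  method <- match.arg(method)
  if (!all(c("time_min", "fluorescence") %in% names(curve)))
    stop_data("curve must have columns `time_min` and `fluorescence`")
  if (nrow(curve) < 10)
    stop_data("decay curve needs >= 10 samples (got %d)", nrow(curve))
  if (is.unsorted(curve$time_min, strictly = TRUE))
    stop_data("`time_min` must be strictly increasing")

  if (method == "biexp") {
    k_guess <- .loglin_rate(curve, discard_initial)
    fit <- minpack.lm::nlsLM(
      fluorescence ~ A * (w * exp(-k1 * time_min) + (1 - w) * exp(-k2 * time_min)),
      data = curve,
      start = list(A = max(curve$fluorescence), w = 0.25,
                   k1 = 10 * k_guess, k2 = k_guess),
      lower = c(A = 0, w = 0, k1 = 1e-6, k2 = 1e-6),
      upper = c(A = Inf, w = 1, k1 = Inf, k2 = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    k <- min(stats::coef(fit)[c("k1", "k2")])
    return(log(2) / k)
  }
  log(2) / .loglin_rate(curve, discard_initial)
}

# Elimination rate constant from a log-linear fit of the post-discard,
# positive-fluorescence segment.
.loglin_rate <- function(curve, discard_initial) {
  seg <- curve[curve$time_min >= discard_initial & curve$fluorescence > 0, ]
  if (nrow(seg) < 8)
    stop_data("elimination segment has %d usable points; >= 8 required",
              nrow(seg))
  fit <- stats::lm(log(fluorescence) ~ time_min, data = seg)
  slope <- stats::coef(fit)[["time_min"]]
  if (slope >= 0)
    stop_data("fluorescence does not decay over the elimination segment")
  -slope
}

#' GFR from the FITC-sinistrin half-life
#'
#' `GFR [ul/min] = conversion / t_half [min] * body_weight [g] / 100 [g]`,
#' with the empirical single-point conversion constant 14616.8 ul for the
#' transcutaneous FITC-sinistrin assay in mice.
#'
#' @param t_half plasma half-life (min).
#' @param body_weight body weight (g).
#' @param conversion empirical conversion factor (ul).
#' @return GFR in ul/min.
#' @examples
#' gfr_from_halflife(14616.8, 100)  # 1 ul/min
#' @export
gfr_from_halflife <- function(t_half, body_weight, conversion = 14616.8) {
  check_positive(t_half, "t_half")
  check_positive(body_weight, "body_weight")
  check_positive(conversion, "conversion")
  conversion / t_half * body_weight / 100
}

#' Normalize longitudinal GFR on baseline and sham
#'
#' Each animal's GFR is first expressed as a ratio to its own baseline
#' measurement, then divided by the sham-group mean ratio at the same time
#' point, so a sham animal tracking its group averages 1 throughout.
#'
#' @param series data.frame with columns `animal_id`, `group`
#'   (`"sham"` among the levels), `time`, `gfr`.
#' @param baseline_time time point used as each animal's baseline.
#' @return `series` with added columns `ratio` (to own baseline) and
#'   `gfr_norm` (ratio over the sham mean ratio).
#' @export
normalize_gfr <- function(series, baseline_time = NULL) {
  need <- c("animal_id", "group", "time", "gfr")
  if (!all(need %in% names(series)))
    stop_data("series must have columns: %s", paste(need, collapse = ", "))
  if (!any(series$group == "sham"))
    stop_data("series must contain a `sham` group")
  baseline_time <- baseline_time %||% min(series$time)

  base <- series[series$time == baseline_time, ]
  if (any(duplicated(base$animal_id)))
    stop_data("multiple baseline rows per animal at time %s",
              format(baseline_time))
  b <- stats::setNames(base$gfr, base$animal_id)
  missing <- setdiff(unique(series$animal_id), names(b))
  if (length(missing))
    stop_data("no baseline measurement for: %s", paste(missing, collapse = ", "))
  if (any(b <= 0)) stop_data("baseline GFR must be positive for all animals")

  series$ratio <- series$gfr / b[series$animal_id]
  sham_mean <- tapply(series$ratio[series$group == "sham"],
                      series$time[series$group == "sham"], mean)
  tkey <- as.character(series$time)
  if (!all(tkey %in% names(sham_mean)))
    stop_data("sham group missing at some time points")
  series$gfr_norm <- as.numeric(series$ratio / as.vector(sham_mean[tkey]))
  series
}

#' ChIP-qPCR sample
#'
#' @param ct_bound Ct of the immunoprecipitated (bound) fraction.
#' @param ct_input Ct of the input chromatin.
#' @param dilution_factor input dilution factor (> 0).
#' @param antibody `"specific"` or `"IgG"`.
#' @return object of class `chip_sample`.
#' @export
chip_sample <- function(ct_bound, ct_input, dilution_factor = 1,
                        antibody = c("specific", "IgG")) {
  antibody <- match.arg(antibody)
  for (nm in c("ct_bound", "ct_input")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop_config("`%s` must be a finite number", nm)
  }
  check_positive(dilution_factor, "dilution_factor")
  structure(list(ct_bound = ct_bound, ct_input = ct_input,
                 dilution_factor = dilution_factor, antibody = antibody),
            class = "chip_sample")
}

#' Dilution-corrected delta-Ct of one ChIP sample
#'
#' `dCt = Ct(bound) - (Ct(input) - log2(dilution_factor))`.
#'
#' @param sample a [chip_sample()].
#' @return delta-Ct in cycles.
#' @export
chip_delta_ct <- function(sample) {
  if (!inherits(sample, "chip_sample"))
    stop_config("`sample` must be built with chip_sample()")
  sample$ct_bound - (sample$ct_input - log2(sample$dilution_factor))
}

#' ChIP fold enrichment over IgG
#'
#' `FR = 2^-(dCt(specific) - dCt(IgG))`, the pulldown of the specific
#' antibody relative to a nonspecific IgG control at the same locus.
#' Identical dilution factors cancel exactly.
#'
#' @param specific,igg [chip_sample()] objects for the specific antibody
#'   and the IgG control.
#' @return fold enrichment (dimensionless).
#' @examples
#' chip_fold_enrichment(
#'   chip_sample(25, 20, 10, "specific"),
#'   chip_sample(27, 20, 10, "IgG"))  # 4
#' @export
chip_fold_enrichment <- function(specific, igg) {
  2^-(chip_delta_ct(specific) - chip_delta_ct(igg))
}
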