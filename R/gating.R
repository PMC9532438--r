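#' Gating configuration for FUCCI event classification
#'
#' @param mcherry_threshold,mvenus_threshold reporter-positivity cutoffs
#'   (a.u.), or `"auto"` to use 5x the channel's background median
#'   (estimated from events below the channel's lower quartile).
#' @param c2_anchor DNA intensity of the diploid G1 (2C) peak (a.u.), or
#'   `"auto"` to calibrate with [calibrate_dna_axis()].
#' @param bin_tolerance half-width of each C-window on the log2 DNA axis;
#'   events below the 2C window are sub-2C, events between or beyond
#'   windows go to the nearest peak.
#' @param doublet_width_max pulse-width cutoff above which events are
#'   excluded as doublets, or `"auto"` for the 99.5th percentile of a
#'   singlet calibration population (events narrower than 1.5x the median
#'   width).
#' @return object of class `gating_config`.
#' @export
gating_config <- function(mcherry_threshold = "auto",
                          mvenus_threshold = "auto",
                          c2_anchor = "auto",
                          bin_tolerance = 0.25,
                          doublet_width_max = "auto") {
  chk <- function(x, name) {
    if (!identical(x, "auto")) check_positive(x, name)
    x
  }
  chk(mcherry_threshold, "mcherry_threshold")
  chk(mvenus_threshold, "mvenus_threshold")
  chk(c2_anchor, "c2_anchor")
  chk(doublet_width_max, "doublet_width_max")
  if (!is.numeric(bin_tolerance) || bin_tolerance <= 0 || bin_tolerance >= 0.5)
    stop_config("`bin_tolerance` must be in (0, 0.5) log2 units")
  structure(list(mcherry_threshold = mcherry_threshold,
                 mvenus_threshold = mvenus_threshold,
                 c2_anchor = c2_anchor,
                 bin_tolerance = bin_tolerance,
                 doublet_width_max = doublet_width_max),
            class = "gating_config")
}

# 5x the background median of one reporter channel; the background is taken
# as the events at or below the channel's lower quartile, which is robust as
# long as under three quarters of events are positive in that channel.
.auto_threshold <- function(x) {
  bg <- x[x <= stats::quantile(x, 0.25)]
  5 * stats::median(bg)
}

.resolve_thresholds <- function(events, cfg) {
  list(
    mcherry = if (identical(cfg$mcherry_threshold, "auto"))
      .auto_threshold(events$mcherry) else cfg$mcherry_threshold,
    mvenus = if (identical(cfg$mvenus_threshold, "auto"))
      .auto_threshold(events$mvenus) else cfg$mvenus_threshold)
}

.check_events <- function(events) {
  need <- c("mcherry", "mvenus", "dna", "width")
  if (!all(need %in% names(events)))
    stop_data("event table must have columns: %s", paste(need, collapse = ", "))
  if (any(events$dna < 0) || any(events$mcherry < 0) || any(events$mvenus < 0))
    stop_data("intensities must be non-negative")
  invisible(events)
}

#' Calibrate the DNA axis from the G1 population
#'
#' Locates the 2C anchor as the mode of the DNA histogram of mCherry-only
#' events (nuclei in G1). The 4C and 8C peaks are then at 2x and 4x the
#' anchor. Requires at least 100 mCherry-only events.
#'
#' @param events event table (see [simulate_fucci_events()] for columns).
#' @param cfg a [gating_config()]; only the reporter thresholds are used.
#' @return the 2C anchor intensity (a.u.).
#' @export
calibrate_dna_axis <- function(events, cfg = gating_config()) {
  .check_events(events)
  thr <- .resolve_thresholds(events, cfg)
  g1 <- events$mcherry > thr$mcherry & events$mvenus <= thr$mvenus
  x <- events$dna[g1]
  x <- x[x > 0]
  if (length(x) < 100)
    stop_data("DNA-axis calibration needs >= 100 mCherry-only events (got %d)",
              length(x))
  lx <- log2(x)
  if (diff(range(lx)) < 1e-9) return(2^lx[1])
  d <- stats::density(lx, n = 1024)
  2^d$x[which.max(d$y)]
}

# Assign each DNA intensity to a bin given the 2C anchor: sub2C below the
# 2C window's lower edge, otherwise the nearest of the 2C/4C/8C+ peaks on
# the log2 axis (out-of-window values included).
.dna_bin <- function(dna, anchor, tol) {
  r <- log2(pmax(dna, .Machine$double.xmin) / anchor)
  k <- pmin(pmax(round(r), 0), 2)
  bins <- c("2C", "4C", "8C_plus")[k + 1L]
  bins[r < -tol] <- "sub2C"
  factor(bins, levels = c("sub2C", "2C", "4C", "8C_plus"))
}

#' Classify flow events into ploidy-by-cell-cycle categories
#'
#' Applies the FUCCI2aR gating map. Events wider than the doublet cutoff
#' are excluded; events negative in both reporter channels are non-induced.
#' The remaining reporter-positive singlets are mapped by (reporter state,
#' DNA bin):
#' \itemize{
#'   \item any reporter-positive event with sub-2C DNA is `dead`;
#'   \item mCherry-only at 2C is `diploid_G1`; at >=4C, `polyploid_noncycling`;
#'   \item double-positive at 2C is `cycling`; at >=4C, `polyploid_cycling`;
#'   \item mVenus-only at 2C or 4C is `cycling`; at >=8C, `polyploid_cycling`.
#' }
#'
#' @param events event table.
#' @param cfg a [gating_config()].
#' @return data.frame with `event_id` (if present in `events`), `class` and
#'   `dna_bin`; the resolved anchor, thresholds and width cutoff are
#'   attached as attribute `"gating"`.
#' @examples
#' ev <- simulate_fucci_events(fucci_sim_config(2000, seed = 1))
#' calls <- classify_events(ev)
#' table(calls$class)
#' @export
classify_events <- function(events, cfg = gating_config()) {
  .check_events(events)
  thr <- .resolve_thresholds(events, cfg)
  anchor <- if (identical(cfg$c2_anchor, "auto"))
    calibrate_dna_axis(events, cfg) else cfg$c2_anchor

  wmax <- cfg$doublet_width_max
  if (identical(wmax, "auto")) {
    singlet <- events$width[events$width < 1.5 * stats::median(events$width)]
    wmax <- stats::quantile(singlet, 0.995, names = FALSE)
  }

  mch <- events$mcherry > thr$mcherry
  mv <- events$mvenus > thr$mvenus
  bin <- .dna_bin(events$dna, anchor, cfg$bin_tolerance)

  cls <- rep("non_induced", nrow(events))
  pos <- mch | mv
  cls[pos & bin == "sub2C"] <- "dead"
  cls[mch & !mv & bin == "2C"] <- "diploid_G1"
  cls[mch & !mv & bin %in% c("4C", "8C_plus")] <- "polyploid_noncycling"
  cls[mch & mv & bin == "2C"] <- "cycling"
  cls[mch & mv & bin %in% c("4C", "8C_plus")] <- "polyploid_cycling"
  cls[!mch & mv & bin %in% c("2C", "4C")] <- "cycling"
  cls[!mch & mv & bin == "8C_plus"] <- "polyploid_cycling"
  cls[events$width > wmax] <- "doublet_excluded"

  out <- data.frame(
    event_id = events$event_id %||% seq_len(nrow(events)),
    class = factor(cls, levels = c("non_induced", "dead", "diploid_G1",
                                   "cycling", "polyploid_noncycling",
                                   "polyploid_cycling", "doublet_excluded")),
    dna_bin = bin)
  attr(out, "gating") <- list(c2_anchor = anchor,
                              mcherry_threshold = thr$mcherry,
                              mvenus_threshold = thr$mvenus,
                              doublet_width_max = wmax)
  out
}

#' Summarize per-sample class fractions
#'
#' Fractions are computed over induced singlet events only: doublet-excluded
#' and non-induced events are removed from the denominator, matching the
#' convention of normalizing on the per-mouse induction percentage.
#'
#' @param calls output of [classify_events()].
#' @return one-row data.frame with columns `dead`, `diploid_G1`, `cycling`,
#'   `polyploid_noncycling`, `polyploid_cycling`, `polyploid_total`,
#'   `n_events`. The first four plus `polyploid_total` sum to 1.
#' @export
summarize_sample <- function(calls) {
  if (!"class" %in% names(calls))
    stop_data("`calls` must be a classification table with a `class` column")
  keep <- !(calls$class %in% c("non_induced", "doublet_excluded"))
  n <- sum(keep)
  if (n == 0)
    stop_data("no induced singlet events: summary denominator is empty")
  f <- function(k) sum(calls$class[keep] == k) / n
  data.frame(dead = f("dead"),
             diploid_G1 = f("diploid_G1"),
             cycling = f("cycling"),
             polyploid_noncycling = f("polyploid_noncycling"),
             polyploid_cycling = f("polyploid_cycling"),
             polyploid_total = f("polyploid_noncycling") + f("polyploid_cycling"),
             n_events = n)
}

#' Redistribute the day-2 cycling pool over its day-3 fates
#'
#' Cells cycling at day 2 are, by day 3, either still cycling, dead, or
#' polyploid. Taking the day-2 cycling fraction as 100%, the three fates
#' get shares `p3_new / c2` (became polyploid), `d3 / c2` (died) and the
#' remainder (still cycling); shares are clipped at zero and renormalized
#' to sum to one.
#'
#' @param c2 cycling fraction at day 2 (must be > 0).
#' @param p3_new newly polyploid fraction at day 3 (day-3 polyploid minus
#'   any pre-existing baseline polyploidy, supplied by the caller).
#' @param d3 fraction that died between day 2 and day 3.
#' @return named numeric vector `still_cycling`, `died`, `became_polyploid`,
#'   summing to 1.
#' @examples
#' round(redistribute_cycling(0.398, 0.17, 0.196), 3)
#' @export
redistribute_cycling <- function(c2, p3_new, d3) {
  check_positive(c2, "c2")
  check_positive(p3_new, "p3_new", strict = FALSE)
  check_positive(d3, "d3", strict = FALSE)
  if (c2 == 0) stop_config("redistribution undefined for c2 = 0")
  poly <- p3_new / c2
  died <- d3 / c2
  shares <- pmax(c(still_cycling = 1 - poly - died, died = died,
                   became_polyploid = poly), 0)
  shares / sum(shares)
}
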