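# Per-nucleus PicoGreen DNA quantification: diploid-reference calibration,
# fold-over-diploid, and marker-stratified comparison.

.check_nuclei <- function(records) {
  need <- c("intensity", "background")
  if (!all(need %in% names(records)))
    stop_data("nucleus table must have columns: %s", paste(need, collapse = ", "))
  if (any(records$intensity < 0))
    stop_data("intensities must be non-negative")
  invisible(records)
}

#' Calibrate the diploid reference intensity
#'
#' Mean background-subtracted PicoGreen intensity of the designated diploid
#' internal-control nuclei (the healthy-biopsy 2C tubular cells imaged at
#' the same settings). At least 20 reference nuclei are required.
#'
#' @param records nucleus table with columns `intensity`, `background`,
#'   `reference_diploid` (and optionally `saturated`; saturated nuclei are
#'   dropped).
#' @param trim optional trim fraction passed to [mean()] as a guard against
#'   reference nuclei that are not truly diploid; 0 (default) is the plain
#'   mean.
#' @return the reference mean (a.u.), strictly positive.
#' @export
calibrate_diploid_reference <- function(records, trim = 0) {
  .check_nuclei(records)
  if (!"reference_diploid" %in% names(records))
    stop_data("nucleus table must flag `reference_diploid` nuclei")
  ref <- records[records$reference_diploid %in% TRUE, , drop = FALSE]
  if ("saturated" %in% names(ref)) ref <- ref[!ref$saturated, , drop = FALSE]
  if (nrow(ref) < 20)
    stop_data("diploid calibration needs >= 20 reference nuclei (got %d)",
              nrow(ref))
  m <- mean(ref$intensity - ref$background, trim = trim)
  if (m <= 0)
    stop_data("non-positive reference mean (%.3f): check background values", m)
  m
}

#' Per-nucleus DNA content as fold over diploid
#'
#' `fold = (intensity - background) / reference_mean`, so a diploid (2C)
#' nucleus scores 1.0 and a tetraploid (4C) nucleus 2.0. Negative folds
#' (background exceeding signal) are clipped to 0 and counted in the
#' `"n_clipped"` attribute. With `scale = "cvalue"` the result is doubled
#' onto the C-value scale (2C = 2).
#'
#' @param records nucleus table with `intensity` and `background`.
#' @param reference_mean diploid reference from
#'   [calibrate_diploid_reference()].
#' @param scale `"fold"` (over diploid, default) or `"cvalue"`.
#' @return numeric vector of folds with attribute `n_clipped`.
#' @export
ploidy_fold <- function(records, reference_mean, scale = c("fold", "cvalue")) {
  .check_nuclei(records)
  scale <- match.arg(scale)
  check_positive(reference_mean, "reference_mean")
  fold <- (records$intensity - records$background) / reference_mean
  n_neg <- sum(fold < 0)
  if (n_neg > 0)
    warning(sprintf("%d negative fold value(s) clipped to 0", n_neg))
  fold <- pmax(fold, 0)
  if (scale == "cvalue") fold <- 2 * fold
  structure(fold, n_clipped = n_neg)
}

#' Compare DNA-content folds between marker groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test of per-nucleus folds
#' between marker-positive and marker-negative nuclei, the standard test
#' for e.g. YAP1-positive versus YAP1-negative tubular nuclei.
#'
#' @param folds numeric vector of fold-over-diploid values.
#' @param labels logical (or two-level) vector of marker status, parallel
#'   to `folds`.
#' @return list with `statistic` (Mann-Whitney U of the first group),
#'   `p_value`, `median_positive`, `median_negative`, `n_positive`,
#'   `n_negative`.
#' @export
compare_marker_groups <- function(folds, labels) {
  if (length(folds) != length(labels))
    stop_data("`folds` and `labels` must have the same length")
  if (is.logical(labels)) {
    pos <- folds[labels]
    neg <- folds[!labels]
  } else {
    lv <- unique(labels)
    if (length(lv) != 2)
      stop_data("`labels` must have exactly two groups (got %d)", length(lv))
    pos <- folds[labels == lv[1]]
    neg <- folds[labels == lv[2]]
  }
  if (length(pos) == 0 || length(neg) == 0)
    stop_data("both marker groups must be non-empty")
  wt <- suppressWarnings(
    stats::wilcox.test(pos, neg, alternative = "two.sided", exact = NULL))
  list(statistic = unname(wt$statistic),
       p_value = wt$p.value,
       median_positive = stats::median(pos),
       median_negative = stats::median(neg),
       n_positive = length(pos),
       n_negative = length(neg))
}
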