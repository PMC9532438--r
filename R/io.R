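# CSV ingestion with column validation. All tables are plain CSVs with a
# header row, as written by the simulators and by run_pipeline().

.read_validated_csv <- function(path, required, what) {
  if (!file.exists(path)) stop_data("%s file not found: %s", what, path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_data("%s file %s is missing column(s): %s",
              what, path, paste(missing, collapse = ", "))
  df
}

#' Read a flow-cytometry event table
#'
#' Expects the column layout written by [simulate_fucci_events()]:
#' `mcherry`, `mvenus`, `dna`, `width` are required; ground-truth columns
#' are carried through when present.
#'
#' @param path CSV path.
#' @return event data.frame.
#' @export
read_flow_events <- function(path) {
  .read_validated_csv(path, c("mcherry", "mvenus", "dna", "width"), "event")
}

#' Read a Confetti tally table
#'
#' One row per region with columns `region`, `n_total_tc`, `n_coloured`,
#' `n_bicoloured` and optionally `n_gfp_excluded`.
#'
#' @param path CSV path.
#' @return list of [confetti_tally()] objects, one per row.
#' @export
read_confetti_tallies <- function(path) {
  df <- .read_validated_csv(
    path, c("region", "n_total_tc", "n_coloured", "n_bicoloured"), "tally")
  if (!"n_gfp_excluded" %in% names(df)) df$n_gfp_excluded <- 0L
  lapply(seq_len(nrow(df)), function(i)
    confetti_tally(df$n_total_tc[i], df$n_coloured[i], df$n_bicoloured[i],
                   df$n_gfp_excluded[i], df$region[i]))
}

#' Read a per-nucleus intensity table
#'
#' @param path CSV path with columns `intensity`, `background`,
#'   `marker_positive`, `tubular`, `reference_diploid`.
#' @return nucleus data.frame.
#' @export
read_nuclei <- function(path) {
  df <- .read_validated_csv(
    path, c("intensity", "background", "marker_positive", "reference_diploid"),
    "nucleus")
  for (col in c("marker_positive", "tubular", "reference_diploid"))
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  df
}

#' Read a decay time series
#'
#' @param path CSV path with columns `time_min`, `fluorescence` (and
#'   optionally `animal_id`, `body_weight_g`).
#' @return decay data.frame.
#' @export
read_decay_curve <- function(path) {
  .read_validated_csv(path, c("time_min", "fluorescence"), "decay")
}

#' Read a ChIP-qPCR Ct table
#'
#' @param path CSV path with columns `sample_id`, `antibody`, `ct_bound`,
#'   `ct_input`, `dilution_factor`.
#' @return ChIP data.frame.
#' @export
read_chip_table <- function(path) {
  .read_validated_csv(
    path, c("antibody", "ct_bound", "ct_input", "dilution_factor"), "ChIP")
}
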