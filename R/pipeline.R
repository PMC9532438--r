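#' Default pipeline configuration
#'
#' Nested list consumed by [run_pipeline()]. Top level: `seed` (global seed
#' fanned out to stages as `seed + stage index`), `stages` (subset of
#' `"fucci"`, `"confetti"`, `"nuclei"`, `"gfr"`, `"chip"`), and one block
#' per stage with generator parameters, or a `*_csv` path to analyse an
#' existing table instead of simulating one.
#'
#' @param seed global integer seed.
#' @return configuration list.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    stages = c("fucci", "confetti", "nuclei", "gfr", "chip"),
    fucci = list(n_cells = 10000, preset = "day2"),
    confetti = list(n_cells = 20000, polyploid_fraction = 0.15),
    nuclei = list(n_nuclei = 400,
                  marker_effect = c(`2C` = 0.45, `4C` = 0.45, `8C` = 0.10)),
    gfr = list(gfr_true = 250, body_weight = 25),
    chip = list(true_fr = 4))
}

.all_stages <- c("fucci", "confetti", "nuclei", "gfr", "chip")

.write_stage_csv <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

.stage_fucci <- function(blk, seed, dir) {
  if (!is.null(blk$events_csv)) {
    events <- read_flow_events(blk$events_csv)
  } else {
    cfg <- fucci_sim_config(
      n_cells = blk$n_cells %||% 10000,
      class_probs = fucci_preset(blk$preset %||% "day2"),
      dna_cv = blk$dna_cv %||% 0.06,
      doublet_rate = blk$doublet_rate %||% 0.05,
      induction_rate = blk$induction_rate %||% 0.85,
      seed = seed)
    events <- simulate_fucci_events(cfg)
  }
  calls <- classify_events(events, gating_config())
  summary <- summarize_sample(calls)
  c(.write_stage_csv(events, dir, "fucci_events.csv"),
    .write_stage_csv(calls, dir, "fucci_calls.csv"),
    .write_stage_csv(summary, dir, "fucci_summary.csv"))
}

.stage_confetti <- function(blk, seed, dir) {
  if (!is.null(blk$tally_csv)) {
    tallies <- read_confetti_tallies(blk$tally_csv)
    files <- character(0)
  } else {
    cfg <- confetti_sim_config(
      n_cells = blk$n_cells %||% 20000,
      polyploid_fraction = blk$polyploid_fraction %||% 0.15,
      induction_efficiency = blk$induction_efficiency %||% 0.847,
      seed = seed)
    cells <- simulate_confetti(cfg)
    tallies <- list(tally_confetti(cells))
    files <- .write_stage_csv(cells, dir, "confetti_cells.csv")
  }
  est <- lapply(tallies, estimate_polyploid_fraction,
                n_bootstrap = blk$n_bootstrap %||% 2000, seed = seed)
  df <- do.call(rbind, lapply(est, function(e) data.frame(
    region = e$region, n_coloured = e$n_coloured,
    bicoloured_pct = 100 * e$b_obs, efficiency_pct = 100 * e$efficiency,
    efficiency_normalized_pct = e$b_corrected_pct,
    polyploid_fraction_pct = 100 * e$p_hat,
    ci_low_pct = 100 * e$ci_low, ci_high_pct = 100 * e$ci_high)))
  c(files, .write_stage_csv(df, dir, "confetti_estimate.csv"))
}

.stage_nuclei <- function(blk, seed, dir) {
  if (!is.null(blk$nuclei_csv)) {
    nuc <- read_nuclei(blk$nuclei_csv)
    files <- character(0)
  } else {
    me <- blk$marker_effect
    if (!is.null(me)) me <- stats::setNames(unlist(me), names(me))
    cfg <- nuclei_sim_config(n_nuclei = blk$n_nuclei %||% 400,
                             marker_effect = me, seed = seed)
    nuc <- simulate_nuclei(cfg)
    files <- .write_stage_csv(nuc, dir, "nuclei.csv")
  }
  ref <- calibrate_diploid_reference(nuc)
  study <- nuc[!nuc$reference_diploid, , drop = FALSE]
  folds <- ploidy_fold(study, ref)
  cmp <- compare_marker_groups(folds, study$marker_positive)
  fold_df <- data.frame(nucleus_id = study$nucleus_id,
                        fold_over_diploid = as.numeric(folds),
                        marker_positive = study$marker_positive)
  test_df <- data.frame(reference_mean = ref,
                        U = cmp$statistic, p_value = cmp$p_value,
                        median_positive = cmp$median_positive,
                        median_negative = cmp$median_negative,
                        n_positive = cmp$n_positive,
                        n_negative = cmp$n_negative)
  c(files, .write_stage_csv(fold_df, dir, "ploidy_folds.csv"),
    .write_stage_csv(test_df, dir, "marker_test.csv"))
}

.stage_gfr <- function(blk, seed, dir) {
  if (!is.null(blk$decay_csv)) {
    curve <- read_decay_curve(blk$decay_csv)
    bw <- blk$body_weight %||% stop_data("`body_weight` required with decay_csv")
    files <- character(0)
  } else {
    cfg <- decay_sim_config(gfr_true = blk$gfr_true %||% 250,
                            body_weight = blk$body_weight %||% 25,
                            seed = seed)
    curve <- simulate_decay(cfg)
    bw <- cfg$body_weight
    files <- .write_stage_csv(curve, dir, "decay_curve.csv")
  }
  t_half <- fit_halflife(curve, discard_initial = blk$discard_initial %||% 10)
  gfr <- gfr_from_halflife(t_half, bw)
  fit_df <- data.frame(t_half_min = t_half, body_weight_g = bw,
                       gfr_ul_min = gfr)
  c(files, .write_stage_csv(fit_df, dir, "gfr_fit.csv"))
}

.stage_chip <- function(blk, seed, dir) {
  if (!is.null(blk$chip_csv)) {
    chip <- read_chip_table(blk$chip_csv)
    files <- character(0)
  } else {
    chip <- simulate_chip(true_fr = blk$true_fr %||% 4, seed = seed)
    files <- .write_stage_csv(chip, dir, "chip_samples.csv")
  }
  spec <- chip[chip$antibody == "specific", , drop = FALSE]
  igg <- chip[chip$antibody == "IgG", , drop = FALSE]
  if (nrow(spec) == 0 || nrow(igg) == 0)
    stop_data("ChIP table needs both `specific` and `IgG` rows")
  mk <- function(row, ab) chip_sample(mean(row$ct_bound), mean(row$ct_input),
                                      row$dilution_factor[1], ab)
  fr <- chip_fold_enrichment(mk(spec, "specific"), mk(igg, "IgG"))
  c(files, .write_stage_csv(
    data.frame(fold_enrichment = fr), dir, "chip_enrichment.csv"))
}

#' Run the full quantification pipeline
#'
#' Executes the requested stages in a fixed order, writes one CSV set per
#' stage plus a JSON manifest recording the configuration, the per-stage
#' seeds and the MD5 checksum of every output file. The same configuration
#' and seed always produce byte-identical outputs.
#'
#' @param config configuration list (see [default_pipeline_config()]) or a
#'   path to a YAML file with the same structure.
#' @param out_dir output directory, created if needed.
#' @return the manifest (class `ploidyscope_manifest`), invisibly.
#' @examples
#' \donttest{
#' dir <- tempfile()
#' m <- run_pipeline(default_pipeline_config(seed = 1), dir)
#' names(m$files)
#' }
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop_config("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_config("`config` must be a list or a YAML path")
  seed <- config$seed %||% 1L
  if (!is.numeric(seed)) stop_config("`seed` must be an integer")
  stages <- config$stages %||% .all_stages
  bad <- setdiff(stages, .all_stages)
  if (length(bad))
    stop_config("unknown stage(s): %s", paste(bad, collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  files <- character(0)
  stage_seeds <- list()
  runner <- list(fucci = .stage_fucci, confetti = .stage_confetti,
                 nuclei = .stage_nuclei, gfr = .stage_gfr,
                 chip = .stage_chip)
  for (st in .all_stages[.all_stages %in% stages]) {
    st_seed <- as.integer(seed) + match(st, .all_stages)
    stage_seeds[[st]] <- st_seed
    files <- c(files, runner[[st]](config[[st]] %||% list(), st_seed, out_dir))
  }

  checksums <- as.list(tools::md5sum(files))
  names(checksums) <- basename(files)
  manifest <- structure(list(
    package = "ploidyscope",
    version = as.character(utils::packageVersion("ploidyscope")),
    created = format(Sys.time(), tz = "UTC"),
    seed = as.integer(seed),
    stages = I(stages),
    stage_seeds = stage_seeds,
    out_dir = normalizePath(out_dir),
    files = checksums), class = "ploidyscope_manifest")
  jsonlite::write_json(unclass(manifest), file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Worked reference calculations
#'
#' Recomputes, at call time, the closed-form quantities of the workflow on
#' canonical inputs: the two-draw colour combinatorics, the efficiency
#' normalization of a 13.3% bi-coloured count at 84.7% recombination
#' efficiency, the cortical fold-change over a 5.9% sham count, the
#' redistribution of a 39.8% cycling pool given 17% newly polyploid and
#' 19.6% dead, the GFR conversion identity, and a hand-checkable ChIP fold
#' enrichment. Percentages are displayed to one decimal.
#'
#' @return data.frame with columns `quantity`, `value`, `display`.
#' @export
worked_examples <- function() {
  redis <- redistribute_cycling(0.398, 0.17, 0.196)
  fr <- chip_fold_enrichment(chip_sample(25, 20, 10, "specific"),
                             chip_sample(27, 20, 10, "IgG"))
  vals <- c(
    bicoloured_prob_pct = 100 * p_bicoloured(3),
    duplicate_prob_pct = 100 * (1 - p_bicoloured(3)),
    efficiency_normalized_bicoloured_pct = correct_for_efficiency(13.3, 0.847),
    cortex_fold_over_sham = 13.3 / 5.9,
    became_polyploid_pct = 100 * redis[["became_polyploid"]],
    died_pct = 100 * redis[["died"]],
    still_cycling_pct = 100 * redis[["still_cycling"]],
    gfr_unit_check_ul_min = gfr_from_halflife(14616.8, 100),
    chip_fold_enrichment = fr)
  data.frame(
    quantity = names(vals),
    value = unname(vals),
    display = ifelse(grepl("_pct$", names(vals)),
                     sprintf("%.1f%%", vals), sprintf("%.2f", vals)))
}

.read_manifest <- function(manifest) {
  if (is.character(manifest) && length(manifest) == 1L) {
    if (!file.exists(manifest)) stop_data("manifest not found: %s", manifest)
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  }
  if (!is.list(manifest) || is.null(manifest$files) ||
      length(manifest$files) == 0)
    stop_data("manifest is empty or incomplete")
  manifest
}

#' Report on a completed pipeline run
#'
#' Reads the outputs referenced by a run manifest and assembles the summary
#' tables: per-sample FUCCI fractions (as percentages, with their sum),
#' Confetti estimates with both the efficiency-normalized percentage and
#' the combinatoric polyploid-fraction estimate labelled separately, the
#' DNA-fold distribution by marker group, the GFR fit and the ChIP
#' enrichment. Also writes `report.md` (and, with `plots = TRUE`, PNG
#' histograms) into the run directory.
#'
#' @param manifest a `ploidyscope_manifest` or path to `manifest.json`.
#' @param plots also write PNG figures (DNA histogram, fold distribution).
#' @return named list of data.frames, invisibly.
#' @export
pipeline_report <- function(manifest, plots = FALSE) {
  manifest <- .read_manifest(manifest)
  dir <- manifest$out_dir
  path <- function(f) file.path(dir, f)
  have <- function(f) f %in% names(manifest$files) && file.exists(path(f))
  tables <- list()

  if (have("fucci_summary.csv")) {
    s <- utils::read.csv(path("fucci_summary.csv"))
    pct <- round(100 * s[, c("dead", "diploid_G1", "cycling",
                             "polyploid_total")], 1)
    pct$total <- rowSums(pct)
    pct$n_events <- s$n_events
    tables$fucci_fractions_pct <- pct
    poly <- round(100 * s[, c("polyploid_noncycling", "polyploid_cycling")], 1)
    tables$fucci_polyploid_split_pct <- poly
  }
  if (have("confetti_estimate.csv")) {
    ce <- utils::read.csv(path("confetti_estimate.csv"))
    tables$confetti <- data.frame(
      region = ce$region,
      bicoloured_pct = round(ce$bicoloured_pct, 1),
      efficiency_pct = round(ce$efficiency_pct, 1),
      efficiency_normalized_bicoloured_pct =
        round(ce$efficiency_normalized_pct, 1),
      polyploid_fraction_3_2_b_pct = round(ce$polyploid_fraction_pct, 1),
      ci_pct = sprintf("[%.1f, %.1f]", ce$ci_low_pct, ce$ci_high_pct))
  }
  if (have("ploidy_folds.csv")) {
    pf <- utils::read.csv(path("ploidy_folds.csv"))
    agg <- stats::aggregate(fold_over_diploid ~ marker_positive, pf,
                            function(x) c(n = length(x), median = stats::median(x),
                                          mean = mean(x)))
    tables$ploidy_folds <- do.call(data.frame, agg)
    if (have("marker_test.csv"))
      tables$marker_test <- utils::read.csv(path("marker_test.csv"))
  }
  if (have("gfr_fit.csv")) tables$gfr <- utils::read.csv(path("gfr_fit.csv"))
  if (have("chip_enrichment.csv"))
    tables$chip <- utils::read.csv(path("chip_enrichment.csv"))
  tables$worked_examples <- worked_examples()

  lines <- c("# ploidyscope run report", "",
             sprintf("- seed: %s", manifest$seed),
             sprintf("- stages: %s", paste(manifest$stages, collapse = ", ")),
             "")
  for (nm in names(tables)) {
    lines <- c(lines, sprintf("## %s", nm), "```",
               utils::capture.output(print(tables[[nm]])), "```", "")
  }
  writeLines(lines, path("report.md"))

  if (plots) {
    if (have("fucci_events.csv")) {
      ev <- utils::read.csv(path("fucci_events.csv"))
      grDevices::png(path("dna_histogram.png"), width = 700, height = 500)
      graphics::hist(log2(ev$dna[ev$dna > 0]), breaks = 100,
                     main = "DNA content (log2)", xlab = "log2 intensity")
      grDevices::dev.off()
    }
    if (have("ploidy_folds.csv")) {
      pf <- utils::read.csv(path("ploidy_folds.csv"))
      grDevices::png(path("ploidy_folds.png"), width = 700, height = 500)
      graphics::hist(pf$fold_over_diploid, breaks = 40,
                     main = "DNA content over diploid", xlab = "fold")
      grDevices::dev.off()
    }
  }
  invisible(tables)
}
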