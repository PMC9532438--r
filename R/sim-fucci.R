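#' FUCCI flow-cytometry simulation configuration
#'
#' Builds a validated configuration for [simulate_fucci_events()]. The
#' generator emulates a fixed, stained single-cell suspension of tubular
#' cells carrying the FUCCI2aR reporter: mCherry-hCdt1 marks G1 nuclei,
#' mVenus-hGem marks S/G2/M nuclei, both channels are high at the G1/S
#' boundary, and a DNA stain reports total DNA content (C-value).
#'
#' Ground-truth classes and how they present on the instrument:
#' \describe{
#'   \item{dead}{reporter-positive debris with sub-2C DNA, drawn uniformly
#'     over `dead_dna_range` (C-units).}
#'   \item{diploid_G1}{mCherry-only, exactly 2C.}
#'   \item{diploid_cycling}{a mix of G1/S boundary (both channels, 2C),
#'     S phase (mVenus-only, DNA uniform in (2C, 4C)) and G2/M
#'     (mVenus-only, 4C).}
#'   \item{polyploid_4C_G1}{mCherry-only, 4C: a tetraploid cell in G1.}
#'   \item{polyploid_cycling_4C}{double-positive tetraploid re-entering the
#'     cycle; DNA 4C at the boundary or uniform in (4C, 8C) during
#'     endoreplication.}
#'   \item{polyploid_cycling_8C}{mVenus-only with 8C DNA.}
#' }
#'
#' DNA intensity is `gain * C-value * lognormal(1, dna_cv)`; doublets are
#' sums of two independent singlets with summed pulse width; non-induced
#' cells show background in both reporter channels.
#'
#' @param n_cells number of events to generate.
#' @param class_probs named probability vector over the six ground-truth
#'   classes (see Details); defaults to the day-2 post-injury preset of
#'   [fucci_preset()].
#' @param dna_cv coefficient of variation of the multiplicative DNA-stain
#'   noise (0.06 is a typical DAPI histogram width).
#' @param doublet_rate probability that an event is a doublet.
#' @param induction_rate probability that a cell expresses the reporter at
#'   all; non-induced cells sit at channel background.
#' @param gain DNA-stain intensity per C-unit (a.u.), so a diploid G1
#'   nucleus averages `2 * gain`.
#' @param dead_dna_range C-value range (length 2, both < 2) for dead-cell
#'   DNA content.
#' @param reporter_background,reporter_positive mean intensity (a.u.) of a
#'   negative and a positive reporter channel.
#' @param reporter_cv coefficient of variation of reporter intensities.
#' @param width_mean,width_cv pulse-width mean (a.u.) and coefficient of
#'   variation for singlets.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return an object of class `fucci_sim_config`.
#' @seealso [simulate_fucci_events()], [fucci_preset()]
#' @export
fucci_sim_config <- function(n_cells,
                             class_probs = fucci_preset("day2"),
                             dna_cv = 0.06,
                             doublet_rate = 0.05,
                             induction_rate = 0.85,
                             gain = 100,
                             dead_dna_range = c(0.5, 1.65),
                             reporter_background = 10,
                             reporter_positive = 1000,
                             reporter_cv = 0.3,
                             width_mean = 50,
                             width_cv = 0.05,
                             seed = 1L) {
  n_cells <- check_count(n_cells, "n_cells")
  class_probs <- check_prob_vector(class_probs, "class_probs", fucci_classes())
  check_positive(dna_cv, "dna_cv", strict = FALSE)
  check_prob(doublet_rate, "doublet_rate")
  check_prob(induction_rate, "induction_rate")
  check_positive(gain, "gain")
  if (length(dead_dna_range) != 2L || any(dead_dna_range <= 0) ||
      dead_dna_range[1] >= dead_dna_range[2] || dead_dna_range[2] >= 2)
    stop_config("`dead_dna_range` must be an increasing pair within (0, 2) C-units")
  check_positive(reporter_background, "reporter_background")
  check_positive(reporter_positive, "reporter_positive")
  check_positive(reporter_cv, "reporter_cv", strict = FALSE)
  check_positive(width_mean, "width_mean")
  check_positive(width_cv, "width_cv", strict = FALSE)
  structure(list(n_cells = n_cells, class_probs = class_probs,
                 dna_cv = dna_cv, doublet_rate = doublet_rate,
                 induction_rate = induction_rate, gain = gain,
                 dead_dna_range = dead_dna_range,
                 reporter_background = reporter_background,
                 reporter_positive = reporter_positive,
                 reporter_cv = reporter_cv,
                 width_mean = width_mean, width_cv = width_cv,
                 seed = as.integer(seed)),
            class = "fucci_sim_config")
}

#' Ground-truth class labels used by the FUCCI simulator
#' @return character vector of the six class names.
#' @export
fucci_classes <- function() {
  c("dead", "diploid_G1", "diploid_cycling",
    "polyploid_4C_G1", "polyploid_cycling_4C", "polyploid_cycling_8C")
}

#' Tubular-cell composition presets
#'
#' Class-probability presets emulating the population structure of a
#' unilateral ischemia-reperfusion time course: a healthy kidney
#' (`"healthy"`, almost all diploid G1), the peak of cell-cycle entry two
#' days after injury (`"day2"`, 39.8% cycling), and day 3 (`"day3"`, cycling
#' collapsed to 8.8% with 17% of cells now at >=4C).
#'
#' @param name one of `"healthy"`, `"day2"`, `"day3"`.
#' @return named probability vector over [fucci_classes()].
#' @export
fucci_preset <- function(name = c("day2", "day3", "healthy")) {
  name <- match.arg(name)
  p <- switch(name,
    healthy = c(dead = 0.010, diploid_G1 = 0.920, diploid_cycling = 0.030,
                polyploid_4C_G1 = 0.030, polyploid_cycling_4C = 0.005,
                polyploid_cycling_8C = 0.005),
    day2 = c(dead = 0.072, diploid_G1 = 0.450, diploid_cycling = 0.398,
             polyploid_4C_G1 = 0.050, polyploid_cycling_4C = 0.020,
             polyploid_cycling_8C = 0.010),
    day3 = c(dead = 0.150, diploid_G1 = 0.592, diploid_cycling = 0.088,
             polyploid_4C_G1 = 0.119, polyploid_cycling_4C = 0.035,
             polyploid_cycling_8C = 0.016))
  check_prob_vector(p, name, fucci_classes())
}

# Draw per-cell (C-value, reporter state) for n cells of known class.
# Reporter state: "mcherry", "mvenus", "both", coded per FUCCI2aR biology.
.fucci_draw_cells <- function(classes, cfg) {
  n <- length(classes)
  cval <- numeric(n)
  rep_state <- character(n)

  idx <- which(classes == "dead")
  if (length(idx)) {
    cval[idx] <- stats::runif(length(idx), cfg$dead_dna_range[1],
                              cfg$dead_dna_range[2])
    # dying cells present as cycling on the reporter (mVenus or double-positive)
    rep_state[idx] <- sample(c("mvenus", "both"), length(idx), replace = TRUE)
  }
  idx <- which(classes == "diploid_G1")
  if (length(idx)) { cval[idx] <- 2; rep_state[idx] <- "mcherry" }
  idx <- which(classes == "diploid_cycling")
  if (length(idx)) {
    phase <- sample(c("boundary", "S", "G2M"), length(idx), replace = TRUE,
                    prob = c(0.3, 0.4, 0.3))
    cval[idx] <- ifelse(phase == "boundary", 2,
                 ifelse(phase == "G2M", 4, stats::runif(length(idx), 2, 4)))
    rep_state[idx] <- ifelse(phase == "boundary", "both", "mvenus")
  }
  idx <- which(classes == "polyploid_4C_G1")
  if (length(idx)) { cval[idx] <- 4; rep_state[idx] <- "mcherry" }
  idx <- which(classes == "polyploid_cycling_4C")
  if (length(idx)) {
    endo <- stats::runif(length(idx)) < 0.5
    cval[idx] <- ifelse(endo, stats::runif(length(idx), 4, 8), 4)
    rep_state[idx] <- "both"
  }
  idx <- which(classes == "polyploid_cycling_8C")
  if (length(idx)) { cval[idx] <- 8; rep_state[idx] <- "mvenus" }

  dna <- cfg$gain * cval * rlnorm_cv1(n, cfg$dna_cv)
  induced <- stats::runif(n) < cfg$induction_rate
  mch_on <- induced & rep_state %in% c("mcherry", "both")
  mv_on <- induced & rep_state %in% c("mvenus", "both")
  mcherry <- ifelse(mch_on, cfg$reporter_positive, cfg$reporter_background) *
    rlnorm_cv1(n, cfg$reporter_cv)
  mvenus <- ifelse(mv_on, cfg$reporter_positive, cfg$reporter_background) *
    rlnorm_cv1(n, cfg$reporter_cv)
  width <- cfg$width_mean * rlnorm_cv1(n, cfg$width_cv)
  data.frame(mcherry = mcherry, mvenus = mvenus, dna = dna, width = width,
             true_class = classes, induced = induced)
}

#' Simulate FUCCI2aR flow-cytometry events
#'
#' Generates a seeded event table with ground truth for every event:
#' singlets carry their true class; doublets are built by summing the DNA,
#' reporter and pulse-width signals of two independent singlets and are
#' flagged `is_doublet` with `true_class = NA`.
#'
#' @param cfg a [fucci_sim_config()].
#' @return data.frame with columns `event_id`, `mcherry`, `mvenus`, `dna`,
#'   `width`, `true_class`, `is_doublet`, `induced`.
#' @examples
#' ev <- simulate_fucci_events(fucci_sim_config(1000, seed = 7))
#' table(ev$true_class, useNA = "ifany")
#' @export
simulate_fucci_events <- function(cfg) {
  if (!inherits(cfg, "fucci_sim_config"))
    stop_config("`cfg` must be built with fucci_sim_config()")
  set.seed(cfg$seed)
  n <- cfg$n_cells
  is_doublet <- stats::runif(n) < cfg$doublet_rate
  n_d <- sum(is_doublet)
  # cells needed: one per singlet event, two per doublet event
  classes <- sample(names(cfg$class_probs), n + n_d, replace = TRUE,
                    prob = cfg$class_probs)
  cells <- .fucci_draw_cells(classes, cfg)

  out <- cells[seq_len(n), ]
  if (n_d > 0) {
    extra <- cells[n + seq_len(n_d), ]
    di <- which(is_doublet)
    for (col in c("mcherry", "mvenus", "dna", "width"))
      out[[col]][di] <- out[[col]][di] + extra[[col]]
    out$true_class[di] <- NA_character_
    out$induced[di] <- out$induced[di] | extra$induced
  }
  data.frame(event_id = seq_len(n),
             mcherry = out$mcherry, mvenus = out$mvenus,
             dna = out$dna, width = out$width,
             true_class = out$true_class,
             is_doublet = is_doublet,
             induced = out$induced)
}
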