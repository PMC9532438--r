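#' Confetti reporter simulation configuration
#'
#' The Confetti reporter fixes one randomly chosen fluorochrome per
#' recombination event. A diploid cell recombines once and becomes
#' mono-coloured; a tetraploid (4C) cell carries two reporter cassettes and
#' recombines twice, independently, so it can end up bi-coloured or
#' twice-the-same-colour. RFP, YFP and CFP recombine with equal probability;
#' GFP is rare and is excluded from downstream counting.
#'
#' @param n_cells number of tubular cells.
#' @param polyploid_fraction probability that a cell is polyploid (4C).
#' @param induction_efficiency probability that the reporter recombined at
#'   all (0.847 matches the efficiency measured in the motivating system).
#' @param colour_probs named probability vector over `RFP`, `YFP`, `CFP`,
#'   `GFP`; GFP should be rare.
#' @param seed integer seed.
#' @return object of class `confetti_sim_config`.
#' @export
confetti_sim_config <- function(n_cells,
                                polyploid_fraction = 0.15,
                                induction_efficiency = 0.847,
                                colour_probs = c(RFP = 0.33, YFP = 0.33,
                                                 CFP = 0.33, GFP = 0.01),
                                seed = 1L) {
  n_cells <- check_count(n_cells, "n_cells")
  check_prob(polyploid_fraction, "polyploid_fraction")
  check_prob(induction_efficiency, "induction_efficiency")
  colour_probs <- check_prob_vector(colour_probs, "colour_probs",
                                    c("RFP", "YFP", "CFP", "GFP"))
  structure(list(n_cells = n_cells,
                 polyploid_fraction = polyploid_fraction,
                 induction_efficiency = induction_efficiency,
                 colour_probs = colour_probs,
                 seed = as.integer(seed)),
            class = "confetti_sim_config")
}

#' Simulate stochastic Confetti recombination
#'
#' Each cell is induced with probability `induction_efficiency`. An induced
#' diploid draws one colour; an induced polyploid draws two independent
#' colours from `colour_probs`. Non-induced cells record no colour.
#'
#' @param cfg a [confetti_sim_config()].
#' @return data.frame with columns `cell_id`, `colour1`, `colour2` (NA for
#'   diploid or non-induced cells), `induced`, `true_polyploid`.
#' @examples
#' cells <- simulate_confetti(confetti_sim_config(500, seed = 3))
#' head(cells)
#' @export
simulate_confetti <- function(cfg) {
  if (!inherits(cfg, "confetti_sim_config"))
    stop_config("`cfg` must be built with confetti_sim_config()")
  set.seed(cfg$seed)
  n <- cfg$n_cells
  polyploid <- stats::runif(n) < cfg$polyploid_fraction
  induced <- stats::runif(n) < cfg$induction_efficiency
  cols <- names(cfg$colour_probs)
  colour1 <- rep(NA_character_, n)
  colour2 <- rep(NA_character_, n)
  idx <- which(induced)
  colour1[idx] <- sample(cols, length(idx), replace = TRUE,
                         prob = cfg$colour_probs)
  idx2 <- which(induced & polyploid)
  colour2[idx2] <- sample(cols, length(idx2), replace = TRUE,
                          prob = cfg$colour_probs)
  data.frame(cell_id = seq_len(n), colour1 = colour1, colour2 = colour2,
             induced = induced, true_polyploid = polyploid)
}

#' Tally a simulated (or imported) Confetti cell table
#'
#' Reduces a per-cell colour table to the counts used by the estimator,
#' mirroring how sections are scored: GFP-containing cells are excluded
#' from both numerator and denominator; bi-coloured means two distinct
#' colours among RFP/YFP/CFP.
#'
#' @param cells data.frame as returned by [simulate_confetti()].
#' @param region optional region label stored in the tally.
#' @return a [confetti_tally()].
#' @export
tally_confetti <- function(cells, region = "sim") {
  need <- c("colour1", "colour2", "induced")
  if (!all(need %in% names(cells)))
    stop_data("cell table must have columns: %s", paste(need, collapse = ", "))
  ind <- cells[cells$induced, , drop = FALSE]
  has_gfp <- (!is.na(ind$colour1) & ind$colour1 == "GFP") |
    (!is.na(ind$colour2) & ind$colour2 == "GFP")
  kept <- ind[!has_gfp, , drop = FALSE]
  bi <- !is.na(kept$colour2) & kept$colour2 != kept$colour1
  confetti_tally(n_total_tc = nrow(cells),
                 n_coloured = nrow(kept),
                 n_bicoloured = sum(bi),
                 n_gfp_excluded = sum(has_gfp),
                 region = region)
}
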