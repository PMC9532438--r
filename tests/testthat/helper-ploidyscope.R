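# Shared fixtures built in code.

# Map from generator ground-truth classes to the gated category each one
# must land in.
truth_to_gate <- c(dead = "dead",
                   diploid_G1 = "diploid_G1",
                   diploid_cycling = "cycling",
                   polyploid_4C_G1 = "polyploid_noncycling",
                   polyploid_cycling_4C = "polyploid_cycling",
                   polyploid_cycling_8C = "polyploid_cycling")

# Three equiprobable countable colours, no GFP.
equal_ryc <- c(RFP = 1 / 3, YFP = 1 / 3, CFP = 1 / 3, GFP = 0)

# Classification accuracy over ground-truth induced singlets that the
# width gate did not abstain on.
gating_accuracy <- function(events, calls) {
  keep <- events$induced & !events$is_doublet &
    calls$class != "doublet_excluded"
  mean(as.character(calls$class[keep]) ==
         truth_to_gate[events$true_class[keep]])
}

# Truth fractions among induced singlets, on the gated category scale.
truth_fractions <- function(events) {
  tr <- truth_to_gate[events$true_class[events$induced & !events$is_doublet]]
  tab <- prop.table(table(factor(tr, levels = unique(truth_to_gate))))
  out <- as.numeric(tab)
  names(out) <- names(tab)
  out
}
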