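# Construct a scenario_result by hand from a day x replicate larval matrix
# (other stages zero), for analysis-layer tests that need controlled input.
fake_scenario <- function(larvae, label = "fake", release_day = 10L) {
  larvae <- as.matrix(larvae)
  nd <- nrow(larvae)
  nr <- ncol(larvae)
  counts <- array(0, dim = c(nd, 6L, nr),
                  dimnames = list(NULL,
                                  c("pest_egg", "pest_larva", "pest_pupa",
                                    "pest_adult", "para_immature",
                                    "para_adult"), NULL))
  for (i in seq_len(nr)) counts[, "pest_larva", i] <- larvae[, i]
  structure(list(label = label, config = NULL, counts = counts,
                 seeds = seq_len(nr),
                 trigger_days = rep(release_day, nr),
                 release_days = rep(list(release_day), nr),
                 boundary_contacts = rep(0, nr)),
            class = "scenario_result")
}
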