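# Stage 2: preprocess the portable-calorimetry stream into the criterion.
#
# Breath-by-breath VO2/VCO2 are binned to 10 s, smoothed with a centred 60 s
# moving average, converted to kcal/min with the Weir equation and
# MET-normalized by each child's Schofield resting EE. Writes the per-subject
# criterion series and reports total session energy expenditure.

source("analysis/00_config.R")

cohort <- study_cohort()
sessions <- study_sessions(cohort)

criterion <- do.call(rbind, lapply(sessions, function(s) {
  ee <- ee_criterion(s$breaths, ree = s$ree,
                     span = nrow(s$hip) / generator_config()$fs)
  data.frame(participant_id = s$participant$id, ee)
}))
data.table::fwrite(criterion, file.path(results_dir, "ee_criterion.csv"))

totals <- tapply(criterion$ee_kcal_min, criterion$participant_id,
                 session_total)
mets <- tapply(criterion$met, criterion$participant_id, mean)
message(sprintf("measured session EE: %.1f +/- %.1f kcal (n = %d)",
                mean(totals), sd(totals), length(totals)))
message(sprintf("mean session intensity: %.2f METs", mean(mets)))
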