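# Shared configuration for the numbered analysis scripts. Each script is a
# thin driver over the playEE package: run them in order from the repository
# root (Rscript analysis/01_simulate.R, ...). All randomness derives from the
# master seed below, so every script is reproducible in isolation.

library(playEE)

master_seed <- 20190601
n_train <- 15
n_holdout <- 10
session_length_s <- 1200 # the 20-minute free-play session
sites <- c("hip", "wrist")
k_list <- c(10, 15, 20)
k_best <- 15

results_dir <- "results"
dir.create(results_dir, recursive = TRUE, showWarnings = FALSE)

# cohort and group assignment shared by every stage
study_cohort <- function() {
  cohort <- make_cohort(n_train + n_holdout, seed = derive_seed(master_seed, 1))
  cohort$group <- c(rep("train", n_train), rep("holdout", n_holdout))
  cohort
}

study_sessions <- function(cohort) {
  synthesize_cohort(cohort, seed = derive_seed(master_seed, 2),
                    session_length = session_length_s)
}
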